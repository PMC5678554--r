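# Independent brute-force oracles, deliberately naive and separate from
# the package's implementations.

# Exhaustive Otsu: for every candidate threshold compute between-class
# variance from first principles (strict > t foreground); smallest tie.
oracle_otsu <- function(values) {
  v <- as.vector(values)
  best_t <- NA_integer_; best_var <- -Inf
  for (t in 0:255) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (length(bg) == 0L || length(fg) == 0L) next
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (s > best_var + 1e-12) { best_var <- s; best_t <- t }
  }
  best_t
}

# Minkowski set definitions, per-pixel loops, out-of-bounds = background
oracle_erode <- function(mask, r = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}

oracle_dilate <- function(mask, r = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj]) hit <- TRUE
    }
    out[i, j] <- hit
  }
  out
}

oracle_clean <- function(mask, r = 1L) {
  e <- oracle_erode(mask, r)
  o <- oracle_dilate(oracle_erode(e, r), r)
  oracle_erode(oracle_dilate(o, r), r)
}

# Area of a disk of radius r centred on a square of half-width h, by
# midpoint-grid quadrature over the square.
oracle_disk_square <- function(r, h = 15, n = 2000) {
  g <- (seq_len(n) - 0.5) / n * 2 * h - h
  inside <- outer(g^2, g^2, `+`) <= r^2
  mean(inside) * (2 * h)^2
}

# Explicit-Euler growth series at 1 degree-day steps, independent of the
# package's integrator.
oracle_euler_series <- function(alpha, beta, tt_max, a0 = 10) {
  tt <- 0:tt_max
  a <- numeric(length(tt)); a[1] <- a0
  for (i in seq_len(length(tt) - 1L))
    a[i + 1] <- a[i] + a[i] * exp(alpha + beta * a[i])
  data.frame(tt = tt, area_cm2 = a)
}

# Brute-force rosette rasterization: per-pixel loop over lobes, same
# geometric definition written independently.
oracle_rosette_count <- function(size, cx, cy, r, n_lobes, ecc, phase) {
  count <- 0L
  a <- 0.55 * r; b <- a * sqrt(1 - ecc^2); d <- 0.45 * r
  for (i in seq_len(size)) for (j in seq_len(size)) {
    x <- j - cx; y <- i - cy
    inside <- x^2 + y^2 <= (0.65 * r)^2
    if (!inside) for (l in seq_len(n_lobes)) {
      phi <- phase + 2 * pi * (l - 1) / n_lobes
      lx <- x - d * cos(phi); ly <- y - d * sin(phi)
      u <- lx * cos(phi) + ly * sin(phi)
      v <- -lx * sin(phi) + ly * cos(phi)
      if ((u / a)^2 + (v / b)^2 <= 1) { inside <- TRUE; break }
    }
    if (inside) count <- count + 1L
  }
  count
}

# Small helper: random logical mask
random_mask <- function(nr, nc, p = 0.4) matrix(runif(nr * nc) < p, nr, nc)
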