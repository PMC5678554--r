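# Synthetic fixtures: ground-truthed rosette scenes, growth trajectories
# and radiation series with the statistical structure the method assumes.
# Material intensities are invented to reproduce the qualitative spectral
# contrasts of blue-filtered NIR imaging (vegetation bright only in the
# NIR-dominated RED channel; bright mineral backgrounds bright in BLUE),
# not measurements of any real substrate.

.material_defaults <- list(
  green_leaf = list(red = c(200, 20), green = c(120, 20), blue = c(45, 15)),
  red_leaf   = list(red = c(200, 20), green = c(60, 15),  blue = c(45, 15)),
  dark_soil  = list(red = c(45, 12),  green = c(50, 12),  blue = c(45, 12)),
  clear_sand = list(red = c(140, 15), green = c(160, 15), blue = c(170, 15)),
  plastic    = list(red = c(55, 10),  green = c(55, 10),  blue = c(60, 10)))

#' Specification of a synthetic rosette scene
#'
#' Describes one (image, ground-truth mask) pair: a lobed rosette plant
#' rendered over a textured background, with the spectral signature of
#' blue-filtered NIR imaging. The `red_leaf` spectral class changes only
#' the visible (GREEN) appearance; its NIR signature is identical to the
#' green-leaf class, since leaf pigmentation does not alter internal-
#' structure NIR reflectance.
#'
#' @param size image side in pixels (square frame).
#' @param background `"dark_soil"`, `"clear_sand"`, `"mixed"` (both
#'   substrates split by a sinuous boundary) or `"plastic"`.
#' @param spectral_class `"green_leaf"` or `"red_leaf"`.
#' @param radius_px nominal rosette radius (centre to lobe tip), pixels;
#'   0 renders a pure-background scene.
#' @param n_lobes number of leaf lobes.
#' @param lobe_ecc eccentricity of the elliptical lobes in `[0, 1)`.
#' @param noise_sd additive Gaussian capture noise, intensity units.
#' @param materials per-material channel `(mean, sd)` list; defaults give
#'   well-separated plant and background modes.
#' @param seed RNG seed making the scene a pure function of this spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(size = 384,
                       background = c("dark_soil", "clear_sand", "mixed",
                                      "plastic"),
                       spectral_class = c("green_leaf", "red_leaf"),
                       radius_px = 104, n_lobes = 8, lobe_ecc = 0.7,
                       noise_sd = 6, materials = .material_defaults,
                       seed = 1) {
  background <- match.arg(background)
  spectral_class <- match.arg(spectral_class)
  if (radius_px < 0) stop_input("'radius_px' must be non-negative")
  if (radius_px > size / 2 - 2)
    stop_input("plant does not fit inside the frame")
  if (lobe_ecc < 0 || lobe_ecc >= 1) stop_input("'lobe_ecc' must be in [0, 1)")
  if (noise_sd < 0) stop_input("'noise_sd' must be non-negative")
  for (m in materials) for (ch in m)
    if (ch[1] < 0 || ch[1] > 255) stop_input("material means must be in [0, 255]")
  structure(list(size = as.integer(size), background = background,
                 spectral_class = spectral_class, radius_px = radius_px,
                 n_lobes = as.integer(n_lobes), lobe_ecc = lobe_ecc,
                 noise_sd = noise_sd, materials = materials,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# TRUE where (row, col) grid points fall inside the rosette: a central
# disk (radius 0.65 r) plus n radial elliptical lobes whose tips reach
# radius_px, giving the moderately scalloped silhouette of a lettuce
# rosette whose leaves overlap heavily.
rasterize_rosette <- function(size, cx, cy, radius_px, n_lobes, lobe_ecc,
                              phase = 0) {
  mask <- matrix(FALSE, size, size)
  if (radius_px <= 0) return(mask)
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  x <- col - cx; y <- row - cy
  core_r <- 0.65 * radius_px
  mask <- x^2 + y^2 <= core_r^2
  a <- 0.55 * radius_px
  b <- a * sqrt(1 - lobe_ecc^2)
  d <- 0.45 * radius_px
  for (i in seq_len(n_lobes)) {
    phi <- phase + 2 * pi * (i - 1) / n_lobes
    lx <- x - d * cos(phi); ly <- y - d * sin(phi)
    u <- lx * cos(phi) + ly * sin(phi)
    v <- -lx * sin(phi) + ly * cos(phi)
    mask <- mask | (u / a)^2 + (v / b)^2 <= 1
  }
  mask
}

# Smooth unit-variance Gaussian random field: iid noise on a coarse grid,
# bilinearly interpolated to full resolution. Models the spatially
# correlated brightness variation of real leaf surfaces and substrates
# (as opposed to per-pixel salt-and-pepper, which photographs do not
# show at material scale).
smooth_field <- function(n, cell = 16) {
  m <- ceiling(n / cell) + 1L
  coarse <- matrix(stats::rnorm(m * m), m, m)
  pos <- (seq_len(n) - 1) / cell + 1
  i0 <- pmin(floor(pos), m - 1L); fi <- pos - i0
  rows <- coarse[i0, , drop = FALSE] * (1 - fi) +
    coarse[i0 + 1L, , drop = FALSE] * fi
  rows[, i0, drop = FALSE] * rep(1 - fi, each = n) +
    rows[, i0 + 1L, drop = FALSE] * rep(fi, each = n)
}

#' Generate a synthetic scene with its ground-truth mask
#'
#' Renders the rosette of `spec` over the chosen background. Each
#' channel is the material mean modulated by a spatially correlated
#' texture field (scaled by the material sd) plus iid capture noise,
#' clipped to 0--255. The returned mask is the exact rasterized plant
#' support, so segmentation error can be measured without any manual
#' reference. Bit-reproducible given the spec (which includes the seed).
#'
#' @param spec a [scene_spec].
#' @return list with `image` (a [bf_image]), `mask` (logical matrix) and
#'   `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(radius_px = 80, seed = 7))
#' sum(sc$mask)  # true plant pixels
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    n <- spec$size
    phase <- stats::runif(1, 0, 2 * pi)
    mask <- rasterize_rosette(n, (n + 1) / 2, (n + 1) / 2, spec$radius_px,
                              spec$n_lobes, spec$lobe_ecc, phase)
    bg1 <- switch(spec$background, mixed = "dark_soil", spec$background)
    bg_is_2 <- matrix(FALSE, n, n)
    if (spec$background == "mixed") {
      # sinuous vertical boundary between the two substrates
      boundary <- n / 2 + n / 8 * sin(seq_len(n) / n * 4 * pi) +
        stats::rnorm(n, 0, 2)
      col_idx <- matrix(seq_len(n), n, n, byrow = TRUE)
      bg_is_2 <- col_idx > matrix(boundary, n, n)
    }
    mat_id <- matrix(bg1, n, n)
    mat_id[bg_is_2] <- "clear_sand"
    mat_id[mask] <- spec$spectral_class
    # material sd drives a spatially correlated texture field (leaf
    # sheen, substrate patchiness); capture noise is iid per pixel
    channel <- function(ch) {
      mu <- vapply(spec$materials, function(m) m[[ch]][1], 0)[mat_id]
      sd <- vapply(spec$materials, function(m) m[[ch]][2], 0)[mat_id]
      v <- mu + sd * as.vector(smooth_field(n)) +
        stats::rnorm(n * n, 0, spec$noise_sd)
      matrix(as.integer(pmin(255, pmax(0, round_half_up(v)))), n, n)
    }
    img <- bf_image(red = channel("red"), green = channel("green"),
                    blue = channel("blue"),
                    id = sprintf("%s_%s_r%d_seed%d", spec$background,
                                 spec$spectral_class, round(spec$radius_px),
                                 spec$seed))
    list(image = img, mask = mask, spec = spec)
  })
}

#' Default synthetic scene suite
#'
#' The fixed evaluation grid: three backgrounds (dark soil, clear sand,
#' mixed) crossed with two plant spectral classes (green and red leaved)
#' and three plant sizes. Sizes correspond to market-stage lettuces of
#' roughly 10, 13 and 16 cm nominal radius imaged at 8 px/cm
#' (radii 80, 104 and 128 px in a 384 px frame). Per-scene seeds are
#' drawn deterministically from `seed`.
#'
#' @param seed master seed for the suite.
#' @param radii plant radii in pixels.
#' @return list of [scene_spec]s (length
#'   `3 * 2 * length(radii)`).
#' @export
default_scene_suite <- function(seed = 1, radii = c(80, 104, 128)) {
  grid <- expand.grid(background = c("dark_soil", "clear_sand", "mixed"),
                      class = c("green_leaf", "red_leaf"),
                      radius = radii, stringsAsFactors = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, nrow(grid)))
  lapply(seq_len(nrow(grid)), function(i)
    scene_spec(background = grid$background[i],
               spectral_class = grid$class[i],
               radius_px = grid$radius[i],
               seed = seeds[i]))
}

#' Specification of a synthetic growth trajectory
#'
#' @param alpha,beta parameters of the expansion-rate model
#'   `RER = exp(alpha + beta * area)`.
#' @param obs_tt thermal times of the simulated imaging dates
#'   (degree-days, strictly increasing).
#' @param noise_sd standard deviation of multiplicative log-normal area
#'   noise (0 = noiseless).
#' @param initial_area_cm2 leaf area at planting, cm^2.
#' @param seed RNG seed.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(alpha = -4.55, beta = -2.127e-3,
                            obs_tt = seq(20, 340, by = 40),
                            noise_sd = 0, initial_area_cm2 = 10, seed = 1) {
  if (any(diff(obs_tt) <= 0))
    stop_input("'obs_tt' must be strictly increasing")
  if (noise_sd < 0) stop_input("'noise_sd' must be non-negative")
  structure(list(alpha = alpha, beta = beta, obs_tt = as.numeric(obs_tt),
                 noise_sd = noise_sd,
                 initial_area_cm2 = initial_area_cm2,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Simulate a plant growth trajectory from the expansion-rate model
#'
#' Integrates `dA/dTT = A * exp(alpha + beta * A)` from the initial area
#' at planting, samples the solution at the requested thermal times, and
#' applies multiplicative log-normal observation noise. With `beta = 0`
#' the solution is the exact exponential
#' `A(TT) = A0 * exp(exp(alpha) * TT)`.
#'
#' @param spec a [trajectory_spec].
#' @param plant_id,treatment labels attached to the returned series.
#' @return a [growth_series].
#' @export
generate_trajectory <- function(spec, plant_id = "sim", treatment = "Control") {
  stopifnot(inherits(spec, "trajectory_spec"))
  times <- sort(unique(c(0, spec$obs_tt)))
  sol <- deSolve::ode(
    y = c(A = spec$initial_area_cm2), times = times,
    func = function(t, y, p) list(y[1] * exp(p$alpha + p$beta * y[1])),
    parms = list(alpha = spec$alpha, beta = spec$beta),
    method = "ode45", atol = 1e-10, rtol = 1e-10)
  area <- stats::approx(sol[, "time"], sol[, "A"], xout = spec$obs_tt)$y
  if (spec$noise_sd > 0)
    area <- with_seed(spec$seed,
                      area * exp(stats::rnorm(length(area), 0, spec$noise_sd)))
  growth_series(plant_id, treatment, tt = spec$obs_tt, area_cm2 = area)
}

#' Specification of a diurnal radiation pattern with shade windows
#'
#' Emulates incident radiation at plant level in an agrivoltaic layout:
#' a clear-sky half-sine diurnal course, with daily windows during which
#' panel strips transmit only a fraction of the light (shade bands
#' sweeping the ground as the sun moves).
#'
#' @param daily_total_mol clear-sky (unshaded) daily total, mol per m^2
#'   per day.
#' @param day_length_h daylight duration, hours.
#' @param windows list of shade windows, each
#'   `list(start, end, transmitted)` with `start`/`end` fractions of the
#'   daylight span in `[0, 1]` and `transmitted` in `[0, 1]`.
#' @param jitter_sd day-to-day log-normal jitter of the daily total
#'   (0 = identical days).
#' @param seed RNG seed for the jitter.
#' @return an object of class `shade_pattern`.
#' @export
shade_pattern <- function(daily_total_mol = 44, day_length_h = 14,
                          windows = list(), jitter_sd = 0, seed = 1) {
  for (w in windows) {
    if (w$transmitted < 0 || w$transmitted > 1)
      stop_input("transmitted fraction must be in [0, 1]")
    if (w$start < 0 || w$end > 1 || w$start >= w$end)
      stop_input("shade window must satisfy 0 <= start < end <= 1")
  }
  structure(list(daily_total_mol = daily_total_mol,
                 day_length_h = day_length_h, windows = windows,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "shade_pattern")
}

#' Generate an incident radiation series
#'
#' Produces per-step incident radiation at plant level (mol per m^2 per
#' step) on a regular sub-hourly grid, midday-centred half-sine each day,
#' scaled so the unshaded daily total matches the pattern; shade windows
#' multiply their span by the transmitted fraction.
#'
#' @param pattern a [shade_pattern].
#' @param days number of days to generate.
#' @param step_min time step in minutes.
#' @param start_date first day (anything `as.Date` accepts).
#' @return data frame with columns `time` (POSIXct, UTC, step midpoints)
#'   and `mol_m2` (radiation in that step).
#' @export
generate_radiation <- function(pattern, days, step_min = 3,
                               start_date = "2015-07-21") {
  stopifnot(inherits(pattern, "shade_pattern"), days >= 1)
  day0 <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")
  L <- pattern$day_length_h * 3600
  sunrise <- (12 - pattern$day_length_h / 2) * 3600
  step <- step_min * 60
  # half-sine: I(t) = peak * sin(pi * u), u in [0,1]; integral = 2/pi * peak * L
  peak <- pattern$daily_total_mol * pi / (2 * L)   # mol m^-2 s^-1
  jit <- if (pattern$jitter_sd > 0)
    with_seed(pattern$seed,
              exp(stats::rnorm(days, 0, pattern$jitter_sd)))
  else rep(1, days)
  out <- vector("list", days)
  for (d in seq_len(days)) {
    mid <- seq(sunrise + step / 2, sunrise + L - step / 2, by = step)
    u <- (mid - sunrise) / L
    val <- peak * sin(pi * u) * step * jit[d]
    for (w in pattern$windows) {
      inw <- u >= w$start & u < w$end
      val[inw] <- val[inw] * w$transmitted
    }
    out[[d]] <- data.frame(
      time = day0 + (d - 1) * 86400 + mid,
      mol_m2 = val)
  }
  do.call(rbind, out)
}
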