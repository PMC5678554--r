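#' Spectral channel subtraction (NEW CHANNEL)
#'
#' Builds the vegetation-contrast raster at the core of the segmentation:
#' per pixel, `max(0, RED - k * BLUE)`. Leaves reflect near-infrared
#' (carried by RED here) and absorb blue, so the subtraction suppresses
#' backgrounds that are bright in both channels while leaving vegetation
#' bright. Negative values correspond to non-vegetative pixels with high
#' BLUE intensity and are clipped to zero. The clipped raster is then
#' linearly min--max rescaled to 0--255 with half-up rounding; a constant
#' raster rescales to all zeros.
#'
#' Subtraction is done in real arithmetic before clipping and rounding,
#' not as saturating 8-bit arithmetic, to avoid double truncation.
#'
#' @param img a [bf_image].
#' @param k subtraction weight in `[0, 1]`; 0.5 by default. Values near 1
#'   darken the whole raster, values near 0 let NIR-bright backgrounds
#'   leak through; results are stable for k in roughly 0.4--0.6.
#' @return an object of class `new_channel`: list with `values` (rescaled
#'   integer matrix, 0--255), `raw` (clipped pre-rescale matrix), `k`,
#'   and `rescaled = TRUE`.
#' @examples
#' img <- bf_image(red = matrix(c(200L, 40L), 1), green = matrix(0L, 1, 2),
#'                 blue = matrix(100L, 1, 2))
#' compute_new_channel(img)$raw   # 150, 0
#' @export
compute_new_channel <- function(img, k = 0.5) {
  stopifnot(inherits(img, "bf_image"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > 1)
    stop_input("'k' must be a single number in [0, 1]")
  raw <- img$red - k * img$blue
  raw[raw < 0] <- 0          # clip: high-BLUE non-vegetative pixels
  rng <- range(raw)
  vals <- if (rng[2] > rng[1]) {
    round_half_up((raw - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    matrix(0, nrow(raw), ncol(raw))   # degenerate: constant raster
  }
  structure(
    list(values = matrix(as.integer(vals), nrow(raw), ncol(raw)),
         raw = raw, k = k, rescaled = TRUE),
    class = "new_channel")
}

#' Otsu threshold of an 8-bit raster
#'
#' Exhaustive search over the 256-bin histogram for the integer threshold
#' maximizing between-class variance; foreground is defined as values
#' strictly greater than the threshold. Ties are broken towards the
#' smallest threshold (favouring a larger plant mask). A constant image
#' has no valid split; its value is returned with a `degenerate`
#' attribute and yields an empty foreground.
#'
#' @param nc a `new_channel` object, or an integer matrix with values in
#'   0--255.
#' @return integer threshold in `[0, 255]`, with attribute `degenerate`
#'   (TRUE for constant input).
#' @export
otsu_threshold <- function(nc) {
  v <- if (inherits(nc, "new_channel")) nc$values else nc
  stopifnot(is.matrix(v), length(v) > 0)
  v <- as.vector(v)
  if (min(v) == max(v))
    return(structure(as.integer(v[1]), degenerate = TRUE))
  h <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  csum  <- cumsum(h)                    # pixels <= t for t = 0..255
  cmean <- cumsum(h * (0:255))
  mu <- cmean[256] / n
  w0 <- csum / n
  mu0 <- ifelse(csum > 0, cmean / csum, 0)
  mu1 <- ifelse(csum < n, (cmean[256] - cmean) / (n - csum), 0)
  sigma_b <- w0 * (1 - w0) * (mu0 - mu1)^2
  sigma_b[csum == 0 | csum == n] <- -Inf  # only splits with two classes
  t <- which.max(sigma_b) - 1L            # which.max takes the first tie
  structure(as.integer(t), degenerate = FALSE)
}

#' Apply a threshold to a raster
#'
#' @param nc a `new_channel` object or integer matrix.
#' @param t threshold in `[0, 255]`; pixels with value `> t` become
#'   foreground.
#' @return logical matrix (TRUE = plant candidate).
#' @export
segment_mask <- function(nc, t) {
  v <- if (inherits(nc, "new_channel")) nc$values else nc
  stopifnot(is.matrix(v), t >= 0, t <= 255)
  v > t
}

#' Morphological cleanup of a segmentation mask
#'
#' Erosion, then opening, then closing, in that order: erosion and
#' opening remove speckle noise, closing fills small holes inside
#' objects. The structuring element is a square of side
#' `2 * structuring_radius + 1`; each stage is repeated `iterations`
#' times. Border pixels are treated as background for erosion.
#'
#' @param mask logical matrix.
#' @param structuring_radius structuring element radius in pixels.
#' @param iterations repetitions of each stage.
#' @return logical matrix of the same dimensions.
#' @export
clean_mask <- function(mask, structuring_radius = 1L, iterations = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask),
            structuring_radius >= 0, iterations >= 0)
  out <- mask
  for (i in seq_len(iterations)) out <- binary_erode(out, structuring_radius)
  for (i in seq_len(iterations)) out <- binary_open(out, structuring_radius)
  for (i in seq_len(iterations)) out <- binary_close(out, structuring_radius)
  out
}

#' Connected components and contours of a binary mask
#'
#' Components are extracted under 8-connectivity, so thin tortuous leaf
#' lobes touching only at corners remain one object. Objects are labelled
#' in scan order (top-to-bottom, then left-to-right) of their first pixel.
#'
#' @param mask logical matrix.
#' @return an object of class `segmented_objects`: list with `n_objects`,
#'   `sizes` (pixel counts per label), `labels` (integer matrix, 0 =
#'   background), and `contours` (list of two-column row/col matrices
#'   tracing each object's outer boundary).
#' @export
extract_objects <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc_ <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc_)
  if (length(fg) == 0L)
    return(structure(list(n_objects = 0L, sizes = integer(0),
                          labels = labels, contours = list()),
                     class = "segmented_objects"))
  id_of <- integer(nr * nc_)
  id_of[fg] <- seq_along(fg)
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    both <- mask & shift_mask(mask, off[1], off[2])
    from <- which(both)
    if (length(from)) {
      to <- from + off[1] + off[2] * nr
      edges[[length(edges) + 1L]] <- cbind(id_of[from], id_of[to])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  # relabel so object 1 holds the scan-order-first pixel
  row_i <- (fg - 1L) %% nr + 1L
  col_j <- (fg - 1L) %/% nr + 1L
  scan_key <- (row_i - 1L) * nc_ + col_j
  first_key <- tapply(scan_key, memb, min)
  relab <- integer(length(first_key))
  relab[order(first_key)] <- seq_along(first_key)
  lab <- relab[memb]
  labels[fg] <- lab
  sizes <- tabulate(lab)
  contours <- lapply(seq_along(sizes), function(l) {
    inside <- labels == l
    pix <- which(inside)
    ri <- (pix - 1L) %% nr + 1L
    cj <- (pix - 1L) %/% nr + 1L
    start <- pix[order((ri - 1L) * nc_ + cj)][1]
    trace_contour(inside, c((start - 1L) %% nr + 1L, (start - 1L) %/% nr + 1L))
  })
  structure(list(n_objects = length(sizes), sizes = sizes,
                 labels = labels, contours = contours),
            class = "segmented_objects")
}

#' @export
print.segmented_objects <- function(x, ...) {
  cat(sprintf("<segmented_objects> %d object(s); sizes: %s px\n",
              x$n_objects, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

# Moore-neighbour boundary tracing from the scan-order-first pixel of one
# component (8-connectivity); returns a (row, col) matrix. The search
# walks the 8 neighbours clockwise starting just past the backtrack
# (background) pixel; tracing stops when the start pixel is re-entered
# from the same direction as the first move (Jacob's criterion).
trace_contour <- function(inside, start) {
  # clockwise neighbour offsets starting west (rows grow downwards)
  offs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  dir_of <- function(delta) which(offs[, 1] == delta[1] & offs[, 2] == delta[2])
  nr <- nrow(inside); nc_ <- ncol(inside)
  at <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc_ &&
    inside[p[1], p[2]]
  pts <- list(start)
  cur <- start
  back_dir <- 1L  # backtrack pixel is west of start (background in scan order)
  first_state <- NULL
  for (iter in seq_len(8L * (sum(inside) + 2L))) {
    found <- FALSE
    for (s in 1:8) {
      d <- ((back_dir - 1L + s) %% 8L) + 1L
      cand <- cur + offs[d, ]
      if (at(cand)) {
        state <- c(cand, d)
        if (is.null(first_state)) {
          first_state <- state
        } else if (identical(state, first_state)) {
          return(do.call(rbind, pts))
        }
        pts[[length(pts) + 1L]] <- cand
        # the neighbour examined just before cand is background; the next
        # search starts from it, seen from cand
        prev_d <- ((back_dir - 1L + s - 1L) %% 8L) + 1L
        bpix <- cur + offs[prev_d, ]
        back_dir <- dir_of(bpix - cand)
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) return(matrix(start, 1, 2))  # isolated pixel
  }
  do.call(rbind, pts)
}

#' Area calibration
#'
#' Conversion from pixel counts to square centimetres, measured with a
#' physical calibration standard placed in the camera's field of view.
#'
#' @param cm2_per_pixel strictly positive conversion factor (cm^2 per
#'   pixel).
#' @return an object of class `calibration`.
#' @export
calibration <- function(cm2_per_pixel) {
  if (!is.numeric(cm2_per_pixel) || length(cm2_per_pixel) != 1L ||
      is.na(cm2_per_pixel) || cm2_per_pixel <= 0)
    stop_input("'cm2_per_pixel' must be a single positive number")
  structure(list(cm2_per_pixel = cm2_per_pixel), class = "calibration")
}

#' Projected plant area from segmented objects
#'
#' Two conventions are supported. `largest_object` assigns the plant the
#' biggest object in the scene, disregarding small spurious objects such
#' as weeds (ties broken by label order, i.e. the first object in scan
#' order). `sum_white` counts every foreground pixel, appropriate for
#' clean scenes or plants whose mask splits into disconnected parts.
#'
#' @param objs a `segmented_objects` result.
#' @param mask the cleaned logical mask the objects were extracted from.
#' @param mode `"largest_object"` or `"sum_white"`.
#' @param calib a [calibration] or a bare `cm2_per_pixel` number.
#' @return an object of class `area_measurement`: list with `area_px`,
#'   `area_cm2`, `mode`, and `empty` (TRUE when no object was found; the
#'   area is then 0 and a warning is raised rather than an error so field
#'   batches never abort on a blank frame).
#' @export
plant_area <- function(objs, mask,
                       mode = c("largest_object", "sum_white"),
                       calib) {
  mode <- match.arg(mode)
  stopifnot(inherits(objs, "segmented_objects"),
            is.logical(mask), is.matrix(mask))
  if (is.numeric(calib)) calib <- calibration(calib)
  stopifnot(inherits(calib, "calibration"))
  empty <- FALSE
  if (mode == "largest_object") {
    if (objs$n_objects == 0L) {
      warning("no object found; returning area 0", call. = FALSE)
      empty <- TRUE
      area_px <- 0L
    } else {
      area_px <- as.integer(max(objs$sizes))  # first max = scan-order tie-break
    }
  } else {
    area_px <- as.integer(sum(mask))
    if (area_px == 0L) empty <- TRUE
  }
  structure(list(area_px = area_px,
                 area_cm2 = area_px * calib$cm2_per_pixel,
                 mode = mode, empty = empty),
            class = "area_measurement")
}

#' False two-colour rendering for visual quality control
#'
#' Presentational only: plant pixels in green, background in dark grey.
#'
#' @param nc a `new_channel` object or matrix (used for dimensions).
#' @param mask logical matrix, same dimensions.
#' @param plant,background RGB triplets in 0--255.
#' @return numeric H x W x 3 array in `[0, 1]`, ready for
#'   [png::writePNG()].
#' @export
false_color <- function(nc, mask,
                        plant = c(0, 200, 0), background = c(40, 40, 40)) {
  v <- if (inherits(nc, "new_channel")) nc$values else nc
  stopifnot(is.matrix(v), is.logical(mask), identical(dim(v), dim(mask)))
  arr <- array(0, dim = c(nrow(v), ncol(v), 3))
  for (ch in 1:3)
    arr[, , ch] <- ifelse(mask, plant[ch], background[ch]) / 255
  arr
}

#' Compare an estimated mask with a ground-truth mask
#'
#' The primary metric mirrors how leaf-area methods are benchmarked
#' against manually contoured references: relative area error
#' `100 * |est - truth| / truth` in percent. Because two masks of equal
#' area can be disjoint, pixelwise intersection-over-union is reported as
#' a secondary diagnostic.
#'
#' @param est,truth logical matrices of identical dimensions.
#' @return list with `error_pct`, `iou`, `est_px`, `truth_px`.
#'   `error_pct` is `NA` (with a warning) when the truth mask is empty;
#'   `iou` is 1 when both masks are empty.
#' @export
evaluate_segmentation <- function(est, truth) {
  stopifnot(is.logical(est), is.logical(truth),
            identical(dim(est), dim(truth)))
  est_px <- sum(est); truth_px <- sum(truth)
  if (truth_px == 0L) {
    warning("empty truth mask: relative area error undefined", call. = FALSE)
    err <- NA_real_
  } else {
    err <- 100 * abs(est_px - truth_px) / truth_px
  }
  inter <- sum(est & truth); uni <- sum(est | truth)
  iou <- if (uni == 0L) 1 else inter / uni
  list(error_pct = err, iou = iou,
       est_px = as.integer(est_px), truth_px = as.integer(truth_px))
}

#' Full leaf-area segmentation pipeline
#'
#' Deterministic composition of the whole procedure: NEW CHANNEL
#' computation, Otsu thresholding, binarization, morphological cleanup,
#' connected components, and area measurement. All intermediates are
#' returned for quality control.
#'
#' @inheritParams compute_new_channel
#' @inheritParams plant_area
#' @inheritParams clean_mask
#' @param calib a [calibration] or `cm2_per_pixel` number.
#' @return an object of class `pym_result`: list with `id`,
#'   `new_channel`, `threshold`, `raw_mask`, `mask` (cleaned),
#'   `objects`, `area` (an `area_measurement`), `degenerate` (TRUE when
#'   thresholding was degenerate or no object was found), and `params`.
#' @examples
#' sc <- generate_scene(scene_spec(seed = 1))
#' res <- run_pym(sc$image, calib = 0.01)
#' res$area$area_cm2
#' @export
run_pym <- function(img, k = 0.5, calib = calibration(1),
                    mode = c("largest_object", "sum_white"),
                    structuring_radius = 1L, iterations = 1L) {
  mode <- match.arg(mode)
  if (is.numeric(calib)) calib <- calibration(calib)
  nc <- compute_new_channel(img, k = k)
  t <- otsu_threshold(nc)
  raw_mask <- segment_mask(nc, t)
  mask <- clean_mask(raw_mask, structuring_radius, iterations)
  objs <- extract_objects(mask)
  area <- withCallingHandlers(
    plant_area(objs, mask, mode, calib),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(id = img$id, new_channel = nc, threshold = t,
         raw_mask = raw_mask, mask = mask, objects = objs, area = area,
         degenerate = isTRUE(attr(t, "degenerate")) || area$empty,
         params = list(k = k, cm2_per_pixel = calib$cm2_per_pixel,
                       mode = mode,
                       structuring_radius = as.integer(structuring_radius),
                       iterations = as.integer(iterations))),
    class = "pym_result")
}

#' @export
print.pym_result <- function(x, ...) {
  cat(sprintf(
    "<pym_result>%s threshold %d; %d object(s); area %d px = %.2f cm^2%s\n",
    if (nzchar(x$id)) paste0(" ", x$id, ":") else "",
    as.integer(x$threshold), x$objects$n_objects,
    x$area$area_px, x$area$area_cm2,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
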