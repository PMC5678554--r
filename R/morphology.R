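# Binary morphology on logical matrices with a square structuring element.
# Pixels outside the image are treated as background, so erosion eats the
# frame border; this convention is fixed so segmented areas are
# bit-reproducible.

# m[i + di, j + dj] with FALSE padding out of bounds
shift_mask <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  rj <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(ri) > 0 && length(rj) > 0)
    out[ri, rj] <- m[ri + di, rj + dj]
  out
}

morph_apply <- function(m, radius, combine) {
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  out <- NULL
  for (k in seq_len(nrow(offs))) {
    s <- shift_mask(m, offs$di[k], offs$dj[k])
    out <- if (is.null(out)) s else combine(out, s)
  }
  out
}

#' Binary erosion, dilation, opening and closing
#'
#' Square structuring element of side `2 * radius + 1`; pixels beyond the
#' image border count as background.
#'
#' @param mask logical matrix.
#' @param radius structuring element radius in pixels.
#' @return logical matrix of the same dimensions.
#' @export
binary_erode <- function(mask, radius = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask), radius >= 0)
  if (radius == 0L) return(mask)
  morph_apply(mask, as.integer(radius), `&`)
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, radius = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask), radius >= 0)
  if (radius == 0L) return(mask)
  morph_apply(mask, as.integer(radius), `|`)
}

#' @rdname binary_erode
#' @export
binary_open <- function(mask, radius = 1L)
  binary_dilate(binary_erode(mask, radius), radius)

#' @rdname binary_erode
#' @export
binary_close <- function(mask, radius = 1L)
  binary_erode(binary_dilate(mask, radius), radius)
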