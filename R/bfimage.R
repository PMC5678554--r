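#' Blue-filtered (VIS+NIR) image container
#'
#' Holds the three 8-bit channels of an image captured through a blue
#' filter with the camera's infrared-blocking filter removed. In such
#' images the RED channel is dominated by near-infrared reflectance (high
#' over leaves, whose internal cell structure reflects NIR strongly) and
#' the BLUE channel carries blue visible light (low over leaves, which
#' absorb blue; high over bright mineral backgrounds).
#'
#' @param red,green,blue integer matrices of identical dimensions with
#'   values in 0--255.
#' @param id free-text capture label.
#' @return an object of class `bf_image` with elements `red`, `green`,
#'   `blue` (integer matrices), `id`, `height`, `width`.
#' @examples
#' img <- bf_image(red = matrix(200L, 4, 4), green = matrix(80L, 4, 4),
#'                 blue = matrix(40L, 4, 4))
#' dim(img)
#' @export
bf_image <- function(red, green, blue, id = "") {
  for (nm in c("red", "green", "blue")) {
    ch <- get(nm)
    if (!is.matrix(ch)) stop_input(sprintf("'%s' must be a matrix", nm))
  }
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    stop_input("channel matrices must share dimensions")
  if (length(red) == 0L) stop_input("image is empty")
  chk <- function(ch) {
    v <- as.vector(ch)
    if (anyNA(v) || any(v < 0 | v > 255) || any(v != floor(v)))
      stop_input("channel intensities must be integers in [0, 255]")
    matrix(as.integer(v), nrow(ch), ncol(ch))
  }
  structure(
    list(red = chk(red), green = chk(green), blue = chk(blue),
         id = as.character(id),
         height = nrow(red), width = ncol(red)),
    class = "bf_image")
}

#' @export
dim.bf_image <- function(x) c(x$height, x$width)

#' @export
print.bf_image <- function(x, ...) {
  cat(sprintf("<bf_image> %dx%d px%s\n", x$height, x$width,
              if (nzchar(x$id)) paste0("  id: ", x$id) else ""))
  invisible(x)
}

#' Read a blue-filtered image from a PNG or TIFF file
#'
#' Reads a 3-channel 8-bit raster and maps its storage channels onto the
#' BLUE/GREEN/RED roles. Cameras deliver either RGB (most file formats) or
#' BGR storage order; declare which with `channel_order`.
#'
#' @param path file path; format is inferred from the extension
#'   (`.png`, `.tif`/`.tiff`).
#' @param channel_order `"rgb"` (default: storage channel 1 is RED) or
#'   `"bgr"` (storage channel 1 is BLUE).
#' @param id capture label; defaults to the file name.
#' @return a [bf_image].
#' @export
read_bf_image <- function(path, channel_order = c("rgb", "bgr"), id = basename(path)) {
  channel_order <- match.arg(channel_order)
  if (!file.exists(path)) stop_input("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop_input("unsupported image format: .", ext,
               " (PNG and TIFF are supported)"))
  if (length(dim(arr)) == 2L) stop_input("expected a 3-channel image: ", path)
  if (dim(arr)[3] < 3L) stop_input("expected >= 3 channels: ", path)
  to255 <- function(m) matrix(as.integer(round_half_up(m * 255)), nrow(m), ncol(m))
  ch <- lapply(1:3, function(i) to255(arr[, , i]))
  if (channel_order == "rgb")
    bf_image(red = ch[[1]], green = ch[[2]], blue = ch[[3]], id = id)
  else
    bf_image(red = ch[[3]], green = ch[[2]], blue = ch[[1]], id = id)
}

#' Write a binary mask as a single-channel PNG
#'
#' Background pixels are written as 0 and plant pixels as 255.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(matrix(ifelse(mask, 1, 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a blue-filtered image to a PNG file
#'
#' Channels are stored in RGB order.
#'
#' @param img a [bf_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bf_image <- function(img, path) {
  stopifnot(inherits(img, "bf_image"))
  arr <- array(0, dim = c(img$height, img$width, 3))
  arr[, , 1] <- img$red / 255
  arr[, , 2] <- img$green / 255
  arr[, , 3] <- img$blue / 255
  png::writePNG(arr, path)
  invisible(path)
}
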