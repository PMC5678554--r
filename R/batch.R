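#' Batch configuration
#'
#' Fixed parameters applied uniformly to every image of a run, so a whole
#' field campaign is processed with one stationary parameter set.
#'
#' @param input_dir directory of input images (PNG/TIFF).
#' @param output_dir directory for the results CSV and optional QC
#'   rasters; created if missing. `NULL` disables all file output.
#' @param k NEW CHANNEL subtraction weight.
#' @param cm2_per_pixel area calibration for the batch.
#' @param mode `"largest_object"` or `"sum_white"`.
#' @param structuring_radius,iterations cleanup parameters, see
#'   [clean_mask()].
#' @param channel_order storage channel order of the files, see
#'   [read_bf_image()].
#' @param pattern optional PCRE with named capture groups `plant` and
#'   `date` applied to file names, e.g.
#'   `"(?<plant>[A-Za-z0-9-]+)_(?<date>\\d{4}-\\d{2}-\\d{2})"`; enables
#'   [assemble_series()].
#' @param save_masks,save_false_color write per-image QC PNGs?
#' @return an object of class `batch_config`.
#' @export
batch_config <- function(input_dir, output_dir = NULL, k = 0.5,
                         cm2_per_pixel = 1,
                         mode = c("largest_object", "sum_white"),
                         structuring_radius = 1L, iterations = 1L,
                         channel_order = c("rgb", "bgr"),
                         pattern = NULL,
                         save_masks = FALSE, save_false_color = FALSE) {
  mode <- match.arg(mode)
  channel_order <- match.arg(channel_order)
  if (!dir.exists(input_dir)) stop_input("input directory not found: ", input_dir)
  structure(list(input_dir = input_dir, output_dir = output_dir, k = k,
                 cm2_per_pixel = cm2_per_pixel, mode = mode,
                 structuring_radius = as.integer(structuring_radius),
                 iterations = as.integer(iterations),
                 channel_order = channel_order, pattern = pattern,
                 save_masks = isTRUE(save_masks),
                 save_false_color = isTRUE(save_false_color)),
            class = "batch_config")
}

parse_plant_date <- function(files, pattern) {
  if (is.null(pattern))
    return(data.frame(plant_id = rep(NA_character_, length(files)),
                      date = rep(NA_character_, length(files))))
  m <- regexpr(pattern, files, perl = TRUE)
  grab <- function(i, name) {
    st <- attr(m, "capture.start")[i, name]
    ln <- attr(m, "capture.length")[i, name]
    if (is.na(st) || st <= 0) NA_character_
    else substr(files[i], st, st + ln - 1L)
  }
  if (is.null(attr(m, "capture.names")) ||
      !all(c("plant", "date") %in% attr(m, "capture.names")))
    stop_input("'pattern' must define named capture groups 'plant' and 'date'")
  data.frame(
    plant_id = vapply(seq_along(files), grab, "", name = "plant"),
    date = vapply(seq_along(files), grab, "", name = "date"))
}

#' Batch-process a directory of images
#'
#' Applies the full segmentation pipeline ([run_pym()]) with one fixed
#' parameter set to every readable image in the input directory and
#' returns one record per file. A file that fails to read or process is
#' flagged in its record (with the error message) and the batch
#' continues; an empty input directory is an error. Records are ordered
#' by file name, so results do not depend on file-system enumeration
#' order.
#'
#' @param config a [batch_config].
#' @return an object of class `batch_result`: list with `records` (data
#'   frame: `file`, `plant_id`, `date`, `area_px`, `area_cm2`,
#'   `threshold`, `n_objects`, `degenerate`, `ok`, `error`) and `params`
#'   (run metadata: parameters, package version, timestamp). If
#'   `output_dir` is set, the records are written to `leaf_areas.csv`
#'   there, plus optional mask / false-colour PNGs per image.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  files <- sort(list.files(config$input_dir,
                           pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) == 0L)
    stop_input("no readable images in ", config$input_dir)
  ids <- parse_plant_date(files, config$pattern)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- lapply(seq_along(files), function(i) {
    f <- files[i]
    rec <- data.frame(file = f, plant_id = ids$plant_id[i],
                      date = ids$date[i], area_px = NA_integer_,
                      area_cm2 = NA_real_, threshold = NA_integer_,
                      n_objects = NA_integer_, degenerate = NA,
                      ok = FALSE, error = NA_character_)
    res <- tryCatch({
      img <- read_bf_image(file.path(config$input_dir, f),
                           channel_order = config$channel_order)
      run_pym(img, k = config$k, calib = config$cm2_per_pixel,
              mode = config$mode,
              structuring_radius = config$structuring_radius,
              iterations = config$iterations)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
      return(rec)
    }
    rec$area_px <- res$area$area_px
    rec$area_cm2 <- res$area$area_cm2
    rec$threshold <- as.integer(res$threshold)
    rec$n_objects <- res$objects$n_objects
    rec$degenerate <- res$degenerate
    rec$ok <- TRUE
    if (!is.null(out_dir)) {
      stem <- tools::file_path_sans_ext(f)
      if (config$save_masks)
        write_mask_png(res$mask, file.path(out_dir, paste0(stem, "_mask.png")))
      if (config$save_false_color)
        png::writePNG(false_color(res$new_channel, res$mask),
                      file.path(out_dir, paste0(stem, "_falsecolor.png")))
    }
    rec
  })
  records <- do.call(rbind, rows)
  result <- structure(
    list(records = records,
         params = list(k = config$k, cm2_per_pixel = config$cm2_per_pixel,
                       mode = config$mode,
                       structuring_radius = config$structuring_radius,
                       iterations = config$iterations,
                       channel_order = config$channel_order,
                       version = as.character(utils::packageVersion("pymleaf")),
                       timestamp = format(Sys.time(), tz = "UTC"))),
    class = "batch_result")
  if (!is.null(out_dir))
    write_batch_csv(result, file.path(out_dir, "leaf_areas.csv"))
  result
}

#' Write / read batch records as a spreadsheet-ready CSV
#'
#' Comma-separated, header row, UTF-8, ISO-8601 dates, `.` decimal.
#' Doubles are written with 17 significant digits so a read round-trips
#' to bit-identical records.
#'
#' @param result a `batch_result`.
#' @param path CSV path.
#' @return `path` (write) or a records data frame (read).
#' @export
write_batch_csv <- function(result, path) {
  stopifnot(inherits(result, "batch_result"))
  rec <- result$records
  rec$area_cm2 <- sprintf("%.17g", rec$area_cm2)
  rec$area_cm2[rec$area_cm2 == "NA"] <- NA
  utils::write.csv(rec, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' @rdname write_batch_csv
#' @export
read_batch_csv <- function(path) {
  rec <- utils::read.csv(path, colClasses = c(
    file = "character", plant_id = "character", date = "character",
    area_px = "integer", area_cm2 = "character", threshold = "integer",
    n_objects = "integer", degenerate = "logical", ok = "logical",
    error = "character"), na.strings = "", fileEncoding = "UTF-8")
  rec$area_cm2 <- as.numeric(rec$area_cm2)  # 17 digits round-trip exactly
  rec
}

#' Assemble per-plant growth series from batch records
#'
#' Groups successful records by plant, orders them by date, joins the
#' cumulative thermal time of each imaging date, and returns one
#' [growth_series] per plant, ready for [rer()] and the radiation
#' budget. Requires the batch to have been run with a filename `pattern`
#' so plant and date are known.
#'
#' @param result a `batch_result` (or its records data frame).
#' @param tt_by_date data frame with columns `date` (matching the
#'   records' date strings) and `tt` (degree-days).
#' @param treatments optional named vector mapping `plant_id` to a
#'   treatment label.
#' @return named list of [growth_series], one per plant.
#' @export
assemble_series <- function(result, tt_by_date, treatments = NULL) {
  rec <- if (inherits(result, "batch_result")) result$records else result
  stopifnot(is.data.frame(rec),
            all(c("date", "tt") %in% names(tt_by_date)))
  rec <- rec[rec$ok & !is.na(rec$plant_id) & !is.na(rec$date), ]
  if (nrow(rec) == 0L) stop_input("no records with plant/date mapping")
  dup <- duplicated(rec[, c("plant_id", "date")])
  if (any(dup))
    stop_input("duplicate (plant, date) records: ",
               paste(rec$plant_id[dup], rec$date[dup], sep = "/",
                     collapse = ", "))
  miss <- setdiff(rec$date, tt_by_date$date)
  if (length(miss))
    stop_input("no thermal time for imaging date(s): ",
               paste(miss, collapse = ", "))
  rec$tt <- tt_by_date$tt[match(rec$date, tt_by_date$date)]
  plants <- sort(unique(rec$plant_id))
  out <- lapply(plants, function(p) {
    d <- rec[rec$plant_id == p, ]
    d <- d[order(d$date), ]
    growth_series(p,
                  treatment = if (!is.null(treatments))
                    treatments[[p]] else "Control",
                  tt = d$tt, area_cm2 = d$area_cm2,
                  time = as.Date(d$date))
  })
  names(out) <- plants
  out
}
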