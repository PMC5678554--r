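#' Cumulative thermal time
#'
#' Thermal time replaces calendar time so growth rates are comparable
#' across days and treatments with different temperatures. Each day
#' contributes the excess of its mean air temperature over a base
#' temperature below which the crop does not grow (3.5 degrees C for
#' lettuce); days colder than the base contribute zero rather than a
#' negative amount.
#'
#' @param temps data frame with columns `day` (strictly increasing
#'   indices) and `mean_temp_c`.
#' @param base base temperature in degrees C.
#' @return data frame with columns `day` and `tt` (cumulative thermal
#'   time in degree-days up to and including that day).
#' @examples
#' thermal_time(data.frame(day = 1:3, mean_temp_c = c(13.5, 3.5, 2.0)))
#' @export
thermal_time <- function(temps, base = 3.5) {
  stopifnot(is.data.frame(temps),
            all(c("day", "mean_temp_c") %in% names(temps)))
  if (nrow(temps) == 0L) stop_input("temperature series is empty")
  if (any(diff(temps$day) <= 0))
    stop_input("day indices must be strictly increasing")
  data.frame(day = temps$day,
             tt = cumsum(pmax(0, temps$mean_temp_c - base)))
}

#' Per-plant growth series
#'
#' @param plant_id plant identifier.
#' @param treatment treatment label (e.g. `"Control"`, `"Below_PVPs"`,
#'   `"Between_PVPs"`).
#' @param tt thermal times at the imaging dates (degree-days,
#'   non-decreasing).
#' @param area_cm2 projected leaf areas (cm^2, positive).
#' @param time optional imaging timestamps (`POSIXct` or `Date`), used
#'   for radiation-interval alignment.
#' @return an object of class `growth_series` (a data frame with columns
#'   `tt`, `area_cm2` and optionally `time`, plus `plant_id` and
#'   `treatment` attributes).
#' @export
growth_series <- function(plant_id, treatment = "Control", tt, area_cm2,
                          time = NULL) {
  stopifnot(length(tt) == length(area_cm2))
  if (any(area_cm2 <= 0)) stop_input("areas must be positive")
  if (any(diff(tt) < 0)) stop_input("thermal times must be non-decreasing")
  df <- data.frame(tt = as.numeric(tt), area_cm2 = as.numeric(area_cm2))
  if (!is.null(time)) {
    stopifnot(length(time) == length(tt))
    df$time <- time
  }
  structure(df, plant_id = as.character(plant_id),
            treatment = as.character(treatment),
            class = c("growth_series", "data.frame"))
}

#' Relative expansion rate between consecutive observations
#'
#' For each pair of consecutive imaging dates, the relative expansion
#' rate is the slope of log projected leaf area against thermal time:
#' `RER_i = (ln A_{i+1} - ln A_i) / (TT_{i+1} - TT_i)`, in reciprocal
#' degree-days. The interval is summarized by the arithmetic mean of its
#' two areas, the abscissa against which the exponential rate model is
#' fitted.
#'
#' @param series a [growth_series] (or data frame with `tt` and
#'   `area_cm2`).
#' @return data frame with one row per interval: `interval`, `rer`
#'   (1/degree-day), `mean_area_cm2`, `dtt`. Intervals with a zero
#'   thermal-time increment get `NA` rer and a warning.
#' @examples
#' s <- growth_series("p1", tt = c(0, 1), area_cm2 = c(10, 20))
#' rer(s)$rer  # ln(2)
#' @export
rer <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("tt", "area_cm2") %in% names(series)))
  n <- nrow(series)
  if (n < 2L) stop_input("need at least 2 observations to compute RER")
  dtt <- diff(series$tt)
  dlog <- diff(log(series$area_cm2))
  r <- dlog / dtt
  if (any(dtt == 0)) {
    warning("zero thermal-time increment: RER undefined for ",
            sum(dtt == 0), " interval(s)", call. = FALSE)
    r[dtt == 0] <- NA_real_
  }
  out <- data.frame(
    interval = seq_len(n - 1L),
    rer = r,
    mean_area_cm2 = (series$area_cm2[-n] + series$area_cm2[-1]) / 2,
    dtt = dtt)
  if (inherits(series, "growth_series")) {
    attr(out, "plant_id") <- attr(series, "plant_id")
    attr(out, "treatment") <- attr(series, "treatment")
  }
  out
}

#' Neighbour-overlap correction of projected leaf area
#'
#' Plants are laid out on a square grid (30 x 30 cm cells by default).
#' Late in the cycle a plant's foliage spills into its neighbours' cells
#' while theirs spills into its own, so the projected area read off an
#' image overestimates the plant's share of ground. The plant is modelled
#' as a disk of equivalent area concentric with its cell; area outside
#' the cell is cut away. With cell half-width h and disk radius
#' `r = sqrt(area / pi)`:
#' area unchanged for `r <= h`; the disk-square intersection
#' `8 * (h * r * sin(acos(h / r)) / 2) + 4 * (pi / 4 - acos(h / r)) * r^2`
#' for `h < r < h * sqrt(2)`; and the full cell `(2 h)^2` once the disk
#' circumscribes it (`r >= h * sqrt(2)`), where the printed intersection
#' formula no longer applies.
#'
#' The correction is continuous at both branch points and non-decreasing
#' in the input area.
#'
#' @param area projected leaf area(s) in cm^2, positive.
#' @param cell_half_width half the planting-cell side, cm.
#' @return corrected area(s) in cm^2, capped at the cell area.
#' @examples
#' overlap_correct(pi * 10^2)        # r = 10 <= 15: unchanged
#' overlap_correct(pi * (15 * sqrt(2))^2)  # full 900 cm^2 cell
#' @export
overlap_correct <- function(area, cell_half_width = 15) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop_input("'area' must be positive and finite")
  h <- cell_half_width
  r <- sqrt(area / pi)
  out <- area
  mid <- r > h & r < h * sqrt(2)
  if (any(mid)) {
    rm_ <- r[mid]
    theta <- acos(h / rm_)
    out[mid] <- 8 * (h * rm_ * sin(theta) / 2) + 4 * (pi / 4 - theta) * rm_^2
  }
  out[r >= h * sqrt(2)] <- (2 * h)^2
  out
}

#' Radiation intercepted by one plant over its growth cycle
#'
#' For each period between consecutive imaging dates, the mean of the two
#' bounding leaf areas (converted from cm^2 to m^2) is multiplied by the
#' incident radiation cumulated over that period at plant level, and the
#' products are summed. The series is anchored at planting with an
#' initial leaf area (10 cm^2 by default, the typical transplant size).
#' Radiation records are assigned to the half-open interval
#' `(time(i-1), time(i)]`.
#'
#' @param times imaging timestamps, one per observation, strictly
#'   increasing and after `planting_time`.
#' @param areas_cm2 projected leaf areas at `times` (cm^2), already
#'   overlap-corrected where relevant.
#' @param radiation data frame with columns `time` and `mol_m2` (incident
#'   radiation per record, mol per m^2), strictly increasing times.
#' @param planting_time timestamp of planting (interval 0 start).
#' @param initial_area_cm2 leaf area at planting, cm^2.
#' @return total intercepted radiation in mol per plant. An error is
#'   raised if any interval contains no radiation record (a coverage gap
#'   would silently zero that interval's contribution).
#' @export
intercepted_radiation <- function(times, areas_cm2, radiation,
                                  planting_time,
                                  initial_area_cm2 = 10) {
  stopifnot(length(times) == length(areas_cm2), length(times) >= 1L,
            is.data.frame(radiation),
            all(c("time", "mol_m2") %in% names(radiation)))
  tnum <- as.numeric(times)
  t0 <- as.numeric(planting_time)
  if (any(diff(tnum) <= 0)) stop_input("imaging times must be strictly increasing")
  if (tnum[1] <= t0) stop_input("first imaging time must be after planting")
  if (any(radiation$mol_m2 < 0)) stop_input("radiation must be non-negative")
  rt <- as.numeric(radiation$time)
  bounds <- c(t0, tnum)
  areas <- c(initial_area_cm2, areas_cm2)
  total <- 0
  for (i in seq_along(tnum)) {
    sel <- rt > bounds[i] & rt <= bounds[i + 1]
    if (!any(sel))
      stop_input(sprintf(
        "radiation coverage gap: no record in imaging interval %d", i))
    inc <- sum(radiation$mol_m2[sel])
    total <- total + (areas[i] + areas[i + 1]) / 2 / 1e4 * inc
  }
  total
}

#' Radiation interception efficiency
#'
#' Ratio of the radiation a plant intercepted over its cycle to the
#' radiation incident at plant level over the same period. Since the
#' numerator is mol per plant and the denominator mol per m^2, the
#' paper-literal ratio carries units of m^2 per plant (the plant's
#' time-averaged intercepting surface). `normalize = TRUE` divides by the
#' ground area allotted to one plant (0.09 m^2 for a 30 x 30 cm cell),
#' giving a dimensionless ground-cover-weighted efficiency.
#'
#' @param intercepted_mol intercepted radiation, mol per plant.
#' @param incident_mol_m2 cumulated incident radiation, mol per m^2,
#'   positive.
#' @param normalize divide by `ground_area_m2`?
#' @param ground_area_m2 ground cell area per plant, m^2.
#' @return RIE (m^2 per plant, or dimensionless if normalized).
#' @export
rie <- function(intercepted_mol, incident_mol_m2, normalize = FALSE,
                ground_area_m2 = 0.09) {
  if (incident_mol_m2 <= 0)
    stop_input("cumulated incident radiation must be positive")
  out <- intercepted_mol / incident_mol_m2
  if (normalize) out <- out / ground_area_m2
  out
}

#' Radiation use efficiency
#'
#' Dry biomass accumulated per unit of intercepted radiation, integrating
#' every physiological step from photon capture to harvested mass.
#'
#' @param dry_mass_g plant dry mass at harvest, g.
#' @param intercepted_mol intercepted radiation over the cycle, mol per
#'   plant, positive.
#' @return RUE in g per mol.
#' @export
rue <- function(dry_mass_g, intercepted_mol) {
  if (any(intercepted_mol <= 0))
    stop_input("intercepted radiation must be positive")
  dry_mass_g / intercepted_mol
}
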