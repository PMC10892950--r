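#' Default ECO zone score table
#'
#' Zone scores are dimensionless integers in 1--50, non-decreasing from zone
#' 1 to zone 8. The exact table used by the ECO method is configurable; this
#' monotone default spans the full permitted range.
#' @return Integer vector of length 8.
#' @export
default_score_table <- function() c(1L, 2L, 3L, 5L, 8L, 15L, 30L, 50L)

#' Default ECO discipline factors
#'
#' Running 1.0, swimming 0.75, cycling 0.5 — the factors weighing muscle
#' damage, energy cost and technique demands of each leg.
#' @return Named numeric vector (swim, bike, run).
#' @export
default_factors <- function() c(swim = 0.75, bike = 0.5, run = 1.0)

#' Build an 8-zone training-intensity model from a threshold report
#'
#' Zones are anchored at the two thresholds following the triphasic model:
#' zones 1--3 sit at or below the first threshold (phase 1, split at 60% and
#' 80% of the threshold intensity), zones 4--5 between the thresholds (phase
#' 2, equal halves) and zones 6--8 at or beyond the second threshold (phase
#' 3, split at the midpoint between the second threshold and the maximal
#' intensity). Heart-rate bounds are interpolated between the threshold HRs.
#'
#' @param report A [threshold_report()].
#' @param discipline `"swim"`, `"bike"` or `"run"`.
#' @param score_table 8 non-decreasing integer scores in 1--50.
#' @param subzone_scheme Fractions of the first-threshold intensity at which
#'   phase-1 sub-zones split (default `c(0.6, 0.8)`).
#' @return A `zone_model`: a list with `discipline`, `unit` and a tibble
#'   `zones` (zone, lower, upper, hr_lower, hr_upper, eco_score, phase,
#'   rpe_band).
#' @export
build_zone_model <- function(report, discipline = c("bike", "run", "swim"),
                             score_table = default_score_table(),
                             subzone_scheme = c(0.6, 0.8)) {
  discipline <- match.arg(discipline)
  stopifnot(inherits(report, "threshold_report"))
  if (length(score_table) != 8 || any(diff(score_table) < 0) ||
      any(score_table < 1 | score_table > 50)) {
    stop("score_table must be 8 non-decreasing values in [1, 50]")
  }
  leg <- report[[discipline]]
  if (is.null(leg)) stop("report carries no thresholds for ", discipline)

  if (discipline == "swim") {
    if (!isTRUE(leg$lt1$detected) || !isTRUE(leg$lt2$detected)) {
      stop("swim thresholds not detected; cannot anchor zones")
    }
    th1 <- leg$lt1$speed; th2 <- leg$lt2$speed; peak <- leg$s_l200
    hr1 <- leg$lt1$hr; hr2 <- leg$lt2$hr
    unit <- "m/s"
  } else {
    if (!isTRUE(leg$vt1$detected) || !isTRUE(leg$vt2$detected)) {
      stop("ventilatory thresholds not detected; cannot anchor zones")
    }
    th1 <- leg$vt1$intensity; th2 <- leg$vt2$intensity
    hr1 <- leg$vt1$hr; hr2 <- leg$vt2$hr
    # maximal intensity: reached at VO2max; approximate as the intensity at
    # the top of the test scaled by the VO2max/VT2 ratio when absent
    peak <- th2 * leg$vo2max / leg$vt2$vo2
    unit <- if (discipline == "bike") "W" else "km/h"
  }
  if (th2 <= th1) stop("second threshold must exceed the first")
  if (peak <= th2) peak <- th2 * 1.1
  hr_max <- leg$hr_max

  bounds <- c(0, subzone_scheme[1] * th1, subzone_scheme[2] * th1, th1,
              (th1 + th2) / 2, th2, (th2 + peak) / 2, peak, Inf)
  hr_at <- stats::approxfun(c(0, th1, th2, peak),
                            c(0.55 * hr_max, hr1, hr2, hr_max), rule = 2)
  zones <- tibble::tibble(
    zone = 1:8,
    lower = bounds[1:8], upper = bounds[2:9],
    hr_lower = hr_at(bounds[1:8]), hr_upper = hr_at(pmin(bounds[2:9], peak)),
    eco_score = as.numeric(score_table),
    phase = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L),
    rpe_band = c(1, 2, 3, 4, 5, 7, 9, 10)
  )
  structure(list(discipline = discipline, unit = unit, zones = zones),
            class = "zone_model")
}

#' Map the 8 zones to the three phases of the triphasic model
#' @return Integer vector: phase (1, 2 or 3) of each zone.
#' @export
zone_phase <- function() c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L)

#' @export
print.zone_model <- function(x, ...) {
  cat(sprintf("<zone_model> %s (%s)\n", x$discipline, x$unit))
  print(x$zones)
  invisible(x)
}
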