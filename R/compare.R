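#' @title Test-to-test performance comparison
#' @description
#' Percent-change tables between two incremental-test sessions (one per
#' discipline) and cross-athlete averages of the season training-intensity
#' distribution.
#' @name comparison
NULL

#' Round half away from zero
#'
#' Commercial rounding (0.05 -> 0.1, -0.05 -> -0.1), as used for displayed
#' percent changes; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent change between two test values
#'
#' `100 * (b - a) / a`, optionally half-up rounded for display.
#'
#' @param a,b Values at the first and second test (`a` must be non-zero).
#' @param digits Decimal places for half-up rounding; `NULL` (default)
#'   returns the exact value.
#' @return Percent change (vectorized).
#' @export
percent_change <- function(a, b, digits = NULL) {
  if (any(a == 0)) stop("percent change undefined for a zero reference value")
  out <- 100 * (b - a) / a
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

marker_rows <- function(report) {
  rows <- list()
  add <- function(discipline, marker, value) {
    if (is.null(value) || length(value) == 0 || is.na(value)) return()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      discipline = discipline, marker = marker, value = as.numeric(value))
  }
  sw <- report$swim
  if (!is.null(sw)) {
    add("swim", "s_l200", sw$s_l200)
    if (isTRUE(sw$lt2$detected)) add("swim", "lt2_speed", sw$lt2$speed)
    if (isTRUE(sw$lt1$detected)) add("swim", "lt1_speed", sw$lt1$speed)
    add("swim", "hr_max", sw$hr_max)
  }
  for (d in c("bike", "run")) {
    leg <- report[[d]]
    if (is.null(leg)) next
    pre <- if (d == "bike") "w" else "s"
    add(d, "vo2max", leg$vo2max)
    add(d, paste0(pre, "_vo2max"), leg$peak_intensity)
    if (isTRUE(leg$vt2$detected)) add(d, paste0(pre, "_vt2"), leg$vt2$intensity)
    if (isTRUE(leg$vt1$detected)) add(d, paste0(pre, "_vt1"), leg$vt1$intensity)
    if (d == "bike" && !is.null(report$body_mass)) {
      add(d, "wkg_vo2max", leg$peak_intensity / report$body_mass)
      if (isTRUE(leg$vt2$detected)) {
        add(d, "wkg_vt2", leg$vt2$intensity / report$body_mass)
      }
      if (isTRUE(leg$vt1$detected)) {
        add(d, "wkg_vt1", leg$vt1$intensity / report$body_mass)
      }
    }
    add(d, "hr_max", leg$hr_max)
  }
  dplyr::bind_rows(rows)
}

#' Build a two-test percent-change comparison table
#'
#' Emits one row per physiological marker available in both threshold
#' reports: swim last-repetition speed, LT speeds and HRmax; cycling VO2max,
#' power at VO2max/VT2/VT1 in W and W/kg and HRmax; running VO2max and the
#' speeds at VO2max/VT2/VT1 plus HRmax. W/kg markers use each test's own
#' body mass. Markers present in only one report are dropped with a
#' warning.
#'
#' @param report1,report2 [threshold_report()] objects from the two test
#'   sessions.
#' @param body_mass1,body_mass2 Optional body masses (kg) overriding those
#'   stored in the reports.
#' @return A tibble: `discipline`, `marker`, `test1`, `test2`, `pct_change`
#'   (half-up rounded to 1 decimal).
#' @export
build_comparison <- function(report1, report2, body_mass1 = NULL,
                             body_mass2 = NULL) {
  stopifnot(inherits(report1, "threshold_report"),
            inherits(report2, "threshold_report"))
  if (!is.null(body_mass1)) report1$body_mass <- body_mass1
  if (!is.null(body_mass2)) report2$body_mass <- body_mass2
  m1 <- marker_rows(report1)
  m2 <- marker_rows(report2)
  joined <- dplyr::inner_join(m1, m2, by = c("discipline", "marker"),
                              suffix = c("_1", "_2"))
  lost <- nrow(m1) + nrow(m2) - 2 * nrow(joined)
  if (lost > 0) {
    warning(lost, " marker(s) present in only one report were dropped")
  }
  tibble::tibble(
    discipline = joined$discipline, marker = joined$marker,
    test1 = joined$value_1, test2 = joined$value_2,
    pct_change = percent_change(joined$value_1, joined$value_2, digits = 1)
  )
}

#' Average training-intensity distribution across athletes
#'
#' Unweighted mean of each athlete's season mean time-TID, reported both
#' exactly and half-up rounded to integer percent (abstract style).
#'
#' @param summaries A data frame with one row per athlete and the season
#'   mean time shares in columns `z1`, `z2`, `z3` (any columns named
#'   `pct_time_z*_mean`, as produced by [summarize_season()], are accepted
#'   too).
#' @return A list with `exact` and `rounded` length-3 named vectors.
#' @export
average_tid <- function(summaries) {
  summaries <- as.data.frame(summaries)
  if (!all(c("z1", "z2", "z3") %in% names(summaries))) {
    alt <- paste0("pct_time_z", 1:3, "_mean")
    if (all(alt %in% names(summaries))) {
      summaries <- stats::setNames(summaries[, alt], c("z1", "z2", "z3"))
    } else {
      stop("need columns z1, z2, z3 (or pct_time_z*_mean)")
    }
  }
  stopifnot(nrow(summaries) >= 1)
  exact <- colMeans(summaries[, c("z1", "z2", "z3")])
  list(exact = exact, rounded = round_half_up(exact, 0))
}
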