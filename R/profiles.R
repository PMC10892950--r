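#' Generate a synthetic athlete profile
#'
#' Draws the physiological parameters of a virtual elite U23 female
#' triathlete. Each parameter is sampled uniformly inside the range spanned by
#' published incremental-test values for athletes of this level: cycling and
#' running VO2max 59--68 mL/kg/min, peak aerobic power 260--315 W, peak
#' running speed 16.9--18.4 km/h, swim speed at the second lactate threshold
#' 1.25--1.35 m/s. The fractions of VO2max at which the first and second
#' ventilatory thresholds sit are drawn around 0.70 and 0.85, typical for
#' trained endurance athletes.
#'
#' @param seed Integer seed; the same seed always returns the identical
#'   profile.
#' @param vt1_frac,vt2_frac Optional fixed threshold fractions of VO2max
#'   (`0 < vt1_frac < vt2_frac < 1`). When `NULL` (default) they are drawn
#'   uniformly in `[0.66, 0.74]` and `[0.82, 0.88]`.
#' @return An object of class `athlete_profile`: a list with fields
#'   `athlete_id`, `body_mass` (kg), `stature` (cm), `vo2max_cycle`,
#'   `vo2max_run` (mL/kg/min), `vt1_frac`, `vt2_frac`, `peak_power` (W),
#'   `peak_speed` (km/h), `swim_lt1_speed`, `swim_lt2_speed` (m/s),
#'   `hr_max` (named bpm vector: swim, bike, run), `baseline_lactate`
#'   (mmol/L), `age` (years), `sex`.
#' @examples
#' p <- generate_profile(seed = 1)
#' p$vo2max_cycle
#' @export
generate_profile <- function(seed, vt1_frac = NULL, vt2_frac = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  rng <- local_rng(seed, "profile")
  on.exit(rng(), add = TRUE)

  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  v1 <- if (is.null(vt1_frac)) runif1(0.66, 0.74) else vt1_frac
  v2 <- if (is.null(vt2_frac)) runif1(0.82, 0.88) else vt2_frac
  stopifnot(v1 > 0, v1 < v2, v2 < 1)

  lt2 <- runif1(1.25, 1.35)
  profile <- structure(list(
    athlete_id       = sprintf("SYN-%06d", as.integer(seed) %% 1000000L),
    body_mass        = runif1(49, 62),
    stature          = runif1(158, 175),
    vo2max_cycle     = runif1(59, 68),
    vo2max_run       = runif1(59, 68),
    vt1_frac         = v1,
    vt2_frac         = v2,
    peak_power       = runif1(260, 315),
    peak_speed       = runif1(16.9, 18.4),
    swim_lt1_speed   = lt2 - runif1(0.05, 0.10),
    swim_lt2_speed   = lt2,
    hr_max           = c(swim = round(runif1(182, 188)),
                         bike = round(runif1(180, 188)),
                         run  = round(runif1(186, 197))),
    baseline_lactate = runif1(0.8, 1.5),
    age              = 21,
    sex              = "female"
  ), class = "athlete_profile")
  validate_profile(profile)
  profile
}

validate_profile <- function(p) {
  stopifnot(
    inherits(p, "athlete_profile"),
    p$vt1_frac < p$vt2_frac, p$vt1_frac > 0, p$vt2_frac < 1,
    p$swim_lt1_speed < p$swim_lt2_speed,
    all(vapply(p[c("body_mass", "stature", "vo2max_cycle", "vo2max_run",
                   "peak_power", "peak_speed", "swim_lt1_speed",
                   "swim_lt2_speed", "baseline_lactate")],
               function(x) is.numeric(x) && x > 0, logical(1))),
    all(p$hr_max > 0)
  )
  invisible(p)
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat("<athlete_profile>", x$athlete_id, "\n")
  cat(sprintf("  body mass %.1f kg, stature %.1f cm\n", x$body_mass, x$stature))
  cat(sprintf("  VO2max %.1f (bike) / %.1f (run) mL/kg/min; VT at %.2f/%.2f of VO2max\n",
              x$vo2max_cycle, x$vo2max_run, x$vt1_frac, x$vt2_frac))
  cat(sprintf("  peak power %.0f W; peak speed %.1f km/h; swim LT1/LT2 %.2f/%.2f m/s\n",
              x$peak_power, x$peak_speed, x$swim_lt1_speed, x$swim_lt2_speed))
  invisible(x)
}

# Seed scoping: every generator draws from its own stream derived from the
# user seed plus a purpose tag, and restores the caller's RNG state on exit.
local_rng <- function(seed, tag) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  offset <- sum(utf8ToInt(tag)) * 1009L
  set.seed((as.integer(seed) %% 2000000000L) + offset)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
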