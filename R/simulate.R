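#' @title Synthetic incremental-test generators
#' @description
#' The generators build gas-exchange traces and lactate curves whose
#' breakpoints are planted by construction: below the first ventilatory
#' threshold (VT1) the ventilatory equivalent for oxygen (VE/VO2) and the
#' end-tidal O2 pressure are flat; from VT1 they rise while the ventilatory
#' equivalent for CO2 (VE/VCO2) stays flat; from VT2 the VE/VCO2 rises and
#' the end-tidal CO2 pressure falls. A trace therefore satisfies the Davis
#' threshold criteria at the planted points exactly, and the planted truth is
#' attached to the object for recovery studies.
#' @name simulate
NULL

# ---- protocol schedules ----------------------------------------------------

cycle_protocol <- function(start_w = 100, inc_w = 5, step_s = 12) {
  list(type = "ramp", start = start_w, inc = inc_w, step_s = step_s,
       unit = "W")
}

run_protocol <- function(n_stages, start_kmh = 12.1, inc_kmh = 0.3,
                         stage_m = 200) {
  speeds <- start_kmh + inc_kmh * (seq_len(n_stages) - 1)
  durations <- stage_m / (speeds / 3.6)          # seconds per 200 m stage
  list(type = "stages", speeds = speeds, durations = durations,
       boundaries = c(0, cumsum(durations)), unit = "km/h")
}

#' Protocol intensity at a given time
#'
#' Evaluates the analytic work-rate/speed schedule of an incremental protocol
#' at arbitrary times (right-continuous step function).
#'
#' @param protocol Protocol descriptor attached to a generated trace.
#' @param t Numeric vector of times (s).
#' @return Numeric vector of work rates (W) or speeds (km/h).
#' @keywords internal
schedule_intensity <- function(protocol, t) {
  if (identical(protocol$type, "ramp")) {
    protocol$start + protocol$inc * floor(t / protocol$step_s)
  } else {
    idx <- findInterval(t, protocol$boundaries, rightmost.closed = FALSE)
    idx <- pmin(pmax(idx, 1L), length(protocol$speeds))
    protocol$speeds[idx]
  }
}

# step times where the schedule changes value (used as breakpoint candidates)
schedule_steps <- function(protocol, t_end) {
  if (identical(protocol$type, "ramp")) {
    seq(0, t_end, by = protocol$step_s)
  } else {
    protocol$boundaries
  }
}

new_gas_trace <- function(samples, discipline, body_mass, protocol, truth) {
  stopifnot(all(diff(samples$time) > 0), all(samples$ve > 0),
            all(samples$vo2 > 0))
  structure(samples, class = c("gas_trace", class(samples)),
            discipline = discipline, body_mass = body_mass,
            protocol = protocol, truth = truth)
}

#' Planted truth of a synthetic trace or curve
#' @param x A generated `gas_trace` or `lactate_curve`.
#' @return The list of planted physiological values.
#' @export
planted_truth <- function(x) attr(x, "truth")

# ---- shared trace machinery ------------------------------------------------

# Builds a trace from a protocol plus piecewise-linear channel kinetics with
# kinks at the planted threshold times t1 < t2 and a VO2 plateau from t_pk.
build_trace <- function(profile, protocol, discipline, vo2max, t_pk, t_end,
                        noise_sd, dt = 5) {
  vo2_rest <- 8
  snap <- schedule_steps(protocol, t_end)

  # threshold times where VO2 crosses the planted fractions, snapped to the
  # protocol's own step grid so planted intensities are clean protocol values
  t_of_frac <- function(f) t_pk * (f * vo2max - vo2_rest) / (vo2max - vo2_rest)
  snap_to <- function(t) snap[which.min(abs(snap - t))]
  t1 <- snap_to(t_of_frac(profile$vt1_frac))
  t2 <- snap_to(t_of_frac(profile$vt2_frac))
  if (t2 <= t1) t2 <- min(snap[snap > t1])
  t1 <- max(t1, snap[4])                       # leave a flat baseline segment
  if (t2 <= t1) t2 <- min(snap[snap > t1])

  time <- seq(0, t_end, by = dt)
  vo2 <- pmin(vo2_rest + (vo2max - vo2_rest) * time / t_pk, vo2max)
  hr_max <- unname(profile$hr_max[[discipline]])
  hr <- pmin(120 + (hr_max - 120) * time / t_pk, hr_max)

  hinge <- function(t, t0) pmax(0, t - t0)
  veo2   <- 24 + 6  * hinge(time, t1) / (t_end - t1)
  peto2  <- 95 + 10 * hinge(time, t1) / (t_end - t1)
  veco2  <- 27 + 5  * hinge(time, t2) / (t_end - t2)
  petco2 <- 38 - 6  * hinge(time, t2) / (t_end - t2)

  vo2_abs <- vo2 * profile$body_mass / 1000     # L/min
  ve <- veo2 * vo2_abs
  vco2 <- ve / veco2

  if (noise_sd > 0) {
    # ventilatory volumes carry the same relative noise as VO2; end-tidal
    # pressures carry absolute instrument noise of the same magnitude (mmHg)
    rel <- noise_sd / mean(vo2)
    jitter <- function(x, sd_x) pmax(x + stats::rnorm(length(x), 0, sd_x), 0.01)
    vo2 <- jitter(vo2, noise_sd)
    ve <- jitter(ve, rel * mean(ve))
    vco2 <- jitter(vco2, rel * mean(vco2))
    peto2 <- jitter(peto2, noise_sd)
    petco2 <- jitter(petco2, noise_sd)
  }

  at <- function(y, t) stats::approx(time, y, xout = t)$y
  clean_hr <- pmin(120 + (hr_max - 120) * time / t_pk, hr_max)
  truth <- list(
    vo2max = vo2max,
    hr_max = hr_max,
    peak_intensity = schedule_intensity(protocol, t_pk),
    vt1 = list(time = t1, vo2 = vo2_rest + (vo2max - vo2_rest) * t1 / t_pk,
               intensity = schedule_intensity(protocol, t1),
               hr = at(clean_hr, t1)),
    vt2 = list(time = t2, vo2 = vo2_rest + (vo2max - vo2_rest) * t2 / t_pk,
               intensity = schedule_intensity(protocol, t2),
               hr = at(clean_hr, t2))
  )

  samples <- tibble::tibble(
    time = time,
    intensity = schedule_intensity(protocol, time),
    vo2 = vo2, vco2 = vco2, ve = ve,
    peto2 = peto2, petco2 = petco2, hr = hr
  )
  new_gas_trace(samples, discipline, profile$body_mass, protocol, truth)
}

#' Generate a synthetic cycling ramp test
#'
#' Ramp protocol starting at 100 W and increasing 5 W every 12 s. VO2 rises
#' quasi-linearly from rest to the profile's cycling VO2max, which is reached
#' at the profile's peak aerobic power and then held (plateau) for the final
#' 90 s of the test while the ramp continues. Gaussian noise of standard
#' deviation `noise_sd` (mL/kg/min, scaled proportionally for the other gas
#' channels) is added to VO2, VCO2, VE and the end-tidal pressures.
#'
#' @param profile An [generate_profile()] athlete profile.
#' @param noise_sd Gas-channel noise standard deviation in mL/kg/min
#'   (default 0 = noiseless). Must be non-negative.
#' @param seed Integer seed for the noise draws.
#' @param dt Sampling interval of the gas analyser in seconds (default 5).
#' @return A `gas_trace` tibble (time s, intensity W, vo2 mL/kg/min,
#'   vco2 L/min, ve L/min, peto2 mmHg, petco2 mmHg, hr bpm) with attributes
#'   `discipline`, `body_mass`, `protocol` and planted `truth`.
#' @export
generate_cycle_trace <- function(profile, noise_sd = 0, seed = 1, dt = 5) {
  validate_profile(profile)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number")
  }
  rng <- local_rng(seed, "cycle"); on.exit(rng(), add = TRUE)
  protocol <- cycle_protocol()
  t_pk <- protocol$step_s * round((profile$peak_power - protocol$start) /
                                    protocol$inc)
  build_trace(profile, protocol, "bike", profile$vo2max_cycle,
              t_pk = t_pk, t_end = t_pk + 90, noise_sd = noise_sd, dt = dt)
}

#' Generate a synthetic running track test
#'
#' Track protocol starting at 12.1 km/h and increasing 0.3 km/h every 200 m
#' (stage duration = 200 m at the current speed). VO2max is reached at the
#' profile's peak running speed and held over the two final stages.
#'
#' @inheritParams generate_cycle_trace
#' @return A `gas_trace` tibble; `intensity` is the stage speed in km/h.
#' @export
generate_run_trace <- function(profile, noise_sd = 0, seed = 1, dt = 5) {
  validate_profile(profile)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number")
  }
  rng <- local_rng(seed, "run"); on.exit(rng(), add = TRUE)
  n_peak <- round((profile$peak_speed - 12.1) / 0.3) + 1  # stage reaching VO2max
  protocol <- run_protocol(n_stages = n_peak + 1)
  t_pk <- protocol$boundaries[n_peak]           # VO2max from start of stage n_peak
  t_end <- protocol$boundaries[n_peak + 2]      # hold through two final stages
  build_trace(profile, protocol, "run", profile$vo2max_run,
              t_pk = t_pk, t_end = t_end, noise_sd = noise_sd, dt = dt)
}

# ---- swim lactate curve ----------------------------------------------------

new_lactate_curve <- function(stages, truth) {
  stopifnot(all(diff(stages$speed) > 0), all(stages$lactate >= 0))
  structure(stages, class = c("lactate_curve", class(stages)), truth = truth)
}

#' Generate a synthetic 7 x 200 m swim lactate test
#'
#' Seven 200 m repetitions at ascending speeds ending at the athlete's
#' maximal 200 m speed, with blood lactate following an exponential rise
#' above the athlete's baseline. The two curve parameters are calibrated
#' numerically so that the fixed-rise threshold rules (0.5 mmol/L above
#' baseline for LT1; a stage-to-stage rise above 1.0 mmol/L for LT2, both
#' linearly interpolated to the crossing concentration) recover the
#' profile's planted LT1/LT2 speeds on the noiseless curve. Optional
#' multiplicative lognormal noise keeps lactate positive.
#'
#' @param profile An athlete profile.
#' @param seed Integer seed for the noise draws.
#' @param noise_sd Lognormal sigma of the multiplicative lactate noise
#'   (default 0 = noiseless).
#' @return A `lactate_curve` tibble (stage, speed m/s, lactate mmol/L,
#'   hr bpm) with planted truth attached.
#' @export
generate_lactate_curve <- function(profile, seed = 1, noise_sd = 0) {
  validate_profile(profile)
  stopifnot(noise_sd >= 0)
  rng <- local_rng(seed, "swim"); on.exit(rng(), add = TRUE)

  la0 <- profile$baseline_lactate
  lt1 <- profile$swim_lt1_speed
  lt2 <- profile$swim_lt2_speed
  s_l200 <- lt2 + 0.08                          # maximal 200 m speed
  speeds <- seq(lt1 - 0.18, s_l200, length.out = 7)

  curve_at <- function(v, c1, c2) la0 + c1 * (exp(c2 * (v - speeds[1])) - 1)

  recover <- function(c1, c2) {
    la <- curve_at(speeds, c1, c2)
    detect_lactate_thresholds(
      new_lactate_curve(tibble::tibble(stage = 1:7, speed = speeds,
                                       lactate = la, hr = 150), NULL))
  }
  objective <- function(par) {
    c1 <- exp(par[1]); c2 <- par[2]
    r <- recover(c1, c2)
    if (!r$lt1$detected || !r$lt2$detected) return(1)
    (r$lt1$speed - lt1)^2 + (r$lt2$speed - lt2)^2
  }
  start <- c(log(0.5 / (exp(20 * (lt1 - speeds[1])) - 1)), 20)
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-12))
  c1 <- exp(fit$par[1]); c2 <- fit$par[2]

  lactate <- curve_at(speeds, c1, c2)
  if (noise_sd > 0) {
    lactate <- lactate * exp(stats::rnorm(7, 0, noise_sd))
  }
  hr_max <- unname(profile$hr_max[["swim"]])
  hr <- round(seq(hr_max - 40, hr_max, length.out = 7))

  truth <- list(lt1_speed = lt1, lt2_speed = lt2, s_l200 = s_l200,
                baseline_lactate = la0, hr_max = hr_max)
  new_lactate_curve(tibble::tibble(stage = 1:7, speed = speeds,
                                   lactate = lactate, hr = hr), truth)
}
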