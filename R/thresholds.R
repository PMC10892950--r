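#' @title Incremental-test processing
#' @description
#' Detection of VO2max (highest 1-min continuous oxygen uptake), the two
#' ventilatory thresholds (Davis criteria operationalized as windowed slope
#' tests on the ventilatory equivalents and end-tidal pressures, with the
#' breakpoint localized by a single-hinge segmented regression on the raw
#' samples) and the two swim lactate thresholds (fixed-rise rules with
#' linear interpolation to the crossing concentration).
#' @name thresholds
NULL

trace_channels <- function(df, body_mass) {
  vo2_abs <- df$vo2 * body_mass / 1000
  tibble::tibble(time = df$time,
                 veo2 = df$ve / vo2_abs,
                 veco2 = df$ve / df$vco2,
                 peto2 = df$peto2,
                 petco2 = df$petco2)
}

#' Average a gas-exchange trace into fixed-width bins
#'
#' Samples are averaged over consecutive non-overlapping windows of
#' `bin_width` seconds (the trailing partial window is kept). The bin's time
#' stamp is the mean of its member sample times; the bin's work rate/speed is
#' the protocol schedule evaluated at the midpoint of the bin interval when
#' the trace carries a protocol, otherwise the mean of the sample
#' intensities.
#'
#' @param trace A `gas_trace`.
#' @param bin_width Bin width in seconds (> 0).
#' @return A `gas_trace` of bin averages.
#' @export
bin_trace <- function(trace, bin_width) {
  stopifnot(inherits(trace, "gas_trace"), bin_width > 0)
  if (nrow(trace) == 0) stop("empty trace")
  t0 <- trace$time[1]
  grp <- floor((trace$time - t0) / bin_width)
  df <- as.data.frame(trace)
  agg <- lapply(split(df, grp), function(d) {
    out <- vapply(d, mean, numeric(1))
    out
  })
  out <- tibble::as_tibble(do.call(rbind, agg))
  protocol <- attr(trace, "protocol")
  if (!is.null(protocol)) {
    mid <- t0 + (sort(unique(grp)) + 0.5) * bin_width
    out$intensity <- schedule_intensity(protocol, pmin(mid, max(trace$time)))
  }
  new_gas_trace(out, attr(trace, "discipline"), attr(trace, "body_mass"),
                protocol, attr(trace, "truth"))
}

# stage-aligned binning for track protocols: one bin per 200 m stage
bin_by_stage <- function(trace) {
  protocol <- attr(trace, "protocol")
  stopifnot(identical(protocol$type, "stages"))
  grp <- findInterval(trace$time, protocol$boundaries,
                      rightmost.closed = FALSE)
  df <- as.data.frame(trace)
  agg <- lapply(split(df, grp), function(d) vapply(d, mean, numeric(1)))
  out <- tibble::as_tibble(do.call(rbind, agg))
  out$intensity <- protocol$speeds[sort(unique(grp))]
  new_gas_trace(out, attr(trace, "discipline"), attr(trace, "body_mass"),
                protocol, attr(trace, "truth"))
}

#' Highest 1-minute oxygen uptake of a test
#'
#' VO2max is the maximum over all continuous 60 s windows of the
#' time-weighted (trapezoidal) mean VO2, windows anchored at sample times.
#'
#' @param trace A `gas_trace` spanning at least 60 s.
#' @param window_s Averaging window in seconds (default 60).
#' @return VO2max in mL/kg/min.
#' @export
detect_vo2max <- function(trace, window_s = 60) {
  stopifnot(inherits(trace, "gas_trace"))
  t <- trace$time; y <- trace$vo2
  if (max(t) - min(t) < window_s) stop("trace shorter than the averaging window")
  # cumulative trapezoid, evaluated exactly at arbitrary points (the VO2
  # signal is treated as piecewise linear between samples)
  ct <- c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  integral_at <- function(x) {
    i <- findInterval(x, t)
    yx <- stats::approx(t, y, xout = x)$y
    ct[i] + (x - t[i]) * (y[i] + yx) / 2
  }
  starts <- t[t + window_s <= max(t) + 1e-9]
  vals <- (integral_at(starts + window_s) - integral_at(starts)) / window_s
  max(vals)
}

# VO2max together with the earliest 1-min window achieving it, and the
# protocol intensity at that window's start (the work rate / speed at which
# VO2max is first sustained)
vo2max_point <- function(trace, window_s = 60) {
  t <- trace$time; y <- trace$vo2
  if (max(t) - min(t) < window_s) stop("trace shorter than the averaging window")
  ct <- c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  integral_at <- function(x) {
    i <- findInterval(x, t)
    yx <- stats::approx(t, y, xout = x)$y
    ct[i] + (x - t[i]) * (y[i] + yx) / 2
  }
  starts <- t[t + window_s <= max(t) + 1e-9]
  vals <- (integral_at(starts + window_s) - integral_at(starts)) / window_s
  t_at <- starts[which(vals >= max(vals) - 1e-9)[1]]
  protocol <- attr(trace, "protocol")
  intensity <- if (!is.null(protocol)) {
    schedule_intensity(protocol, t_at)
  } else {
    stats::approx(t, trace$intensity, xout = t_at, method = "constant",
                  f = 0, rule = 2)$y
  }
  list(vo2max = max(vals), time = t_at, intensity = unname(intensity))
}

# ---- ventilatory thresholds ------------------------------------------------

# fitted rise of channel y over the window of bins starting at b
window_rise <- function(tt, yy) {
  if (length(tt) < 2) return(0)
  slope <- stats::coef(stats::lm.fit(cbind(1, tt), yy))[2]
  unname(slope * (max(tt) - min(tt)))
}

# single-hinge segmented regression: y = a + m * max(0, t - tau).
# Returns the breakpoint tau minimizing SSE over the candidate set; exact on
# noiseless piecewise-linear channels because protocol step times are
# candidates.
hinge_breakpoint <- function(t, y, candidates) {
  candidates <- sort(unique(candidates))
  sse <- vapply(candidates, function(tau) {
    x <- pmax(0, t - tau)
    xc <- x - mean(x); yc <- y - mean(y)
    sxx <- sum(xc^2)
    if (sxx < 1e-12) return(sum(yc^2))
    sum(yc^2) - sum(xc * yc)^2 / sxx
  }, numeric(1))
  best <- min(sse)
  ties <- which(sse <= best + 1e-9)
  ties[1]
  candidates[ties[1]]
}

default_bin_width <- function(trace) {
  if (identical(attr(trace, "discipline"), "bike")) 30 else NA_real_
}

prepare_detection <- function(trace, bin_width) {
  protocol <- attr(trace, "protocol")
  if (is.null(bin_width)) bin_width <- default_bin_width(trace)
  binned <- if (is.na(bin_width) && identical(protocol$type, "stages")) {
    bin_by_stage(trace)
  } else {
    if (is.na(bin_width)) bin_width <- 30
    bin_trace(trace, bin_width)
  }
  mass <- attr(trace, "body_mass")
  list(bins = trace_channels(binned, mass),
       bin_intensity = binned$intensity,
       raw = trace_channels(trace, mass),
       trace = trace, protocol = protocol)
}

not_detected <- function(reason) {
  list(detected = FALSE, time = NA_real_, vo2 = NA_real_,
       intensity = NA_real_, hr = NA_real_, reason = reason)
}

threshold_point <- function(prep, tau) {
  trace <- prep$trace
  intensity <- if (!is.null(prep$protocol)) {
    schedule_intensity(prep$protocol, tau)
  } else {
    stats::approx(trace$time, trace$intensity, xout = tau,
                  method = "constant", f = 0, rule = 2)$y
  }
  list(detected = TRUE, time = tau,
       vo2 = stats::approx(trace$time, trace$vo2, xout = tau, rule = 2)$y,
       intensity = unname(intensity),
       hr = stats::approx(trace$time, trace$hr, xout = tau, rule = 2)$y,
       reason = NULL)
}

# scan binned channels for the earliest window satisfying `crit`, a function
# of the named per-channel fitted rises and two tolerance vectors: `rise_tol`
# (a channel must exceed it to count as rising/falling) and `flat_tol_v` (a
# channel within it counts as flat). Both floor at flat_tol x IQR and scale
# with the channel's bin-level noise, estimated robustly from second
# differences so that noiseless piecewise-linear channels keep a ~zero
# tolerance and exact breakpoints.
gate_scan <- function(bins, window, flat_tol, crit, from = 1L) {
  n <- nrow(bins)
  chans <- c("veo2", "veco2", "peto2", "petco2")
  w <- window
  rise_noise_factor <- (w - 1) / sqrt(sum((seq_len(w) - mean(seq_len(w)))^2))
  tols <- lapply(chans, function(ch) {
    y <- bins[[ch]]
    sigma <- if (length(y) >= 4) {
      stats::mad(diff(y, differences = 2)) / sqrt(6)
    } else 0
    base <- max(flat_tol * stats::IQR(y), 1e-9)
    c(rise = max(base, rise_noise_factor * sigma),
      flat = max(base, 2.5 * rise_noise_factor * sigma))
  })
  rise_tol <- vapply(tols, `[[`, numeric(1), "rise"); names(rise_tol) <- chans
  flat_tol_v <- vapply(tols, `[[`, numeric(1), "flat"); names(flat_tol_v) <- chans
  for (b in seq.int(from, n - window + 1L)) {
    idx <- b:(b + window - 1L)
    rises <- vapply(chans, function(ch) {
      window_rise(bins$time[idx], bins[[ch]][idx])
    }, numeric(1))
    if (crit(rises, rise_tol, flat_tol_v)) return(b)
  }
  NA_integer_
}

breakpoint_candidates <- function(prep, lo, hi) {
  t <- prep$raw$time
  cand <- seq(lo, hi, by = 1)
  if (!is.null(prep$protocol)) {
    steps <- schedule_steps(prep$protocol, max(t))
    cand <- c(cand, steps[steps >= lo & steps <= hi])
  }
  cand[cand >= min(t) & cand <= max(t)]
}

#' Detect the first ventilatory threshold (VT1)
#'
#' VT1 is the earliest point where the ventilatory equivalent for oxygen
#' (VE/VO2) and the end-tidal O2 pressure both rise while the ventilatory
#' equivalent for CO2 stays flat. The trace is binned (30 s for cycling,
#' per-stage for track tests), windows of `window` consecutive bins are
#' scanned for the criteria (a channel is "rising" when its fitted rise over
#' the window exceeds `flat_tol` times the channel's interquartile range),
#' and the threshold time is then localized sub-bin by a single-breakpoint
#' hinge regression of VE/VO2 on the raw samples. VO2, work rate/speed and
#' heart rate are reported at the localized time, the work rate/speed read
#' from the protocol schedule.
#'
#' @param trace A `gas_trace`.
#' @param bin_width Bin width in s; `NULL` uses the discipline default.
#' @param window Detection window in bins (default 3).
#' @param flat_tol Slope flatness tolerance as a fraction of the channel IQR
#'   (default 0.05).
#' @return A list with `detected` plus, when detected, `time` (s), `vo2`
#'   (mL/kg/min), `intensity` (W or km/h), `hr` (bpm); a not-detected result
#'   carries a `reason` instead of throwing.
#' @export
detect_vt1 <- function(trace, bin_width = NULL, window = 3, flat_tol = 0.05) {
  prep <- prepare_detection(trace, bin_width)
  if (nrow(prep$bins) < 6) stop("need at least 6 bins for threshold detection")
  b <- gate_scan(prep$bins, window, flat_tol, function(r, rise, flat) {
    r[["veo2"]] > rise[["veo2"]] && r[["peto2"]] > rise[["peto2"]] &&
      r[["veco2"]] <= flat[["veco2"]]
  })
  if (is.na(b)) return(not_detected("no window satisfies the VT1 criteria"))
  t_end <- max(prep$raw$time)
  cand <- breakpoint_candidates(prep, min(prep$raw$time) + 15, t_end - 15)
  tau <- hinge_breakpoint(prep$raw$time, prep$raw$veo2, cand)
  threshold_point(prep, tau)
}

#' Detect the second ventilatory threshold (VT2)
#'
#' VT2 is the earliest point at or after VT1 where VE/VO2 and VE/VCO2 both
#' rise and the end-tidal CO2 pressure falls. Localization is by hinge
#' regression of VE/VCO2 on the raw samples, restricted to times at or after
#' the detected VT1.
#'
#' @inheritParams detect_vt1
#' @param vt1 Optional result of [detect_vt1()]; computed when `NULL`.
#' @return As [detect_vt1()].
#' @export
detect_vt2 <- function(trace, bin_width = NULL, window = 3, flat_tol = 0.05,
                       vt1 = NULL) {
  prep <- prepare_detection(trace, bin_width)
  if (nrow(prep$bins) < 6) stop("need at least 6 bins for threshold detection")
  if (is.null(vt1)) vt1 <- detect_vt1(trace, bin_width, window, flat_tol)
  from <- 1L
  t_lo <- min(prep$raw$time) + 15
  if (isTRUE(vt1$detected)) {
    from <- max(1L, findInterval(vt1$time, prep$bins$time))
    t_lo <- vt1$time
  }
  b <- gate_scan(prep$bins, window, flat_tol, function(r, rise, flat) {
    r[["veo2"]] > rise[["veo2"]] && r[["veco2"]] > rise[["veco2"]] &&
      r[["petco2"]] < -rise[["petco2"]]
  }, from = from)
  if (is.na(b)) return(not_detected("no window satisfies the VT2 criteria"))
  t_end <- max(prep$raw$time)
  cand <- breakpoint_candidates(prep, t_lo, t_end - 15)
  tau <- hinge_breakpoint(prep$raw$time, prep$raw$veco2, cand)
  if (isTRUE(vt1$detected)) tau <- max(tau, vt1$time)
  threshold_point(prep, tau)
}

# ---- lactate thresholds ----------------------------------------------------

#' Detect swim lactate thresholds by the fixed-rise rules
#'
#' LT1 is the first stage whose lactate exceeds the baseline (stage-1 value)
#' by at least `rise1` mmol/L; LT2 is the first later stage whose lactate
#' exceeds the previous stage's by more than `rise2` mmol/L. The threshold
#' speed is linearly interpolated between the flagged stage and its
#' predecessor at the exact crossing concentration (baseline + `rise1` for
#' LT1, previous stage + `rise2` for LT2).
#'
#' @param curve A `lactate_curve` with at least 4 stages.
#' @param rise1 LT1 rise above baseline, mmol/L (default 0.5).
#' @param rise2 LT2 rise above the previous stage, mmol/L (default 1.0).
#' @return A list with elements `lt1` and `lt2`, each `detected` plus
#'   `stage`, `speed` (m/s), `lactate` (mmol/L) and `hr` (bpm) when found.
#' @export
detect_lactate_thresholds <- function(curve, rise1 = 0.5, rise2 = 1.0) {
  stopifnot(inherits(curve, "lactate_curve"), rise1 > 0, rise2 > 0)
  if (nrow(curve) < 4) stop("need at least 4 stages")
  la <- curve$lactate; v <- curve$speed; hr <- curve$hr
  n <- length(la)
  miss <- list(detected = FALSE, stage = NA_integer_, speed = NA_real_,
               lactate = NA_real_, hr = NA_real_)

  interp_at <- function(j, conc) {
    f <- (conc - la[j - 1]) / (la[j] - la[j - 1])
    list(detected = TRUE, stage = j,
         speed = v[j - 1] + f * (v[j] - v[j - 1]),
         lactate = conc,
         hr = hr[j - 1] + f * (hr[j] - hr[j - 1]))
  }

  c1 <- la[1] + rise1
  j1 <- which(la >= c1)[1]
  lt1 <- if (is.na(j1) || j1 < 2) miss else interp_at(j1, c1)

  lt2 <- miss
  if (lt1$detected) {
    rises <- c(NA, diff(la))
    j2 <- which(seq_len(n) > lt1$stage & rises > rise2)[1]
    if (!is.na(j2)) lt2 <- interp_at(j2, la[j2 - 1] + rise2)
  }
  list(lt1 = lt1, lt2 = lt2)
}

# ---- combined report -------------------------------------------------------

#' Assemble a per-athlete threshold report
#'
#' Runs the detection stack on whichever incremental tests are supplied and
#' collects the physiological markers needed downstream: VO2max, VT1/VT2
#' with work rate or speed and HR for cycling and running, LT1/LT2 speeds
#' and the last-repetition speed (S_L200) for swimming, and the maximum HR of
#' each test. Missing inputs simply leave the corresponding markers out.
#'
#' @param bike_trace,run_trace Optional `gas_trace` objects.
#' @param lactate Optional `lactate_curve`.
#' @param body_mass Athlete body mass (kg), used for W/kg markers downstream.
#' @param ... Passed to the detectors (e.g. `flat_tol`).
#' @return A `threshold_report` list with components `swim`, `bike`, `run`
#'   (those supplied) and `body_mass`.
#' @export
threshold_report <- function(bike_trace = NULL, run_trace = NULL,
                             lactate = NULL, body_mass = NULL, ...) {
  rep <- list(body_mass = body_mass)
  leg <- function(trace) {
    vt1 <- detect_vt1(trace, ...)
    vt2 <- detect_vt2(trace, vt1 = vt1, ...)
    pk <- vo2max_point(trace)
    list(vo2max = pk$vo2max, peak_intensity = pk$intensity,
         vt1 = vt1, vt2 = vt2, hr_max = max(trace$hr))
  }
  if (!is.null(bike_trace)) rep$bike <- leg(bike_trace)
  if (!is.null(run_trace)) rep$run <- leg(run_trace)
  if (!is.null(lactate)) {
    lt <- detect_lactate_thresholds(lactate)
    rep$swim <- list(lt1 = lt$lt1, lt2 = lt$lt2,
                     s_l200 = max(lactate$speed), hr_max = max(lactate$hr))
  }
  structure(rep, class = "threshold_report")
}
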