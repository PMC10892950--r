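# Shared fixtures and independent oracles.

# gas trace built directly from channel vectors (bypasses the generators)
make_trace <- function(time, vo2, veo2 = 24, veco2 = 27, peto2 = 95,
                       petco2 = 38, hr = 150, body_mass = 55,
                       discipline = "bike", intensity = 100,
                       protocol = NULL) {
  n <- length(time)
  r <- function(x) rep_len(x, n)
  vo2 <- r(vo2)
  ve <- r(veo2) * vo2 * body_mass / 1000
  df <- tibble::tibble(time = time, intensity = r(intensity), vo2 = vo2,
                       vco2 = ve / r(veco2), ve = ve, peto2 = r(peto2),
                       petco2 = r(petco2), hr = r(hr))
  triseason:::new_gas_trace(df, discipline, body_mass, protocol, NULL)
}

# exhaustive sliding-window oracle for the 1-min VO2 (trapezoidal mean),
# written as an explicit loop independent of the implementation
oracle_vo2max <- function(trace, window_s = 60) {
  t <- trace$time; y <- trace$vo2
  best <- -Inf
  for (i in seq_along(t)) {
    a <- t[i]; b <- a + window_s
    if (b > max(t) + 1e-9) break
    tt <- t[t >= a - 1e-12 & t <= b + 1e-12]
    yy <- y[t >= a - 1e-12 & t <= b + 1e-12]
    if (abs(tt[length(tt)] - b) > 1e-9) {
      yy <- c(yy, approx(t, y, xout = b)$y)
      tt <- c(tt, b)
    }
    area <- 0
    for (k in seq_len(length(tt) - 1)) {
      area <- area + (tt[k + 1] - tt[k]) * (yy[k] + yy[k + 1]) / 2
    }
    best <- max(best, area / window_s)
  }
  best
}

# per-minute ECO re-summation: one score added per whole minute in a zone
oracle_eco <- function(minutes, scores, factor) {
  total <- 0
  for (z in 1:8) {
    whole <- floor(minutes[z])
    if (whole > 0) for (m in seq_len(whole)) total <- total + scores[z]
    total <- total + (minutes[z] - whole) * scores[z]
  }
  factor * total
}

# hand-built threshold report (for zone-model tests without running detection)
make_report <- function(discipline = "run", vt1 = 13.3, vt2 = 15.1,
                        vo2max = 64, vt1_vo2 = 45, vt2_vo2 = 55,
                        hr1 = 160, hr2 = 178, hr_max = 190,
                        body_mass = 55) {
  pt <- function(int, vo2, hr) {
    list(detected = TRUE, time = NA, vo2 = vo2, intensity = int, hr = hr)
  }
  leg <- list(vo2max = vo2max, peak_intensity = vt2 * vo2max / vt2_vo2,
              vt1 = pt(vt1, vt1_vo2, hr1), vt2 = pt(vt2, vt2_vo2, hr2),
              hr_max = hr_max)
  rep <- list(body_mass = body_mass)
  rep[[discipline]] <- leg
  structure(rep, class = "threshold_report")
}

session_row <- function(discipline = "run", minutes = c(60, 0, 0, 0, 0, 0, 0, 0),
                        week = 1L, date = as.Date("2021-01-04")) {
  stopifnot(length(minutes) == 8)
  out <- tibble::tibble(date = date, week = week, discipline = discipline)
  for (z in 1:8) out[[paste0("z", z)]] <- minutes[z]
  out
}
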