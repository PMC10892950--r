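#' @title Training-load scoring and aggregation
#' @description
#' ECO scoring (minutes-in-zone x zone score x discipline factor), weekly
#' roll-ups of load, hours and training-intensity distribution, the
#' polarization index, and season-level summary statistics.
#' @name load
NULL

zone_cols <- function() paste0("z", 1:8)

validate_sessions <- function(sessions) {
  need <- c("date", "week", "discipline", zone_cols())
  miss <- setdiff(need, names(sessions))
  if (length(miss)) stop("session log misses columns: ", paste(miss, collapse = ", "))
  zm <- as.matrix(sessions[, zone_cols()])
  if (any(zm < 0)) stop("negative minutes-in-zone")
  bad <- sessions$discipline %in% c("swim", "bike", "run", "strength")
  if (!all(bad)) stop("unknown discipline: ",
                      paste(unique(sessions$discipline[!bad]), collapse = ", "))
  invisible(sessions)
}

#' ECO load of a single session
#'
#' The ECO (objective load equivalent) of a session is the discipline factor
#' times the sum over zones of minutes-in-zone times the zone score.
#' Strength/core sessions carry zero ECOs.
#'
#' @param session A single session: a one-row data frame (or list) with
#'   `discipline` and minutes `z1`..`z8`.
#' @param model A `zone_model` for the session's discipline, or a bare
#'   numeric score table of length 8.
#' @param factors Named discipline factors (default run 1.0, swim 0.75,
#'   bike 0.5).
#' @return ECO load (arbitrary units).
#' @export
session_eco <- function(session, model = default_score_table(),
                        factors = default_factors()) {
  minutes <- as.numeric(unlist(session[zone_cols()]))
  if (any(minutes < 0)) stop("negative minutes-in-zone")
  disc <- as.character(session[["discipline"]])
  if (disc == "strength") return(0)
  scores <- if (inherits(model, "zone_model")) {
    if (!identical(model$discipline, disc)) {
      stop("session discipline '", disc, "' does not match model discipline '",
           model$discipline, "'")
    }
    model$zones$eco_score
  } else {
    as.numeric(model)
  }
  stopifnot(length(scores) == 8)
  unname(factors[[disc]] * sum(minutes * scores))
}

#' Polarization index of a training-intensity distribution
#'
#' `PI = log10((z1 / z2) * z3)` with the three phase shares expressed in
#' percent of training time. The index is undefined (returned as `NA`) when
#' phase 2 or phase 3 — or, degenerately, phase 1 — holds no time. A TID
#' with PI above 2.00 a.u. is conventionally called polarized.
#'
#' @param z1,z2,z3 Percent of training time in phases 1--3 (vectors allowed;
#'   each triple must be non-negative and sum to 100).
#' @return Polarization index in arbitrary units (`NA` where undefined).
#' @export
polarization_index <- function(z1, z2, z3) {
  if (any(c(z1, z2, z3) < 0)) stop("negative phase shares")
  if (any(abs(z1 + z2 + z3 - 100) > 0.01)) {
    stop("phase shares must sum to 100")
  }
  out <- ifelse(z1 > 0 & z2 > 0 & z3 > 0, log10((z1 / z2) * z3), NA_real_)
  as.numeric(out)
}

#' Classify a TID from its polarization index
#'
#' @param pi_value Polarization index (a.u.); vectorized.
#' @param threshold Classification cut-off (default 2.00; strictly greater
#'   counts as polarized).
#' @return `"polarized"` or `"non-polarized"` (`NA` for undefined PI).
#' @export
classify_tid <- function(pi_value, threshold = 2.0) {
  ifelse(is.na(pi_value), NA_character_,
         ifelse(pi_value > threshold, "polarized", "non-polarized"))
}

#' Summarize one training week
#'
#' Rolls the week's sessions up to hours, ECOs (total and per discipline),
#' the percent of training time and of ECOs per phase of the triphasic
#' model, and the weekly polarization index (from the time shares). An empty
#' week yields a zero-hour summary with undefined PI.
#'
#' @param sessions Session records of a single week (columns `date`, `week`,
#'   `discipline`, `z1`..`z8` minutes).
#' @param score_table 8 zone scores (default [default_score_table()]).
#' @param factors Discipline factors (default [default_factors()]).
#' @param week Week index, only needed when `sessions` is empty.
#' @return A one-row tibble (`week_summary`): week, n_sessions, hours,
#'   ecos_total, ecos_swim, ecos_bike, ecos_run, time_z1..z3, eco_z1..z3,
#'   polarization_index.
#' @export
summarize_week <- function(sessions, score_table = default_score_table(),
                           factors = default_factors(), week = NULL) {
  if (nrow(sessions) == 0) {
    stopifnot(!is.null(week))
    return(tibble::tibble(week = week, n_sessions = 0L, hours = 0,
                          ecos_total = 0, ecos_swim = 0, ecos_bike = 0,
                          ecos_run = 0, time_z1 = NA_real_, time_z2 = NA_real_,
                          time_z3 = NA_real_, eco_z1 = NA_real_,
                          eco_z2 = NA_real_, eco_z3 = NA_real_,
                          polarization_index = NA_real_))
  }
  validate_sessions(sessions)
  stopifnot(length(unique(sessions$week)) == 1)
  zm <- as.matrix(sessions[, zone_cols()])
  endurance <- sessions$discipline != "strength"
  fac <- unname(unlist(factors[sessions$discipline]))
  fac[!endurance] <- 0
  eco_sess <- fac * as.numeric(zm %*% score_table)

  phase <- zone_phase()
  min_phase <- vapply(1:3, function(p) sum(zm[endurance, phase == p, drop = FALSE]),
                      numeric(1))
  eco_phase <- vapply(1:3, function(p) {
    sum(fac * as.numeric(zm[, phase == p, drop = FALSE] %*%
                           score_table[phase == p]))
  }, numeric(1))

  total_min <- sum(min_phase)
  time_pct <- if (total_min > 0) 100 * min_phase / total_min else rep(NA_real_, 3)
  eco_pct <- if (sum(eco_phase) > 0) 100 * eco_phase / sum(eco_phase) else rep(NA_real_, 3)
  by_disc <- function(d) sum(eco_sess[sessions$discipline == d])

  tibble::tibble(
    week = sessions$week[1], n_sessions = nrow(sessions),
    hours = sum(zm) / 60,
    ecos_total = sum(eco_sess),
    ecos_swim = by_disc("swim"), ecos_bike = by_disc("bike"),
    ecos_run = by_disc("run"),
    time_z1 = time_pct[1], time_z2 = time_pct[2], time_z3 = time_pct[3],
    eco_z1 = eco_pct[1], eco_z2 = eco_pct[2], eco_z3 = eco_pct[3],
    polarization_index = if (total_min > 0 && all(time_pct[2:3] > 0) &&
                               time_pct[1] > 0) {
      polarization_index(time_pct[1], time_pct[2], time_pct[3])
    } else {
      NA_real_
    }
  )
}

#' Summarize every week of a season
#'
#' @inheritParams summarize_week
#' @param sessions Session records of any number of weeks.
#' @return A tibble with one [summarize_week()] row per week, ordered by
#'   week index.
#' @export
summarize_weeks <- function(sessions, score_table = default_score_table(),
                            factors = default_factors()) {
  validate_sessions(sessions)
  parts <- split(sessions, sessions$week)
  out <- dplyr::bind_rows(lapply(parts, summarize_week,
                                 score_table = score_table, factors = factors))
  dplyr::arrange(out, .data$week)
}

#' Season-level training summary
#'
#' Computes the season statistic set from weekly summaries: mean and sample
#' SD (n - 1) of weekly ECOs and hours with their extreme weeks, mean (SD)
#' percent of ECOs by discipline and by phase, mean (SD) percent of training
#' time by phase, and the season polarization index, defined as the mean of
#' the defined weekly PIs (not the PI of the mean TID).
#'
#' @param weeks A tibble of weekly summaries from [summarize_weeks()].
#' @return A one-row tibble of season statistics (`*_mean`, `*_sd`, maxima
#'   and minima), including `polarization_index` and its classification.
#' @export
summarize_season <- function(weeks) {
  stopifnot(nrow(weeks) >= 1)
  m <- function(x) mean(x, na.rm = TRUE)
  s <- function(x) stats::sd(x, na.rm = TRUE)
  disc_pct <- function(d) {
    ifelse(weeks$ecos_total > 0, 100 * weeks[[paste0("ecos_", d)]] /
             weeks$ecos_total, NA_real_)
  }
  pi_season <- m(weeks$polarization_index)
  tibble::tibble(
    weeks_n = nrow(weeks),
    ecos_mean = m(weeks$ecos_total), ecos_sd = s(weeks$ecos_total),
    ecos_max = max(weeks$ecos_total), ecos_min = min(weeks$ecos_total),
    hours_mean = m(weeks$hours), hours_sd = s(weeks$hours),
    hours_max = max(weeks$hours), hours_min = min(weeks$hours),
    pct_ecos_swim_mean = m(disc_pct("swim")), pct_ecos_swim_sd = s(disc_pct("swim")),
    pct_ecos_bike_mean = m(disc_pct("bike")), pct_ecos_bike_sd = s(disc_pct("bike")),
    pct_ecos_run_mean = m(disc_pct("run")), pct_ecos_run_sd = s(disc_pct("run")),
    pct_ecos_z1_mean = m(weeks$eco_z1), pct_ecos_z1_sd = s(weeks$eco_z1),
    pct_ecos_z2_mean = m(weeks$eco_z2), pct_ecos_z2_sd = s(weeks$eco_z2),
    pct_ecos_z3_mean = m(weeks$eco_z3), pct_ecos_z3_sd = s(weeks$eco_z3),
    pct_time_z1_mean = m(weeks$time_z1), pct_time_z1_sd = s(weeks$time_z1),
    pct_time_z2_mean = m(weeks$time_z2), pct_time_z2_sd = s(weeks$time_z2),
    pct_time_z3_mean = m(weeks$time_z3), pct_time_z3_sd = s(weeks$time_z3),
    polarization_index = pi_season,
    tid_class = classify_tid(pi_season)
  )
}
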