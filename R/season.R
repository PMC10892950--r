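#' Generate a synthetic season of training sessions
#'
#' Realizes a [season_plan()] as individual swim/bike/run sessions with
#' minutes in each of the 8 intensity zones. Weekly totals track the plan:
#' hours within +/-2% of the weekly target (multiplicative jitter), the
#' time TID within +/-1.5 percentage points of the weekly target, and the
#' discipline split of training time chosen so that the resulting ECO split
#' is close to one third per leg with swimming and running slightly above
#' cycling. Within each phase, minutes are spread over that phase's zones
#' with fixed weights (phase 1 mostly zones 2--3, phase 3 mostly zone 6).
#' The sum of per-zone minutes of every session equals the session duration
#' by construction.
#'
#' @param profile An athlete profile (identifies the athlete in the log).
#' @param plan A `season_plan`.
#' @param seed Integer seed; identical seeds reproduce the season
#'   bit-for-bit.
#' @param start_date Monday anchoring week 1 (ISO week convention).
#' @param time_shares Length-3 share of weekly training time per discipline
#'   (swim, bike, run).
#' @param forced_sessions Optional session tibble returned as-is (after
#'   validation), bypassing generation — useful for degenerate plans.
#' @return A tibble of session records: `athlete_id`, `date`, `week`,
#'   `discipline`, `z1`..`z8` (minutes).
#' @export
generate_season <- function(profile, plan, seed = 1,
                            start_date = as.Date("2021-01-04"),
                            time_shares = c(swim = 0.345, bike = 0.41,
                                            run = 0.245),
                            forced_sessions = NULL) {
  validate_profile(profile)
  stopifnot(inherits(plan, "season_plan"))
  if (!is.null(forced_sessions)) {
    validate_sessions(forced_sessions)
    return(tibble::as_tibble(forced_sessions))
  }
  rng <- local_rng(seed, "season"); on.exit(rng(), add = TRUE)

  phase_map <- zone_phase()
  zone_weights <- list(`1` = c(0.15, 0.35, 0.5), `2` = c(0.55, 0.45),
                       `3` = c(0.9, 0.08, 0.02))
  disciplines <- c("swim", "bike", "run")

  weeks <- lapply(seq_len(nrow(plan)), function(i) {
    wk <- plan[i, ]
    total_min <- wk$hours * 60 * stats::runif(1, 0.98, 1.02)

    # realized weekly TID: small jitter around the plan target
    tid <- c(wk$z1, wk$z2, wk$z3) + stats::rnorm(3, 0, 0.4)
    tid <- pmax(tid, 0.2)
    tid <- 100 * tid / sum(tid)

    # discipline split of time, jittered then renormalized
    shares <- time_shares * exp(stats::rnorm(3, 0, 0.08))
    shares <- shares / sum(shares)

    rows <- list()
    for (d in seq_along(disciplines)) {
      disc_min <- total_min * shares[d]
      n_sess <- max(1L, round(disc_min / 75))
      # weekly zone minutes for this discipline
      zmin <- numeric(8)
      for (p in 1:3) {
        zmin[phase_map == p] <- disc_min * tid[p] / 100 * zone_weights[[p]]
      }
      # split every zone's minutes across the discipline's sessions
      split_w <- matrix(stats::rgamma(n_sess * 8, shape = 4), nrow = n_sess)
      split_w <- sweep(split_w, 2, colSums(split_w), "/")
      sess_zones <- sweep(split_w, 2, zmin, "*")
      day <- sort(sample(0:6, n_sess, replace = TRUE))
      for (k in seq_len(n_sess)) {
        rows[[length(rows) + 1L]] <- c(
          list(date = start_date + (wk$week - 1) * 7 + day[k],
               week = wk$week, discipline = disciplines[d]),
          stats::setNames(as.list(sess_zones[k, ]), zone_cols())
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(weeks)
  out <- dplyr::arrange(out, .data$week, .data$date, .data$discipline)
  tibble::as_tibble(cbind(athlete_id = profile$athlete_id, out))
}

#' Generate a season-long anthropometric series
#'
#' Five ISAK measurement sessions across the season (default weeks 1, 12,
#' 22, 33 and 44) with slowly decreasing skinfolds (about 12% total decline)
#' and a slight rebound at the final measurement, near-stable body mass and
#' girths — the pattern typically seen over an endurance season.
#'
#' @param profile An athlete profile.
#' @param weeks Season weeks at which measurements are taken.
#' @param seed Integer seed.
#' @param start_date Monday anchoring week 1.
#' @return A tibble of anthropometric records (one row per measurement):
#'   `date`, `week`, `body_mass`, `stature`, `age`, `sex`, six `sf_*`
#'   skinfolds (mm) and four `g_*` girths (cm).
#' @export
generate_anthro_series <- function(profile, weeks = c(1, 12, 22, 33, 44),
                                   seed = 1,
                                   start_date = as.Date("2021-01-04")) {
  validate_profile(profile)
  rng <- local_rng(seed, "anthro"); on.exit(rng(), add = TRUE)
  n <- length(weeks)
  base_sf <- c(sf_subscapular = 8, sf_triceps = 11, sf_supraspinal = 7,
               sf_abdominal = 13, sf_front_thigh = 16, sf_medial_calf = 9)
  base_g <- c(g_arm_relaxed = 26, g_arm_flexed = 27.5, g_thigh = 54,
              g_calf = 34.5)
  # decline to ~88% by the 4th measurement, slight rebound at the last
  drift <- seq(1, 0.88, length.out = max(n - 1, 1))
  drift <- c(drift, drift[length(drift)] * 1.03)[seq_len(n)]
  rows <- lapply(seq_len(n), function(i) {
    sf <- base_sf * drift[i] * exp(stats::rnorm(6, 0, 0.015))
    g <- base_g * exp(stats::rnorm(4, 0, 0.004))
    c(list(date = start_date + (weeks[i] - 1) * 7,
           week = weeks[i],
           body_mass = profile$body_mass + stats::rnorm(1, 0, 0.3),
           stature = profile$stature,
           age = profile$age, sex = profile$sex),
      as.list(sf), as.list(g))
  })
  tibble::as_tibble(dplyr::bind_rows(rows))
}
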