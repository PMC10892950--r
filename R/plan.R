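#' Build a season plan
#'
#' A season plan fixes, for every week, the periodization phase, the target
#' training hours and the target time-based training-intensity distribution
#' (TID) across the three phases of the triphasic model.
#'
#' @param hours Numeric vector of weekly target hours (one entry per week).
#' @param tid Matrix or data frame with columns `z1`, `z2`, `z3` giving the
#'   target percentage of training time per phase for each week. Each row
#'   must sum to 100 (within 0.01).
#' @param phase Character vector of periodization phases, one per week; one
#'   of `"general-prep"`, `"specific-prep"`, `"competition"`,
#'   `"accumulation"`, `"transformation"`, `"taper"`.
#' @return A tibble of class `season_plan` with columns `week`, `phase`,
#'   `hours`, `z1`, `z2`, `z3`.
#' @export
season_plan <- function(hours, tid, phase = NULL) {
  n <- length(hours)
  stopifnot(n >= 1, all(hours > 0))
  tid <- as.data.frame(tid)
  stopifnot(nrow(tid) == n, all(c("z1", "z2", "z3") %in% names(tid)))
  sums <- rowSums(tid[, c("z1", "z2", "z3")])
  if (any(abs(sums - 100) > 0.01)) {
    stop("TID percentages must sum to 100 in every week")
  }
  if (is.null(phase)) phase <- rep("general-prep", n)
  phase <- match.arg(phase, several.ok = TRUE,
                     choices = c("general-prep", "specific-prep", "competition",
                                 "accumulation", "transformation", "taper"))
  phase <- rep_len(phase, n)
  out <- tibble::tibble(week = seq_len(n), phase = phase, hours = hours,
                        z1 = tid$z1, z2 = tid$z2, z3 = tid$z3)
  class(out) <- c("season_plan", class(out))
  out
}

#' Default 50-week periodized season plan
#'
#' Emulates the season structure of an elite U23 triathlete's year: a
#' traditional periodization for the first competition block (general
#' preparation weeks 1--16, specific preparation 17--26, competitions 27--34)
#' followed by a short block periodization for the second (accumulation
#' 35--37 peaking in week 37, transformation 38--40, taper/competition to the
#' end). Weekly hours build from roughly 8 h to a season peak above 15 h with
#' a lighter recovery week every fourth week, then are rescaled so the season
#' mean equals `mean_hours`. The TID is polarized in most weeks
#' (around 82/6/12 % of time in phases 1/2/3) with occasional more pyramidal
#' weeks during the preparatory periods.
#'
#' @param n_weeks Number of weeks in the season (default 50).
#' @param mean_hours Season mean of weekly training hours (default 12.2).
#' @param peak_hours Target maximum weekly hours (default 17.6).
#' @param min_hours Lower clamp on weekly hours (default 5.5).
#' @param tid_target Length-3 base TID (percent time in phases 1--3).
#' @return A `season_plan` tibble.
#' @export
default_season_plan <- function(n_weeks = 50, mean_hours = 12.2,
                                peak_hours = 17.6, min_hours = 5.5,
                                tid_target = c(82, 6, 12)) {
  stopifnot(n_weeks >= 1, mean_hours > 0, peak_hours >= mean_hours,
            length(tid_target) == 3, abs(sum(tid_target) - 100) < 0.01)
  w <- seq_len(n_weeks)

  phase <- rep("taper", n_weeks)
  phase[w <= min(16, n_weeks)] <- "general-prep"
  phase[w > 16 & w <= 26] <- "specific-prep"
  phase[w > 26 & w <= 34] <- "competition"
  phase[w > 34 & w <= 37] <- "accumulation"
  phase[w > 37 & w <= 40] <- "transformation"
  phase[w > 40] <- "taper"

  # hour template: linear build, dip in competition weeks, peak at the end of
  # the accumulation block, taper afterwards; every 4th week is a recovery week
  rel <- 0.75 + 0.5 * pmin(w, 20) / 20
  rel[phase == "competition"] <- 0.95
  rel[phase == "accumulation"] <- c(1.15, 1.3, 1.5)[seq_len(sum(phase == "accumulation"))]
  rel[phase == "transformation"] <- 1.1
  rel[phase == "taper"] <- seq(0.95, 0.55, length.out = sum(phase == "taper"))
  rel[w %% 4 == 0 & phase %in% c("general-prep", "specific-prep")] <-
    rel[w %% 4 == 0 & phase %in% c("general-prep", "specific-prep")] * 0.7

  hours <- rel / mean(rel) * mean_hours
  peak_i <- which.max(hours)
  hours[peak_i] <- peak_hours
  hours <- hours / mean(hours) * mean_hours
  hours[peak_i] <- max(hours[peak_i], peak_hours)  # keep the season peak
  hours <- pmax(hours, min_hours)

  # pyramidal weeks: early-season weeks shift time from phase 3 into phase 2
  tid <- matrix(rep(tid_target, n_weeks), ncol = 3, byrow = TRUE,
                dimnames = list(NULL, c("z1", "z2", "z3")))
  pyramidal <- which(phase %in% c("general-prep", "accumulation") & w %% 3 == 1)
  tid[pyramidal, 2] <- tid[pyramidal, 2] + 5
  tid[pyramidal, 3] <- pmax(tid[pyramidal, 3] - 5, 1)
  tid[pyramidal, 1] <- 100 - tid[pyramidal, 2] - tid[pyramidal, 3]

  season_plan(hours, as.data.frame(tid), phase)
}
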