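#' @title Delimited file formats
#' @description
#' Comma-separated, header-row formats for traces, lactate curves, session
#' logs and anthropometric records. Generated traces carry a YAML sidecar
#' (`<file>.yml`) recording the protocol and the planted truth so recovery
#' studies can reload them.
#' @name io
NULL

#' Write / read a session log
#'
#' Columns: `athlete_id` (optional), `date` (ISO-8601), `week` (1-based),
#' `discipline`, `z1`..`z8` minutes. On reading, malformed rows are rejected
#' with line-numbered messages.
#'
#' @param sessions Session tibble.
#' @param path File path.
#' @return `read_session_log()` returns the validated session tibble;
#'   `write_session_log()` returns `path` invisibly.
#' @export
write_session_log <- function(sessions, path) {
  validate_sessions(sessions)
  utils::write.csv(as.data.frame(sessions), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "week", "discipline", zone_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("session log misses columns: ", paste(miss, collapse = ", "))
  zm <- as.matrix(df[, zone_cols()])
  problems <- character()
  bad_neg <- which(apply(zm < 0 | is.na(zm), 1, any))
  if (length(bad_neg)) {
    problems <- c(problems, sprintf("line %d: negative or missing minutes",
                                    bad_neg + 1L))
  }
  bad_disc <- which(!df$discipline %in% c("swim", "bike", "run", "strength"))
  if (length(bad_disc)) {
    problems <- c(problems, sprintf("line %d: unknown discipline '%s'",
                                    bad_disc + 1L, df$discipline[bad_disc]))
  }
  bad_week <- which(is.na(suppressWarnings(as.integer(df$week))) | df$week < 1)
  if (length(bad_week)) {
    problems <- c(problems, sprintf("line %d: invalid week index", bad_week + 1L))
  }
  if (length(problems)) stop("invalid session log:\n",
                             paste(problems, collapse = "\n"))
  df$date <- as.Date(df$date)
  df$week <- as.integer(df$week)
  tibble::as_tibble(df)
}

#' Write / read a gas-exchange trace
#'
#' The trace samples go to `path` as CSV; the discipline, body mass,
#' protocol and any planted truth go to a YAML sidecar at `<path>.yml`,
#' restored on reading when present. The same reader accepts real exported
#' tables with identical headers (then without protocol metadata).
#'
#' @param trace A `gas_trace`.
#' @param path CSV file path.
#' @return `read_trace()` returns the `gas_trace`; the writer returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gas_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(discipline = attr(trace, "discipline"),
               body_mass = attr(trace, "body_mass"),
               protocol = attr(trace, "protocol"),
               truth = attr(trace, "truth"))
  yaml::write_yaml(meta, paste0(path, ".yml"), precision = 15)
  invisible(path)
}

#' @rdname write_trace
#' @param body_mass Body mass (kg) used for the ventilatory-equivalent
#'   computation when the sidecar is absent.
#' @export
read_trace <- function(path, body_mass = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  protocol <- meta$protocol
  if (!is.null(protocol) && identical(protocol$type, "stages")) {
    protocol$speeds <- as.numeric(protocol$speeds)
    protocol$durations <- as.numeric(protocol$durations)
    protocol$boundaries <- as.numeric(protocol$boundaries)
  }
  new_gas_trace(df, meta$discipline,
                body_mass %||% meta$body_mass, protocol, meta$truth)
}

#' Write / read a swim lactate curve
#' @param curve A `lactate_curve`.
#' @param path CSV file path.
#' @return `read_lactate_curve()` returns the `lactate_curve`; the writer
#'   returns `path` invisibly.
#' @export
write_lactate_curve <- function(curve, path) {
  stopifnot(inherits(curve, "lactate_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  if (!is.null(attr(curve, "truth"))) {
    yaml::write_yaml(list(truth = attr(curve, "truth")), paste0(path, ".yml"),
                     precision = 15)
  }
  invisible(path)
}

#' @rdname write_lactate_curve
#' @export
read_lactate_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(path, ".yml")
  truth <- if (file.exists(side)) yaml::read_yaml(side)$truth else NULL
  new_lactate_curve(df, truth)
}

#' Write / read anthropometric records
#' @param records Anthropometric record tibble.
#' @param path CSV file path.
#' @return `read_anthro_records()` returns the validated tibble; the writer
#'   returns `path` invisibly.
#' @export
write_anthro_records <- function(records, path) {
  validate_anthro(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_anthro_records
#' @export
read_anthro_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tibble::as_tibble(utils::read.csv(path))
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  validate_anthro(df)
  df
}

#' Bundled example data sets
#'
#' `example_markers()`: physiological and performance markers of three elite
#' U23 female triathletes measured in two incremental-test sessions (season
#' weeks 4 and 16): swim last-repetition and lactate-threshold speeds,
#' cycling power and running speed at VO2max and at the ventilatory
#' thresholds, and maximal heart rates, together with the percent change
#' reported at the time. `example_season_summary()`: the same athletes'
#' season training summaries (weekly ECOs and hours, percent ECOs by
#' discipline and phase, percent training time by phase, polarization
#' index).
#'
#' @return A tibble.
#' @export
example_markers <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "example_markers.csv", package = "triseason",
                mustWork = TRUE)))
}

#' @rdname example_markers
#' @export
example_season_summary <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "example_season_summary.csv", package = "triseason",
                mustWork = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
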