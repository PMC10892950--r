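#' Pipeline configuration
#'
#' Collects every operationalized constant of the analysis in one validated
#' object: the 8-zone ECO score table, the discipline factors, the trace
#' binning and Davis-criteria detection parameters, the lactate fixed-rise
#' parameters, the polarization-index cut-off and the random seed.
#'
#' @param score_table 8 non-decreasing zone scores in 1--50.
#' @param factors Named discipline factors in (0, 1].
#' @param bin_width_s Cycling bin width in seconds (track tests always bin
#'   per stage).
#' @param window Detection window in bins.
#' @param flat_tol Slope flatness tolerance (fraction of channel IQR).
#' @param lt_rise1,lt_rise2 Lactate rises (mmol/L) defining LT1/LT2.
#' @param pi_threshold Polarization cut-off (a.u.).
#' @param seed Integer random seed.
#' @return A `pipeline_config` list with a `digest` identifying the
#'   configuration.
#' @export
pipeline_config <- function(score_table = default_score_table(),
                            factors = default_factors(),
                            bin_width_s = 30, window = 3, flat_tol = 0.05,
                            lt_rise1 = 0.5, lt_rise2 = 1.0,
                            pi_threshold = 2.0, seed = 1L) {
  stopifnot(length(score_table) == 8, all(diff(score_table) >= 0),
            all(score_table >= 1 & score_table <= 50),
            all(factors > 0 & factors <= 1),
            all(c("swim", "bike", "run") %in% names(factors)),
            bin_width_s > 0, window >= 2, flat_tol > 0,
            lt_rise1 > 0, lt_rise2 > 0, pi_threshold > 0)
  cfg <- list(score_table = score_table, factors = factors,
              bin_width_s = bin_width_s, window = window,
              flat_tol = flat_tol, lt_rise1 = lt_rise1, lt_rise2 = lt_rise2,
              pi_threshold = pi_threshold, seed = as.integer(seed))
  tmp <- tempfile(); on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  cfg$digest <- unname(tools::md5sum(tmp))
  structure(cfg, class = "pipeline_config")
}

#' Run the full season-analysis pipeline
#'
#' Executes the analysis stages on whatever inputs are supplied:
#' thresholds from the incremental tests, zone models anchored at the
#' thresholds, weekly and season load/TID summaries from the session log,
#' the body-composition evolution, and the test-1 vs test-2 comparison
#' table. Stages whose inputs are missing are skipped, and their absence is
#' noted in the bundle; identical config and inputs yield an identical
#' bundle.
#'
#' @param inputs A list with any of: `test1`, `test2` (each a list with
#'   `bike`, `run` `gas_trace`s and `swim` `lactate_curve`), `sessions`
#'   (session tibble) and `anthro` (anthropometric records).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage output is
#'   written as a delimited file plus a `manifest.yml` carrying the config
#'   (including its digest).
#' @return A `pipeline_bundle` list: `config`, `reports`, `zone_models`,
#'   `weeks`, `season`, `evolution`, `comparison`, `notes`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character()
  bundle <- list(config = config)

  make_report <- function(tests, label) {
    if (is.null(tests)) return(NULL)
    for (part in c("bike", "run", "swim")) {
      if (is.null(tests[[part]])) {
        notes <<- c(notes, sprintf("%s: %s test missing; its markers omitted",
                                   label, part))
      }
    }
    threshold_report(
      bike_trace = tests$bike, run_trace = tests$run, lactate = tests$swim,
      body_mass = tests$body_mass
    )
  }
  bundle$reports <- list(test1 = make_report(inputs$test1, "test1"),
                         test2 = make_report(inputs$test2, "test2"))

  ref <- bundle$reports$test2 %||% bundle$reports$test1
  if (!is.null(ref)) {
    bundle$zone_models <- list()
    for (d in c("bike", "run", "swim")) {
      bundle$zone_models[[d]] <- tryCatch(
        build_zone_model(ref, d, score_table = config$score_table),
        error = function(e) {
          notes <<- c(notes, sprintf("zones/%s: %s", d, conditionMessage(e)))
          NULL
        })
    }
  }

  if (!is.null(inputs$sessions)) {
    bundle$weeks <- summarize_weeks(inputs$sessions,
                                    score_table = config$score_table,
                                    factors = config$factors)
    bundle$season <- summarize_season(bundle$weeks)
  } else {
    notes <- c(notes, "no session log: load/TID stages skipped")
  }

  if (!is.null(inputs$anthro) && nrow(inputs$anthro) >= 2) {
    bundle$evolution <- track_season(inputs$anthro)
  } else {
    notes <- c(notes, "no anthropometric series: evolution stage skipped")
  }

  if (!is.null(bundle$reports$test1) && !is.null(bundle$reports$test2)) {
    bundle$comparison <- withCallingHandlers(
      build_comparison(bundle$reports$test1, bundle$reports$test2),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else {
    notes <- c(notes, "fewer than two test sessions: comparison skipped")
  }

  bundle$notes <- notes
  class(bundle) <- "pipeline_bundle"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      if (!is.null(x)) utils::write.csv(as.data.frame(x),
                                        file.path(out_dir, name),
                                        row.names = FALSE)
    }
    wr(bundle$weeks, "week_summaries.csv")
    wr(bundle$season, "season_summary.csv")
    wr(bundle$evolution, "anthro_evolution.csv")
    wr(bundle$comparison, "comparison.csv")
    yaml::write_yaml(list(config = unclass(config), notes = notes),
                     file.path(out_dir, "manifest.yml"))
  }
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n")
  cat("  stages:", paste(setdiff(names(x), c("config", "notes")),
                         collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:\n", paste("   -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
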