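#' @title ISAK body-composition estimation
#' @description
#' Sum of six skinfolds, fat percentage via the Withers female body-density
#' equation with the Siri transform, skeletal muscle mass via the Lee
#' anthropometric model with fold-corrected girths, and season tracking of
#' these markers. Equation coefficients are vendored as a constants file
#' (`inst/extdata/anthro_equations.yaml`) with a frozen worked example
#' rather than buried in code.
#' @name anthropometry
NULL

sf_cols <- function() paste0("sf_", c("subscapular", "triceps", "supraspinal",
                                      "abdominal", "front_thigh",
                                      "medial_calf"))
g_cols <- function() paste0("g_", c("arm_relaxed", "arm_flexed", "thigh",
                                    "calf"))

#' Vendored body-composition equation constants
#' @return Named list parsed from the package constants file.
#' @export
anthro_constants <- function() {
  yaml::read_yaml(system.file("extdata", "anthro_equations.yaml",
                              package = "triseason", mustWork = TRUE))
}

validate_anthro <- function(records) {
  need <- c("body_mass", "stature", sf_cols(), g_cols())
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("anthro record misses: ", paste(miss, collapse = ", "))
  vals <- as.matrix(records[, need])
  if (any(vals <= 0)) stop("all anthropometric measurements must be positive")
  invisible(records)
}

#' Sum of the six ISAK skinfolds
#'
#' @param records Anthropometric records (rows) with the six `sf_*` columns
#'   in mm.
#' @return Numeric vector of fold sums (mm), one per record.
#' @export
sum_skinfolds <- function(records) {
  validate_anthro(records)
  unname(rowSums(records[, sf_cols()]))
}

#' Fat percentage from skinfolds
#'
#' Body density from the vendored Withers female skinfold equation
#' (log10 of the sum of the triceps, subscapular, supraspinal and medial
#' calf folds), converted to percent fat with the Siri (default) or Brozek
#' transform. Densities outside the plausible range are flagged and returned
#' as `NA` with a warning.
#'
#' @param records Anthropometric records.
#' @param transform `"siri"` or `"brozek"`.
#' @return Fat percentage per record.
#' @export
fat_percentage <- function(records, transform = c("siri", "brozek")) {
  validate_anthro(records)
  transform <- match.arg(transform)
  k <- anthro_constants()
  eq <- k$withers_female
  folds <- rowSums(records[, paste0("sf_", eq$skinfolds)])
  density <- eq$intercept - eq$slope * log10(folds)
  lim <- eq$density_plausible
  bad <- density <= lim[1] | density >= lim[2]
  if (any(bad)) {
    warning(sum(bad), " record(s) with implausible body density flagged NA")
    density[bad] <- NA_real_
  }
  tr <- k[[transform]]
  unname(tr$numerator / density - tr$offset)
}

#' Skeletal muscle mass from girths and folds
#'
#' Girths are corrected for the overlying skinfold
#' (`girth_cm - pi * fold_mm / 10`) and fed to the vendored Lee
#' anthropometric model together with stature, age and sex.
#'
#' @param records Anthropometric records with `age` (years) and `sex`
#'   (`"female"`/`"male"`) columns.
#' @return Skeletal muscle mass in kg per record.
#' @export
muscle_mass <- function(records) {
  validate_anthro(records)
  k <- anthro_constants()$lee_muscle
  pairs <- k$girth_fold_pairs
  cg <- sapply(names(pairs), function(girth) {
    records[[paste0("g_", girth)]] - pi * records[[paste0("sf_", pairs[[girth]])]] / 10
  })
  cg <- matrix(cg, ncol = length(pairs),
               dimnames = list(NULL, names(pairs)))
  if (any(cg <= 0)) stop("fold-corrected girth is non-positive")
  sex_num <- ifelse(records$sex == "male", 1, 0)
  ht_m <- records$stature / 100
  unname(ht_m * (k$c_arm * cg[, "arm_relaxed"]^2 +
                   k$c_thigh * cg[, "thigh"]^2 +
                   k$c_calf * cg[, "calf"]^2) +
           k$sex_coef * sex_num + k$age_coef * records$age +
           k$race_coef + k$intercept)
}

#' Season evolution of body composition
#'
#' For an ordered series of measurement sessions, computes the sum of six
#' skinfolds, fat percentage, skeletal muscle mass and lean mass
#' (`body_mass * (1 - fat_pct / 100)`), plus each marker's change relative
#' to the first measurement.
#'
#' @param records At least two anthropometric records, in measurement order.
#' @param transform Density-to-fat transform, see [fat_percentage()].
#' @return A tibble with one row per measurement: the four markers and
#'   their `delta_*` columns versus the first measurement.
#' @export
track_season <- function(records, transform = "siri") {
  validate_anthro(records)
  if (nrow(records) < 2) stop("need at least 2 measurements to track a season")
  out <- tibble::tibble(
    measurement = seq_len(nrow(records)),
    date = if ("date" %in% names(records)) records$date else NA,
    body_mass = records$body_mass,
    sum6 = sum_skinfolds(records),
    fat_pct = fat_percentage(records, transform),
    muscle_mass = muscle_mass(records)
  )
  out$lean_mass <- out$body_mass * (1 - out$fat_pct / 100)
  for (v in c("body_mass", "sum6", "fat_pct", "muscle_mass", "lean_mass")) {
    out[[paste0("delta_", v)]] <- out[[v]] - out[[v]][1]
  }
  out
}
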