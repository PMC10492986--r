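# Synthetic adolescent cohorts with known ground truth.
#
# Latent standardized compartment scores (z_nat, z_sat, z_vat) are drawn from
# a correlated trivariate normal; cardiovascular outcomes are built on the
# standardized scale as effects %*% predictors + noise, with the residual
# variance chosen so every outcome has unit variance; raw columns are then
# affine (or, for the skewed variables, shifted-lognormal) maps of the
# latents, anchored to the magnitudes a neck-to-knee adolescent cohort
# reports. Pulse pressure and mean BP are derived from the generated
# systolic/diastolic pressures, not planted independently.

#' Default planted effect matrix
#'
#' Standardized effects of \{nat, sat, vat, age, sex\} on each directly
#' generated outcome. The default plants the qualitative pattern reported for
#' adolescent 3-compartment analyses: nonadipose tissue drives LV mass,
#' LVEDV, SV, mass:EDV and systolic BP (positively) and heart rate
#' (negatively); subcutaneous fat drives worse diastolic ratios, higher
#' diastolic BP and heart rate, higher CO/TAC and lower SVR; visceral fat
#' drives nothing.
#'
#' @param outcomes outcome names (directly generated set).
#' @return numeric matrix, rows `nat`, `sat`, `vat`, `age`, `sex`.
#' @export
default_effects <- function(outcomes = setdiff(cardiovascular_outcomes(),
                                               c("mbp", "pulse_pressure"))) {
  eff <- matrix(0, nrow = 5, ncol = length(outcomes),
                dimnames = list(c("nat", "sat", "vat", "age", "sex"), outcomes))
  planted <- list(
    nat = c(lv_mass = 0.8, lvedv = 0.7, sv = 0.64, mass_to_edv = 0.37,
            sbp = 0.35, heart_rate = -0.33),
    sat = c(e_a = -0.48, septal_ea = -0.45, lateral_ea = -0.42, dbp = 0.42,
            svr = -0.35, heart_rate = 0.34, co = 0.3, tac = 0.25),
    age = c(sbp = 0.1, lvedv = 0.1),
    sex = c(lv_mass = 0.25, sv = 0.2))
  for (pred in names(planted)) {
    hit <- intersect(names(planted[[pred]]), outcomes)
    eff[pred, hit] <- planted[[pred]][hit]
  }
  eff
}

#' Specify a synthetic cohort
#'
#' @param n subjects (>= 10).
#' @param effects standardized effect matrix (rows `nat`, `sat`, `vat`,
#'   `age`, `sex`; columns outcomes); see [default_effects()]. A zero matrix
#'   gives a null cohort.
#' @param compartment_cor 3x3 correlation matrix of the latent nat/sat/vat
#'   scores (must be positive definite).
#' @param skewed_vars which raw compartment columns are drawn as
#'   shifted lognormals of their latent (default `sat` and `vat`), so the
#'   zero-skewness transform stage is exercised.
#' @param n_clinic number of obesity-clinic recruits to flag (the subjects
#'   with the highest BMI z-scores).
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 82L, effects = default_effects(),
                        compartment_cor = matrix(c(1, 0.5, 0.35,
                                                   0.5, 1, 0.6,
                                                   0.35, 0.6, 1), 3, 3),
                        skewed_vars = c("sat", "vat"), n_clinic = 3L, seed = 1L) {
  if (n < 10L) stop_validation("n must be >= 10")
  if (!all(rownames(effects) == c("nat", "sat", "vat", "age", "sex"))) {
    stop_validation("effects rows must be nat, sat, vat, age, sex")
  }
  ev <- eigen(compartment_cor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) stop_validation("compartment_cor is not positive definite")
  # full predictor correlation: compartments correlated, age/sex independent
  sigma <- diag(5)
  sigma[1:3, 1:3] <- compartment_cor
  expl <- colSums(effects * (sigma %*% effects))
  if (any(expl >= 1)) {
    stop_validation("effects imply non-positive residual variance for: ",
                    paste(colnames(effects)[expl >= 1], collapse = ", "))
  }
  structure(class = "cohort_spec", list(
    n = as.integer(n), effects = effects, compartment_cor = compartment_cor,
    sigma = sigma, skewed_vars = skewed_vars, n_clinic = as.integer(n_clinic),
    seed = as.integer(seed)))
}

# raw-scale anchors: centre and spread per outcome
OUTCOME_SCALE <- list(
  sbp = c(113, 8), dbp = c(59, 6), svr = c(14, 2.5), co = c(5.9, 1.1),
  sv = c(87, 15), heart_rate = c(68, 10), lvedv = c(147, 22), lvef = c(62, 5),
  lv_mass = c(108, 28), mass_to_edv = c(0.78, 0.09), e_a = c(1.75, 0.45),
  septal_ea = c(2.1, 0.5), lateral_ea = c(2.8, 0.6), pwv_aao = c(4.2, 1.1),
  pwv_dao = c(3.9, 1.1), tac = c(1.65, 0.35))

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @param reference LMS reference for the derived anthropometric z-scores.
#' @return data.frame of class `cohort_table`, one row per subject, with
#'   attributes `effects` (the true standardized effect matrix), `latents`
#'   (the latent standardized compartment scores) and `spec`.
#' @export
generate_cohort <- function(spec, reference = synthetic_lms_reference()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  L <- chol(spec$compartment_cor)
  z3 <- matrix(stats::rnorm(n * 3), n, 3) %*% L   # z_nat, z_sat, z_vat
  age <- stats::runif(n, 13, 18)
  p_male <- 0.56                                  # 36/82 female
  sex <- stats::rbinom(n, 1L, p_male)
  z_age <- (age - 15.5) / sqrt((18 - 13)^2 / 12)
  z_sex <- (sex - p_male) / sqrt(p_male * (1 - p_male))
  Z <- cbind(z3, z_age, z_sex)

  outcomes <- colnames(spec$effects)
  expl <- colSums(spec$effects * (spec$sigma %*% spec$effects))
  zout <- Z %*% spec$effects +
    matrix(stats::rnorm(n * length(outcomes)), n) %*% diag(sqrt(1 - expl),
                                                           length(outcomes))
  colnames(zout) <- outcomes

  cohort <- data.frame(id = sprintf("S%03d", seq_len(n)), age = age, sex = sex)
  # compartments: nat normal; sat/vat shifted-lognormal when listed as skewed
  cohort$nat <- 34 + 6.5 * z3[, 1]
  cohort$sat <- if ("sat" %in% spec$skewed_vars) {
    2 + exp(log(13) + 0.55 * z3[, 2])
  } else 15 + 6 * z3[, 2]
  cohort$vat <- if ("vat" %in% spec$skewed_vars) {
    0.15 + exp(log(0.65) + 0.6 * z3[, 3])
  } else 0.8 + 0.35 * z3[, 3]
  cohort$nat <- pmax(cohort$nat, 5)

  height_z <- 0.7 * z3[, 1] + sqrt(1 - 0.49) * stats::rnorm(n)
  cohort$height <- 163 + 6.5 * height_z + 7 * sex
  # slab covers roughly 70% of body mass; tissue densities ~1.05 / 0.92 g/mL
  cohort$weight <- (1.05 * cohort$nat + 0.92 * (cohort$sat + cohort$vat)) / 0.72 +
    stats::rnorm(n, 0, 2)
  cohort$weight <- pmax(cohort$weight, 25)
  cohort$waist <- 58 + 0.95 * cohort$sat + 6 * cohort$vat + 2 * sex +
    stats::rnorm(n, 0, 2.5)

  for (oc in outcomes) {
    sc <- OUTCOME_SCALE[[oc]] %||% c(0, 1)
    cohort[[oc]] <- sc[1] + sc[2] * zout[, oc]
  }
  # derived pressures: identity holds by construction
  cohort$pulse_pressure <- pmax(cohort$sbp - cohort$dbp, 5)
  cohort$mbp <- cohort$dbp + cohort$pulse_pressure / 3

  cohort <- anthro_augment(cohort, reference)
  cohort$clinic_recruit <- rank(-cohort$bmi_z, ties.method = "first") <= spec$n_clinic

  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "effects") <- spec$effects
  attr(cohort, "latents") <- data.frame(z_nat = z3[, 1], z_sat = z3[, 2],
                                        z_vat = z3[, 3])
  attr(cohort, "spec") <- spec
  cohort
}

#' Write / read a cohort table as CSV
#' @param cohort a cohort data.frame.
#' @param path CSV path.
#' @return `path` / the cohort.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$weight_status <- as.character(out$weight_status)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_validation("cohort CSV not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(cohort$id)) stop_validation("duplicated subject ids")
  if ("weight_status" %in% names(cohort)) {
    cohort$weight_status <- factor(cohort$weight_status,
      levels = c("underweight/out-of-range", "normal", "overweight/obese"))
  }
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
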