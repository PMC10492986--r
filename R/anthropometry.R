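# Anthropometry: BMI, Haycock body surface area, LMS z-scores and the
# WHO-style weight-status classification used for two-group comparisons.

#' Body mass index
#'
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @return BMI in kg/m2.
#' @export
bmi <- function(height_cm, weight_kg) {
  check_positive(height_cm, "height_cm"); check_positive(weight_kg, "weight_kg")
  weight_kg / (height_cm / 100)^2
}

#' Haycock body surface area
#'
#' BSA = 0.024265 x weight^0.5378 x height^0.3964 (weight kg, height cm).
#'
#' @inheritParams bmi
#' @return BSA in m2.
#' @export
bsa_haycock <- function(height_cm, weight_kg) {
  check_positive(height_cm, "height_cm"); check_positive(weight_kg, "weight_kg")
  0.024265 * weight_kg^0.5378 * height_cm^0.3964
}

#' Load an LMS reference table
#'
#' Schema: columns `measure`, `sex` (`"female"`/`"male"`), `age_years`, `L`,
#' `M`, `S`. Published references (e.g. WHO BMI-for-age, waist and
#' waist:height tables) can be dropped in as CSVs with this schema; the
#' package bundles a clearly synthetic reference for tests and demos.
#'
#' @param path CSV path; default is the bundled synthetic reference.
#' @return data.frame of class `lms_reference`.
#' @export
load_lms_reference <- function(path = system.file("extdata", "lms_synthetic.csv",
                                                  package = "bodycomp3")) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measure", "sex", "age_years", "L", "M", "S")
  if (!all(need %in% names(ref))) {
    stop_validation("LMS reference must have columns ", paste(need, collapse = ", "))
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop_validation("LMS reference needs M > 0 and S > 0")
  ref <- ref[order(ref$measure, ref$sex, ref$age_years), ]
  class(ref) <- c("lms_reference", "data.frame")
  ref
}

# interpolate L, M, S at the requested ages (linear in age, per sex/measure)
lms_at <- function(reference, measure, sex, age) {
  sub <- reference[reference$measure == measure & reference$sex == as.character(sex), ]
  if (!nrow(sub)) stop_validation("no LMS rows for measure '", measure, "', sex '", sex, "'")
  span <- range(sub$age_years)
  if (any(age < span[1] | age > span[2])) {
    stop_validation("age outside the reference span [", span[1], ", ", span[2],
                    "] years for measure '", measure, "'")
  }
  list(L = stats::approx(sub$age_years, sub$L, xout = age)$y,
       M = stats::approx(sub$age_years, sub$M, xout = age)$y,
       S = stats::approx(sub$age_years, sub$S, xout = age)$y)
}

#' LMS z-score
#'
#' z = ((x/M)^L - 1) / (L S), with the limit ln(x/M)/S as L -> 0. L, M and S
#' are interpolated linearly in age within sex and measure.
#'
#' @param value measurement (same units as the reference's M).
#' @param age age in years (within the reference span).
#' @param sex `"female"` or `"male"` (vectorized).
#' @param reference an [load_lms_reference()] table.
#' @param measure which reference measure to use.
#' @return z-score(s).
#' @export
lms_zscore <- function(value, age, sex, reference, measure = "bmi") {
  check_positive(value, "value")
  n <- max(length(value), length(age), length(sex))
  value <- rep_len(value, n); age <- rep_len(age, n); sex <- rep_len(as.character(sex), n)
  z <- numeric(n)
  for (s in unique(sex)) {
    i <- sex == s
    p <- lms_at(reference, measure, s, age[i])
    small <- abs(p$L) < 1e-7
    zi <- ((value[i] / p$M)^p$L - 1) / (p$L * p$S)
    zi[small] <- log(value[i][small] / p$M[small]) / p$S[small]
    z[i] <- zi
  }
  z
}

#' Invert an LMS z-score back to the measurement scale
#'
#' @inheritParams lms_zscore
#' @param z z-score(s).
#' @return measurement value(s).
#' @export
lms_inverse <- function(z, age, sex, reference, measure = "bmi") {
  n <- max(length(z), length(age), length(sex))
  z <- rep_len(z, n); age <- rep_len(age, n); sex <- rep_len(as.character(sex), n)
  out <- numeric(n)
  for (s in unique(sex)) {
    i <- sex == s
    p <- lms_at(reference, measure, s, age[i])
    small <- abs(p$L) < 1e-7
    xi <- p$M * (1 + p$L * p$S * z[i])^(1 / p$L)
    xi[small] <- p$M[small] * exp(p$S[small] * z[i][small])
    out[i] <- xi
  }
  out
}

#' Weight-status classification from the BMI z-score
#'
#' Cut-offs: z > 1 overweight/obese; -2 < z <= 1 normal; z <= -2
#' underweight/out-of-range (flagged and excluded from two-group analyses).
#'
#' @param bmi_z BMI z-score(s).
#' @return factor with levels `underweight/out-of-range`, `normal`,
#'   `overweight/obese`.
#' @export
classify_weight_status <- function(bmi_z) {
  if (any(!is.finite(bmi_z))) stop_validation("bmi_z must be finite")
  cut(bmi_z, breaks = c(-Inf, -2, 1, Inf),
      labels = c("underweight/out-of-range", "normal", "overweight/obese"),
      right = TRUE)
}

#' Build the bundled synthetic LMS reference
#'
#' A smooth, clearly synthetic LMS table (ages 10-22, both sexes, measures
#' `bmi` kg/m2, `waist` cm, `waist_height` unitless) for tests and demos. It
#' is not a growth standard; swap in published tables for real analyses.
#'
#' @return data.frame of class `lms_reference`.
#' @export
synthetic_lms_reference <- function() {
  ages <- seq(10, 22, by = 0.5)
  grid <- expand.grid(sex = c("female", "male"), age_years = ages,
                      stringsAsFactors = FALSE)
  male <- as.numeric(grid$sex == "male")
  build <- function(measure, L, M, S) {
    data.frame(measure = measure, sex = grid$sex, age_years = grid$age_years,
               L = L, M = M, S = S)
  }
  ref <- rbind(
    build("bmi",
          L = -1.6 + 0.02 * (grid$age_years - 16),
          M = 15.6 + 0.45 * grid$age_years - 0.35 * male,
          S = 0.115 + 0.01 * male),
    build("waist",
          L = -0.8 - 0.1 * male,
          M = 47 + 1.55 * grid$age_years + 2.2 * male,
          S = 0.095 + 0.01 * male),
    build("waist_height",
          L = -1.1,
          M = 0.452 - 0.002 * (grid$age_years - 16) + 0.008 * male,
          S = 0.075))
  ref <- ref[order(ref$measure, ref$sex, ref$age_years), ]
  rownames(ref) <- NULL
  class(ref) <- c("lms_reference", "data.frame")
  ref
}

#' Anthropometric summary for a cohort table
#'
#' Adds `bmi`, `bsa`, `bmi_z`, `waist_z`, `waist_height_z` and `weight_status`
#' columns from raw height/weight/waist/age/sex.
#'
#' @param cohort data.frame with columns `height`, `weight`, `waist`, `age`,
#'   `sex` (0 = female, 1 = male, or `"female"`/`"male"`).
#' @param reference an LMS reference table.
#' @return the cohort with derived columns appended.
#' @export
anthro_augment <- function(cohort, reference = synthetic_lms_reference()) {
  need <- c("height", "weight", "waist", "age", "sex")
  if (!all(need %in% names(cohort))) {
    stop_validation("cohort needs columns ", paste(need, collapse = ", "))
  }
  sex_chr <- if (is.numeric(cohort$sex)) {
    ifelse(cohort$sex > 0, "male", "female")
  } else as.character(cohort$sex)
  cohort$bmi <- bmi(cohort$height, cohort$weight)
  cohort$bsa <- bsa_haycock(cohort$height, cohort$weight)
  cohort$bmi_z <- lms_zscore(cohort$bmi, cohort$age, sex_chr, reference, "bmi")
  cohort$waist_z <- lms_zscore(cohort$waist, cohort$age, sex_chr, reference, "waist")
  cohort$waist_height_z <- lms_zscore(cohort$waist / cohort$height, cohort$age,
                                      sex_chr, reference, "waist_height")
  cohort$weight_status <- classify_weight_status(cohort$bmi_z)
  cohort
}
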