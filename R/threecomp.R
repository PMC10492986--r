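# Statistical core: zero-skewness log transform, OLS residualization, the
# sequential 3-compartment construction (NAT, rSAT, rVAT), standardized
# age/sex-adjusted association models, the model grids and the
# clinic-recruit sensitivity re-run.

#' Zero-skewness log transform
#'
#' Finds the shift k such that `ln(x - k)` has exactly zero sample skewness
#' (the transform Stata exposes as `lnskew0`). For negatively skewed input
#' the mirrored form `ln(k - x)` is used. k is located by root-finding on the
#' sample skewness of the transformed values.
#'
#' @param x numeric sample, length >= 8, non-constant.
#' @param tol tolerance on the transformed skewness.
#' @return list with `k` (shift), `y` (transformed sample), `sign` (+1 for
#'   `ln(x - k)`, -1 for `ln(k - x)`), `skewness` (of `y`).
#' @export
lnskew0 <- function(x, tol = 1e-8) {
  x <- x[is.finite(x)]
  if (length(x) < 8L) stop_validation("lnskew0 needs at least 8 finite values")
  if (stats::sd(x) == 0) stop_validation("lnskew0 undefined for a constant sample")
  g1 <- sample_skewness(x)
  sgn <- if (g1 >= 0) 1 else -1
  z <- sgn * x                      # positively skewed working sample
  rng <- diff(range(z))
  if (abs(g1) < tol) {
    # already zero-skew to tolerance: a far shift leaves the sample affine;
    # pick the shift magnitude that best preserves zero skewness numerically
    ks <- min(z) - 10^seq(6, 14) * rng
    sk <- vapply(ks, function(k) abs(sample_skewness(log(z - k))), 0)
    sk[!is.finite(sk)] <- Inf
    k <- ks[which.min(sk)]
    y <- log(z - k)
    return(list(k = sgn * k, y = y, sign = sgn, skewness = sample_skewness(y)))
  }
  f <- function(k) sample_skewness(log(z - k))
  lo <- min(z) - 1e6 * rng          # ~affine: skewness ~ skew(z) > 0
  hi <- min(z) - 1e-9 * rng         # left tail stretched: skewness -> -Inf
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0 || fhi >= 0) {
    stop_estimation("no zero-skewness root in bracket [", format(lo), ", ",
                    format(hi), "]; skewness at ends ", format(flo), " / ", format(fhi))
  }
  k <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75,
                      maxiter = 2000L)$root
  # polish until the skewness criterion itself is met
  for (i in 1:50) {
    if (abs(f(k)) < tol) break
    dk <- 1e-6 * rng
    slope <- (f(k + dk) - f(k - dk)) / (2 * dk)
    if (!is.finite(slope) || slope == 0) break
    k <- k - f(k) / slope
  }
  y <- log(z - k)
  list(k = sgn * k, y = y, sign = sgn, skewness = sample_skewness(y))
}

#' Residualize a variable on a covariate set
#'
#' Ordinary-least-squares residuals of `y` on `X` with an intercept; the
#' residuals are orthogonal to every column of `X` and to the constant.
#'
#' @param y numeric response.
#' @param X numeric matrix/data.frame of covariates (or a single vector).
#' @return residual vector.
#' @export
residualize <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop_validation("y and X lengths differ")
  if (length(y) <= ncol(X) + 1L) stop_validation("need n > ncol(X) + 1")
  Xi <- cbind(`(intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(Xi))]]
    stop_validation("rank-deficient covariate set; collinear column(s): ",
                    paste(bad, collapse = ", "))
  }
  unname(qr.resid(qrx, y))
}

#' Sequential three-compartment construction
#'
#' Builds the statistically independent body-composition predictors in the
#' lipid-spillover order: rSAT is SAT residualized on NAT, rVAT is VAT
#' residualized on NAT and rSAT. NAT, rSAT and rVAT are pairwise
#' uncorrelated by construction.
#'
#' @param nat,sat,vat compartment volumes (L), equal lengths, n >= 10.
#' @return data.frame of class `three_compartments` with columns `nat`,
#'   `rsat`, `rvat`; attribute `flags` notes degenerate (zero-variance)
#'   residuals.
#' @export
build_three_compartments <- function(nat, sat, vat) {
  n <- length(nat)
  if (length(sat) != n || length(vat) != n) stop_validation("compartment lengths differ")
  if (n < 10L) stop_validation("need at least 10 subjects")
  rsat <- residualize(sat, cbind(nat = nat))
  rvat <- residualize(vat, cbind(nat = nat, rsat = rsat))
  flags <- character()
  if (stats::sd(rsat) < 1e-12 * max(stats::sd(sat), 1)) flags <- c(flags, "degenerate_rsat")
  if (stats::sd(rvat) < 1e-12 * max(stats::sd(vat), 1)) flags <- c(flags, "degenerate_rvat")
  out <- data.frame(nat = nat, rsat = rsat, rvat = rvat)
  class(out) <- c("three_compartments", "data.frame")
  attr(out, "flags") <- flags
  out
}

#' Significance flag at the P < 0.01 rule
#'
#' @param p p value(s) in \[0, 1\].
#' @return character: `"significant"` (p < 0.01), `"trend"` (0.01 <= p <
#'   0.05), `"ns"` otherwise.
#' @export
significance_mark <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_validation("p must lie in [0, 1]")
  ifelse(p < 0.01, "significant", ifelse(p < 0.05, "trend", "ns"))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_validation("zero-variance variable cannot be z-scored")
  (x - mean(x)) / s
}

#' Standardized, covariate-adjusted association model
#'
#' Fits one multiple linear regression of a z-scored outcome on z-scored
#' continuous predictors plus covariates (age z-scored, binary sex centered
#' so its coefficient stays interpretable). The reported `r` for each
#' predictor is its standardized coefficient in the joint model; `p` comes
#' from the coefficient's t statistic. Skewed outcomes (sample skewness above
#' `skew_trigger`) are passed through [lnskew0()] before z-scoring when
#' `transform = "auto"`.
#'
#' @param data data.frame.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param covariates covariate column names (default age and sex).
#' @param transform `"auto"`, `"never"`, or `"always"` (lnskew0 the outcome).
#' @param skew_trigger absolute skewness above which `"auto"` transforms.
#' @param r_type `"std_beta"` (default: the standardized coefficient) or
#'   `"partial_r"` (the partial correlation, computed as the correlation of
#'   the outcome and predictor after both are residualized on the remaining
#'   regressors). The two coincide for a single predictor with no covariates.
#' @return data.frame rows: `outcome`, `predictor`, `r`, `p`, `n`,
#'   `transformed`, `significance`.
#' @export
standardized_association <- function(data, outcome, predictors,
                                     covariates = c("age", "sex"),
                                     transform = c("auto", "never", "always"),
                                     skew_trigger = 0.5,
                                     r_type = c("std_beta", "partial_r")) {
  transform <- match.arg(transform)
  r_type <- match.arg(r_type)
  cols <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) stop_validation("missing columns: ",
                                            paste(missing_cols, collapse = ", "))
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(cols) + 1L) stop_validation("too few complete cases (n = ", n, ")")

  y <- d[[outcome]]
  transformed <- FALSE
  do_tr <- transform == "always" ||
    (transform == "auto" && is.finite(sample_skewness(y)) &&
       abs(sample_skewness(y)) > skew_trigger)
  if (do_tr) {
    y <- lnskew0(y)$y
    transformed <- TRUE
  }
  ym <- zscore(y)

  std_col <- function(v) {
    u <- unique(v)
    if (length(u) == 2L) v - mean(v) else zscore(v)  # binary: center only
  }
  Xp <- vapply(predictors, function(p) zscore(d[[p]]), numeric(n))
  Xc <- if (length(covariates)) {
    vapply(covariates, function(p) std_col(d[[p]]), numeric(n))
  } else NULL
  X <- cbind(Xp, Xc)
  colnames(X) <- c(predictors, covariates)
  df <- data.frame(.y = ym, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  rows <- match(predictors, rownames(sm))
  r_val <- if (r_type == "std_beta") {
    unname(sm[rows, "Estimate"])
  } else {
    # Frisch-Waugh construction: residualize outcome and each predictor on
    # everything else in the model, then correlate
    vapply(predictors, function(p) {
      others <- X[, setdiff(colnames(X), p), drop = FALSE]
      if (ncol(others)) {
        stats::cor(residualize(ym, others), residualize(X[, p], others))
      } else stats::cor(ym, X[, p])
    }, 0)
  }
  data.frame(outcome = outcome, predictor = predictors,
             r = unname(r_val),
             p = unname(sm[rows, "Pr(>|t|)"]),
             n = n, transformed = transformed,
             significance = significance_mark(unname(sm[rows, "Pr(>|t|)"])),
             stringsAsFactors = FALSE)
}

#' Cardiovascular outcome set of the association tables
#' @return character vector of outcome column names.
#' @export
cardiovascular_outcomes <- function() {
  c("sbp", "dbp", "mbp", "pulse_pressure", "svr", "co", "sv", "heart_rate",
    "lvedv", "lvef", "lv_mass", "mass_to_edv", "e_a", "septal_ea",
    "lateral_ea", "pwv_aao", "pwv_dao", "tac")
}

#' Association grid over outcomes for a named model specification
#'
#' Model specs:
#' * `"anthro"`: three separate single-predictor models per outcome (BMI z,
#'   waist z, waist:height z), each adjusted for age and sex.
#' * `"bmi-adj-nat"`: BMI z residualized on NAT as the single predictor.
#' * `"three-comp"`: NAT, rSAT and rVAT entered jointly with age and sex.
#'
#' @param cohort cohort data.frame (needs the compartment, z-score and
#'   outcome columns).
#' @param model one of `"anthro"`, `"bmi-adj-nat"`, `"three-comp"`.
#' @param outcomes outcome columns (default [cardiovascular_outcomes()],
#'   restricted to those present).
#' @param transform passed to [standardized_association()].
#' @return data.frame of class `association_table` with columns `outcome`,
#'   `predictor`, `model`, `r`, `p`, `n`, `transformed`, `significance`.
#' @export
association_grid <- function(cohort, model = c("anthro", "bmi-adj-nat", "three-comp"),
                             outcomes = NULL, transform = "auto") {
  if (!is.character(model) || !model[1] %in% c("anthro", "bmi-adj-nat", "three-comp")) {
    stop_validation("unknown model spec: ", paste(model[1], collapse = ""),
                    " (expected anthro, bmi-adj-nat or three-comp)")
  }
  model <- model[1]
  outcomes <- outcomes %||% intersect(cardiovascular_outcomes(), names(cohort))
  if (!length(outcomes)) stop_validation("no outcome columns found in cohort")

  work <- cohort
  pred_sets <- switch(model,
    "anthro" = as.list(c("bmi_z", "waist_z", "waist_height_z")),
    "bmi-adj-nat" = {
      work$bmi_z_adj_nat <- residualize(work$bmi_z, cbind(nat = work$nat))
      list("bmi_z_adj_nat")
    },
    "three-comp" = {
      tc <- build_three_compartments(work$nat, work$sat, work$vat)
      work$rsat <- tc$rsat
      work$rvat <- tc$rvat
      list(c("nat", "rsat", "rvat"))
    })
  res <- do.call(rbind, lapply(outcomes, function(oc) {
    do.call(rbind, lapply(pred_sets, function(ps) {
      standardized_association(work, oc, ps, transform = transform)
    }))
  }))
  res$model <- model
  res <- res[c("outcome", "predictor", "model", "r", "p", "n", "transformed",
               "significance")]
  class(res) <- c("association_table", "data.frame")
  res
}

#' Sensitivity re-run excluding flagged participants
#'
#' Re-fits an association grid with and without subjects whose flag column is
#' `TRUE` (e.g. obesity-clinic recruits) and reports per-row coefficient
#' differences.
#'
#' @param cohort cohort data.frame.
#' @param flag name of a logical flag column.
#' @param model model spec for [association_grid()].
#' @param ... passed to [association_grid()].
#' @return list with `full`, `excluded` (association tables) and `comparison`
#'   (merged table with `r_full`, `r_excluded`, `delta_r`).
#' @export
sensitivity_exclude <- function(cohort, flag = "clinic_recruit",
                                model = "three-comp", ...) {
  if (!flag %in% names(cohort)) stop_validation("flag column '", flag, "' not found")
  keep <- !as.logical(cohort[[flag]])
  if (!any(keep)) stop_validation("all subjects flagged: empty analysis set")
  full <- association_grid(cohort, model, ...)
  excluded <- association_grid(cohort[keep, , drop = FALSE], model, ...)
  cmp <- merge(full[c("outcome", "predictor", "r", "p")],
               excluded[c("outcome", "predictor", "r", "p")],
               by = c("outcome", "predictor"), suffixes = c("_full", "_excluded"))
  cmp$delta_r <- cmp$r_excluded - cmp$r_full
  list(full = full, excluded = excluded, comparison = cmp)
}
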