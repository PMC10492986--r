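test_that("lnskew0 recovers a known shift and zeroes skewness", {
  set.seed(101)
  x <- 5 + rlnorm(1e5, meanlog = 0, sdlog = 1)
  res <- lnskew0(x)
  expect_lt(abs(res$skewness), 1e-6)
  expect_lt(abs(sample_skewness(res$y)), 1e-6)
  expect_equal(res$k, 5, tolerance = 0.1)
  expect_lt(res$k, min(x))

  # negative skew handled by the mirrored form
  xn <- 20 - rlnorm(5000, 0, 0.8)
  rn <- lnskew0(xn)
  expect_lt(abs(rn$skewness), 1e-6)
  expect_identical(rn$sign, -1)

  # exactly zero-skew input is left (numerically) zero-skew
  sym <- rep(c(-2, -1, 0, 1, 2), 4) + 10
  expect_lt(abs(lnskew0(sym)$skewness), 1e-6)

  expect_error(lnskew0(rep(3, 20)), class = "bodycomp3_validation_error")
  expect_error(lnskew0(c(1, 2, 3)), class = "bodycomp3_validation_error")
})

test_that("residualize returns OLS residuals orthogonal to X and the constant", {
  set.seed(7)
  x <- rnorm(100)
  y <- 3 + 2 * x + rnorm(100)
  r <- residualize(y, x)
  expect_lt(abs(cor(r, x)), 1e-12)
  expect_lt(abs(mean(r)), 1e-12)
  # y orthogonal to X already -> residual is y - mean(y)
  x2 <- rep(c(-1, 1), 50)
  y2 <- rnorm(100); y2 <- y2 - mean(y2)
  y2 <- y2 - x2 * sum(y2 * x2) / sum(x2 * x2)
  expect_equal(residualize(y2, x2), y2, tolerance = 1e-12)
  # y = x exactly -> residuals 0
  expect_equal(residualize(x, x), rep(0, 100), tolerance = 1e-12)
  # rank deficiency names the collinear column
  X <- cbind(a = x, b = 2 * x)
  expect_error(residualize(y, X), regexp = "b",
               class = "bodycomp3_validation_error")
})

test_that("three-compartment construction is orthogonal and matches Gram-Schmidt", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 82
    nat <- rnorm(n, 34, 6)
    sat <- 2 + exp(rnorm(n, log(13), 0.5)) + 0.3 * nat
    vat <- 0.2 + 0.02 * sat + 0.01 * nat + rlnorm(n, log(0.5), 0.5)
    tc <- build_three_compartments(nat, sat, vat)
    cm <- cor(tc)
    expect_lt(max(abs(cm[upper.tri(cm)])), 1e-10)
    expect_lt(abs(mean(tc$rsat)), 1e-10)
    expect_lt(abs(mean(tc$rvat)), 1e-10)

    # independent Gram-Schmidt oracle on centered vectors
    u1 <- nat - mean(nat)
    sc <- sat - mean(sat)
    gs_rsat <- sc - sum(sc * u1) / sum(u1 * u1) * u1
    vc <- vat - mean(vat)
    gs_rvat <- vc - sum(vc * u1) / sum(u1 * u1) * u1 -
      sum(vc * gs_rsat) / sum(gs_rsat * gs_rsat) * gs_rsat
    expect_equal(tc$rsat, gs_rsat, tolerance = 1e-10)
    expect_equal(tc$rvat, gs_rvat, tolerance = 1e-10)
  }

  # sat exactly proportional to nat -> degenerate rsat, flagged
  nat <- rnorm(50, 30, 5)
  tc2 <- build_three_compartments(nat, 0.5 * nat, rlnorm(50))
  expect_true("degenerate_rsat" %in% attr(tc2, "flags"))
  expect_lt(sd(tc2$rsat), 1e-10)

  expect_error(build_three_compartments(1:5, 1:5, 1:5),
               class = "bodycomp3_validation_error")
})

test_that("standardized associations behave as standardized coefficients", {
  set.seed(11)
  d <- data.frame(y = rnorm(200), age = runif(200, 13, 18),
                  sex = rbinom(200, 1, 0.5))
  d$x <- d$y                                  # predictor identical to outcome
  row <- suppressWarnings(
    standardized_association(d, "y", "x", covariates = character()))
  expect_equal(row$r, 1, tolerance = 1e-10)
  expect_lt(row$p, 1e-100)

  # Frisch-Waugh: partial_r equals the t-statistic identity t/sqrt(t^2+df)
  d$x2 <- 0.5 * d$y + rnorm(200)
  pr <- standardized_association(d, "y", "x2", r_type = "partial_r")
  fit <- lm(scale(y) ~ scale(x2) + scale(age) + I(sex - mean(sex)), data = d)
  tval <- summary(fit)$coefficients[2, "t value"]
  expect_equal(pr$r, tval / sqrt(tval^2 + fit$df.residual), tolerance = 1e-10)

  # zero-variance variable errors
  d$z <- 1
  expect_error(standardized_association(d, "y", "z"),
               class = "bodycomp3_validation_error")

  # skewed outcome is lnskew0-transformed under the auto rule
  d$sk <- exp(rnorm(200))
  expect_true(standardized_association(d, "sk", "x2")$transformed)
  expect_false(standardized_association(d, "sk", "x2",
                                        transform = "never")$transformed)
})

test_that("a planted standardized effect is recovered", {
  eff <- default_effects(); eff[] <- 0
  eff["nat", "lv_mass"] <- 0.8
  co <- generate_cohort(cohort_spec(n = 2000L, effects = eff, seed = 21L))
  est <- standardized_association(co, "lv_mass", "nat")$r
  expect_equal(est, 0.8, tolerance = 0.05)
})

test_that("association_grid produces the model grids deterministically", {
  co <- generate_cohort(cohort_spec(seed = 5L))
  g3 <- association_grid(co, "three-comp")
  expect_equal(nrow(g3), 18 * 3)              # 18 outcomes x 3 compartments
  expect_identical(g3, association_grid(co, "three-comp"))
  ga <- association_grid(co, "anthro")
  expect_equal(nrow(ga), 18 * 3)              # 3 single-predictor models
  gb <- association_grid(co, "bmi-adj-nat")
  expect_equal(nrow(gb), 18)
  expect_identical(unique(gb$predictor), "bmi_z_adj_nat")
  expect_error(association_grid(co, "banana"),
               class = "bodycomp3_validation_error")
})

test_that("the planted sign pattern lands on the right compartments", {
  co <- generate_cohort(cohort_spec(n = 200L, seed = 8L))
  g <- association_grid(co, "three-comp")
  pick <- function(oc, pred) g[g$outcome == oc & g$predictor == pred, ]
  lvm <- pick("lv_mass", "nat")
  expect_gt(lvm$r, 0); expect_identical(lvm$significance, "significant")
  ea <- pick("e_a", "rsat")
  expect_lt(ea$r, 0); expect_identical(ea$significance, "significant")
  # visceral fat was planted with no effects
  expect_false(any(pick("lv_mass", "rvat")$significance == "significant"))
})

test_that("sensitivity exclusion reruns the grid on the reduced cohort", {
  co <- generate_cohort(cohort_spec(n = 82L, n_clinic = 3L, seed = 2L))
  res <- sensitivity_exclude(co, model = "three-comp")
  expect_equal(unique(res$full$n), 82)
  expect_equal(unique(res$excluded$n), 79)
  expect_true(all(c("r_full", "r_excluded", "delta_r") %in% names(res$comparison)))

  co$none <- FALSE
  same <- sensitivity_exclude(co, flag = "none", model = "bmi-adj-nat")
  expect_identical(same$full, same$excluded)

  co$all <- TRUE
  expect_error(sensitivity_exclude(co, flag = "all"),
               class = "bodycomp3_validation_error")
})

test_that("significance marks follow the printed threshold rule", {
  expect_identical(significance_mark(c(0.005, 0.017, 0.5, 0.01, 0.0499)),
                   c("significant", "trend", "ns", "trend", "trend"))
  expect_error(significance_mark(1.2), class = "bodycomp3_validation_error")
})
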