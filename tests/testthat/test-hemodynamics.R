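test_that("early-systolic window finds the linear segment", {
  # linear for the first 8 samples after the foot, then strongly curved
  t <- seq(0, 300, by = 10)                       # 31 samples
  q <- c(0, 0, seq(20, 160, by = 20),             # foot at sample 3, 8 linear
         150, 130, 100, 70, 40, 20, rep(10, 15))  # then rounds over
  a <- 450 + q / 4
  wf <- data.frame(t_ms = t, q_ml_s = q, a_mm2 = a)
  win <- early_systolic_window(wf, max_frac = 1)
  expect_equal(attr(win, "foot"), 3L)
  expect_true(abs(length(win) - 8L) <= 1L)
  expect_false(attr(win, "low_linearity"))

  # globally linear upstroke: window spans the allowed fraction of systole
  q2 <- pmin(seq(0, 600, by = 20), 300)
  wf2 <- data.frame(t_ms = t, q_ml_s = q2[seq_along(t)],
                    a_mm2 = 450 + q2[seq_along(t)] / 4)
  win2 <- early_systolic_window(wf2, max_frac = 1)
  expect_gte(length(win2), 10L)

  flat <- data.frame(t_ms = t, q_ml_s = rep(0, length(t)), a_mm2 = rep(450, length(t)))
  expect_error(early_systolic_window(flat), class = "bodycomp3_estimation_error")
})

test_that("pwv_qa is exact on noise-free waveforms and robust to units", {
  wf <- generate_waveform(waveform_spec(true_pwv = 4, noise_sd = 0))
  expect_equal(as.numeric(pwv_qa(wf)), 4, tolerance = 1e-6)
  expect_equal(as.numeric(pwv_qa(wf, method = "ols")), 4, tolerance = 1e-9)

  # scale equivariance: Q*k -> pwv*k; A*k -> pwv/k; A + c -> unchanged
  wf_q <- wf; wf_q$q_ml_s <- wf$q_ml_s * 3
  win <- early_systolic_window(wf)
  expect_equal(as.numeric(pwv_qa(wf_q, window = win)), 12, tolerance = 1e-6)
  wf_a <- wf; wf_a$a_mm2 <- wf$a_mm2 * 2
  expect_equal(as.numeric(pwv_qa(wf_a, window = win)), 2, tolerance = 1e-6)
  wf_c <- wf; wf_c$a_mm2 <- wf$a_mm2 + 500
  expect_equal(as.numeric(pwv_qa(wf_c, window = win)), 4, tolerance = 1e-6)

  wf_flat <- wf; wf_flat$a_mm2 <- rep(450, nrow(wf))
  expect_error(pwv_qa(wf_flat, window = win), class = "bodycomp3_estimation_error")
})

test_that("pwv error shrinks with the noise level", {
  noise <- c(0.05, 0.02, 0.01, 0)
  err <- vapply(noise, function(ns) {
    est <- vapply(1:40, function(s) {
      spec <- waveform_noise_frac(waveform_spec(true_pwv = 4, seed = s), ns)
      as.numeric(pwv_qa(generate_waveform(spec)))
    }, 0)
    mean(abs(est - 4))
  }, 0)
  expect_lt(err[4], 1e-6)
  expect_lt(err[3], err[1])
  expect_lt(mean(abs(err)), 0.5)
})

test_that("volumetric and pressure formulas match one-line arithmetic", {
  expect_equal(stroke_volume(141, 59), 82, tolerance = 1e-12)
  expect_equal(ejection_fraction(141, 59), 100 * 82 / 141, tolerance = 1e-12)
  expect_equal(ejection_fraction(141, 0), 100)
  expect_equal(ejection_fraction(141, 141), 0)
  expect_equal(lv_mass(100), 105, tolerance = 1e-12)
  expect_equal(lv_mass(0), 0)
  expect_equal(lv_mass(123.4), 129.57, tolerance = 1e-12)
  expect_equal(tac(82, 111, 58), 82 / 53, tolerance = 1e-12)
  expect_equal(as.numeric(svr(111, 58, 5.6, mbp = 80)), 80 / 5.6, tolerance = 1e-12)
  expect_equal(cardiac_output(70, 60), 4.2, tolerance = 1e-12)

  expect_error(stroke_volume(100, 120), class = "bodycomp3_validation_error")
  expect_error(lv_mass(-1), class = "bodycomp3_validation_error")
  expect_error(tac(82, 90, 90), class = "bodycomp3_estimation_error")
  expect_error(svr(111, 58, 0), class = "bodycomp3_estimation_error")
})

test_that("hemodynamic_summary assembles the index set and flags derived mbp", {
  wf <- generate_waveform(waveform_spec(true_pwv = 4.5, noise_sd = 0))
  hs <- hemodynamic_summary(wf, edv = 141, esv = 59, myocardial_volume = 100,
                            sbp = 111, dbp = 58, heart_rate = 69)
  expect_equal(hs$pwv_m_s, 4.5, tolerance = 1e-6)
  expect_equal(hs$sv_ml, 82)
  expect_equal(hs$lv_mass_g, 105)
  expect_equal(hs$co_l_min, 82 * 69 / 1000, tolerance = 1e-12)
  expect_equal(hs$svr_wu, (58 + 53 / 3) / hs$co_l_min, tolerance = 1e-12)
  expect_true(hs$mbp_derived)
  hs2 <- hemodynamic_summary(NULL, 141, 59, 100, 111, 58, 69, mbp = 80)
  expect_false(hs2$mbp_derived)
  expect_equal(hs2$svr_wu, 80 / (82 * 69 / 1000), tolerance = 1e-12)
})
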