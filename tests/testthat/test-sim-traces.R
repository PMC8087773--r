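test_that("rising-phase traces follow the activation model point-wise", {
  S_A <- 7.1; A_max <- 14.1; t_d <- 0.015; I <- 10
  tr <- sim_rising_phase(S_A, A_max, t_d, I, dt = 1e-3, duration = 0.1)
  expected <- ifelse(tr$t <= t_d, 0,
                     A_max * (1 - exp(-S_A * I * (tr$t - t_d)^2)))
  expect_equal(tr$value, expected, tolerance = 1e-12)
  # zero up to the delay, saturating towards A_max
  expect_true(all(tr$value[tr$t <= t_d] == 0))
  long <- sim_rising_phase(S_A, A_max, t_d, I = 50, dt = 5e-3, duration = 3)
  expect_equal(max(long$value), A_max, tolerance = 1e-6)
})

test_that("rising-phase generator validates arguments and records truth", {
  expect_error(sim_rising_phase(1, 1, 0.01, 1, dt = -1), "positive")
  expect_error(sim_rising_phase(1, 1, 0.01, 1, duration = 0.005), "duration")
  tr <- sim_rising_phase(2, 5, 0.01, 3, noise_sd = 0.5, seed = 7)
  tr2 <- sim_rising_phase(2, 5, 0.01, 3, noise_sd = 0.5, seed = 7)
  expect_identical(tr$value, tr2$value)
  expect_equal(attr(tr, "truth")$S_A, 2)
})

test_that("b-wave peak follows the saturation law", {
  half <- sim_bwave(S_B = 1, B_max = 100, I = 1, dt = 2e-4)
  expect_equal(max(half$value), 50, tolerance = 1e-9)
  sat <- sim_bwave(S_B = 1, B_max = 100, I = 1e8, dt = 2e-4)
  expect_equal(max(sat$value), 100, tolerance = 1e-6)
  none <- sim_bwave(S_B = 1, B_max = 100, I = 0, dt = 2e-4)
  expect_equal(max(abs(none$value)), 0)
})

test_that("injected oscillation survives band-pass extraction at its stated swing", {
  tr <- sim_bwave(S_B = 1, B_max = 400, I = 100, op = op_spec(120, 10), dt = 2e-4)
  res <- op_amplitude(tr, b_max = 400)
  expect_true(res$found)
  expect_equal(res$amplitude, 20, tolerance = 0.1)
  expect_equal(res$normalized, 0.05, tolerance = 0.1)
})

test_that("out-of-band oscillation frequencies warn but still generate", {
  expect_warning(sp <- op_spec(50, 5), "75-300")
  expect_false(sp$in_band)
  tr <- sim_bwave(S_B = 1, B_max = 100, I = 10, op = sp, dt = 2e-4)
  expect_false(attr(tr, "truth")$op_in_band)
})

test_that("ERG cohorts have the right design and sensitivity scaling", {
  cfg <- sim_config(seed = 5, n_pairs = 7)
  coh <- sim_erg_cohort(cfg, sensitivity_factor = 1.5)
  # 7 pairs x 2 genotypes = 14 sessions, 2 eyes each
  expect_equal(nrow(dplyr::distinct(coh$traces, mouse)), 14)
  expect_equal(nrow(coh$truth), 28)
  expect_setequal(unique(coh$traces$flash_intensity), c(0.00022, 0.011))
  # conservation: every (mouse, eye) appears exactly once in truth
  expect_equal(nrow(dplyr::distinct(coh$truth, mouse, eye)), 28)
  # mean KO/WT sensitivity ratio approaches the factor over many seeds
  ratios <- vapply(1:40, function(s) {
    tr <- sim_erg_cohort(sim_config(seed = s, n_pairs = 2))$truth
    mean(tr$S_B[tr$genotype == "KO"]) / mean(tr$S_B[tr$genotype == "WT"])
  }, numeric(1))
  expect_equal(mean(ratios), 1.5, tolerance = 0.05)
})

test_that("unit sensitivity factor with no noise gives mirror-image sessions", {
  cfg <- sim_config(seed = 2, n_pairs = 3, noise_sd = 0)
  coh <- sim_erg_cohort(cfg, sensitivity_factor = 1, cv_eye = 0, op_coupling = FALSE,
                        cv_op = 0)
  wt <- dplyr::filter(coh$traces, genotype == "WT")
  ko <- dplyr::filter(coh$traces, genotype == "KO")
  expect_equal(wt$value, ko$value, tolerance = 1e-12)
})

test_that("cohort generation is bit-identical under a fixed config", {
  cfg <- sim_config(seed = 9, n_pairs = 2, noise_sd = 3)
  a <- sim_erg_cohort(cfg)
  b <- sim_erg_cohort(cfg)
  expect_identical(a, b)
})

test_that("paired-sample generator honours its noise model", {
  exact <- sim_paired_samples(5, true_ratio = 1.34, cv = 0, seed = 1)
  expect_equal(exact$y / exact$x, rep(1.34, 5))
  s1 <- sim_paired_samples(8, 1.4, cv = 0.3, seed = 11)
  s2 <- sim_paired_samples(8, 1.4, cv = 0.3, seed = 11)
  expect_identical(s1, s2)
  expect_error(sim_paired_samples(8, 1.4, cv = -0.1), "cv")
  expect_error(sim_paired_samples(1, 1.4), "n")
  # unit means in both structures
  big <- sim_paired_samples(20000, 2, cv = 0.4, seed = 3, structure = "independent")
  expect_equal(mean(big$x), 1, tolerance = 0.02)
  expect_equal(mean(big$y), 2, tolerance = 0.03)
})
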