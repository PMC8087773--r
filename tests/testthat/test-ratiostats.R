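test_that("two-step batch normalization leaves unit pair means", {
  df <- tibble::tibble(
    slide = c(1, 1, 1, 1, 2, 2),
    pair = c(1, 1, 2, 2, 3, 3),
    genotype = rep(c("WT", "KO"), 3),
    value = c(2, 3, 4, 5, 30, 90)
  )
  out <- normalize_paired_batches(df)
  pm <- tapply(out$value, out$pair, mean)
  expect_equal(as.vector(pm), rep(1, 3), tolerance = 1e-12)
  # within-pair ratios survive both steps
  xy <- pairs_to_xy(out)
  expect_equal(xy$y / xy$x, c(3 / 2, 5 / 4, 3), tolerance = 1e-12)
  # rescaling one slide is invisible
  df2 <- df
  df2$value[df2$slide == 2] <- df2$value[df2$slide == 2] * 10
  expect_equal(normalize_paired_batches(df2)$value, out$value, tolerance = 1e-12)
  # worked two-pair case on one slide, by hand:
  # slide mean 14/4 = 3.5 -> values/3.5; pair 1 mean = (2+3)/(2*3.5) -> x = 2*2/5
  hand <- normalize_paired_batches(df[1:4, ])
  expect_equal(hand$value, c(2 * 2 / 5, 2 * 3 / 5, 2 * 4 / 9, 2 * 5 / 9),
               tolerance = 1e-12)
  expect_error(normalize_paired_batches(dplyr::mutate(df, value = 0)), "positive")
})

test_that("jackknife chain is exact on constant-ratio data", {
  x <- c(0.4, 1.1, 2.2, 3.5)
  est <- jackknife_ratio(x, 2 * x)
  expect_equal(est$r, 2)
  expect_equal(est$r_c, 2)
  expect_equal(est$s, 0)
  expect_equal(est$s_c, 0)
  expect_equal(est$r_i, rep(2, 4))
})

test_that("jackknife quantities match direct evaluation of the formulas", {
  x <- c(1, 2, 3); y <- c(2, 3, 7)
  est <- jackknife_ratio(x, y)
  expect_equal(est$r, 12 / 6)
  expect_equal(est$r_i, c(10 / 5, 9 / 4, 5 / 3))
  expect_equal(est$s, sqrt(mean((est$r_i - 2)^2)))
  expect_equal(est$r_c, 3 * 2 - (2 / 3) * sum(est$r_i))
  expect_equal(est$s_c, sqrt(sum((est$r_i - est$r_c)^2) / 2))
  expect_error(jackknife_ratio(c(1, -2, 0.5), c(1, 1, 1)), "denominator")
  expect_error(jackknife_ratio(1, 2), "n >= 2")
})

test_that("bias correction beats the plain ratio in a small Monte-Carlo", {
  set.seed(101)
  mc4 <- oracle_ratio_mc(20000, 4, R = 1.4, cv = 0.5)
  mc16 <- oracle_ratio_mc(20000, 16, R = 1.4, cv = 0.5)
  expect_lt(abs(mean(mc4$rc) - 1.4), abs(mean(mc4$r) - 1.4))
  expect_lt(abs(mean(mc16$rc) - 1.4), abs(mean(mc16$r) - 1.4))
  # and the generator + estimator agree with the vectorised oracle
  smp <- sim_paired_samples(6, 1.4, cv = 0.3, seed = 5, structure = "independent")
  est <- jackknife_ratio(smp)
  expect_equal(est$r, sum(smp$y) / sum(smp$x))
})

test_that("paired t handles regular and degenerate inputs", {
  x <- c(1, 2, 3)
  expect_equal(paired_t(x, x)$p.value, 1)
  expect_true(paired_t(x, x)$degenerate)
  shift <- paired_t(x, x + 2)
  expect_equal(shift$p.value, 0)
  # agreement with the closed-form statistic on a known triple
  y <- c(1.4, 2.9, 3.1)
  d <- y - x
  t_manual <- mean(d) / (sd(d) / sqrt(3))
  res <- paired_t(x, y)
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(t_manual), 2), tolerance = 1e-12)
})

test_that("correlation estimates and t-transform p-values are correct", {
  res <- correlations(1:5, (1:5)^3)
  expect_equal(res$estimate[res$method == "spearman"], 1)
  expect_equal(res$p.value[res$method == "spearman"], 0)
  dec <- correlations(1:3, c(9, 4, 1))
  expect_equal(dec$estimate[dec$method == "spearman"], -1)
  set.seed(6)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  res <- correlations(x, y)
  ct <- cor.test(x, y)  # Pearson p in R is the same t-transform
  expect_equal(res$estimate[1], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p.value[1], ct$p.value, tolerance = 1e-12)
  rho <- cor(rank(x), rank(y))
  expect_equal(res$estimate[2], rho, tolerance = 1e-12)
  expect_equal(res$p.value[2],
               2 * pt(-abs(rho * sqrt(10 / (1 - rho^2))), 10), tolerance = 1e-12)
  expect_error(correlations(rep(1, 5), 1:5), "zero variance")
})

test_that("relabelling pairs changes no test result", {
  set.seed(7)
  x <- rlnorm(8); y <- 1.3 * x * rlnorm(8, sdlog = 0.2)
  perm <- sample(8)
  expect_equal(glance(jackknife_ratio(x, y)), glance(jackknife_ratio(x[perm], y[perm])))
  expect_equal(paired_t(x, y)$p.value, paired_t(x[perm], y[perm])$p.value)
  expect_equal(correlations(x, y)$p.value, correlations(x[perm], y[perm])$p.value)
})
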