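test_that("equal means give t = 0 and p = 1", {
  res <- welch_t(3, 0.5, 6, 3, 0.7, 9)
  expect_equal(res$t, 0)
  expect_equal(res$p.value, 1)
})

test_that("equal SEMs and sizes give the Satterthwaite limit v = 2(n-1)", {
  n <- 8
  res <- welch_t(1, 0.3, n, 0, 0.3, n)
  expect_equal(res$v, 2 * (n - 1), tolerance = 1e-12)
})

test_that("the incomplete-beta p matches the t distribution exactly", {
  for (t in c(-3.2, -0.7, 0.4, 1.1, 2.5, 6)) {
    for (v in c(2.3, 5, 11.7, 40)) {
      expect_equal(stats::pbeta(v / (v + t^2), v / 2, 0.5),
                   2 * pt(-abs(t), v), tolerance = 1e-12)
    }
  }
  # and against numeric quadrature of the t density
  res <- welch_t(5.1, 0.8, 7, 3.9, 0.5, 12)
  expect_equal(res$p.value, oracle_t_two_sided(res$t, res$v), tolerance = 1e-9)
})

test_that("welch p equals the pooled Student p when SEMs and sizes coincide", {
  set.seed(8)
  x <- rnorm(9, 1); y <- rnorm(9, 0)
  # force equal SEMs by feeding equal summary stats
  s <- 0.4
  ours <- welch_t(mean(x), s, 9, mean(y), s, 9)
  t_pooled <- (mean(x) - mean(y)) / sqrt(2 * s^2)
  expect_equal(ours$p.value, 2 * pt(-abs(t_pooled), 16), tolerance = 1e-12)
})

test_that("double-difference reduces to the single test and detects shifts", {
  # samples 3 and 4 nearly degenerate: t approaches the two-sample value
  a <- c(1.2, 0.8); s <- c(0.1, 0.12); v <- c(6, 6)
  single <- welch_t(a[1], s[1], v[1], a[2], s[2], v[2])
  dd <- welch_double_diff(c(a, 0, 0), c(s, 1e-9, 1e-9), c(v, 6, 6))
  expect_equal(dd$t, single$t, tolerance = 1e-6)
  expect_equal(dd$v, single$v, tolerance = 1e-4)
  expect_equal(dd$p.value, single$p.value, tolerance = 1e-6)
  # a1 - a2 == a3 - a4 gives t = 0, p = 1
  null <- welch_double_diff(c(2, 1, 5, 4), rep(0.2, 4), rep(5, 4))
  expect_equal(null$t, 0)
  expect_equal(null$p.value, 1)
})

test_that("degenerate summary statistics are rejected", {
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "undefined")
  expect_error(welch_t(1, 0.1, 1, 2, 0.1, 5), "size")
  expect_error(welch_double_diff(1:4, rep(0, 4), rep(5, 4)), "undefined")
})
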