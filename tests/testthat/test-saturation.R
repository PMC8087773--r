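test_that("b-wave amplitude is peak minus pre-flash baseline", {
  tr <- sim_bwave(S_B = 1, B_max = 100, I = 1, dt = 2e-4)  # peak 50, baseline 0
  expect_equal(bwave_amplitude(tr)$B, 50, tolerance = 1e-9)
  flat <- new_trace(rep(0, 500), dt = 1e-3, t_flash = 0.1)
  expect_equal(bwave_amplitude(flat)$B, 0)
  # constant +10 uV offset cancels through the baseline
  off <- tr
  off$value <- off$value + 10
  expect_equal(bwave_amplitude(off)$B, 50, tolerance = 1e-9)
  expect_error(bwave_amplitude(tr, window = c(9, 10)), "no samples")
})

test_that("two-point saturation inversion recovers exact parameters", {
  S <- 1; Bm <- 1
  I <- c(1, 1e6)
  pts <- tibble::tibble(I = I, B = Bm * S * I / (1 + S * I))
  fit <- fit_saturation(pts)
  expect_equal(fit$S_B, 1, tolerance = 1e-12)
  expect_equal(fit$B_max, 1, tolerance = 1e-12)
  expect_identical(fit$method, "two-point")
})

test_that("algebraic inversion agrees with a numeric least-squares oracle", {
  set.seed(21)
  for (k in 1:50) {
    S <- 10^runif(1, -3, 3)
    Bm <- 10^runif(1, 0, 3)
    I <- sort(10^runif(2, -3, 3) / S)
    if (I[2] / I[1] < 3) I[2] <- I[1] * 3
    B <- Bm * S * I / (1 + S * I)
    fit <- fit_saturation(tibble::tibble(I = I, B = B))
    orc <- oracle_saturation_two_point(I, B)
    expect_equal(fit$S_B, unname(orc["S_B"]), tolerance = 1e-9)
    expect_equal(fit$B_max, unname(orc["B_max"]), tolerance = 1e-9)
  }
})

test_that("overdetermined saturation fits recover parameters by least squares", {
  S <- 2000; Bm <- 400
  I <- c(0.00022, 0.0011, 0.0044, 0.011, 0.05)
  pts <- tibble::tibble(I = I, B = Bm * S * I / (1 + S * I))
  fit <- fit_saturation(pts)
  expect_identical(fit$method, "least-squares")
  expect_equal(fit$S_B, S, tolerance = 1e-6)
  expect_equal(fit$B_max, Bm, tolerance = 1e-6)
})

test_that("the scotopic two-flash protocol yields a finite positive fit", {
  I <- c(0.00022, 0.011)
  B <- 400 * 2000 * I / (1 + 2000 * I)
  fit <- fit_saturation(tibble::tibble(I = I, B = B))
  expect_gt(fit$S_B, 0)
  expect_gt(fit$B_max, 0)
  expect_true(is.finite(fit$S_B) && is.finite(fit$B_max))
})

test_that("inconsistent amplitudes are rejected", {
  # amplitude decreasing with intensity has no positive solution
  expect_error(fit_saturation(tibble::tibble(I = c(1, 10), B = c(50, 30))),
               "inconsistent")
  expect_error(fit_saturation(tibble::tibble(I = c(1, 1), B = c(1, 2))),
               "distinct")
})

test_that("photon density converts to isomerizations via the collecting area", {
  expect_equal(photons_to_isomerizations(20), 10)
  expect_equal(photons_to_isomerizations(0), 0)
  expect_equal(photons_to_isomerizations(7, collecting_area = 1), 7)
  expect_error(photons_to_isomerizations(-1), "non-negative")
})
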