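test_that("rising-window rules follow the peak-relative conventions", {
  # construct a response-positive trace with a controllable peak time
  mk <- function(t_peak, dur = 0.1, dt = 1e-4) {
    t <- seq(0, dur, by = dt)
    v <- exp(-(t - t_peak)^2 / (2 * 0.003^2))
    new_trace(-v, dt = dt, polarity = "corneal-positive")  # A-wave: corneal-negative
  }
  t_d <- 0.004
  # peak 4 ms after t_d: window ends at the peak
  w1 <- select_rising_window(mk(t_d + 0.004), t_d, mode = "erg_awave")
  expect_equal(w1, c(t_d, t_d + 0.004), tolerance = 1e-9)
  # peak 12 ms after t_d: window ends 5 ms before the peak
  w2 <- select_rising_window(mk(t_d + 0.012), t_d, mode = "erg_awave")
  expect_equal(w2[2], t_d + 0.012 - 0.005, tolerance = 1e-9)
  # alternative reading: cap the window length at 5 ms
  w3 <- select_rising_window(mk(t_d + 0.012), t_d, mode = "erg_awave",
                             rule = "cap_length")
  expect_equal(w3[2], t_d + 0.005, tolerance = 1e-9)
  # rod mode: fixed 60 ms from t_d
  tr <- sim_rising_phase(7, 14, 0.015, 10, dt = 1e-3, duration = 0.2)
  w4 <- select_rising_window(tr, 0.015, mode = "rod_photocurrent")
  expect_equal(diff(w4), 0.060, tolerance = 1e-9)
  expect_error(select_rising_window(tr, 5), "outside")
})

test_that("noise-free round trips recover the representative parameter sets", {
  # rod photocurrent regime
  rod <- lapply(c(2, 8, 32), function(I)
    sim_rising_phase(7.1, 14.1, 0.015, I, dt = 1e-3, duration = 0.09))
  f1 <- fit_rising_phase(rod, mode = "rod_photocurrent")
  expect_equal(f1$S_A, 7.1, tolerance = 1e-6)
  expect_equal(f1$A_max, 14.1, tolerance = 1e-6)
  expect_equal(f1$t_d, 0.015, tolerance = 1e-4)
  # ERG A-wave regime (corneal-negative traces, flipped internally)
  erg <- lapply(c(0.05, 1, 1000), function(I) {
    tr <- sim_rising_phase(2200, 317, 0.004, I, dt = 2e-4, duration = 0.045,
                           polarity = "photocurrent")
    flip <- new_trace(-tr$value, dt = 2e-4, polarity = "corneal-positive",
                      flash_intensity = I)
    flip
  })
  f2 <- fit_rising_phase(erg, mode = "erg_awave")
  expect_equal(f2$S_A, 2200, tolerance = 1e-6)
  expect_equal(f2$A_max, 317, tolerance = 1e-6)
  expect_equal(f2$t_d, 0.004, tolerance = 1e-4)
})

test_that("round-trip recovery holds over a random parameter grid", {
  set.seed(31)
  for (k in 1:6) {
    S_A <- 10^runif(1, 0.3, 1.3)
    A_max <- 10^runif(1, 0.8, 2)
    t_d <- runif(1, 0.0145, 0.0165)
    trs <- lapply(c(3, 12, 40), function(I)
      sim_rising_phase(S_A, A_max, t_d, I, dt = 1e-3, duration = 0.09))
    f <- fit_rising_phase(trs, mode = "rod_photocurrent")
    expect_equal(f$S_A, S_A, tolerance = 1e-6)
    expect_equal(f$A_max, A_max, tolerance = 1e-6)
    expect_equal(f$t_d, t_d, tolerance = 1e-6)
  }
})

test_that("scaling all amplitudes scales A_max and leaves S_A and t_d alone", {
  trs <- lapply(c(3, 12, 40), function(I)
    sim_rising_phase(6, 20, 0.015, I, dt = 1e-3, duration = 0.09))
  doubled <- lapply(trs, function(tr) {
    out <- tr
    out$value <- 2 * tr$value
    out
  })
  f1 <- fit_rising_phase(trs, mode = "rod_photocurrent")
  f2 <- fit_rising_phase(doubled, mode = "rod_photocurrent")
  expect_equal(f2$A_max, 2 * f1$A_max, tolerance = 1e-8)
  expect_equal(f2$S_A, f1$S_A, tolerance = 1e-8)
  expect_equal(f2$t_d, f1$t_d, tolerance = 1e-8)
})

test_that("per-mouse summaries average the per-unit fits", {
  fits <- tibble::tibble(
    mouse = c("m1", "m1", "m2", "m3", "m3", "m3", "m3"),
    genotype = c("WT", "WT", "WT", "KO", "KO", "KO", "KO"),
    S_B = c(2, 4, 5, NA, NA, NA, NA),
    A_max = c(NA, NA, NA, 10, 12, 14, 16)
  )
  s <- summarize_cohort(fits, by = c("mouse", "genotype"))
  expect_equal(s$S_B[s$mouse == "m1"], 3)
  expect_equal(s$A_max[s$mouse == "m3"], 13)
  expect_equal(s$n_units[s$mouse == "m2"], 1)  # single eye kept, flagged n=1
  expect_error(summarize_cohort(fits, by = "absent"), "grouping")
})
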