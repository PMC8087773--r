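# Hand-built stack: ONL background exactly 2 raw units; OPL features are
# expressed as (1 + profile) * 2 so normalized values are 1 + profile.
make_bar_stack <- function(bars, nz = 3, ny = 30, nx = 60) {
  ref <- array(2, dim = c(nz, ny, nx))
  for (b in bars) {
    prof <- b$peak * (1 - 0.5 * abs(seq_along(b$xs) - b$ipeak) / length(b$xs))
    ref[2, b$y, b$xs] <- 2 * (1 + prof)
  }
  confocal_stack(
    channels = list(reference = ref, target = ref),
    voxel_size = c(x = 0.1, y = 0.1, z = 0.3),
    roi = c(x = 0, y = 0, width = nx * 0.1, height = 1.5),
    onl = c(x = 0, y = 2.0, width = nx * 0.1, height = 1.0)
  )
}

test_that("ONL normalization sets the background to 1 and cancels scaling", {
  st <- make_bar_stack(list(list(y = 7, xs = 20:24, ipeak = 3, peak = 4)))
  norm <- normalize_to_onl(st)
  d <- dim(norm$channels$reference)
  expect_equal(mean(norm$channels$reference[, 21:30, ]), 1, tolerance = 1e-12)
  scaled <- st
  scaled$channels <- lapply(st$channels, function(v) v * 13.7)
  norm2 <- normalize_to_onl(scaled)
  expect_equal(norm2$channels$reference, norm$channels$reference, tolerance = 1e-12)
  # constant stack of value 7 normalizes to all ones
  flat <- st
  flat$channels <- lapply(st$channels, function(v) array(7, dim = dim(v)))
  expect_equal(unique(as.vector(normalize_to_onl(flat)$channels$reference)), 1)
  # zero background cannot be normalized
  zero <- st
  zero$channels <- lapply(st$channels, function(v) array(0, dim = dim(v)))
  expect_error(normalize_to_onl(zero), "not positive")
})

test_that("strict 3D maxima match an exhaustive neighbour-check oracle", {
  # single spike
  vol <- array(0, dim = c(3, 5, 5))
  vol[2, 3, 3] <- 5
  mx <- find_local_maxima_3d(vol, threshold = 1)
  expect_equal(nrow(mx), 1)
  expect_equal(c(mx$z, mx$y, mx$x), c(2, 3, 3))
  # constant volume: plateaus yield nothing
  expect_equal(nrow(find_local_maxima_3d(array(5, dim = c(3, 4, 4)))), 0)
  # synthetic blobs against the brute-force oracle
  sim <- sim_confocal_stack(sim_config(seed = 8), n_rod = 3, n_cone = 1,
                            roi_width = 25)
  norm <- normalize_to_onl(sim$stack)
  d <- dim(norm$channels$reference)
  roi_vol <- norm$channels$reference[, 1:75, , drop = FALSE]
  got <- find_local_maxima_3d(roi_vol)
  want <- oracle_local_maxima(roi_vol)
  expect_equal(nrow(got), nrow(want))
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_equal(key(cbind(got$z, got$y, got$x)), key(want))
  # detected centres sit on the ground-truth centres
  expect_setequal(paste(got$z, got$y, got$x),
                  paste(sim$truth$z, sim$truth$y, sim$truth$x))
})

test_that("tip mask thresholds at background and removes specks", {
  expect_equal(max(build_tip_mask(matrix(0, 10, 10))), 0)
  img <- matrix(1, 20, 20)
  img[8:12, 8:12] <- 3
  lab <- build_tip_mask(img)
  expect_equal(max(lab), 1)
  expect_true(lab[10, 10] == 1)
  # a single above-threshold pixel is removed as noise
  img2 <- matrix(1, 10, 10)
  img2[5, 5] <- 9
  expect_equal(max(build_tip_mask(img2)), 0)
})

test_that("classification follows the 0.5 / 1.1 um extent criteria", {
  bars <- list(
    list(y = 6, xs = 10:14, ipeak = 3, peak = 5),   # 0.2 um/side -> rod
    list(y = 8, xs = 25:37, ipeak = 7, peak = 5),   # 1.3 um total -> cone
    list(y = 10, xs = 45:53, ipeak = 2, peak = 5)   # 0.1/0.7 um sides -> excluded
  )
  st <- normalize_to_onl(make_bar_stack(bars))
  roi_vol <- st$channels$reference[, 1:15, , drop = FALSE]
  mx <- find_local_maxima_3d(roi_vol)
  mask <- build_tip_mask(z_avg <- apply(roi_vol, c(2, 3), mean))
  rec <- classify_and_sum(st, mx, mask)
  rec <- dplyr::arrange(rec, x)
  expect_equal(rec$class, c("rod", "cone", "excluded"))
  # extents agree with a brute-force pixel scan of the averaged image
  for (i in seq_len(nrow(rec))) {
    ext <- oracle_run_extent(z_avg, rec$y[i], rec$x[i])
    expect_equal(rec$extent_left_um[i], ext["left"] * 0.1, ignore_attr = TRUE)
    expect_equal(rec$extent_right_um[i], ext["right"] * 0.1, ignore_attr = TRUE)
  }
})

test_that("window sums equal brute-force pixel sums in background units", {
  sim <- sim_confocal_stack(sim_config(seed = 12), n_rod = 3, n_cone = 1,
                            roi_width = 25)
  q <- quantify_section(sim$stack)
  norm <- normalize_to_onl(sim$stack)
  zimg <- apply(norm$channels$target[, 1:75, , drop = FALSE], c(2, 3), mean)
  for (i in seq_len(nrow(q$puncta))) {
    y <- q$puncta$y[i]; x <- q$puncta$x[i]
    manual <- sum(zimg[(y - 5):(y + 5), (x - 5):(x + 5)] - 1)
    expect_equal(q$puncta$sum_target[i], manual, tolerance = 1e-12)
  }
})

test_that("OPL mean is thresholded, background-subtracted and flags empty ROIs", {
  sim <- sim_confocal_stack(sim_config(seed = 13), n_rod = 4, n_cone = 0,
                            roi_width = 25)
  norm <- normalize_to_onl(sim$stack)
  opl <- opl_mean_intensity(norm)
  # brute-force oracle: z-average ROI, keep pixels > 1, average (value - 1)
  zimg <- apply(norm$channels$reference[, 1:75, , drop = FALSE], c(2, 3), mean)
  manual <- sum((zimg - 1)[zimg > 1]) / length(zimg)
  expect_equal(opl$opl_mean[opl$channel == "reference"], manual, tolerance = 1e-12)
  # a background-only ROI scores 0 and is flagged
  empty <- sim_confocal_stack(sim_config(seed = 13), n_rod = 0, n_cone = 0,
                              roi_width = 25)
  opl0 <- opl_mean_intensity(normalize_to_onl(empty$stack))
  expect_true(all(opl0$flagged))
  expect_true(all(opl0$opl_mean == 0))
})

test_that("section quantification is complete, correct and scale invariant", {
  sim <- sim_confocal_stack(sim_config(seed = 14), n_rod = 6, n_cone = 2,
                            roi_width = 40)
  q <- quantify_section(sim$stack)
  # detection completeness and perfect classification
  expect_equal(nrow(q$puncta), nrow(sim$truth))
  got <- dplyr::arrange(q$puncta, z, y, x)[, c("z", "y", "x", "class")]
  want <- dplyr::arrange(sim$truth, z, y, x)[, c("z", "y", "x", "class")]
  expect_equal(tibble::as_tibble(got), tibble::as_tibble(want))
  # rescaling the raw slide changes nothing downstream
  scaled <- sim$stack
  scaled$channels <- lapply(scaled$channels, function(v) v * 0.37)
  q2 <- quantify_section(scaled)
  expect_equal(q2$summary, q$summary, tolerance = 1e-12)
  expect_equal(q2$opl, q$opl, tolerance = 1e-12)
  # empty stack: no puncta, class averages undefined
  empty <- sim_confocal_stack(sim_config(seed = 14), n_rod = 0, n_cone = 0,
                              roi_width = 25)
  q0 <- quantify_section(empty$stack)
  expect_equal(nrow(q0$puncta), 0)
  expect_true(all(!q0$summary$defined))
})

test_that("infeasible punctum placement fails loudly", {
  expect_error(sim_confocal_stack(sim_config(seed = 1), n_rod = 50, n_cone = 10,
                                  roi_width = 30),
               "cannot place")
})
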