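#' Simulate a two-channel confocal stack with ground truth
#'
#' Builds a synthetic z-stack emulating an OPL section co-stained for a
#' punctum-marker reference channel (mGluR6 proxy) and a target protein
#' channel (RGS7 / G-beta-5 proxy). The image contains an OPL band (the
#' quantification ROI) holding the puncta and an ONL band of pure
#' background. Rod-tip puncta are small isotropic blobs; cone-tip puncta are
#' horizontally elongated patches. Both channels share punctum centres; the
#' target-channel amplitude is multiplied by `effect` (the KO/WT staining
#' ratio for knockout sections).
#'
#' Blobs are Gaussian profiles truncated at `trunc_frac` of their peak, so
#' the above-background footprint is finite and the rod/cone extent
#' criteria (at most 0.5 um each side of the centre for rods, more than
#' 1.1 um total for cones) hold with a safety margin of at least two
#' pixels, making the ground-truth classification unambiguous. Punctum
#' centres are laid out with a guaranteed minimum separation larger than
#' the 1.1 x 1.1 um quantification window; if the requested puncta cannot
#' fit in the ROI at that separation, generation fails.
#'
#' Raw intensities are `onl_mean * (1 + signal)` with the OPL background
#' equal to the ONL background, so after [normalize_to_onl()] the
#' background is exactly 1 and blob intensities are in background units.
#'
#' @param config a [sim_config()] (voxel size and seed).
#' @param n_rod,n_cone number of rod and cone puncta.
#' @param channel_intensities named numeric: peak blob intensity per channel
#'   in ONL-background units, names `reference` and `target`.
#' @param effect multiplier applied to target-channel amplitudes
#'   (1 for WT; the KO/WT effect ratio for KO sections).
#' @param roi_width,roi_height OPL ROI size in micrometres (defaults:
#'   105 x 7.5 um).
#' @param onl_height,gap ONL band height and OPL-ONL gap (um).
#' @param nz number of z slices.
#' @param onl_mean raw background level (arbitrary camera units).
#' @param sigma_rod,sigma_cone_x,sigma_cone_y,sigma_z Gaussian widths (um).
#' @param trunc_frac truncation threshold as a fraction of blob peak.
#' @param rod_sep,cone_sep horizontal slot widths per punctum (um).
#' @param amp_jitter_cv per-punctum log-normal amplitude jitter (unit mean).
#' @param img_noise `"none"`, `"gaussian"`, or `"poisson-gaussian"` voxel
#'   noise added to the raw stack.
#' @param img_noise_sd Gaussian noise SD in ONL-background units.
#' @param seed seed for placement/noise; defaults to `config$seed`.
#' @return A list: `stack` (a raw [confocal_stack()]) and `truth` (tibble
#'   with one row per punctum: voxel centre `z`,`y`,`x` in ROI-frame pixel
#'   coordinates, `class`, injected `ref_amp`, `target_amp`).
#' @export
#' @examples
#' sim <- sim_confocal_stack(sim_config(seed = 1), n_rod = 4, n_cone = 1,
#'                           roi_width = 30)
#' sim$truth
sim_confocal_stack <- function(config = sim_config(), n_rod = 20, n_cone = 4,
                               channel_intensities = c(reference = 4, target = 5),
                               effect = 1,
                               roi_width = 105, roi_height = 7.5,
                               onl_height = 3, gap = 0.6, nz = 9,
                               onl_mean = 50,
                               sigma_rod = 0.12, sigma_cone_x = 0.55,
                               sigma_cone_y = 0.12, sigma_z = 0.3,
                               trunc_frac = 0.05,
                               rod_sep = 2.5, cone_sep = 4.5,
                               amp_jitter_cv = 0,
                               img_noise = c("none", "gaussian", "poisson-gaussian"),
                               img_noise_sd = 0.05,
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_rod >= 0, n_cone >= 0, effect > 0)
  img_noise <- match.arg(img_noise)
  if (is.null(seed)) seed <- config$seed
  vs <- config$voxel_size
  dx <- vs[["x"]]; dy <- vs[["y"]]; dz <- vs[["z"]]
  ncol_x <- round(roi_width / dx)
  h_opl <- round(roi_height / dy)
  h_gap <- round(gap / dy)
  h_onl <- round(onl_height / dy)
  nrow_y <- h_opl + h_gap + h_onl
  margin_x <- 2                                  # um kept clear at ROI ends
  n <- n_rod + n_cone
  slot <- c(rep(rod_sep, n_rod), rep(cone_sep, n_cone))
  if (n > 0 && sum(slot) + 2 * margin_x > roi_width) {
    stop(sprintf("cannot place %d rod + %d cone puncta in a %g um ROI at the required separation",
                 n_rod, n_cone, roi_width), call. = FALSE)
  }

  with_seed(seed, {
    classes <- c(rep("rod", n_rod), rep("cone", n_cone))
    ord <- if (n > 1) sample.int(n) else seq_len(n)
    classes <- classes[ord]
    slot <- slot[ord]
    # pack slots left-to-right, spreading any slack uniformly
    slack <- if (n > 0) (roi_width - 2 * margin_x - sum(slot)) / n else 0
    centres_x_um <- margin_x + cumsum(slot + slack) - (slot + slack) / 2
    y_lo <- 1.5; y_hi <- roi_height - 1.5
    centres_y_um <- if (n > 0) runif(n, y_lo, y_hi) else numeric(0)
    zc <- if (n > 0) sample(seq(ceiling(nz / 2) - 1, ceiling(nz / 2) + 1), n, replace = TRUE) else integer(0)
    xi <- pmin(pmax(round(centres_x_um / dx), 1L), ncol_x)
    yi <- pmin(pmax(round(centres_y_um / dy), 1L), h_opl)

    base_ref <- channel_intensities[["reference"]]
    base_tgt <- channel_intensities[["target"]]
    jit_ref <- rlnorm_unit(n, amp_jitter_cv)
    jit_tgt <- rlnorm_unit(n, amp_jitter_cv)
    ref_amp <- base_ref * jit_ref
    tgt_amp <- base_tgt * jit_tgt * effect

    sig_ref <- array(0, dim = c(nz, nrow_y, ncol_x))
    sig_tgt <- array(0, dim = c(nz, nrow_y, ncol_x))
    for (i in seq_len(n)) {
      sx <- if (classes[i] == "rod") sigma_rod else sigma_cone_x
      sy <- if (classes[i] == "rod") sigma_rod else sigma_cone_y
      g <- blob_profile(zc[i], yi[i], xi[i], sx, sy, sigma_z, vs,
                        trunc_frac, dim_zyx = c(nz, nrow_y, ncol_x))
      sig_ref[g$idx] <- sig_ref[g$idx] + ref_amp[i] * g$val
      sig_tgt[g$idx] <- sig_tgt[g$idx] + tgt_amp[i] * g$val
    }

    raw_ref <- onl_mean * (1 + sig_ref)
    raw_tgt <- onl_mean * (1 + sig_tgt)
    if (img_noise != "none") {
      nv <- length(raw_ref)
      if (img_noise == "poisson-gaussian") {
        raw_ref <- stats::rpois(nv, raw_ref) + 0
        raw_tgt <- stats::rpois(nv, raw_tgt) + 0
        dim(raw_ref) <- dim(raw_tgt) <- c(nz, nrow_y, ncol_x)
      }
      raw_ref <- raw_ref + rnorm(nv, sd = img_noise_sd * onl_mean)
      raw_tgt <- raw_tgt + rnorm(nv, sd = img_noise_sd * onl_mean)
      dim(raw_ref) <- dim(raw_tgt) <- c(nz, nrow_y, ncol_x)
    }

    stack <- confocal_stack(
      channels = list(reference = raw_ref, target = raw_tgt),
      voxel_size = vs,
      roi = c(x = 0, y = 0, width = ncol_x * dx, height = h_opl * dy),
      onl = c(x = 0, y = (h_opl + h_gap) * dy, width = ncol_x * dx,
              height = h_onl * dy)
    )
    truth <- tibble::tibble(
      punctum = seq_len(n), class = classes,
      z = zc, y = as.integer(yi), x = as.integer(xi),
      ref_amp = ref_amp, target_amp = tgt_amp
    )
    list(stack = stack, truth = truth)
  })
}

# Truncated separable Gaussian stamped around a voxel centre.
# Returns linear indices and values for the non-zero region.
blob_profile <- function(zc, yc, xc, sigma_x, sigma_y, sigma_z, voxel_size,
                         trunc_frac, dim_zyx) {
  dx <- voxel_size[["x"]]; dy <- voxel_size[["y"]]; dz <- voxel_size[["z"]]
  r <- sqrt(-2 * log(trunc_frac))                # truncation radius in sigmas
  xs <- seq.int(max(1L, xc - ceiling(r * sigma_x / dx)),
                min(dim_zyx[3], xc + ceiling(r * sigma_x / dx)))
  ys <- seq.int(max(1L, yc - ceiling(r * sigma_y / dy)),
                min(dim_zyx[2], yc + ceiling(r * sigma_y / dy)))
  zs <- seq.int(max(1L, zc - ceiling(r * sigma_z / dz)),
                min(dim_zyx[1], zc + ceiling(r * sigma_z / dz)))
  gx <- exp(-((xs - xc) * dx)^2 / (2 * sigma_x^2))
  gy <- exp(-((ys - yc) * dy)^2 / (2 * sigma_y^2))
  gz <- exp(-((zs - zc) * dz)^2 / (2 * sigma_z^2))
  g <- outer(gz, outer(gy, gx))                  # (z, y, x)
  g[g < trunc_frac] <- 0
  keep <- which(g > 0)
  grid <- as.matrix(expand.grid(z = zs, y = ys, x = xs))
  idx <- grid[keep, 1] + (grid[keep, 2] - 1) * dim_zyx[1] +
    (grid[keep, 3] - 1) * dim_zyx[1] * dim_zyx[2]
  list(idx = idx, val = g[keep])
}

#' Simulate a matched WT/KO pair of stacks
#'
#' Generates two sections with identical punctum placement and amplitudes,
#' except that the knockout target channel is scaled by the configured
#' `effect_ratio` — emulating a littermate pair stained and imaged
#' together. Noise-free, the KO/WT ratio of any linear intensity statistic
#' of the target channel equals `effect_ratio` exactly.
#'
#' @inheritParams sim_confocal_stack
#' @param pair index of the pair; combined with `config$seed` to derive a
#'   deterministic per-pair stream.
#' @param ... passed on to [sim_confocal_stack()].
#' @return List with elements `WT` and `KO`, each a
#'   [sim_confocal_stack()] result.
#' @export
sim_stack_pair <- function(config = sim_config(), pair = 1L, ...) {
  s <- derive_seed(config$seed, pair)
  list(
    WT = sim_confocal_stack(config, effect = 1, seed = s, ...),
    KO = sim_confocal_stack(config, effect = config$effect_ratio, seed = s, ...)
  )
}
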