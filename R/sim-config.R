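#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators. The defaults
#' mirror the experimental design the generators emulate: 7 wild-type/knockout
#' littermate pairs, ERG sampling at 0.2 ms, confocal voxels of
#' 0.1 x 0.1 um in-plane and 0.3 um per slice, and a true KO/WT staining
#' effect ratio of 1.4.
#'
#' @param seed integer root seed; every generator derives deterministic
#'   per-object substreams from it, so a fixed config yields bit-identical
#'   output.
#' @param n_pairs number of WT/KO littermate pairs (>= 1).
#' @param effect_ratio true KO/WT staining intensity ratio (> 0),
#'   applied to the target channel of KO stacks.
#' @param noise_sd additive Gaussian noise SD for traces, in amplitude units.
#' @param sample_dt trace sample interval in seconds (> 0).
#' @param voxel_size named numeric `c(x=, y=, z=)`, micrometres per pixel
#'   in-plane and micrometres per z slice.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_pairs = 7)
sim_config <- function(seed = 1L, n_pairs = 7L, effect_ratio = 1.4,
                       noise_sd = 0, sample_dt = 2e-4,
                       voxel_size = c(x = 0.1, y = 0.1, z = 0.3)) {
  if (!is.numeric(effect_ratio) || effect_ratio <= 0) {
    stop("`effect_ratio` must be > 0", call. = FALSE)
  }
  if (!is.numeric(sample_dt) || sample_dt <= 0) {
    stop("`sample_dt` must be > 0", call. = FALSE)
  }
  if (!is.numeric(n_pairs) || n_pairs < 1) stop("`n_pairs` must be >= 1", call. = FALSE)
  vs <- voxel_size[c("x", "y", "z")]
  if (any(is.na(vs)) || any(vs <= 0)) {
    stop("`voxel_size` must be named c(x=, y=, z=) and positive", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_pairs = as.integer(n_pairs),
      effect_ratio = effect_ratio, noise_sd = noise_sd,
      sample_dt = sample_dt, voxel_size = vs
    ),
    class = "sim_config"
  )
}
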