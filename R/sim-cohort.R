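#' Simulate an ERG cohort of WT/KO littermate pairs
#'
#' For each littermate pair, generates scotopic B-wave sessions for a
#' wild-type and a knockout mouse (two eyes each, one dim and one saturating
#' flash per eye, emulating the two-flash sensitivity protocol). The
#' knockout sensitivity `S_B` is scaled by `sensitivity_factor` relative to
#' its littermate while `B_max` is drawn from the same distribution for both
#' genotypes, so the cohort carries a sensitivity effect but no amplitude
#' effect. An oscillatory component rides the saturating-flash response;
#' with `op_coupling = TRUE` its amplitude is proportional to the eye's
#' `S_B`, producing a positive oscillation-vs-sensitivity correlation.
#'
#' Mouse-level parameters are log-normal with unit mean, so
#' `mean(KO S_B) / mean(WT S_B)` equals `sensitivity_factor` in expectation.
#' With `sensitivity_factor = 1` and `noise_sd = 0` the KO session is an
#' exact copy of the WT session (cv terms apply identically), so downstream
#' paired tests are degenerate by symmetry.
#'
#' @param config a [sim_config()]; `seed`, `n_pairs`, `noise_sd` and
#'   `sample_dt` are used.
#' @param sensitivity_factor true KO/WT ratio of `S_B`.
#' @param s_b_base,b_max_base population-typical sensitivity
#'   (\[cd.s/m2\]^-1) and saturating amplitude (uV).
#' @param flashes numeric vector of flash intensities (cd.s/m2); the default
#'   is the dim / saturating scotopic pair used by the two-flash protocol.
#' @param cv_mouse,cv_eye log-normal coefficients of variation of
#'   mouse-level parameters and eye-level deviations.
#' @param op_coupling logical; couple oscillation amplitude to `S_B`.
#' @param op_freq,op_gain oscillation frequency (Hz) and amplitude scale
#'   (uV at `S_B = s_b_base`).
#' @param cv_op log-normal cv of the oscillation amplitude around its mean.
#' @return A list with `traces` (long tibble: pair, genotype, mouse, eye,
#'   flash_intensity, t, value; attributes `dt`, `t_flash`) and `truth`
#'   (one row per eye with the true `S_B`, `B_max`, oscillation amplitude).
#' @export
#' @examples
#' coh <- sim_erg_cohort(sim_config(seed = 1, n_pairs = 2))
#' dplyr::count(coh$traces, genotype)
sim_erg_cohort <- function(config = sim_config(),
                           sensitivity_factor = 1.5,
                           s_b_base = 2000, b_max_base = 400,
                           flashes = c(0.00022, 0.011),
                           cv_mouse = 0.15, cv_eye = 0.07,
                           op_coupling = TRUE, op_freq = 120,
                           op_gain = 20, cv_op = 0.2) {
  stopifnot(inherits(config, "sim_config"), length(flashes) >= 1)
  n_pairs <- config$n_pairs
  sat_flash <- max(flashes)
  with_seed(config$seed, {
    truth <- vector("list", n_pairs * 4L)
    rows <- vector("list", 0L)
    k <- 0L
    for (p in seq_len(n_pairs)) {
      sb_wt <- s_b_base * rlnorm_unit(1, cv_mouse)
      bmax_wt <- b_max_base * rlnorm_unit(1, cv_mouse)
      for (gt in c("WT", "KO")) {
        sb_mouse <- if (gt == "WT") sb_wt else sensitivity_factor * sb_wt
        bmax_mouse <- bmax_wt
        mouse <- sprintf("P%02d_%s", p, gt)
        for (eye in c("L", "R")) {
          sb_eye <- sb_mouse * rlnorm_unit(1, cv_eye)
          bmax_eye <- bmax_mouse * rlnorm_unit(1, cv_eye)
          op_amp <- if (op_coupling) {
            op_gain * (sb_eye / s_b_base) * rlnorm_unit(1, cv_op)
          } else {
            op_gain * rlnorm_unit(1, cv_op)
          }
          k <- k + 1L
          truth[[k]] <- tibble::tibble(
            pair = p, genotype = gt, mouse = mouse, eye = eye,
            S_B = sb_eye, B_max = bmax_eye, op_amp = op_amp
          )
          for (I in flashes) {
            tr <- sim_bwave(
              S_B = sb_eye, B_max = bmax_eye, I = I,
              op = if (I == sat_flash) quiet_op_spec(op_freq, op_amp) else NULL,
              dt = config$sample_dt, noise_sd = config$noise_sd
            )
            rows[[length(rows) + 1L]] <- tibble::tibble(
              pair = p, genotype = gt, mouse = mouse, eye = eye,
              flash_intensity = I, t = tr$t, value = tr$value
            )
          }
        }
      }
    }
    traces <- dplyr::bind_rows(rows)
    attr(traces, "dt") <- config$sample_dt
    attr(traces, "t_flash") <- 0
    list(traces = traces, truth = dplyr::bind_rows(truth[seq_len(k)]))
  })
}

# log-normal with exact unit mean and coefficient of variation cv
rlnorm_unit <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# op_spec without the out-of-band warning (cohort frequencies are in band
# by default; re-validate silently for internal use)
quiet_op_spec <- function(freq, amp) {
  suppressWarnings(op_spec(freq, amp))
}

#' Simulate paired WT/KO staining intensities
#'
#' Generates `n` WT intensities `x_i`, log-normal about 1 with coefficient
#' of variation `cv`, and KO intensities
#' `y_i = true_ratio * x_i * e_i` with unit-mean log-normal noise `e_i`
#' (same `cv`). With `cv = 0` every pair satisfies `y_i / x_i = true_ratio`
#' exactly.
#'
#' With `structure = "independent"` the two members are measured with
#' independent noise (`x_i` log-normal about 1, `y_i` log-normal about
#' `true_ratio`), the regime in which the plain ratio-of-sums estimator
#' carries its classic O(1/n) bias — use this for studying the jackknife
#' bias correction. The default `"shared"` structure keeps the noise on
#' `y` multiplicative on `x`, matching paired staining where both members
#' share a section-level intensity.
#'
#' @param n number of pairs (>= 2).
#' @param true_ratio true KO/WT intensity ratio (> 0).
#' @param cv coefficient of variation of the log-normal noise (>= 0).
#' @param seed optional seed; the same seed reproduces the same sample.
#' @param structure `"shared"` (default) or `"independent"`; see Details.
#' @return A tibble with columns `pair`, `x`, `y`; attribute `"truth"`
#'   records `true_ratio` and `cv`.
#' @export
#' @examples
#' sim_paired_samples(6, true_ratio = 1.4, cv = 0.2, seed = 1)
sim_paired_samples <- function(n, true_ratio, cv = 0.2, seed = NULL,
                               structure = c("shared", "independent")) {
  structure <- match.arg(structure)
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (!is.numeric(true_ratio) || true_ratio <= 0) {
    stop("`true_ratio` must be > 0", call. = FALSE)
  }
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  with_seed(seed, {
    x <- rlnorm_unit(n, cv)
    y <- if (structure == "shared") {
      true_ratio * x * rlnorm_unit(n, cv)
    } else {
      true_ratio * rlnorm_unit(n, cv)
    }
    out <- tibble::tibble(pair = seq_len(n), x = x, y = y)
    attr(out, "truth") <- list(true_ratio = true_ratio, cv = cv)
    out
  })
}
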