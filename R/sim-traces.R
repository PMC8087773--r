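#' Simulate a photoreceptor rising-phase trace
#'
#' Generates the activation phase of a flash response under the delayed
#' Gaussian-exponential model
#' \deqn{A(I,t)/A_{max} = 1 - \exp(-S_A I (t - t_d)^2)}
#' i.e. zero up to the fixed delay `t_d` after the flash, then a rising
#' phase that saturates towards `A_max`. Only the rising phase is modelled;
#' an optional plateau cap (`plateau_frac < 1`) holds the trace at
#' `plateau_frac * A_max` once reached, standing in for the unmodelled
#' recovery phase.
#'
#' @param S_A sensitivity (per-intensity-unit per second squared, > 0).
#' @param A_max saturating amplitude (> 0), pA for photocurrent or uV for
#'   the ERG A-wave.
#' @param t_d fixed delay in seconds (> 0).
#' @param I flash intensity (> 0), in the unit that matches `S_A`.
#' @param dt sample interval in seconds (> 0).
#' @param duration trace duration in seconds (> `t_d`); flash at time 0.
#' @param noise_sd additive Gaussian noise SD (amplitude units).
#' @param plateau_frac fraction of `A_max` at which the rising phase is
#'   capped (default 1 = follow the model asymptote).
#' @param seed optional seed for the noise stream.
#' @param polarity passed to [new_trace()].
#' @param intensity_unit unit label for `I`.
#' @return An `rs_trace` with ground truth stored in attribute `"truth"`.
#' @export
#' @examples
#' tr <- sim_rising_phase(S_A = 7.1, A_max = 14.1, t_d = 0.015, I = 10,
#'                        dt = 1e-3, duration = 0.1)
#' attr(tr, "truth")
sim_rising_phase <- function(S_A, A_max, t_d, I, dt = 1e-3, duration = 0.2,
                             noise_sd = 0, plateau_frac = 1, seed = NULL,
                             polarity = "photocurrent",
                             intensity_unit = "R*/rod") {
  for (nm in c("S_A", "A_max", "t_d", "I", "dt", "duration")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
    }
  }
  if (duration <= t_d) stop("`duration` must exceed `t_d`", call. = FALSE)
  t <- seq(0, duration, by = dt)
  clean <- rising_phase_model(t, S_A = S_A, A_max = A_max, t_d = t_d, I = I)
  cap <- plateau_frac * A_max
  clean <- pmin(clean, cap)
  value <- if (noise_sd > 0) {
    with_seed(seed, clean + rnorm(length(clean), sd = noise_sd))
  } else {
    clean
  }
  out <- new_trace(value, dt = dt, t_flash = 0, polarity = polarity,
                   flash_intensity = I, intensity_unit = intensity_unit)
  attr(out, "truth") <- tibble::tibble(S_A = S_A, A_max = A_max, t_d = t_d,
                                       I = I, noise_sd = noise_sd)
  out
}

# The activation model itself; t relative to the flash.
rising_phase_model <- function(t, S_A, A_max, t_d, I) {
  dtd <- pmax(t - t_d, 0)
  A_max * (1 - exp(-S_A * I * dtd^2))
}

#' Describe an oscillatory-potential component for simulation
#'
#' @param freq oscillation frequency in Hz; physiological oscillatory
#'   potentials lie in 75-300 Hz, and a frequency outside that band is
#'   generated but triggers a warning and is flagged in the ground truth.
#' @param amp peak amplitude (uV) of the oscillation; the injected
#'   peak-to-trough swing is approximately `2 * amp`.
#' @param n_cycles width of the Gaussian envelope, in oscillation cycles.
#' @return A list describing the component.
#' @export
op_spec <- function(freq, amp, n_cycles = 1.5) {
  stopifnot(is.numeric(freq), freq > 0, is.numeric(amp), amp >= 0)
  in_band <- freq >= 75 && freq <= 300
  if (!in_band) {
    warning(sprintf("oscillation frequency %g Hz is outside the 75-300 Hz band", freq),
            call. = FALSE)
  }
  list(freq = freq, amp = amp, n_cycles = n_cycles, in_band = in_band)
}

#' Simulate an ERG B-wave trace
#'
#' The peak amplitude follows the hyperbolic saturation law
#' \deqn{B/B_{max} = S_B I / (1 + S_B I)}
#' The kinetic waveform itself is not constrained by the saturation law;
#' a gamma-function rise-and-decay \eqn{(t/t_{pk})^k e^{k(1 - t/t_{pk})}}
#' scaled so its peak equals the law's amplitude is used, because only the
#' peak amplitude and the rising phase feed the downstream analysis. An
#' optional oscillatory component ([op_spec()]) is added as a
#' Gaussian-windowed sinusoid centred on the rising phase, emulating
#' oscillatory potentials riding the B-wave.
#'
#' @param S_B sensitivity, the inverse of the half-saturating intensity
#'   (>= 0).
#' @param B_max saturating B-wave amplitude in uV (>= 0).
#' @param I flash intensity (>= 0).
#' @param op optional [op_spec()] oscillation descriptor.
#' @param dt sample interval in seconds.
#' @param duration trace duration in seconds; flash at time 0, preceded by
#'   `pre_flash` seconds of baseline.
#' @param pre_flash baseline duration before the flash (s).
#' @param t_peak time-to-peak of the gamma kinetics (s).
#' @param shape_k gamma shape parameter.
#' @param noise_sd additive Gaussian noise SD (uV).
#' @param seed optional seed for the noise stream.
#' @param intensity_unit unit label for `I`.
#' @return An `rs_trace` (corneal-positive) with attribute `"truth"`
#'   recording `S_B`, `B_max`, `I`, the true peak amplitude and the
#'   injected oscillation.
#' @export
#' @examples
#' tr <- sim_bwave(S_B = 1, B_max = 100, I = 1, dt = 2e-4)
#' attr(tr, "truth")$peak  # 50 at half-saturation
sim_bwave <- function(S_B, B_max, I, op = NULL, dt = 2e-4, duration = 0.35,
                      pre_flash = 0.05, t_peak = 0.08, shape_k = 4,
                      noise_sd = 0, seed = NULL, intensity_unit = "cd.s/m2") {
  stopifnot(S_B >= 0, B_max >= 0, I >= 0, dt > 0, duration > 0)
  peak <- B_max * S_B * I / (1 + S_B * I)
  if (S_B == 0 && I == 0) peak <- 0
  t <- seq(-pre_flash, duration, by = dt)
  tf <- pmax(t, 0)
  kin <- (tf / t_peak)^shape_k * exp(shape_k * (1 - tf / t_peak))
  clean <- peak * kin
  if (!is.null(op) && op$amp > 0) {
    # centre the oscillation where the b-wave crosses half its peak
    half_idx <- which(clean >= peak / 2 & t > 0)[1]
    centre <- if (is.na(half_idx)) t_peak / 2 else t[half_idx]
    width <- op$n_cycles / op$freq
    env <- exp(-(t - centre)^2 / (2 * width^2))
    clean <- clean + op$amp * env * sin(2 * pi * op$freq * (t - centre))
  }
  value <- if (noise_sd > 0) {
    with_seed(seed, clean + rnorm(length(clean), sd = noise_sd))
  } else {
    clean
  }
  out <- new_trace(value, dt = dt, t_flash = 0, t0 = -pre_flash,
                   polarity = "corneal-positive",
                   flash_intensity = I, intensity_unit = intensity_unit)
  attr(out, "truth") <- tibble::tibble(
    S_B = S_B, B_max = B_max, I = I, peak = peak,
    op_freq = if (is.null(op)) NA_real_ else op$freq,
    op_amp = if (is.null(op)) NA_real_ else op$amp,
    op_in_band = if (is.null(op)) NA else op$in_band
  )
  out
}
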