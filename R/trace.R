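#' Construct a physiological trace
#'
#' A trace is a tibble with columns `t` (seconds) and `value` (amplitude:
#' microvolts for ERG, picoamps for photocurrent) plus metadata attributes:
#' the sample interval `dt`, the flash time `t_flash`, the recording
#' `polarity` and the flash intensity `flash_intensity` (with its unit).
#' Traces are ordinary tibbles, so all dplyr verbs apply; the analysis
#' functions read the metadata through the accessors below.
#'
#' @param value numeric vector of sampled amplitudes (finite, length >= 2).
#' @param dt sample interval in seconds (> 0).
#' @param t_flash flash onset time in seconds (default 0; samples start at
#'   `t0`).
#' @param t0 time of the first sample in seconds.
#' @param polarity `"corneal-positive"` for ERG or `"photocurrent"` for
#'   suction-electrode recordings (stored response-positive).
#' @param flash_intensity flash strength; units given by `intensity_unit`.
#' @param intensity_unit character, e.g. `"cd.s/m2"` or `"R*/rod"`.
#' @param ... additional id tags (mouse, genotype, eye, ...) stored as
#'   attributes.
#' @return A `rs_trace` tibble with columns `t`, `value`.
#' @export
#' @examples
#' tr <- new_trace(sin(seq(0, 1, by = 0.01)), dt = 0.01)
#' trace_dt(tr)
new_trace <- function(value, dt, t_flash = 0, t0 = 0,
                      polarity = c("corneal-positive", "photocurrent"),
                      flash_intensity = NA_real_, intensity_unit = NA_character_,
                      ...) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (length(value) < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(value))) stop("trace values must be finite", call. = FALSE)
  polarity <- match.arg(polarity)
  out <- tibble::tibble(t = t0 + dt * (seq_along(value) - 1), value = as.double(value))
  attr(out, "dt") <- dt
  attr(out, "t_flash") <- t_flash
  attr(out, "polarity") <- polarity
  attr(out, "flash_intensity") <- flash_intensity
  attr(out, "intensity_unit") <- intensity_unit
  tags <- list(...)
  if (length(tags)) attr(out, "tags") <- tags
  class(out) <- c("rs_trace", class(out))
  out
}

#' Trace metadata accessors
#'
#' @param x an `rs_trace`.
#' @return `trace_dt()`, `trace_t_flash()`, `trace_intensity()` return
#'   scalars; `trace_polarity()` a string.
#' @export
trace_dt <- function(x) attr(x, "dt")

#' @rdname trace_dt
#' @export
trace_t_flash <- function(x) attr(x, "t_flash")

#' @rdname trace_dt
#' @export
trace_polarity <- function(x) attr(x, "polarity")

#' @rdname trace_dt
#' @export
trace_intensity <- function(x) attr(x, "flash_intensity")

#' @export
autoplot.rs_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = trace_t_flash(object), linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "time (s)",
      y = if (identical(trace_polarity(object), "photocurrent")) "current (pA)" else "voltage (µV)"
    )
}
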