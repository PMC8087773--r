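#' Measure the B-wave amplitude of a flash response
#'
#' Amplitude is the post-flash maximum minus the pre-flash baseline (mean
#' of the `baseline_s` seconds before the flash), clamped at zero. The
#' paper-convention pre-processing — 22.5 Hz low-pass filtering — is the
#' caller's responsibility (see [filter_butterworth()]). A trough-to-peak
#' mode is available for recordings without a usable pre-flash baseline.
#'
#' @param trace an `rs_trace` holding a corneal-positive flash response.
#' @param window numeric `c(start, end)` in seconds (absolute trace time)
#'   within which the peak is sought; default is flash-to-end.
#' @param baseline_s length of the pre-flash baseline segment (s).
#' @param mode `"baseline"` (default) or `"trough_to_peak"`.
#' @return A one-row tibble: `I` (flash intensity), `B` (amplitude),
#'   `t_peak`, `baseline`.
#' @export
#' @examples
#' tr <- sim_bwave(S_B = 1, B_max = 100, I = 1, dt = 2e-4)
#' bwave_amplitude(tr)$B  # ~50 at half-saturation
bwave_amplitude <- function(trace, window = NULL, baseline_s = 0.05,
                            mode = c("baseline", "trough_to_peak")) {
  stopifnot(inherits(trace, "rs_trace"))
  mode <- match.arg(mode)
  tf <- trace_t_flash(trace)
  if (is.null(window)) window <- c(tf, max(trace$t))
  sel <- trace$t >= window[1] & trace$t <= window[2]
  if (!any(sel)) stop("amplitude window contains no samples", call. = FALSE)
  post <- trace$value[sel]
  i_pk <- which.max(post)
  ref <- if (mode == "baseline") {
    base_sel <- trace$t < tf & trace$t >= tf - baseline_s
    if (any(base_sel)) mean(trace$value[base_sel]) else 0
  } else {
    min(post[seq_len(i_pk)])
  }
  tibble::tibble(
    I = trace_intensity(trace),
    B = max(post[i_pk] - ref, 0),
    t_peak = trace$t[sel][i_pk],
    baseline = ref
  )
}

#' Fit the hyperbolic saturation law to B-wave amplitudes
#'
#' Fits \deqn{B / B_{max} = S_B I / (1 + S_B I)} where `S_B` is the inverse
#' of the half-saturating intensity. With exactly two measurements the
#' parameters are solved algebraically: the law is linear in reciprocal
#' coordinates, \eqn{1/B = 1/B_{max} + 1/(B_{max} S_B I)}, giving the
#' standard two-flash estimate. With more than two measurements a nonlinear
#' least-squares fit is used, started from the reciprocal-coordinate
#' regression.
#'
#' @param points a data frame with columns `I` (flash intensity, >= 2
#'   distinct values) and `B` (amplitude, > 0), e.g. rows from
#'   [bwave_amplitude()].
#' @return A `saturation_fit` object; see [tidy.saturation_fit()].
#' @export
#' @examples
#' pts <- tibble::tibble(I = c(0.00022, 0.011),
#'                       B = 400 * 2000 * I / (1 + 2000 * I))
#' glance(fit_saturation(pts))
fit_saturation <- function(points) {
  points <- as.data.frame(points)[, c("I", "B")]
  if (anyNA(points) || nrow(points) < 2 || length(unique(points$I)) < 2) {
    stop("need >= 2 measurements at distinct intensities", call. = FALSE)
  }
  if (any(points$B <= 0) || any(points$I <= 0)) {
    stop("intensities and amplitudes must be positive", call. = FALSE)
  }
  if (nrow(points) == 2) {
    # exact inversion: 1/B = a + b / I with a = 1/B_max, b = 1/(S_B B_max)
    b <- diff(1 / points$B) / diff(1 / points$I)
    a <- 1 / points$B[1] - b / points$I[1]
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
      stop("amplitudes are inconsistent with the saturation law (no positive solution)",
           call. = FALSE)
    }
    fit <- list(S_B = a / b, B_max = 1 / a, method = "two-point")
  } else {
    inv_b <- 1 / points$B
    inv_i <- 1 / points$I
    cf <- stats::coef(stats::lm(inv_b ~ inv_i))
    start <- list(S_B = if (cf[1] > 0 && cf[2] > 0) unname(cf[1] / cf[2]) else 1 / stats::median(points$I),
                  B_max = if (cf[1] > 0) unname(1 / cf[1]) else 1.5 * max(points$B))
    m <- tryCatch(
      minpack.lm::nlsLM(B ~ B_max * S_B * I / (1 + S_B * I),
                        data = points, start = start,
                        lower = c(S_B = 1e-12, B_max = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14)),
      error = function(e) stop("saturation fit failed: ", conditionMessage(e), call. = FALSE)
    )
    cf <- stats::coef(m)
    fit <- list(S_B = unname(cf["S_B"]), B_max = unname(cf["B_max"]),
                method = "least-squares")
  }
  structure(c(fit, list(n = nrow(points), data = tibble::as_tibble(points))),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> S_B = %.6g (1/intensity), B_max = %.6g  [%s, n = %d]\n",
              x$S_B, x$B_max, x$method, x$n))
  invisible(x)
}

#' Tidy a saturation fit
#'
#' @param x a `saturation_fit`.
#' @param ... unused.
#' @return `tidy()`: tibble of terms/estimates. `glance()`: one-row tibble
#'   with `S_B`, `B_max`, `n`, `method`.
#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble::tibble(term = c("S_B", "B_max"), estimate = c(x$S_B, x$B_max))
}

#' @rdname tidy.saturation_fit
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(S_B = x$S_B, B_max = x$B_max, n = x$n, method = x$method)
}

#' @export
autoplot.saturation_fit <- function(object, ...) {
  grid <- tibble::tibble(I = exp(seq(log(min(object$data$I) / 3),
                                     log(max(object$data$I) * 3), length.out = 200)))
  grid$B <- object$B_max * object$S_B * grid$I / (1 + object$S_B * grid$I)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$I, y = .data$B)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "flash intensity", y = "B-wave amplitude")
}

#' Convert photon density to photoisomerizations per rod
#'
#' Flash strength at the retina, expressed as photons per square
#' micrometre, times the rod effective collecting area gives the expected
#' number of photoisomerizations (R*) per rod. The default collecting area
#' is 0.5 um^2.
#'
#' @param photon_density photons per um^2 (>= 0, vectorised).
#' @param collecting_area rod collecting area in um^2 (>= 0).
#' @return Photoisomerizations per rod.
#' @export
#' @examples
#' photons_to_isomerizations(20)  # 10 R*/rod
photons_to_isomerizations <- function(photon_density, collecting_area = 0.5) {
  if (any(photon_density < 0) || collecting_area < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  photon_density * collecting_area
}
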