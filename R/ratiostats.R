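#' Two-step normalization of paired staining batches
#'
#' Pre-processing that removes batch and pair scale factors before ratio
#' estimation: first the average staining intensity of all samples on each
#' blot or slide is normalized to 1, then the average intensity of each
#' WT/KO pair is normalized to 1. After the second step every pair mean is
#' exactly 1, and rescaling any single slide by a positive constant leaves
#' the output unchanged. Within-pair ratios `y_i / x_i` are untouched by
#' either step.
#'
#' @param df a data frame with columns `slide` (blot/slide id), `pair`
#'   (pair id), `genotype` (`"WT"` / `"KO"`) and `value` (> 0).
#' @return The input tibble with `value` replaced by its normalized
#'   version.
#' @export
#' @examples
#' df <- tibble::tibble(slide = 1, pair = c(1, 1, 2, 2),
#'                      genotype = c("WT", "KO", "WT", "KO"),
#'                      value = c(2, 3, 4, 5))
#' normalize_paired_batches(df)
normalize_paired_batches <- function(df) {
  need <- c("slide", "pair", "genotype", "value")
  if (!all(need %in% names(df))) {
    stop("`df` needs columns slide, pair, genotype, value", call. = FALSE)
  }
  if (any(df$value <= 0) || anyNA(df$value)) {
    stop("staining intensities must be positive", call. = FALSE)
  }
  out <- df |>
    dplyr::group_by(.data$slide) |>
    dplyr::mutate(value = norm_to_unit_mean(.data$value, "slide")) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$pair) |>
    dplyr::mutate(value = norm_to_unit_mean(.data$value, "pair")) |>
    dplyr::ungroup()
  tibble::as_tibble(out)
}

norm_to_unit_mean <- function(v, what) {
  m <- mean(v)
  if (!is.finite(m) || m <= 0) {
    stop(sprintf("zero or invalid %s mean; cannot normalize", what), call. = FALSE)
  }
  v / m
}

#' Reshape a normalized batch table to paired WT/KO columns
#'
#' @param df output of [normalize_paired_batches()] (or any table with
#'   `pair`, `genotype`, `value`), one WT and one KO sample per pair.
#' @return A tibble `pair`, `x` (WT), `y` (KO).
#' @export
pairs_to_xy <- function(df) {
  wide <- df |>
    dplyr::select("pair", "genotype", "value") |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "value")
  if (!all(c("WT", "KO") %in% names(wide))) {
    stop("each pair needs one WT and one KO sample", call. = FALSE)
  }
  tibble::tibble(pair = wide$pair, x = wide$WT, y = wide$KO)
}

#' Jackknife bias-corrected paired ratio
#'
#' For paired WT/KO intensities \eqn{(x_i, y_i)}, the direct ratio
#' estimate and its leave-one-out companions are
#' \deqn{r = \frac{\sum y_i}{\sum x_i}, \qquad
#'       r_i = \frac{\sum_{j \ne i} y_j}{\sum_{j \ne i} x_j}}
#' with jackknife standard deviation \eqn{s^2 = \frac{1}{n}\sum (r_i - r)^2}.
#' The direct estimate is biased at order \eqn{1/n}; the jackknife
#' bias-corrected estimate
#' \deqn{r_c = n r - \frac{n-1}{n} \sum_i r_i}
#' reduces the bias to \eqn{O(n^{-2})}, with corrected standard deviation
#' \eqn{s_c^2 = \frac{1}{n-1}\sum (r_i - r_c)^2.}
#' When `y = c * x` exactly, the estimator chain returns
#' `r = r_c = c` and `s = s_c = 0`.
#'
#' @param x WT intensities (all > 0), or a data frame with columns `x`,
#'   `y` (in which case `y` is ignored).
#' @param y KO intensities, same length as `x`.
#' @return A `ratio_estimate` object with fields `r`, `r_i`, `s`, `r_c`,
#'   `s_c`, `n`; see [tidy.ratio_estimate()].
#' @export
#' @examples
#' jackknife_ratio(c(1, 2, 3), c(2, 3, 7))
jackknife_ratio <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  n <- length(x)
  if (n < 2 || length(y) != n) {
    stop("need n >= 2 pairs of equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in pairs", call. = FALSE)
  sx <- sum(x); sy <- sum(y)
  if (any(sx - x <= 0)) {
    stop("degenerate sample: a leave-one-out denominator is not positive",
         call. = FALSE)
  }
  if (sx <= 0) stop("sum of WT intensities must be positive", call. = FALSE)
  r <- sy / sx
  r_i <- (sy - y) / (sx - x)
  s <- sqrt(mean((r_i - r)^2))
  r_c <- n * r - (n - 1) / n * sum(r_i)
  s_c <- sqrt(sum((r_i - r_c)^2) / (n - 1))
  structure(list(r = r, r_i = r_i, s = s, r_c = r_c, s_c = s_c, n = n),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate> r = %.4g (s = %.3g); bias-corrected r_c = %.4g (s_c = %.3g); n = %d\n",
              x$r, x$s, x$r_c, x$s_c, x$n))
  invisible(x)
}

#' Tidy a jackknife ratio estimate
#'
#' @param x a `ratio_estimate`.
#' @param ... unused.
#' @return `tidy()`: terms `r` and `r_c` with their jackknife SDs.
#'   `glance()`: one-row tibble `r`, `s`, `r_c`, `s_c`, `n`.
#' @export
tidy.ratio_estimate <- function(x, ...) {
  tibble::tibble(term = c("r", "r_c"), estimate = c(x$r, x$r_c),
                 std.error = c(x$s, x$s_c))
}

#' @rdname tidy.ratio_estimate
#' @export
glance.ratio_estimate <- function(x, ...) {
  tibble::tibble(r = x$r, s = x$s, r_c = x$r_c, s_c = x$s_c, n = x$n)
}

#' @export
autoplot.ratio_estimate <- function(object, ...) {
  df <- tibble::tibble(i = seq_len(object$n), r_i = object$r_i)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$r_i)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$r, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$r_c, colour = "firebrick") +
    ggplot2::labs(x = "left-out pair", y = "leave-one-out ratio",
                  subtitle = sprintf("r = %.3f (dashed), r_c = %.3f (red)",
                                     object$r, object$r_c))
}

#' Paired Student's t-test on WT/KO pairs
#'
#' Two-sided p-value for the mean within-pair difference. Degenerate
#' inputs are resolved explicitly: identical pairs give p = 1, and zero
#' variance with a nonzero mean difference gives p = 0, both flagged.
#'
#' @param x,y paired measurements (same length, n >= 2); or a data frame
#'   with columns `x`, `y`.
#' @return One-row tibble: `estimate` (mean difference), `t`, `df`,
#'   `p.value`, `degenerate`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(1.4, 2.9, 3.1))
paired_t <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  n <- length(x)
  if (n < 2 || length(y) != n) stop("need n >= 2 pairs", call. = FALSE)
  d <- y - x
  if (sd(d) == 0) {
    return(tibble::tibble(estimate = mean(d),
                          t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                          df = n - 1,
                          p.value = if (mean(d) == 0) 1 else 0,
                          degenerate = TRUE))
  }
  ht <- stats::t.test(y, x, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value,
                 degenerate = FALSE)
}

#' Pearson and Spearman correlation with t-transform p-values
#'
#' Computes the Pearson coefficient on values and the Spearman coefficient
#' on (average-tie) ranks. Both p-values use the transformation of a
#' correlation over `n` pairs to a t-statistic with `n - 2` degrees of
#' freedom, \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}, two-sided.
#'
#' @param x,y numeric vectors, length n >= 3; or a data frame with
#'   columns `x`, `y`.
#' @return A tibble with rows `pearson` and `spearman`: `estimate`,
#'   `statistic`, `p.value`, `n`.
#' @export
#' @examples
#' correlations(1:6, c(2, 1, 4, 3, 6, 5))
correlations <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  rp <- stats::cor(x, y)
  rs <- stats::cor(rank(x), rank(y))
  purrr::map2_dfr(c(pearson = rp, spearman = rs), c("pearson", "spearman"),
                  function(r, m) {
    tstat <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
    tibble::tibble(method = m, estimate = r, statistic = tstat,
                   p.value = if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), n - 2),
                   n = n)
  })
}
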