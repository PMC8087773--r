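#' Welch's t-test from summary statistics
#'
#' For two samples summarized by mean `a`, standard error of the mean `s`
#' and size `v`, the statistic and Welch-Satterthwaite effective degrees
#' of freedom are
#' \deqn{t = \frac{a_1 - a_2}{\sqrt{s_1^2 + s_2^2}}, \qquad
#'       v \approx \frac{(s_1^2+s_2^2)^2}{\frac{s_1^4}{v_1-1} + \frac{s_2^4}{v_2-1}}}
#' and the two-sided p-value is evaluated through the regularized
#' incomplete beta function,
#' \deqn{p = I_{v/(v+t^2)}\left(\frac{v}{2}, \frac{1}{2}\right),}
#' the closed form of the two-tailed t-distribution probability.
#'
#' @param a1,s1,v1 mean, SEM and size of the first sample (`v1 >= 2`,
#'   `s1 >= 0`).
#' @param a2,s2,v2 same for the second sample.
#' @return One-row tibble: `t`, `v` (effective df), `p.value`.
#' @export
#' @examples
#' welch_t(5, 0.5, 8, 4, 0.4, 10)
welch_t <- function(a1, s1, v1, a2, s2, v2) {
  check_summary(a1, s1, v1, "1")
  check_summary(a2, s2, v2, "2")
  if (s1 == 0 && s2 == 0) {
    stop("both SEMs are zero: statistic undefined", call. = FALSE)
  }
  t <- (a1 - a2) / sqrt(s1^2 + s2^2)
  v <- (s1^2 + s2^2)^2 / (s1^4 / (v1 - 1) + s2^4 / (v2 - 1))
  tibble::tibble(t = t, v = v, p.value = welch_p(t, v))
}

# two-sided p through the regularized incomplete beta function
welch_p <- function(t, v) {
  stats::pbeta(v / (v + t^2), v / 2, 1 / 2)
}

check_summary <- function(a, s, v, which) {
  if (!is.finite(a) || !is.finite(s) || s < 0) {
    stop(sprintf("invalid mean/SEM for sample %s", which), call. = FALSE)
  }
  if (!is.finite(v) || v < 2) {
    stop(sprintf("sample %s must have size >= 2", which), call. = FALSE)
  }
  invisible(NULL)
}

#' Welch's double-difference t-test (ratio-of-ratios comparison)
#'
#' Extends [welch_t()] to the difference of two differences over four
#' summarized samples:
#' \deqn{t = \frac{(a_1 - a_2) - (a_3 - a_4)}{\sqrt{s_1^2+s_2^2+s_3^2+s_4^2}}}
#' with the four-term Satterthwaite degrees of freedom
#' \deqn{v \approx \frac{(s_1^2+s_2^2+s_3^2+s_4^2)^2}
#'   {\sum_k s_k^4/(v_k-1)}.}
#' With all samples in log expression, \eqn{(a_1-a_2)-(a_3-a_4)} is the
#' log ratio-of-ratios, so this tests whether the relative level of one
#' protein versus another differs between two genotypes while unknown
#' multiplicative factors cancel. Internally the natural log is assumed;
#' the choice of base only rescales `t`'s numerator and denominator
#' identically, so the p-value is base-invariant.
#'
#' @param a,s,v numeric vectors of length 4: means, SEMs and sizes of the
#'   four (log-scale) samples, ordered so the comparison is
#'   `(a[1] - a[2]) - (a[3] - a[4])`.
#' @return One-row tibble: `t`, `v`, `p.value`.
#' @export
#' @examples
#' welch_double_diff(a = c(1.2, 0.8, 1.0, 0.9), s = rep(0.1, 4), v = rep(4, 4))
welch_double_diff <- function(a, s, v) {
  stopifnot(length(a) == 4, length(s) == 4, length(v) == 4)
  for (k in 1:4) check_summary(a[k], s[k], v[k], as.character(k))
  if (all(s == 0)) stop("all four SEMs are zero: statistic undefined", call. = FALSE)
  t <- ((a[1] - a[2]) - (a[3] - a[4])) / sqrt(sum(s^2))
  vv <- sum(s^2)^2 / sum(s^4 / (v - 1))
  tibble::tibble(t = t, v = vv, p.value = welch_p(t, vv))
}

#' Relative dimer-pool protein level from absolute abundances
#'
#' Normalizes the abundance of the remaining RGS protein pool in a mutant
#' to the total wild-type pool: `sum(level) / sum(reference_levels)`.
#' Used for placing knockout data on a common normalized-level axis, e.g.
#' a single remaining paralog measured in fmol per 10 mg against the sum
#' of both paralogs in wild type.
#'
#' @param level abundance(s) in the mutant (same units as reference).
#' @param reference_levels abundance(s) making up the wild-type pool.
#' @return `sum(level) / sum(reference_levels)`.
#' @export
#' @examples
#' relative_pool_level(35, c(20, 23))  # 35/43
relative_pool_level <- function(level, reference_levels) {
  stopifnot(all(level >= 0), all(reference_levels >= 0),
            sum(reference_levels) > 0)
  sum(level) / sum(reference_levels)
}
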