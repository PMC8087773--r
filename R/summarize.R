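#' Summarize per-eye or per-rod fits to per-mouse values
#'
#' Each ERG parameter is measured per eye (two eyes per mouse) and each
#' photocurrent parameter per rod (typically 3-6 rods per mouse); the
#' per-mouse value is the arithmetic mean over those units. Genotype and
#' pair labels are carried through for the downstream paired statistics.
#' Mice represented by a single unit are kept and flagged (`n_units = 1`).
#'
#' @param fits a tibble with one row per eye/rod containing the id columns
#'   in `by` plus numeric parameter columns (e.g. `S_B`, `B_max`, `S_A`,
#'   `A_max`, `op_norm`).
#' @param by character; grouping columns identifying a mouse (labels such
#'   as `pair` and `genotype` should be included so they propagate).
#' @return A tibble with one row per mouse: the mean of every numeric
#'   column and `n_units`.
#' @export
#' @examples
#' fits <- tibble::tibble(mouse = c("m1", "m1", "m2"),
#'                        genotype = c("WT", "WT", "KO"),
#'                        S_B = c(2, 4, 3))
#' summarize_cohort(fits)
summarize_cohort <- function(fits, by = c("mouse", "genotype", "pair")) {
  stopifnot(is.data.frame(fits))
  by <- intersect(by, names(fits))
  if (!length(by)) stop("no grouping columns found in `fits`", call. = FALSE)
  num_cols <- setdiff(names(fits)[vapply(fits, is.numeric, TRUE)], by)
  if (!length(num_cols)) stop("no numeric parameter columns to average", call. = FALSE)
  fits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(num_cols), mean),
      n_units = dplyr::n(),
      .groups = "drop"
    )
}
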