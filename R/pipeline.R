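#' Run the ERG cohort analysis end-to-end
#'
#' Simulates (or accepts) a WT/KO littermate ERG cohort and reproduces the
#' cohort-level analysis: 22.5 Hz low-pass filtering, B-wave amplitude
#' measurement at the dim and saturating flashes, two-point saturation
#' fitting per eye, oscillatory-potential extraction on the saturating
#' flash, per-mouse averaging over eyes, paired KO-vs-WT tests on
#' sensitivity and maximum amplitude, and the correlation of normalized
#' oscillation amplitude with sensitivity across mice.
#'
#' @param config a [sim_config()] controlling the simulated cohort.
#' @param traces optional long trace tibble (columns `pair`, `genotype`,
#'   `mouse`, `eye`, `flash_intensity`, `t`, `value`; attributes `dt`,
#'   `t_flash`) to analyse instead of simulating; e.g. from
#'   [read_traces_csv()].
#' @param sensitivity_factor,op_coupling passed to [sim_erg_cohort()] when
#'   simulating.
#' @param out_dir optional directory; when given, the eye fits, mouse
#'   summary, test table and a JSON config snapshot are written there.
#' @param ... further arguments to [sim_erg_cohort()].
#' @return A list: `eye_fits` (per-eye `S_B`, `B_max`, `op_amp`,
#'   `op_norm`), `mouse_summary`, `tests` (paired tests on `S_B` and
#'   `B_max`), `op_correlation` (Pearson/Spearman of `op_norm` vs `S_B`),
#'   and `truth` when simulated.
#' @export
#' @examples
#' \donttest{
#' rep <- run_erg_pipeline(sim_config(seed = 1, n_pairs = 3))
#' rep$tests
#' }
run_erg_pipeline <- function(config = sim_config(), traces = NULL,
                             sensitivity_factor = 1.5, op_coupling = TRUE,
                             out_dir = NULL, ...) {
  truth <- NULL
  if (is.null(traces)) {
    coh <- sim_erg_cohort(config, sensitivity_factor = sensitivity_factor,
                          op_coupling = op_coupling, ...)
    traces <- coh$traces
    truth <- coh$truth
  }
  dt <- attr(traces, "dt")
  tf <- attr(traces, "t_flash") %||% 0
  keys <- c("pair", "genotype", "mouse", "eye")
  keys <- intersect(keys, names(traces))

  eye_fits <- traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      flashes <- sort(unique(g$flash_intensity))
      meas <- purrr::map_dfr(flashes, function(I) {
        gi <- g[g$flash_intensity == I, ]
        tr <- new_trace(gi$value, dt = dt, t_flash = tf, t0 = min(gi$t),
                        polarity = "corneal-positive", flash_intensity = I)
        bwave_amplitude(filter_butterworth(tr, "lowpass", 22.5))
      })
      fit <- fit_saturation(meas[, c("I", "B")])
      sat_I <- max(flashes)
      gi <- g[g$flash_intensity == sat_I, ]
      tr_sat <- new_trace(gi$value, dt = dt, t_flash = tf, t0 = min(gi$t),
                          polarity = "corneal-positive", flash_intensity = sat_I)
      op <- op_amplitude(tr_sat, b_max = fit$B_max)
      tibble::tibble(S_B = fit$S_B, B_max = fit$B_max,
                     op_amp = op$amplitude, op_norm = op$normalized)
    }) |>
    dplyr::ungroup()

  mouse_summary <- summarize_cohort(eye_fits, by = setdiff(keys, "eye"))

  wide <- function(param) {
    mouse_summary |>
      dplyr::select("pair", "genotype", dplyr::all_of(param)) |>
      tidyr::pivot_wider(names_from = "genotype", values_from = dplyr::all_of(param))
  }
  tests <- purrr::map_dfr(c("S_B", "B_max"), function(param) {
    w <- wide(param)
    w <- w[stats::complete.cases(w), ]
    pt <- paired_t(w$WT, w$KO)
    tibble::tibble(parameter = param, n_pairs = nrow(w),
                   mean_WT = mean(w$WT), mean_KO = mean(w$KO),
                   p.value = pt$p.value)
  })

  op_correlation <- correlations(mouse_summary$S_B, mouse_summary$op_norm)

  report <- list(eye_fits = eye_fits, mouse_summary = mouse_summary,
                 tests = tests, op_correlation = op_correlation, truth = truth)
  if (!is.null(out_dir)) {
    write_report(report[c("eye_fits", "mouse_summary", "tests", "op_correlation")],
                 out_dir, config)
  }
  report
}

#' Run the imaging cohort analysis end-to-end
#'
#' Simulates matched WT/KO stack pairs ([sim_stack_pair()]), quantifies
#' each section ([quantify_section()]), applies the two-step batch
#' normalization per slide/pair, and estimates jackknife bias-corrected
#' KO/WT ratios for the OPL mean and the rod- and cone-tip punctal
#' averages in each channel. The reference channel acts as the unmodified
#' control (its true ratio is 1).
#'
#' @param config a [sim_config()]; `n_pairs` and `effect_ratio` define
#'   the cohort.
#' @param out_dir optional output directory (CSV tables + config
#'   snapshot).
#' @param ... passed to [sim_confocal_stack()] (e.g. `n_rod`, `n_cone`,
#'   `roi_width`, `img_noise`).
#' @return A list: `sections` (per section x class x channel values),
#'   `ratios` (per quantity x channel: `r`, `s`, `r_c`, `s_c`, `n`), and
#'   `truth`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_imaging_pipeline(sim_config(seed = 1, n_pairs = 3,
#'                                        effect_ratio = 1.42),
#'                             n_rod = 6, n_cone = 2, roi_width = 40)
#' rep$ratios
#' }
run_imaging_pipeline <- function(config = sim_config(), out_dir = NULL, ...) {
  rows <- list()
  truth <- list()
  for (p in seq_len(config$n_pairs)) {
    pr <- sim_stack_pair(config, pair = p, ...)
    for (gt in c("WT", "KO")) {
      q <- quantify_section(pr[[gt]]$stack,
                            sample_id = sprintf("pair%02d_%s", p, gt))
      vals <- dplyr::bind_rows(
        q$opl |>
          dplyr::transmute(channel = .data$channel, quantity = "opl",
                           value = .data$opl_mean),
        q$summary |>
          dplyr::transmute(channel = .data$channel, quantity = .data$class,
                           value = .data$mean_sum)
      )
      vals$pair <- p
      vals$genotype <- gt
      rows[[length(rows) + 1L]] <- vals
      truth[[length(truth) + 1L]] <- dplyr::mutate(pr[[gt]]$truth, pair = p,
                                                   genotype = gt)
    }
  }
  sections <- dplyr::bind_rows(rows)

  ratios <- sections |>
    dplyr::group_by(.data$channel, .data$quantity) |>
    dplyr::group_modify(function(g, key) {
      if (anyNA(g$value) || any(g$value <= 0)) {
        return(tibble::tibble(r = NA_real_, s = NA_real_, r_c = NA_real_,
                              s_c = NA_real_, n = sum(!is.na(g$value)) / 2,
                              defined = FALSE))
      }
      norm <- normalize_paired_batches(
        tibble::tibble(slide = g$pair, pair = g$pair,
                       genotype = g$genotype, value = g$value))
      est <- jackknife_ratio(pairs_to_xy(norm))
      cbind(glance(est), tibble::tibble(defined = TRUE))
    }) |>
    dplyr::ungroup()

  report <- list(sections = sections, ratios = ratios,
                 truth = dplyr::bind_rows(truth))
  if (!is.null(out_dir)) {
    write_report(report[c("sections", "ratios")], out_dir, config)
  }
  report
}

# Write report tables + a config snapshot for provenance.
write_report <- function(tables, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    write_result_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  snap <- unclass(config)
  snap$voxel_size <- as.list(snap$voxel_size)
  jsonlite::write_json(snap, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
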