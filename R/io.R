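#' Write and read trace tables as tidy CSV
#'
#' The on-disk dialect is one row per sample with columns `mouse`,
#' `genotype`, `eye`, `flash_intensity`, `t`, `value` (plus any extra id
#' columns present, e.g. `pair`); times are seconds and intensities carry
#' their unit in the `intensity_unit` column. `read_traces_csv()`
#' validates the table (uniform positive sample interval per trace, finite
#' values) and restores the `dt` / `t_flash` attributes that the analysis
#' functions use; violations are reported with the offending row.
#'
#' @param traces a long trace tibble (as from [sim_erg_cohort()]).
#' @param path file path.
#' @param intensity_unit unit recorded in the file.
#' @return `write_traces_csv()`: `path`, invisibly. `read_traces_csv()`:
#'   the validated tibble with attributes `dt`, `t_flash`.
#' @export
write_traces_csv <- function(traces, path, intensity_unit = "cd.s/m2") {
  df <- as.data.frame(traces)
  df$intensity_unit <- intensity_unit
  utils::write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("flash_intensity", "t", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trace CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    bad <- which(!is.finite(df$value))[1]
    stop(sprintf("non-finite trace value at row %d", bad), call. = FALSE)
  }
  key_cols <- intersect(c("mouse", "genotype", "eye", "pair", "flash_intensity"),
                        names(df))
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  dts <- unlist(lapply(split(df$t, key), function(t) diff(sort(t))))
  if (length(dts) == 0) stop("traces have fewer than 2 samples", call. = FALSE)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-9 + 1e-6 * dt)) {
    bad <- which(abs(dts - dt) > 1e-9 + 1e-6 * dt)[1]
    stop(sprintf("non-uniform or non-positive sample interval (near sample %d)", bad),
         call. = FALSE)
  }
  attr(df, "dt") <- dt
  attr(df, "t_flash") <- 0
  attr(df, "polarity") <- "corneal-positive"
  df
}

#' Write and read confocal stacks as multi-page TIFF plus JSON sidecar
#'
#' The stack is stored as a channel-major multi-page 32-bit float TIFF
#' (all z slices of channel 1, then channel 2, ...) with intensities
#' rescaled to `[0, 1]`; the scale factor, channel names, dimensions,
#' voxel size and the ROI/ONL annotations go to a JSON sidecar at
#' `<path>.json`. Reading without the sidecar is an error, since the
#' voxel size and annotations are required for quantification. The round
#' trip is exact up to 32-bit float precision.
#'
#' @param stack a [confocal_stack()].
#' @param path TIFF file path.
#' @return `write_stack_tiff()`: `path`, invisibly. `read_stack_tiff()`:
#'   the restored [confocal_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "confocal_stack"))
  top <- max(unlist(lapply(stack$channels, max)), 1e-12)
  pages <- list()
  for (ch in names(stack$channels)) {
    v <- stack$channels[[ch]] / top
    for (z in seq_len(dim(v)[1])) {
      pages[[length(pages) + 1L]] <- v[z, , ]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  d <- dim(stack$channels[[1]])
  meta <- list(
    channels = names(stack$channels), nz = d[1], ny = d[2], nx = d[3],
    scale = top,
    voxel_size = as.list(stack$voxel_size),
    roi = as.list(stack$roi), onl = as.list(stack$onl),
    normalized = isTRUE(stack$normalized)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar '", sidecar,
         "': voxel size and annotations are required", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("channels", "nz", "ny", "nx", "scale", "voxel_size", "roi", "onl")) {
    if (is.null(meta[[f]])) {
      stop(sprintf("metadata sidecar is missing field '%s'", f), call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$nz
  chans <- list()
  for (i in seq_along(meta$channels)) {
    v <- array(0, dim = c(nz, meta$ny, meta$nx))
    for (z in seq_len(nz)) {
      v[z, , ] <- pages[[(i - 1) * nz + z]] * meta$scale
    }
    chans[[meta$channels[i]]] <- v
  }
  st <- confocal_stack(chans, voxel_size = unlist(meta$voxel_size),
                       roi = unlist(meta$roi), onl = unlist(meta$onl))
  st$normalized <- isTRUE(meta$normalized)
  st
}

#' Write a results table as CSV
#'
#' Thin wrapper keeping full double precision; one row per record.
#'
#' @param df a data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  utils::write.csv(format(as.data.frame(df), digits = 17, scientific = NA,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
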