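#' Mean OPL staining intensity of a section
#'
#' The z-averaged ROI image of each channel is thresholded at the ONL
#' background level (pixels not strictly above `threshold` times the
#' background are zeroed), and the mean over the ROI is returned in
#' background units. By default the background level itself is subtracted
#' from the surviving pixels (`subtract_background = TRUE`), so a section
#' with no specific staining scores 0 and the statistic scales linearly
#' with staining brightness; `subtract_background = FALSE` reproduces the
#' plain thresholded mean. Zeroed pixels are kept in the denominator by
#' default (`include_zeros = TRUE`); excluding them averages only the
#' surviving pixels.
#'
#' @param stack an ONL-normalized [confocal_stack()] (see
#'   [normalize_to_onl()]).
#' @param threshold background-threshold multiplier (the background is 1
#'   after normalization).
#' @param subtract_background,include_zeros see Details.
#' @return A tibble with one row per channel: `channel`, `opl_mean`,
#'   `n_above` (pixels above threshold), `flagged` (TRUE when no pixel
#'   survives thresholding; `opl_mean` is then 0).
#' @export
opl_mean_intensity <- function(stack, threshold = 1, subtract_background = TRUE,
                               include_zeros = TRUE) {
  stopifnot(inherits(stack, "confocal_stack"))
  if (!isTRUE(stack$normalized)) {
    stop("stack must be ONL-normalized first (normalize_to_onl)", call. = FALSE)
  }
  d <- dim(stack$channels[[1]])
  px <- rect_px(stack$roi, stack$voxel_size, d)
  purrr::map_dfr(names(stack$channels), function(ch) {
    img <- z_average(stack$channels[[ch]][, px$ys, px$xs, drop = FALSE])
    keep <- img > threshold
    vals <- ifelse(keep, if (subtract_background) img - threshold else img, 0)
    n_above <- sum(keep)
    m <- if (n_above == 0) 0 else if (include_zeros) mean(vals) else sum(vals) / n_above
    tibble::tibble(channel = ch, opl_mean = m, n_above = n_above,
                   flagged = n_above == 0)
  })
}

#' Find strict 3D local maxima
#'
#' A voxel is a local maximum when its value is strictly greater than all
#' of its (up to) 26 neighbours; out-of-volume neighbours are treated as
#' smaller, so border voxels can qualify. Plateaus (ties) yield no maximum,
#' which keeps the result deterministic. Voxels at or below `threshold`
#' are never maxima.
#'
#' @param vol numeric 3D array `(z, y, x)`, e.g. the normalized reference
#'   channel restricted to the ROI.
#' @param threshold minimum value for a candidate maximum (default 1, the
#'   ONL background in normalized units).
#' @return A tibble `z`, `y`, `x`, `value`, sorted by decreasing value
#'   (ties broken by coordinates). May be empty.
#' @export
find_local_maxima_3d <- function(vol, threshold = 1) {
  stopifnot(length(dim(vol)) == 3)
  d <- dim(vol)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  is_max <- core > threshold
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (!any(is_max)) break
    nb <- pad[(2 + dz):(d[1] + 1 + dz),
              (2 + dy):(d[2] + 1 + dy),
              (2 + dx):(d[3] + 1 + dx), drop = FALSE]
    is_max <- is_max & (core > nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(z = integer(), y = integer(), x = integer(),
                          value = numeric()))
  }
  out <- tibble::tibble(z = as.integer(unname(idx[, 1])),
                        y = as.integer(unname(idx[, 2])),
                        x = as.integer(unname(idx[, 3])),
                        value = as.vector(vol[idx]))
  dplyr::arrange(out, dplyr::desc(.data$value), .data$z, .data$y, .data$x)
}

#' Build the 2D dendritic-tip mask
#'
#' Candidate tip areas are pixels of the z-averaged reference image
#' strictly above the ONL-background threshold; connected components
#' (8-connectivity) smaller than `min_size` pixels are removed as noise.
#' The exact construction of the tip mask is a reconstruction — the
#' published procedure states only the background threshold — so the
#' threshold multiplier and minimum size are exposed.
#'
#' @param img numeric matrix `(y, x)`: the z-averaged, ONL-normalized
#'   reference image (ROI).
#' @param threshold background multiplier (background = 1).
#' @param min_size minimum component area in pixels (default 4, i.e. a
#'   2 x 2 block).
#' @return An integer label matrix, 0 = background, 1..k = components.
#' @export
build_tip_mask <- function(img, threshold = 1, min_size = 4) {
  stopifnot(is.matrix(img))
  lab <- label_components(img > threshold)
  if (max(lab) > 0) {
    sizes <- tabulate(lab, nbins = max(lab))
    drop <- which(sizes < min_size)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      # relabel compactly
      keep <- sort(unique(lab[lab > 0]))
      if (length(keep)) {
        remap <- integer(max(keep))
        remap[keep] <- seq_along(keep)
        pos <- lab > 0
        lab[pos] <- remap[lab[pos]]
      }
    }
  }
  lab
}

# 8-connected component labelling by iterative flood fill.
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      y <- ((cur - 1L) %% nr) + 1L
      x <- ((cur - 1L) %/% nr) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy < 1L || yy > nr || xx < 1L || xx > nc) next
        j <- yy + (xx - 1L) * nr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

#' Classify detected puncta and sum channel intensities in windows
#'
#' Each reference-channel maximum is assigned the tip-mask component under
#' it and classified by the component's horizontal extent along the row
#' through the maximum: a rod-tip punctum extends at most 0.5 um on each
#' side of the centre; a cone-tip patch extends more than 1.1 um in total
#' (including the centre); anything between satisfies neither criterion
#' and is excluded, as are maxima outside the mask. For every punctum and
#' channel, the window sum is the sum of `value - 1` (ONL-background
#' units, background subtracted; optionally clipped at zero) over the
#' `window_um` x `window_um` window of the z-averaged image centred at the
#' maximum; the window is converted to the nearest odd pixel count.
#' Puncta whose window would leave the image are flagged and excluded.
#'
#' @param stack an ONL-normalized [confocal_stack()].
#' @param maxima tibble from [find_local_maxima_3d()] (ROI-frame voxel
#'   coordinates).
#' @param mask label matrix from [build_tip_mask()] (same ROI frame).
#' @param window_um square window side in micrometres (default 1.1).
#' @param rod_max_um,cone_min_um classification cutoffs in micrometres.
#' @param clip_negative clip background-subtracted values at 0 before
#'   summing (default FALSE).
#' @return A tibble with one row per punctum: coordinates, `class`
#'   (`"rod"`, `"cone"`, `"excluded"`), extents (um), `window_ok`, and one
#'   `sum_<channel>` column per channel.
#' @export
classify_and_sum <- function(stack, maxima, mask, window_um = 1.1,
                             rod_max_um = 0.5, cone_min_um = 1.1,
                             clip_negative = FALSE) {
  stopifnot(inherits(stack, "confocal_stack"), is.matrix(mask))
  if (!isTRUE(stack$normalized)) {
    stop("stack must be ONL-normalized first (normalize_to_onl)", call. = FALSE)
  }
  d <- dim(stack$channels[[1]])
  px <- rect_px(stack$roi, stack$voxel_size, d)
  dx <- stack$voxel_size[["x"]]
  zimgs <- lapply(stack$channels, function(v) z_average(v[, px$ys, px$xs, drop = FALSE]))
  half <- (odd_window_px(window_um, dx) - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)

  rows <- purrr::pmap_dfr(maxima, function(z, y, x, value) {
    lab <- if (y >= 1 && y <= nr && x >= 1 && x <= nc) mask[y, x] else 0L
    if (lab == 0L) {
      return(tibble::tibble(z = z, y = y, x = x, value = value,
                            class = "excluded", in_mask = FALSE,
                            extent_left_um = NA_real_, extent_right_um = NA_real_,
                            extent_total_um = NA_real_, window_ok = NA))
    }
    run <- component_run(mask, y, x, lab)
    left <- (x - run[1]) * dx
    right <- (run[2] - x) * dx
    total <- (run[2] - run[1] + 1) * dx
    cls <- if (max(left, right) <= rod_max_um) "rod"
           else if (total > cone_min_um) "cone"
           else "excluded"
    window_ok <- y - half >= 1 && y + half <= nr && x - half >= 1 && x + half <= nc
    if (!window_ok) cls <- "excluded"
    tibble::tibble(z = z, y = y, x = x, value = value, class = cls,
                   in_mask = TRUE, extent_left_um = left,
                   extent_right_um = right, extent_total_um = total,
                   window_ok = window_ok)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(z = integer(), y = integer(), x = integer(),
                           value = numeric(), class = character(),
                           in_mask = logical(), extent_left_um = numeric(),
                           extent_right_um = numeric(),
                           extent_total_um = numeric(), window_ok = logical())
  }
  for (ch in names(zimgs)) {
    rows[[paste0("sum_", ch)]] <- purrr::pmap_dbl(
      rows[, c("y", "x", "window_ok")],
      function(y, x, window_ok) {
        if (!isTRUE(window_ok)) return(NA_real_)
        w <- zimgs[[ch]][(y - half):(y + half), (x - half):(x + half)] - 1
        if (clip_negative) w <- pmax(w, 0)
        sum(w)
      }
    )
  }
  rows
}

# Horizontal run of pixels of component `lab` through (y, x).
component_run <- function(mask, y, x, lab) {
  nc <- ncol(mask)
  x0 <- x
  while (x0 > 1 && mask[y, x0 - 1] == lab) x0 <- x0 - 1
  x1 <- x
  while (x1 < nc && mask[y, x1 + 1] == lab) x1 <- x1 + 1
  c(x0, x1)
}

# Physical window -> nearest odd pixel count (>= 1).
odd_window_px <- function(window_um, dx) {
  n <- max(1, round(window_um / dx))
  if (n %% 2 == 0) n <- n + if ((window_um / dx) >= n) 1 else -1
  max(1L, as.integer(n))
}

#' Quantify one retinal section end-to-end
#'
#' Runs the full image pipeline on a raw stack: ONL normalization, OPL
#' mean intensity per channel, 3D local-maxima detection on the
#' thresholded reference channel within the ROI, dendritic-tip mask
#' construction from the z-averaged reference, and per-punctum
#' classification and window sums. Per-class (rod / cone) averages of the
#' window sums are computed per channel; classes with no detected puncta
#' are flagged undefined.
#'
#' @param stack a raw [confocal_stack()] with `reference` among its
#'   channels.
#' @param reference name of the punctum-marker channel.
#' @param window_um,threshold,min_size,clip_negative passed to the stages.
#' @param sample_id optional label (e.g. `"retina1_superior"`).
#' @return A `section_quant` list: `opl` (per-channel OPL means), `puncta`
#'   (per-punctum records), `summary` (per class x channel: `n`,
#'   `mean_sum`, `defined`), `sample_id`.
#' @export
#' @examples
#' sim <- sim_confocal_stack(sim_config(seed = 1), n_rod = 4, n_cone = 1,
#'                           roi_width = 30)
#' q <- quantify_section(sim$stack)
#' q$summary
quantify_section <- function(stack, reference = "reference", window_um = 1.1,
                             threshold = 1, min_size = 4,
                             clip_negative = FALSE, sample_id = NA_character_) {
  stopifnot(inherits(stack, "confocal_stack"))
  if (!reference %in% names(stack$channels)) {
    stop(sprintf("reference channel '%s' not present", reference), call. = FALSE)
  }
  norm <- if (isTRUE(stack$normalized)) stack else normalize_to_onl(stack)
  opl <- opl_mean_intensity(norm, threshold = threshold)
  d <- dim(norm$channels[[1]])
  px <- rect_px(norm$roi, norm$voxel_size, d)
  ref_roi <- norm$channels[[reference]][, px$ys, px$xs, drop = FALSE]
  maxima <- find_local_maxima_3d(ref_roi, threshold = threshold)
  mask <- build_tip_mask(z_average(ref_roi), threshold = threshold,
                         min_size = min_size)
  puncta <- classify_and_sum(norm, maxima, mask, window_um = window_um,
                             clip_negative = clip_negative)
  sum_cols <- grep("^sum_", names(puncta), value = TRUE)
  summary <- tidyr::expand_grid(class = c("rod", "cone"), channel = sum_cols) |>
    purrr::pmap_dfr(function(class, channel) {
      v <- puncta[[channel]][puncta$class == class]
      v <- v[!is.na(v)]
      tibble::tibble(class = class,
                     channel = sub("^sum_", "", channel),
                     n = length(v),
                     mean_sum = if (length(v)) mean(v) else NA_real_,
                     defined = length(v) > 0)
    })
  structure(list(opl = opl, puncta = puncta, summary = summary,
                 sample_id = sample_id),
            class = "section_quant")
}

#' @export
print.section_quant <- function(x, ...) {
  cat(sprintf("<section_quant> %s: %d puncta (%d rod, %d cone, %d excluded)\n",
              if (is.na(x$sample_id)) "section" else x$sample_id,
              nrow(x$puncta), sum(x$puncta$class == "rod"),
              sum(x$puncta$class == "cone"), sum(x$puncta$class == "excluded")))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.section_quant <- function(x, ...) x$summary

#' @export
glance.section_quant <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    n_puncta = nrow(x$puncta),
    n_rod = sum(x$puncta$class == "rod"),
    n_cone = sum(x$puncta$class == "cone"),
    n_excluded = sum(x$puncta$class == "excluded")
  )
}
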