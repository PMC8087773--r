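#' Construct a two-channel confocal image stack
#'
#' A `confocal_stack` holds per-channel 3D intensity arrays indexed
#' `[z, y, x]`, the voxel size in micrometres, and two rectangular
#' annotations in physical units: the outer-plexiform-layer region of
#' interest (`roi`) where puncta are quantified, and an outer-nuclear-layer
#' region (`onl`) whose mean intensity defines the non-specific background
#' used for normalization and thresholding.
#'
#' Rectangles are `c(x=, y=, width=, height=)` in micrometres, with the
#' origin at the corner of pixel (1,1) and half-open pixel conversion, so
#' abutting rectangles never share pixels.
#'
#' @param channels named list of numeric 3D arrays, all the same dim
#'   `(z, y, x)`.
#' @param voxel_size named numeric `c(x=, y=, z=)` in micrometres.
#' @param roi,onl annotation rectangles (micrometres), within image bounds.
#' @return A `confocal_stack` object.
#' @export
confocal_stack <- function(channels, voxel_size, roi, onl) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    stop("`channels` must be a named list of 3D arrays", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("every channel must be a 3D array (z, y, x)", call. = FALSE)
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  vs <- voxel_size[c("x", "y", "z")]
  if (any(is.na(vs)) || any(vs <= 0)) {
    stop("`voxel_size` must be named c(x=, y=, z=) and positive", call. = FALSE)
  }
  d <- dims[[1]]
  for (nm in c("roi", "onl")) {
    r <- get(nm)
    if (length(r) != 4 || any(is.na(r[c("x", "y", "width", "height")]))) {
      stop(sprintf("`%s` must be c(x=, y=, width=, height=)", nm), call. = FALSE)
    }
    px <- rect_px(r, vs, d)
    if (length(px$xs) == 0 || length(px$ys) == 0) {
      stop(sprintf("`%s` is empty or outside image bounds", nm), call. = FALSE)
    }
  }
  structure(
    list(channels = channels, voxel_size = vs,
         roi = roi[c("x", "y", "width", "height")],
         onl = onl[c("x", "y", "width", "height")],
         normalized = FALSE),
    class = "confocal_stack"
  )
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<confocal_stack> %d channel(s) [%s], %d z x %d y x %d x voxels\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  cat(sprintf("  voxel %g x %g um, %g um/slice; %s\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"],
              if (isTRUE(x$normalized)) "ONL-normalized" else "raw"))
  invisible(x)
}

# Physical rectangle (um) -> pixel index lists in the (y, x) plane.
# Half-open: a pixel belongs to the rectangle iff its leading edge does.
rect_px <- function(rect, voxel_size, dim_zyx) {
  dx <- voxel_size[["x"]]; dy <- voxel_size[["y"]]
  x0 <- floor(rect[["x"]] / dx) + 1L
  x1 <- floor((rect[["x"]] + rect[["width"]]) / dx + 1e-9)
  y0 <- floor(rect[["y"]] / dy) + 1L
  y1 <- floor((rect[["y"]] + rect[["height"]]) / dy + 1e-9)
  list(
    xs = seq.int(max(1L, x0), min(dim_zyx[3], x1)),
    ys = seq.int(max(1L, y0), min(dim_zyx[2], y1))
  )
}

# Mean over z of one channel -> 2D matrix (y, x).
z_average <- function(vol) {
  apply(vol, c(2, 3), mean)
}

#' Normalize a stack to its ONL background
#'
#' Divides every channel by the mean intensity of its own ONL annotation
#' (over all z slices), so that after normalization the non-specific
#' background level equals 1 in every channel. This removes slide-to-slide
#' exposure differences: rescaling all raw intensities by any positive
#' constant leaves the normalized stack unchanged.
#'
#' @param stack a [confocal_stack()].
#' @return The stack with every channel in units of its ONL background and
#'   `normalized = TRUE`.
#' @export
normalize_to_onl <- function(stack) {
  stopifnot(inherits(stack, "confocal_stack"))
  d <- dim(stack$channels[[1]])
  px <- rect_px(stack$onl, stack$voxel_size, d)
  for (ch in names(stack$channels)) {
    m <- mean(stack$channels[[ch]][, px$ys, px$xs])
    if (!is.finite(m) || m <= 0) {
      stop(sprintf("ONL mean of channel '%s' is not positive; cannot normalize", ch),
           call. = FALSE)
    }
    stack$channels[[ch]] <- stack$channels[[ch]] / m
  }
  stack$normalized <- TRUE
  stack
}
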