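# Cell-envelope, nucleus and punctum segmentation: projection, CLAHE,
# global/adaptive thresholding, connected components, size filtering,
# optional watershed. Ties at thresholds go to background (strict ">").

#' Segmentation parameters
#'
#' @param projection z-projection method for stacks: `"max"` (default, the
#'   usual choice for punctate and reticular markers), `"mean"` or `"sum"`.
#' @param clahe_enabled apply contrast-limited adaptive histogram
#'   equalization before global thresholding of the envelope channel.
#' @param clahe_tile CLAHE tile size in pixels (>= 2, < image size).
#' @param clahe_clip CLAHE clip limit as a fraction of tile histogram mass.
#' @param threshold_method `"otsu"` (default; ImageJ's default auto method),
#'   `"triangle"` or `"fixed"`.
#' @param fixed_threshold threshold used iff `threshold_method = "fixed"`.
#' @param adaptive_block odd window size (pixels) for local-mean adaptive
#'   thresholding.
#' @param adaptive_offset additive offset on the local mean.
#' @param min_area_px,max_area_px component area filter, in pixels.
#' @param watershed_enabled split touching nuclei by watershed on the
#'   interior distance transform.
#' @param connectivity pixel connectivity for components: 8 (default,
#'   matching ImageJ particle analysis) or 4.
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(projection = "max",
                       clahe_enabled = TRUE, clahe_tile = 64,
                       clahe_clip = 0.01,
                       threshold_method = "otsu", fixed_threshold = NA_real_,
                       adaptive_block = 33L, adaptive_offset = 0,
                       min_area_px = 0L, max_area_px = Inf,
                       watershed_enabled = FALSE, connectivity = 8L) {
  projection <- match.arg(projection, c("max", "mean", "sum"))
  threshold_method <- match.arg(threshold_method,
                                c("otsu", "triangle", "fixed"))
  adaptive_block <- as.integer(adaptive_block)
  stopifnot(adaptive_block >= 3L, adaptive_block %% 2L == 1L,
            clahe_tile >= 2, clahe_clip > 0,
            min_area_px >= 0, max_area_px > 0, min_area_px <= max_area_px,
            connectivity %in% c(4L, 8L))
  if (threshold_method == "fixed" && !is.finite(fixed_threshold))
    stop("fixed_threshold must be finite when threshold_method = 'fixed'",
         call. = FALSE)
  structure(list(projection = projection,
                 clahe_enabled = isTRUE(clahe_enabled),
                 clahe_tile = clahe_tile, clahe_clip = clahe_clip,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 adaptive_block = adaptive_block,
                 adaptive_offset = adaptive_offset,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 watershed_enabled = isTRUE(watershed_enabled),
                 connectivity = as.integer(connectivity)),
            class = "seg_params")
}

#' Project an image stack to a single plane
#'
#' @param stack a list of numeric matrices of identical dimension, or a
#'   single matrix (returned unchanged).
#' @param method `"max"`, `"mean"` or `"sum"`.
#' @return a numeric matrix.
#' @export
project_stack <- function(stack, method = c("max", "mean", "sum")) {
  method <- match.arg(method)
  if (is.matrix(stack)) return(stack)
  if (!is.list(stack) || length(stack) == 0L)
    stop("stack must be a matrix or non-empty list of matrices",
         call. = FALSE)
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch across planes", call. = FALSE)
  arr <- array(unlist(stack), dim = c(dims[1, 1], dims[2, 1], length(stack)))
  out <- switch(method,
                max  = apply(arr, c(1, 2), max),
                mean = rowMeans(arr, dims = 2),
                sum  = rowSums(arr, dims = 2))
  out
}

# Linear rescale to [0,1]; constant images map to 0 everywhere.
rescale01 <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Contrast-limited adaptive histogram equalization
#'
#' Rescales to \[0, 1\] and applies CLAHE; with `clahe_enabled = FALSE` only
#' the rescale is performed. Constant images return all zeros (there is no
#' contrast to enhance).
#'
#' @param img numeric matrix.
#' @param params a [seg_params()] object.
#' @return numeric matrix with values in \[0, 1\].
#' @export
enhance_clahe <- function(img, params = seg_params()) {
  validate_channel(img)
  out <- rescale01(img)
  if (!params$clahe_enabled || max(out) == 0) return(out)
  if (params$clahe_tile >= min(dim(img)))
    stop("clahe_tile must be smaller than the image", call. = FALSE)
  nx <- max(2L, round(nrow(img) / params$clahe_tile))
  ny <- max(2L, round(ncol(img) / params$clahe_tile))
  bins <- 256L
  limit <- max(1, params$clahe_clip * bins)
  res <- EBImage::clahe(out, nx = nx, ny = ny, bins = bins, limit = limit)
  out <- pmin(pmax(as.numeric(res), 0), 1)
  dim(out) <- dim(img)
  out
}

# Triangle threshold on a 256-bin histogram over the observed range:
# maximize distance between histogram and the line from the peak to the
# farthest empty tail bin. Returns intensity value at the chosen bin edge.
threshold_triangle_value <- function(img, levels = 256L) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  h <- tabulate(pmin(floor((img - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
                     levels), nbins = levels)
  pk <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  tail_bin <- if ((pk - lo) >= (hi - pk)) lo else hi
  span <- seq(min(pk, tail_bin), max(pk, tail_bin))
  # distance from histogram points to the peak-tail chord
  x1 <- pk; y1 <- h[pk]; x2 <- tail_bin; y2 <- h[tail_bin]
  d <- abs((y2 - y1) * span - (x2 - x1) * h[span] + x2 * y1 - y2 * x1)
  best <- span[which.max(d)]
  rng[1] + best / levels * (rng[2] - rng[1])
}

#' Global threshold to a binary mask
#'
#' Foreground pixels satisfy intensity strictly greater than the threshold.
#' Automatic thresholds use a 256-bin histogram over the observed range; a
#' constant image yields an all-background mask with a warning.
#'
#' @param img numeric matrix.
#' @param method `"otsu"`, `"triangle"` or `"fixed"`.
#' @param fixed_threshold threshold for `method = "fixed"`.
#' @return integer 0/1 matrix (a mask label map).
#' @export
threshold_global <- function(img, method = c("otsu", "triangle", "fixed"),
                             fixed_threshold = NA_real_) {
  method <- match.arg(method)
  validate_channel(img)
  rng <- range(img)
  if (method != "fixed" && rng[2] - rng[1] <= 0) {
    warning("constant image: no automatic threshold separates one value; ",
            "returning all-background mask")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  t <- switch(method,
    otsu = EBImage::otsu(img, range = rng, levels = 256L),
    triangle = threshold_triangle_value(img),
    fixed = fixed_threshold)
  as_mask(img > t)
}

#' Local-mean adaptive threshold
#'
#' A pixel is foreground iff its intensity exceeds the mean over the
#' `block x block` window centered on it plus `offset`. Windows are clipped
#' at the image border (the mean runs over the in-image pixels only), so a
#' block covering the whole image reduces exactly to thresholding at the
#' global mean.
#'
#' @param img numeric matrix.
#' @param block odd window size >= 3.
#' @param offset additive offset.
#' @return integer 0/1 matrix.
#' @export
threshold_adaptive <- function(img, block = 33L, offset = 0) {
  validate_channel(img)
  block <- as.integer(block)
  if (block < 3L || block %% 2L == 0L)
    stop("block must be odd and >= 3", call. = FALSE)
  mu <- local_mean(img, block)
  as_mask(img > mu + offset)
}

# Exact clipped box mean via a 2D integral image.
local_mean <- function(img, block) {
  h <- (block - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  S <- rbind(0, cbind(0, t(apply(apply(img, 2L, cumsum), 1L, cumsum))))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  tot <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  tot / cnt
}

#' Label connected components of a mask
#'
#' Components are labeled 1..K in raster order (row-major from the top-left)
#' of each component's first pixel, so labeling is deterministic.
#'
#' @param mask integer 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  m <- as_mask(mask)
  .label_cc(m, as.integer(connectivity))
}

# Drop components outside [min_area, max_area] and relabel 1..K in raster
# order of each survivor's first pixel.
area_filter_relabel <- function(labels, min_area, max_area) {
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels)
  keep <- which(areas >= min_area & areas <= max_area)
  lut <- integer(length(areas))
  if (length(keep)) {
    # raster order of first pixel: column-major scan transposed to row-major
    first <- vapply(keep, function(k) {
      idx <- which(labels == k)
      r <- (idx - 1L) %% nrow(labels)
      c <- (idx - 1L) %/% nrow(labels)
      min(r * ncol(labels) + c)
    }, numeric(1))
    lut[keep[order(first)]] <- seq_along(keep)
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0L
  out[nz] <- lut[labels[nz]]
  out
}

#' Segment nuclei from the nuclear channel
#'
#' Global threshold, connected components, area filtering, optional
#' watershed splitting of touching nuclei (seeded from the interior
#' Euclidean distance transform), then deterministic relabeling.
#'
#' @param nuclear_img numeric matrix (or list of planes, projected first).
#' @param params a [seg_params()] object.
#' @return integer label matrix of nuclei; empty (all zero, with a warning)
#'   if nothing survives the filters.
#' @export
segment_nuclei <- function(nuclear_img, params = seg_params()) {
  img <- project_stack(nuclear_img, params$projection)
  mask <- threshold_global(img, params$threshold_method,
                           params$fixed_threshold)
  labels <- label_components(mask, params$connectivity)
  labels <- area_filter_relabel(labels, params$min_area_px,
                                params$max_area_px)
  if (params$watershed_enabled && max(labels) > 0L) {
    m <- as_mask(labels)
    dm <- EBImage::distmap(m, metric = "euclidean")
    ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    ws <- matrix(as.integer(ws), nrow(m), ncol(m))
    labels <- area_filter_relabel(ws, params$min_area_px,
                                  params$max_area_px)
  }
  if (max(labels) == 0L)
    warning("no nuclei found; radial analyses require at least one nucleus")
  labels
}

#' Segment the cell-envelope mask
#'
#' Project, CLAHE-enhance, globally threshold, fill holes and keep
#' sufficiently large components. A supplied `override` mask is returned
#' unchanged; this is the hook for manually corrected masks.
#'
#' @param envelope_img numeric matrix or list of planes.
#' @param params a [seg_params()] object.
#' @param override optional pre-computed 0/1 mask returned as-is.
#' @return integer 0/1 mask matrix.
#' @export
segment_cell_mask <- function(envelope_img, params = seg_params(),
                              override = NULL) {
  if (!is.null(override)) {
    stopifnot(is.matrix(override))
    return(as_mask(override))
  }
  img <- project_stack(envelope_img, params$projection)
  img <- enhance_clahe(img, params)
  mask <- threshold_global(img, params$threshold_method,
                           params$fixed_threshold)
  mask <- as_mask(EBImage::fillHull(mask))
  labels <- label_components(mask, params$connectivity)
  labels <- area_filter_relabel(labels, params$min_area_px,
                                params$max_area_px)
  out <- as_mask(labels)
  if (sum(out) == 0L)
    stop("empty cell mask: no cell territory definable", call. = FALSE)
  out
}

#' Label particles (puncta) in a binary mask
#'
#' Connected components with the configured connectivity, filtered to
#' `[min_area_px, max_area_px]` and relabeled 1..N in raster order.
#'
#' @param mask integer 0/1 matrix.
#' @param params a [seg_params()] object.
#' @return integer label matrix of particles.
#' @export
label_particles <- function(mask, params = seg_params()) {
  labels <- label_components(mask, params$connectivity)
  area_filter_relabel(labels, params$min_area_px, params$max_area_px)
}
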