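# Lysosome positioning with a ratiometric pH proxy: per-particle channel
# means and ratio, centroid distances to the nuclear and plasma membranes,
# normalized radial position, quartile binning and per-cell quartile means.

#' Measure particles: area, centroid and channel intensities
#'
#' Centroids are intensity-unweighted means of member pixel coordinates,
#' reported 0-based (row, col). The ratio is `mean_num / mean_den`;
#' particles with `mean_den <= den_floor` are flagged invalid (their ratio
#' is NA) rather than inflated by an epsilon, which would distort the
#' ratio statistic.
#'
#' @param particles integer label matrix.
#' @param num pH-sensitive (numerator) channel matrix.
#' @param den pH-insensitive (denominator) channel matrix.
#' @param den_floor minimum acceptable denominator mean (default 0).
#' @return data.frame: particle_id, area_px, row, col, mean_num, mean_den,
#'   ratio, valid.
#' @export
measure_particles <- function(particles, num, den, den_floor = 0) {
  stopifnot(all(dim(particles) == dim(num)), all(dim(particles) == dim(den)))
  n <- max(particles)
  if (n == 0L)
    return(data.frame(particle_id = integer(), area_px = integer(),
                      row = numeric(), col = numeric(), mean_num = numeric(),
                      mean_den = numeric(), ratio = numeric(),
                      valid = logical()))
  idx <- which(particles > 0L)
  lab <- particles[idx]
  r0 <- (idx - 1L) %% nrow(particles)        # 0-based row
  c0 <- (idx - 1L) %/% nrow(particles)       # 0-based col
  area <- tabulate(lab, nbins = n)
  mean_by <- function(v) as.numeric(rowsum(v, lab, reorder = TRUE)) / area
  mrow <- mean_by(r0); mcol <- mean_by(c0)
  mnum <- mean_by(num[idx]); mden <- mean_by(den[idx])
  valid <- mden > den_floor
  ratio <- ifelse(valid, mnum / mden, NA_real_)
  data.frame(particle_id = seq_len(n), area_px = area, row = mrow,
             col = mcol, mean_num = mnum, mean_den = mden, ratio = ratio,
             valid = valid)
}

# Boundary pixels of a set: members with a 4-neighbor outside the set (or on
# the image edge, when include_frame). Returns 0-based (row, col) matrix.
boundary_pixels <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- member
  inner <- pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)]
  idx <- which(member & !inner)
  cbind(row = (idx - 1L) %% nr, col = (idx - 1L) %/% nr)
}

min_dist_to <- function(pt, coords) {
  if (nrow(coords) == 0L) return(Inf)
  sqrt(min((coords[, 1] - pt[1])^2 + (coords[, 2] - pt[2])^2))
}

#' Radial position of particle centroids
#'
#' For each centroid: `d_nuc`, the straight-line distance to the nearest
#' nucleus pixel (0 inside a nucleus); `d_pm`, the distance to the nearest
#' out-of-cell-mask pixel (the frame edge counts as outside, matching
#' [distance_to_border()]); `rel_pos = d_nuc / (d_nuc + d_pm)`, 0 at the
#' nuclear membrane and 1 at the plasma membrane; and `cell_id`, the label
#' of the nearest nucleus (ties to the lower label). Centroids outside the
#' cell mask are flagged `in_mask = FALSE` and carry NA positions.
#'
#' @param records data.frame from [measure_particles()] (needs `row`,
#'   `col`, 0-based).
#' @param nuclei integer nucleus label matrix.
#' @param cell_mask integer 0/1 matrix.
#' @return the records with columns d_nuc, d_pm, rel_pos, cell_id, in_mask,
#'   in_nucleus appended.
#' @export
radial_position <- function(records, nuclei, cell_mask) {
  stopifnot(all(dim(nuclei) == dim(cell_mask)))
  if (max(nuclei) == 0L) stop("need at least one nucleus", call. = FALSE)
  m <- as_mask(cell_mask)
  nr <- nrow(m); nc <- ncol(m)
  labs <- setdiff(sort(unique(as.integer(nuclei))), 0L)
  nuc_bound <- lapply(labs, function(k) boundary_pixels(nuclei == k))
  # candidate out-of-mask pixels: background adjacent to the mask, plus the
  # virtual ring just outside the frame handled analytically below
  bg_bound <- boundary_pixels(m == 0L)
  n <- nrow(records)
  d_nuc <- d_pm <- rel <- rep(NA_real_, n)
  cell <- rep(NA_integer_, n)
  in_mask <- in_nuc <- rep(FALSE, n)
  for (i in seq_len(n)) {
    p <- c(records$row[i], records$col[i])
    pr <- as.integer(round(p[1])) + 1L   # back to 1-based pixel
    pc <- as.integer(round(p[2])) + 1L
    pr <- min(max(pr, 1L), nr); pc <- min(max(pc, 1L), nc)
    in_mask[i] <- m[pr, pc] == 1L
    if (!in_mask[i]) next
    inside <- nuclei[pr, pc]
    dk <- vapply(nuc_bound, function(b) min_dist_to(p, b), numeric(1))
    if (inside > 0L) {
      in_nuc[i] <- TRUE
      d_nuc[i] <- 0
      cell[i] <- inside
    } else {
      d_nuc[i] <- min(dk)
      cell[i] <- labs[which(dk <= d_nuc[i] + 1e-9)[1]]
    }
    d_pm[i] <- if (nrow(bg_bound) > 0L) min_dist_to(p, bg_bound) else
      min(p[1] + 1, nr - p[1], p[2] + 1, nc - p[2])  # frame as background
    denom <- d_nuc[i] + d_pm[i]
    rel[i] <- if (denom > 0) d_nuc[i] / denom else 0
  }
  records$d_nuc <- d_nuc
  records$d_pm <- d_pm
  records$rel_pos <- rel
  records$cell_id <- cell
  records$in_mask <- in_mask
  records$in_nucleus <- in_nuc
  records
}

#' Assign a radial-position quartile
#'
#' Bins `[0, .25]`, `(.25, .5]`, `(.5, .75]`, `(.75, 1]` labeled 0.25, 0.50,
#' 0.75, 1.0 — upper edges belong to their bin, and rel_pos 0 falls in the
#' first bin.
#'
#' @param rel_pos numeric vector in \[0, 1\].
#' @return numeric vector of quartile labels.
#' @export
assign_quartile <- function(rel_pos) {
  ok <- is.na(rel_pos) | (rel_pos >= 0 & rel_pos <= 1)
  if (!all(ok)) stop("rel_pos out of [0, 1]", call. = FALSE)
  q <- ceiling(pmax(rel_pos, .Machine$double.eps) / 0.25) * 0.25
  pmin(q, 1.0)
}

#' Per-cell per-quartile mean ratio
#'
#' Valid particles are grouped by (cell_id, quartile); each group reports
#' the arithmetic mean ratio and its particle count. Empty quartiles are
#' omitted, not imputed.
#'
#' @param records data.frame with cell_id, quartile, ratio, valid.
#' @return data.frame: cell_id, quartile, mean_ratio, n_particles, sorted.
#' @export
summarize_quartiles <- function(records) {
  keep <- records$valid & !is.na(records$quartile) & !is.na(records$cell_id)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(cell_id = integer(), quartile = numeric(),
                      mean_ratio = numeric(), n_particles = integer()))
  key <- interaction(r$cell_id, r$quartile, drop = TRUE)
  agg <- data.frame(cell_id = tapply(r$cell_id, key, `[`, 1L),
                    quartile = tapply(r$quartile, key, `[`, 1L),
                    mean_ratio = tapply(r$ratio, key, mean),
                    n_particles = as.integer(tapply(r$ratio, key, length)))
  rownames(agg) <- NULL
  agg[order(agg$cell_id, agg$quartile), , drop = FALSE]
}

#' Lysosome positioning pipeline for one image set
#'
#' Segments particles from the denominator (pH-insensitive) channel by
#' adaptive thresholding and particle analysis, measures both channels,
#' computes radial positions against the nuclei and cell mask, assigns
#' quartiles and summarizes per cell.
#'
#' @param imgset an [image_set()] with ratio_num and ratio_den channels
#'   (and envelope/nuclear unless masks are supplied).
#' @param params a [seg_params()] object (adaptive_block/offset, area
#'   filter, connectivity).
#' @param den_floor see [measure_particles()].
#' @param cell_mask,nuclei optional pre-computed masks.
#' @param image_id identifier added to both output tables.
#' @return list with `particles` (full per-particle table), `quartiles`
#'   (per-cell per-quartile summary) and `particle_labels`.
#' @export
lysosome_pipeline <- function(imgset, params = seg_params(),
                              den_floor = 0, cell_mask = NULL,
                              nuclei = NULL, image_id = "image") {
  ch <- imgset$channels
  if (is.null(cell_mask))
    cell_mask <- segment_cell_mask(ch$envelope, params)
  if (is.null(nuclei))
    nuclei <- segment_nuclei(ch$nuclear, params)
  pm <- threshold_adaptive(ch$ratio_den, params$adaptive_block,
                           params$adaptive_offset)
  labels <- label_particles(pm, params)
  rec <- measure_particles(labels, ch$ratio_num, ch$ratio_den, den_floor)
  rec <- radial_position(rec, nuclei, cell_mask)
  rec$quartile <- ifelse(rec$in_mask, assign_quartile(rec$rel_pos), NA_real_)
  rec <- cbind(image_id = image_id, rec)
  quart <- summarize_quartiles(rec)
  if (nrow(quart)) quart <- cbind(image_id = image_id, quart)
  list(particles = rec, quartiles = quart, particle_labels = labels)
}
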