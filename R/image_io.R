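# I/O for multi-channel TIFF images, integer label maps and measurement
# tables. Defines the pixel conventions used by every other module.

CHANNEL_ROLES <- c("envelope", "nuclear", "signal", "ratio_num", "ratio_den")

validate_channel <- function(pixels, name = "channel") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop(name, ": channel pixels must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop(name, ": channel must be at least 1x1", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop(name, ": intensities must be finite", call. = FALSE)
  if (any(pixels < 0))
    stop(name, ": intensities must be >= 0", call. = FALSE)
  invisible(pixels)
}

#' Bundle named channels into an image set
#'
#' An image set is a named list of co-registered channel matrices sharing one
#' pixel grid. Channel names are roles from
#' `c("envelope", "nuclear", "signal", "ratio_num", "ratio_den")`.
#'
#' @param channels named list of numeric matrices, all of identical dimension,
#'   with finite nonnegative intensities.
#' @param pixel_size_um optional positive scalar, micrometres per pixel.
#' @return object of class `image_set` with elements `channels` and
#'   `pixel_size_um`.
#' @export
image_set <- function(channels, pixel_size_um = NULL) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("channels must be a non-empty named list", call. = FALSE)
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         "; roles are ", paste(CHANNEL_ROLES, collapse = ", "), call. = FALSE)
  for (nm in names(channels)) validate_channel(channels[[nm]], nm)
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share identical dimensions", call. = FALSE)
  if (!is.null(pixel_size_um)) {
    stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
              pixel_size_um > 0)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "image_set")
}

#' Read a multi-channel image set from a TIFF file
#'
#' Reads a single- or multi-page TIFF and maps pages to channel roles. Pages
#' are indexed 1-based. Intensities are returned as stored (for float TIFFs)
#' or on the \[0, 1\] scale the tiff package uses for integer TIFFs; all
#' downstream measurements are invariant to this global scale except raw
#' intensity densities.
#'
#' @param path path to a TIFF file.
#' @param channel_map named integer vector mapping roles (see [image_set()])
#'   to 1-based page indices, e.g. `c(envelope = 1, nuclear = 2, signal = 3)`.
#' @param pixel_size_um optional micrometres per pixel.
#' @return an [image_set()].
#' @export
read_image_set <- function(path, channel_map, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stop("channel_map must be a named vector of page indices", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, collapse_gray)
  idx <- as.integer(channel_map)
  if (any(idx < 1L) || any(idx > length(pages)))
    stop("page index out of range: file has ", length(pages),
         " page(s), requested ", paste(idx, collapse = ", "), call. = FALSE)
  shapes <- vapply(pages[idx], dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("shape mismatch: mapped pages have differing dimensions",
         call. = FALSE)
  chans <- setNames(pages[idx], names(channel_map))
  image_set(chans, pixel_size_um = pixel_size_um)
}

# RGB(A) pages are averaged over color planes; grayscale pages pass through.
collapse_gray <- function(page) {
  if (length(dim(page)) == 3L) {
    nch <- min(dim(page)[3], 3L)
    page <- apply(page[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  page
}

#' Write a measurement table as deterministic CSV
#'
#' Writes RFC-4180 CSV (UTF-8, '.' decimal, header row). Floating point values
#' carry at least 10 significant digits. Rows are sorted by `key_cols` so the
#' same table always produces byte-identical files.
#'
#' @param table a data.frame; character, numeric and logical columns only.
#' @param path output file path.
#' @param key_cols columns to sort by; defaults to all columns, left to right.
#' @export
write_table <- function(table, path, key_cols = names(table)) {
  stopifnot(is.data.frame(table))
  if (ncol(table) == 0L) stop("table schema is empty", call. = FALSE)
  key_cols <- intersect(key_cols, names(table))
  if (nrow(table) > 1L && length(key_cols))
    table <- table[do.call(order, table[key_cols]), , drop = FALSE]
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.12g", out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = ",", quote = which(vapply(table, is.character,
              logical(1))), row.names = FALSE, col.names = TRUE, eol = "\n",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an integer label map as TIFF
#'
#' Labels round-trip losslessly through [read_labelmap()]. Maps with labels
#' up to 65535 are written as 16-bit; larger labels promote the file to
#' 32-bit (exact for labels below 2^23).
#'
#' @param lm integer matrix of nonnegative labels, 0 = background.
#' @param path output file path.
#' @export
write_labelmap <- function(lm, path) {
  stopifnot(is.matrix(lm))
  if (any(lm < 0) || any(lm != round(lm)))
    stop("labels must be nonnegative integers", call. = FALSE)
  mx <- max(lm)
  if (mx <= 65535) {
    tiff::writeTIFF(lm / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  } else {
    tiff::writeTIFF(lm / 4294967295, path, bits.per.sample = 32L,
                    reduce = FALSE)
  }
  invisible(path)
}

#' Read an integer label map written by [write_labelmap()]
#' @param path path to the label-map TIFF.
#' @return integer matrix.
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tiff::readTIFF(path, as.is = FALSE, info = TRUE)
  bits <- attr(x, "bits.per.sample")
  x <- collapse_gray(x)
  scale <- if (!is.null(bits) && bits == 32L) 4294967295 else 65535
  matrix(as.integer(round(x * scale)), nrow(x), ncol(x))
}

as_mask <- function(x) {
  stopifnot(is.matrix(x))
  out <- (x != 0) + 0L
  dim(out) <- dim(x)
  out
}
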