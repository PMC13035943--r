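# Masked Pearson colocalization between two channels.

#' Pearson colocalization of two channels within a mask
#'
#' Standard Pearson correlation over the masked pixel pairs:
#' sum((a - mean(a)) * (b - mean(b))) /
#' sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)).
#' A channel that is constant within the mask has no defined correlation
#' and raises an error (it is not reported as 0). Stacks should be
#' z-projected (or pooled) before calling; see [project_stack()].
#'
#' @param ch1,ch2 numeric matrices of identical dimension.
#' @param mask optional 0/1 matrix restricting the pixels used; default is
#'   the whole image.
#' @return list with `pcc` (in \[-1, 1\]), `n_pixels` and `mask_source`
#'   (`"whole_image"` or `"provided"`).
#' @export
pearson_coloc <- function(ch1, ch2, mask = NULL) {
  stopifnot(is.matrix(ch1), is.matrix(ch2), all(dim(ch1) == dim(ch2)))
  source <- if (is.null(mask)) "whole_image" else "provided"
  if (is.null(mask)) {
    a <- as.numeric(ch1); b <- as.numeric(ch2)
  } else {
    stopifnot(all(dim(mask) == dim(ch1)))
    sel <- as_mask(mask) == 1L
    a <- ch1[sel]; b <- ch2[sel]
  }
  if (length(a) < 2L)
    stop("need at least 2 mask pixels", call. = FALSE)
  da <- a - mean(a); db <- b - mean(b)
  ssa <- sum(da^2); ssb <- sum(db^2)
  if (ssa == 0 || ssb == 0)
    stop("constant channel within mask: Pearson correlation undefined",
         call. = FALSE)
  pcc <- sum(da * db) / sqrt(ssa * ssb)
  list(pcc = max(min(pcc, 1), -1), n_pixels = length(a),
       mask_source = source)
}
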