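# Shared fixtures: brute-force oracles and tiny geometric images built in
# code. All distances follow the package convention: pixel centers, (row,
# col), Euclidean.

# O(N^2) exhaustive distance-to-background oracle.
brute_force_edt <- function(mask) {
  m <- mask != 0
  bg <- which(!m, arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  fg <- which(m, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    p <- fg[i, ]
    out[p[1], p[2]] <- sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))
  }
  out
}

# Binary disk in a matrix, 1-based center.
disk <- function(shape, cr, cc, radius) {
  (outer((seq_len(shape[1]) - cr)^2, (seq_len(shape[2]) - cc)^2, `+`)
   <= radius^2) + 0L
}

# One circular cell with a concentric circular nucleus.
single_cell_masks <- function(shape = c(101L, 101L), r_cell = 40,
                              r_nuc = 10) {
  cr <- (shape[1] + 1) / 2
  list(cell_mask = disk(shape, cr, cr, r_cell),
       nuclei = disk(shape, cr, cr, r_nuc),
       center = c(cr, cr), r_cell = r_cell, r_nuc = r_nuc)
}

# Direct-formula Pearson oracle.
pearson_oracle <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Exhaustive 256-bin between-class-variance Otsu oracle; returns the
# intensity at the maximizing bin boundary.
otsu_oracle <- function(x, levels = 256L) {
  rng <- range(x)
  b <- pmin(floor((x - rng[1]) / diff(rng) * levels) + 1L, levels)
  h <- tabulate(b, nbins = levels)
  p <- h / sum(h)
  best <- -Inf; best_t <- 1L
  mu_t <- sum(p * seq_len(levels))
  w0 <- 0; mu0 <- 0
  for (t in seq_len(levels - 1L)) {
    w0 <- w0 + p[t]; mu0 <- mu0 + p[t] * t
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    v <- (mu_t * w0 - mu0)^2 / (w0 * w1)
    if (v > best) { best <- v; best_t <- t }
  }
  rng[1] + best_t / levels * diff(rng)
}
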