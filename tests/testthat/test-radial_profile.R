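test_that("distance to border matches hand geometry", {
  m <- matrix(0L, 3, 3); m[2, 2] <- 1L
  expect_equal(distance_to_border(m)[2, 2], 1.0)

  m2 <- matrix(0L, 7, 7); m2[2:6, 2:6] <- 1L
  expect_equal(distance_to_border(m2)[4, 4], 3.0)
  expect_true(all(distance_to_border(m2)[m2 == 0L] == 0))

  # all-foreground: the frame edge acts as background
  m3 <- matrix(1L, 5, 5)
  d3 <- distance_to_border(m3)
  expect_equal(d3[1, 1], 1.0)
  expect_equal(d3[3, 3], 3.0)

  expect_error(distance_to_border(matrix(0L, 3, 3)), "empty")
})

test_that("distance to border equals the exhaustive oracle on random masks", {
  set.seed(101)
  for (i in 1:100) {
    m <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    if (sum(m) == 0) next
    expect_equal(distance_to_border(m), brute_force_edt(m),
                 tolerance = 1e-9)
  }
})

test_that("distance from nuclei gives Voronoi labels with lower-label ties", {
  nuc <- matrix(0L, 5, 5); nuc[3, 3] <- 1L
  dn <- distance_from_nuclei(nuc)
  expect_equal(dn$distance[3, 5], 2.0)
  expect_equal(dn$distance[3, 3], 0.0)
  expect_true(all(dn$nearest == 1L))

  nuc2 <- matrix(0L, 1, 5); nuc2[1, 1] <- 1L; nuc2[1, 5] <- 2L
  dn2 <- distance_from_nuclei(nuc2)
  expect_equal(dn2$nearest[1, 2], 1L)
  expect_equal(dn2$nearest[1, 4], 2L)
  expect_equal(dn2$nearest[1, 3], 1L)  # equidistant: lower label

  expect_error(distance_from_nuclei(matrix(0L, 3, 3)), "empty")
})

test_that("territories partition the cytoplasm and measure d_max", {
  fx <- single_cell_masks(r_cell = 20, r_nuc = 5, shape = c(51L, 51L))
  terrs <- assign_territories(fx$cell_mask, fx$nuclei)
  expect_length(terrs, 1L)
  t1 <- terrs[[1]]
  cyto <- sum(fx$cell_mask == 1L & fx$nuclei == 0L)
  expect_equal(length(t1$pixels), cyto)
  expect_equal(t1$d_max, fx$r_cell - fx$r_nuc, tolerance = 0.1)

  # two nuclei: disjoint territories covering the cytoplasm exactly
  shape <- c(40L, 80L)
  cm <- disk(shape, 20, 20, 15) + disk(shape, 20, 60, 15)
  cm <- (cm > 0) + 0L
  nuc <- disk(shape, 20, 20, 5) + 2L * disk(shape, 20, 60, 5)
  terrs2 <- assign_territories(cm, nuc)
  expect_length(terrs2, 2L)
  expect_length(intersect(terrs2[[1]]$pixels, terrs2[[2]]$pixels), 0L)
  expect_equal(length(terrs2[[1]]$pixels) + length(terrs2[[2]]$pixels),
               sum(cm == 1L & nuc == 0L))
})

test_that("annuli are disjoint level sets conserving area", {
  fx <- single_cell_masks(r_cell = 20, r_nuc = 5, shape = c(51L, 51L))
  terrs <- assign_territories(fx$cell_mask, fx$nuclei)
  ann <- build_annuli(terrs[[1]], n_annuli = 3L, shape = c(51L, 51L))
  expect_equal(ann$n, 3L)
  expect_equal(sum(ann$labels > 0L), length(terrs[[1]]$pixels))
  expect_equal(sort(unique(ann$labels[ann$labels > 0L])), 1:3)
  expect_equal(ann$r_outer, c(1, 2, 3) / 3)

  one <- build_annuli(terrs[[1]], n_annuli = 1L, shape = c(51L, 51L))
  expect_true(all(one$labels[terrs[[1]]$pixels] == 1L))

  # boundary pixel exactly at d_max/3 belongs to annulus 1 ((lo, hi] bins)
  terr <- list(nucleus_id = 1L, pixels = c(1L, 2L, 3L),
               dist = c(1, 3, 9), d_max = 9)
  a <- build_annuli(terr, n_annuli = 3L, shape = c(3L, 1L))
  expect_equal(a$labels[1:3], c(1L, 1L, 3L))

  # thickness mode: k = ceiling(d / t), final partial annulus
  at <- build_annuli(terr, thickness_px = 4, shape = c(3L, 1L))
  expect_equal(at$n, 3L)
  expect_equal(at$labels[1:3], c(1L, 1L, 3L))
  expect_equal(at$r_outer[3], 1)
})

test_that("profile measurement normalizes intensity per territory", {
  fx <- single_cell_masks(r_cell = 20, r_nuc = 5, shape = c(51L, 51L))
  terrs <- assign_territories(fx$cell_mask, fx$nuclei)
  t1 <- terrs[[1]]
  ann <- build_annuli(t1, n_annuli = 4L, shape = c(51L, 51L))

  # uniform signal: fractions proportional to areas, density constant
  sig <- matrix(7, 51, 51)
  p <- measure_radial_profile(ann, sig, t1, fx$cell_mask,
                              background_mode = "none")
  expect_equal(p$intensity_fraction, p$area_px / sum(p$area_px))
  expect_equal(p$intensity_density, rep(7, 4))
  expect_equal(sum(p$intensity_fraction), 1, tolerance = 1e-12)

  # all signal in the outermost annulus
  sig2 <- matrix(0, 51, 51)
  sig2[ann$labels == 4L] <- 5
  p2 <- measure_radial_profile(ann, sig2, t1, fx$cell_mask,
                               background_mode = "none")
  expect_equal(p2$intensity_fraction, c(0, 0, 0, 1))

  # global intensity scaling: fractions invariant, density scales
  p3 <- measure_radial_profile(ann, sig2 * 10, t1, fx$cell_mask,
                               background_mode = "none")
  expect_equal(p3$intensity_fraction, p2$intensity_fraction)
  expect_equal(p3$intensity_density, p2$intensity_density * 10)

  # zero total signal: flagged, fractions reported as 0
  p4 <- measure_radial_profile(ann, matrix(0, 51, 51), t1, fx$cell_mask,
                               background_mode = "none")
  expect_false(p4$signal_valid)
  expect_equal(p4$intensity_fraction, rep(0, 4))

  # median-outside background is subtracted and clipped at 0
  sig5 <- matrix(2, 51, 51)
  sig5[ann$labels == 1L] <- 12
  p5 <- measure_radial_profile(ann, sig5, t1, fx$cell_mask,
                               background_mode = "median_outside")
  expect_equal(p5$intensity_fraction, c(1, 0, 0, 0))
})

test_that("profile tables are long-format, ordered and conserving", {
  fx <- single_cell_masks(r_cell = 20, r_nuc = 5, shape = c(51L, 51L))
  terrs <- assign_territories(fx$cell_mask, fx$nuclei)
  ann <- build_annuli(terrs[[1]], n_annuli = 3L, shape = c(51L, 51L))
  sig <- matrix(runif(51 * 51), 51, 51)
  p <- measure_radial_profile(ann, sig, terrs[[1]], fx$cell_mask)
  p2 <- p; p2$nucleus_id <- 2L
  tab <- profile_table(list(p2, p), image_id = "img1")
  expect_equal(nrow(tab), 6L)
  expect_equal(names(tab)[1:7],
               c("image_id", "nucleus_id", "annulus_index", "r_norm",
                 "area_px", "intensity_fraction", "intensity_density"))
  expect_equal(tab$nucleus_id, rep(c(1L, 2L), each = 3L))
  sums <- tapply(tab$intensity_fraction, tab$nucleus_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("radial profiles separate perinuclear from peripheral densities", {
  # one synthetic cell, 500 puncta, known Beta radial density
  run_one <- function(alpha, beta, seed) {
    sp <- scene_spec(image_shape = c(256L, 256L), n_cells = 1L,
                     cell_radius_px = c(mean = 90, sd = 0),
                     nucleus_radius_px = c(mean = 20, sd = 0),
                     n_puncta_per_cell = 500L, radial_alpha = alpha,
                     radial_beta = beta, noise = FALSE, seed = seed)
    sc <- generate_scene(sp)
    r <- radial_profile_pipeline(sc$images, cell_mask = sc$truth$cell_mask,
                                 nuclei = sc$truth$nuclei, n_annuli = 10L)
    r$table
  }
  tab_wt <- run_one(2, 5, 31L)
  tab_ko <- run_one(5, 2, 32L)
  wmean <- function(tab) sum(tab$intensity_fraction * tab$r_norm)
  expect_gt(wmean(tab_ko) - wmean(tab_wt), 0.2)
  expect_lt(max(abs(tab_wt$intensity_fraction - beta_bin_masses(2, 5, 10))),
            0.05)
  expect_lt(max(abs(tab_ko$intensity_fraction - beta_bin_masses(5, 2, 10))),
            0.05)
})

test_that("moving signal outward strictly increases the weighted mean", {
  frac <- c(0.3, 0.4, 0.2, 0.1)
  r <- c(0.25, 0.5, 0.75, 1)
  base <- sum(frac * r)
  for (j in 1:3) for (k in (j + 1):4) {
    shifted <- frac
    shifted[j] <- shifted[j] - 0.05
    shifted[k] <- shifted[k] + 0.05
    expect_gt(sum(shifted * r), base)
  }
})
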