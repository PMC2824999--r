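test_that("the standard lattice has the documented structure", {
  cells <- standard_tally_cells()
  expect_equal(sum(cells$radial), 32)
  expect_true(all(cells$volume > 0))
  # ring volume identity 2 pi y dy dz
  rings <- cells[cells$kind == "ring", ]
  expect_equal(rings$volume, 2 * pi * rings$y * 0.05 * 0.05,
               tolerance = 1e-12)
  # the on-axis positions blocked by the capsule/cable are absent
  expect_false(any(cells$y == 0 & abs(cells$z) < 0.3))
  # transverse lattice cells merged with the radial set, not duplicated
  expect_equal(nrow(cells[cells$y == 5 & cells$z == 0, ]), 1)
  expect_true(cells$radial[cells$y == 5 & cells$z == 0] &&
                cells$lattice[cells$y == 5 & cells$z == 0])
})

test_that("track-length scoring is exact for single segments", {
  cells <- standard_tally_cells()
  # zero-length segment scores nothing
  seg0 <- data.frame(x = -10, y = 5, z = 0, ux = 1, uy = 0, uz = 0,
                     length = 0, energy = 1.25, weight = 1, history = 0)
  sc0 <- score_track_segments(cells, seg0)
  expect_true(all(sc0$fluence_sum == 0))
  # chord through the ring cell at (y=5, z=0): closed-form in-cell length
  seg <- data.frame(x = -10, y = 5, z = 0, ux = 1, uy = 0, uz = 0,
                    length = 20, energy = 1.25, weight = 1, history = 0)
  sc <- score_track_segments(cells, seg)
  i <- which(sc$radial & sc$y == 5 & sc$z == 0)
  chord <- 2 * sqrt(5.025^2 - 25)
  expect_equal(sc$fluence_sum[i] * sc$volume[i], chord, tolerance = 1e-9)
  # axial segment through a disk cell scores exactly its 0.5 mm depth
  segz <- data.frame(x = 0, y = 0, z = -2, ux = 0, uy = 0, uz = 1,
                     length = 4, energy = 1.25, weight = 1, history = 0)
  scz <- score_track_segments(cells, segz)
  disks <- which(scz$kind == "disk" & abs(scz$z) <= 1.9)
  expect_true(all(abs(scz$fluence_sum[disks] * scz$volume[disks] - 0.05)
                  < 1e-9))
})

test_that("ring-cell fluence is unbiased under a uniform isotropic flux", {
  set.seed(55)
  n <- 4e5
  segs <- uniform_flux_segments(n, L = 4, R = 25, H = 40)
  cells <- coarse_test_cells()
  sc <- score_track_segments(cells, segs)
  expected <- n * 4 / (pi * 25^2 * 40)
  sd_sum <- sqrt(pmax(sc$fluence_ssq - sc$fluence_sum^2 / n, 0))
  z <- (sc$fluence_sum - expected) / sd_sum
  # fluence independent of ring radius: per-cell z-scores behave like N(0,1)
  expect_true(all(abs(z) < 4))
  expect_gte(mean(abs(z) < 3), 0.95)
})

test_that("kerma equals fluence times E mu_en/rho on the same segments", {
  set.seed(56)
  segs <- uniform_flux_segments(2e4)
  cells <- coarse_test_cells()
  sc <- score_track_segments(cells, segs, medium = "water")
  scored <- sc$fluence_sum > 0
  ratio <- sc$kerma_sum[scored] / sc$fluence_sum[scored]
  # one exact conversion factor across all cells (the scorer's own lookup)
  expect_lt(diff(range(ratio)), 1e-12)
  expect_equal(ratio[1], 1 * mu_en_over_rho("water", 1), tolerance = 1e-4)
})

test_that("finalize reproduces hand-computed statistics", {
  # all-equal per-history scores: zero variance
  out <- finalize_scores(10, 10, 10)    # ten histories each scoring 1
  expect_equal(out$mean, 2 * 1)         # x2 photons per decay
  expect_equal(out$rel_1sigma, 0)
  # two histories scoring 0 and 2x: mean x, sd of mean = x
  x <- 0.37
  out2 <- finalize_scores(2 * x, (2 * x)^2, 2)
  expect_equal(out2$mean, 2 * x)
  expect_equal(out2$rel_1sigma, 1, tolerance = 1e-12)
})

test_that("uncertainty estimate has ~68% single-sigma coverage", {
  # many independent replicates of a small uniform-flux scoring experiment
  set.seed(57)
  cells <- coarse_test_cells()[c(8, 9), ]    # two well-sampled rings
  hits <- 0
  trials <- 0
  for (rep in 1:40) {
    n <- 4e3
    segs <- uniform_flux_segments(n)
    sc <- score_track_segments(cells, segs)
    expected <- n * 4 / (pi * 25^2 * 40)
    sd_sum <- sqrt(pmax(sc$fluence_ssq - sc$fluence_sum^2 / n, 0))
    trials <- trials + nrow(sc)
    hits <- hits + sum(abs(sc$fluence_sum - expected) < sd_sum)
  }
  expect_gt(hits / trials, 0.68 - 3 * sqrt(0.68 * 0.32 / trials))
  expect_lt(hits / trials, 0.68 + 3 * sqrt(0.68 * 0.32 / trials))
})

test_that("spectra normalize to one and degenerate tallies error", {
  sp <- tibble::tibble(position = c(1, 1, 2, 2),
                       e_lo = c(0.1, 0.3, 0.1, 0.3),
                       e_hi = c(0.3, 0.5, 0.3, 0.5),
                       fluence = c(3, 1, 0.5, 0.5))
  out <- normalize_spectrum(sp)
  expect_equal(as.numeric(tapply(out$fluence, out$position, sum)),
               c(1, 1), tolerance = 1e-12)
  expect_equal(out$fluence[1], 0.75)
  sp$fluence <- 0
  expect_error(normalize_spectrum(sp), "empty")
  one <- tibble::tibble(position = 1, e_lo = 0.1, e_hi = 0.3, fluence = 5)
  expect_equal(normalize_spectrum(one)$fluence, 1)
})

test_that("spectrum bins are contiguous with 2 keV line bins", {
  edges <- spectrum_bin_edges()
  expect_true(all(diff(edges) > 0))
  w <- diff(edges)
  i117 <- which(edges == 1.169)
  expect_equal(edges[i117 + 1], 1.171)
  i133 <- which(edges == 1.329)
  expect_equal(edges[i133 + 1], 1.331)
  # widths: regular 20 keV, the 2 keV line bins, and the 19 keV neighbours
  expect_true(all(abs(w - 0.02) < 1e-12 | abs(w - 0.002) < 1e-12 |
                    abs(w - 0.019) < 1e-12))
})

test_that("point detector agrees with a ring tally at the same radius", {
  # air sphere: both estimators see the same field at 50 cm
  cells <- standard_tally_cells(radial_r = c(1, 50),
                                lattice_y = numeric(0),
                                lattice_z = c(-5, 5))
  res <- run_simulation(run_config(phantom_air_sphere(), n_histories = 5e5,
                                   seed = 314, cells = cells,
                                   detectors = 50, score_medium = "air"))
  ring <- res$cells[res$cells$y == 50, ]
  det <- res$detectors
  diff <- abs(ring$kerma_rate_per_activity - det$kerma_rate_per_activity)
  sig <- sqrt((ring$kerma_rate_per_activity * ring$rel_1sigma)^2 +
                (det$kerma_rate_per_activity * det$rel_1sigma)^2)
  expect_lt(diff, 3 * sig)
})
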