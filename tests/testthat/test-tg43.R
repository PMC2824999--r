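test_that("unit conversion to activity units is exact and invertible", {
  expect_equal(per_decay_to_activity_units(1), 3.6e5)
  expect_equal(per_decay_to_activity_units(0), 0)
  x <- 2.345e-16
  expect_equal(per_decay_to_activity_units(x) / 3.6e5, x, tolerance = 1e-15)
})

test_that("line geometry function limits and symmetries", {
  # far field: G_L r^2 -> 1
  expect_equal(line_geometry_function(1000) * 1000^2, 1, tolerance = 1e-6)
  # theta <-> pi - theta symmetry at random points
  set.seed(4)
  r <- runif(50, 0.3, 30)
  th <- runif(50, 0.05, pi / 2)
  expect_equal(line_geometry_function(r, th),
               line_geometry_function(r, pi - th), tolerance = 1e-12)
  # point-source dose rate constant times G_L(1 cm, 90 deg) for L = 3.5 mm
  expect_equal(round(1.094 * line_geometry_function(1, pi / 2, 0.35), 3),
               1.083)
  # continuous across the ring/axial transition
  near <- line_geometry_function(2, 1e-6)
  axial <- 1 / (2^2 - 0.35^2 / 4)
  expect_equal(near, axial, tolerance = 1e-6)
  expect_error(line_geometry_function(0.1, 0), "active segment")
})

test_that("backscatter energy follows the Compton formula", {
  expect_equal(round(backscatter_energy(1.25), 3), 0.212)
  # low-energy limit: E' -> E
  expect_lt(abs(backscatter_energy(0.001) / 0.001 - 1), 0.01)
  # high-energy asymptote m_e c^2 / 2
  expect_lt(abs(backscatter_energy(1e4) / (0.51099895 / 2) - 1), 0.001)
})

test_that("air-kerma strength fit recovers constructed series", {
  # exact inverse-square: intercept c, zero slope
  y <- c(25, 50, 75, 100)
  cc <- 3.1e-7
  fit <- fit_air_kerma_strength(
    tibble::tibble(y = y, kerma_rate_per_activity = cc / y^2))
  expect_equal(fit$sk_per_A, cc, tolerance = 1e-12)
  expect_equal(fit$b, 0, tolerance = 1e-12)
  # linear build-up k y^2 = c + 0.001 y recovered exactly
  fit2 <- fit_air_kerma_strength(
    tibble::tibble(y = y, kerma_rate_per_activity = (cc + 0.001 * y) / y^2))
  expect_equal(fit2$sk_per_A, cc, tolerance = 1e-9)
  expect_equal(fit2$b, 0.001, tolerance = 1e-12)
  expect_error(fit_air_kerma_strength(
    tibble::tibble(y = 25, kerma_rate_per_activity = 1)), "2 distinct")
  td <- tidy(fit2)
  expect_equal(td$estimate[td$term == "sk_per_A"], cc, tolerance = 1e-9)
  expect_true(all(c("sk_per_A", "b", "r.squared") %in% names(glance(fit2))))
})

test_that("dose rate constant is the plain ratio with quadrature errors", {
  expect_equal(dose_rate_constant(3e-7, 3e-7)$lambda, 1)
  pair <- known_ratio_pair(1.086)
  fit <- fit_air_kerma_strength(pair$air_series)
  lam <- dose_rate_constant(pair$reference_dose_rate, fit$sk_per_A)
  expect_equal(lam$lambda, 1.086, tolerance = 1e-12)
  for (target in c(1.0, 1.094)) {
    p <- known_ratio_pair(target)
    f <- fit_air_kerma_strength(p$air_series)
    expect_equal(dose_rate_constant(p$reference_dose_rate, f$sk_per_A)$lambda,
                 target, tolerance = 1e-12)
  }
  lam2 <- dose_rate_constant(1, 1, 0.003, 0.004)
  expect_equal(lam2$rel_1sigma, 0.005)
  expect_error(dose_rate_constant(-1, 1), "positive")
})

test_that("radial dose function divides out the geometry factor", {
  # geometry-only field: g_L identically one
  r <- c(0.5, 1, 2, 5, 10, 20)
  prof <- tibble::tibble(r = r, dose = 7.7 * line_geometry_function(r))
  gl <- radial_dose_function(prof)
  expect_equal(gl$g_L, rep(1, length(r)), tolerance = 1e-12)
  # exponential modulation recovered in closed form
  prof2 <- tibble::tibble(r = r,
                          dose = line_geometry_function(r) * exp(-0.01 * r))
  gl2 <- radial_dose_function(prof2)
  expect_equal(gl2$g_L, exp(-0.01 * (r - 1)), tolerance = 1e-12)
  # normalization point is exactly one
  expect_identical(gl2$g_L[r == 1], 1)
  expect_error(radial_dose_function(tibble::tibble(r = c(2, 3),
                                                   dose = c(1, 1))),
               "reference radius")
})

test_that("polynomial fit recovers known coefficients", {
  r <- seq(0.2, 20, length.out = 40)
  a <- c(1.01, -0.012, -3e-4, 4e-6)
  gl <- tibble::tibble(r = r, g_L = a[1] + a[2] * r + a[3] * r^2 + a[4] * r^3)
  fit <- fit_radial_polynomial(gl)
  expect_equal(unname(fit$coefficients), a, tolerance = 1e-10)
  # constant data: a0 only
  glc <- tibble::tibble(r = r, g_L = 0.9)
  fitc <- fit_radial_polynomial(glc)
  expect_equal(unname(fitc$coefficients), c(0.9, 0, 0, 0), tolerance = 1e-10)
  expect_error(fit_radial_polynomial(gl[1:3, ]), "at least")
  expect_equal(predict(fit, 2), a[1] + a[2] * 2 + a[3] * 4 + a[4] * 8,
               tolerance = 1e-9)
})

test_that("the published water g_L table is fitted within its rounding", {
  gl <- gl_published()
  fit <- fit_radial_polynomial(tibble::tibble(r = gl$r, g_L = gl$water))
  expect_equal(unname(fit$coefficients["a0"]), 1.0118, tolerance = 0.005)
  # cubic describes the table to better than one unit in the second decimal
  expect_lt(max(abs(fit$residuals)), 0.01)
})

test_that("dose-rate tables divide kerma by S_K and keep the lattice", {
  cells <- standard_tally_cells()
  sk <- 3e-7
  cells$kerma_rate_per_activity <- sk          # flat field equal to S_K/A
  cells$rel_1sigma <- 0.01
  tab <- build_dose_rate_table(cells, sk, rel_1sigma_sk = 0.005)
  expect_equal(tab$dose_rate_per_sk, rep(1, nrow(tab)))
  expect_equal(tab$rel_1sigma, rep(sqrt(0.01^2 + 0.005^2), nrow(tab)))
  expect_equal(nrow(tab), sum(cells$lattice))
  expect_error(build_dose_rate_table(cells, 0), "positive")
})

test_that("phantom comparison reports percent differences", {
  gl <- gl_published()
  w <- tibble::tibble(r = gl$r, g_L = gl$water, rel_1sigma = 0)
  p <- tibble::tibble(r = gl$r, g_L = gl$pmma, rel_1sigma = 0)
  cmp <- compare_phantoms(w, p)
  # printed-table arithmetic at 10 cm: (0.840 - 0.860) / 0.860
  expect_equal(cmp$pct_diff[cmp$r == 10], 100 * (0.840 - 0.860) / 0.860,
               tolerance = 1e-9)
  # water against itself is identically zero
  self <- compare_phantoms(w, w)
  expect_true(all(self$pct_diff == 0))
  # constructed +3% offset is reported everywhere
  p3 <- tibble::tibble(r = gl$r, g_L = gl$water * 1.03, rel_1sigma = 0)
  expect_equal(compare_phantoms(w, p3)$pct_diff, rep(3, nrow(w)),
               tolerance = 1e-9)
  expect_error(compare_phantoms(w, p[1:5, ]), "mismatch")
})
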