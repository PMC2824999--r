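test_that("element tables satisfy their structural invariants", {
  for (s in element_properties()$symbol) {
    tab <- element_table(s)
    expect_true(all(diff(tab$energy_mev) > 0))
    expect_lte(tab$energy_mev[1], 0.010)
    expect_gte(tab$energy_mev[nrow(tab)], 1.40)
    expect_true(all(tab$photoelectric >= 0))
    expect_true(all(tab$incoherent >= 0))
    expect_true(all(tab$coherent >= 0))
    expect_true(all(tab$pair >= 0))
    expect_true(all(tab$pair[tab$energy_mev < 1.022] == 0))
  }
})

test_that("build_material validates and renormalizes compositions", {
  expect_error(build_material(c(Xx = 1), 1), "unknown element")
  expect_error(build_material(c(H = 0.5, O = 0.4), 1), "1e-3")
  expect_error(build_material(c(H = 1), 0), "density")
  m <- build_material(c(H = 0.0810, C = 0.6000, O = 0.3200), 1.19)
  expect_equal(sum(m$composition), 1, tolerance = 1e-12)

  w <- build_material(c(H = 0.112, O = 0.888), 0.998, "water")
  expect_length(w$composition, 2)
  expect_s3_class(w, "material")
})

test_that("a single-element material reproduces the element table exactly", {
  co <- build_material(c(Co = 1.0), 8.9)
  tab <- element_table("Co")
  for (p in c("photoelectric", "incoherent", "coherent", "pair")) {
    expect_identical(co$table[[p]], tab[[p]])
  }
  # and on-node lookups are exact table values
  i <- c(1, 10, 30)
  expect_equal(mu_total(co, tab$energy_mev[i], "incoherent", per_mass = TRUE),
               tab$incoherent[i], tolerance = 1e-12)
})

test_that("mixture rule: mu/rho equals the Bragg re-sum oracle", {
  for (key in c("water", "pmma", "solid_water", "steel316l")) {
    m <- standard_material(key)
    E <- m$table$energy_mev
    for (p in c("photoelectric", "incoherent", "coherent")) {
      oracle <- bragg_sum(m$composition, E, p)
      expect_equal(m$table[[p]], oracle, tolerance = 1e-12)
    }
  }
  # PMMA at 1.25 MeV: hand-weighted sum over the three element tables
  pmma <- standard_material("pmma")
  total <- sum(vapply(c("photoelectric", "incoherent", "coherent", "pair"),
                      function(p) bragg_sum(pmma$composition, 1.25, p), 0))
  expect_equal(mu_total(pmma, 1.25), 1.190 * total, tolerance = 1e-10)
})

test_that("interpolation is exact on nodes and monotone between them", {
  w <- standard_material("water")
  E <- w$table$energy_mev
  expect_equal(mu_total(w, E[5], per_mass = TRUE),
               sum(unlist(w$table[5, -1])), tolerance = 1e-12)
  mid <- sqrt(E[5] * E[6])
  v <- mu_total(w, c(E[5], mid, E[6]))
  expect_true(v[2] <= max(v[1], v[3]) && v[2] >= min(v[1], v[3]))
  expect_error(mu_total(w, 2.0), "outside")
  expect_error(mu_total(w, 0.005), "outside")
})

test_that("process probabilities are a proper distribution", {
  set.seed(42)
  mats <- material_library()
  keys <- setdiff(names(mats), "vacuum")
  E <- runif(1000, 0.010, 1.40)
  key <- sample(keys, 1000, replace = TRUE)
  for (k in unique(key)) {
    p <- process_probabilities(mats[[k]], E[key == k])
    tot <- p$photoelectric + p$incoherent + p$coherent + p$pair
    expect_equal(tot, rep(1, nrow(p)), tolerance = 1e-12)
    expect_true(all(as.matrix(p[, -1]) >= 0))
  }
  # below the pair threshold the pair probability is exactly zero
  expect_equal(process_probabilities(mats$water, 0.5)$pair, 0)
  # Compton dominates at the 60Co energies
  expect_gt(process_probabilities(mats$water, 1.25)$incoherent, 0.95)
})

test_that("mass energy-absorption lookups behave", {
  tab <- muen_table("water")
  i <- match(0.1, tab$energy_mev)
  expect_equal(mu_en_over_rho("water", 0.1), tab$muen_over_rho[i])
  # manual log-log interpolation between the bracketing rows at 1.17 MeV
  lo <- max(which(tab$energy_mev <= 1.17))
  manual <- exp(approx(log(tab$energy_mev[lo + 0:1]),
                       log(tab$muen_over_rho[lo + 0:1]), log(1.17))$y)
  expect_equal(mu_en_over_rho("water", 1.17), manual, tolerance = 1e-12)
  ratio <- mu_en_over_rho("water", 1.25) / mu_en_over_rho("air", 1.25)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
  expect_error(mu_en_over_rho("water", 5), "outside")
})

test_that("effective atomic number follows the power-law mean", {
  co <- build_material(c(Co = 1.0), 8.9)
  expect_equal(effective_atomic_number(co, 2.94), 27)
  expect_equal(effective_atomic_number(co, 1), 27)
  w <- standard_material("water")
  expect_equal(effective_atomic_number(w), 7.4, tolerance = 0.01)
  # two-element mixture with equal electron fractions, p = 1: arithmetic mean
  props <- element_properties()
  AC <- props$A[props$symbol == "C"]
  AO <- props$A[props$symbol == "O"]
  wC <- (AC / 6) / (AC / 6 + AO / 8)
  mix <- build_material(c(C = wC, O = 1 - wC), 1)
  expect_equal(effective_atomic_number(mix, 1), 7, tolerance = 1e-12)
})

test_that("coefficient tables round-trip through serialization bit-exactly", {
  tab <- element_table("Fe")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_xs_table(tab, f, header = "round-trip test")
  back <- read_xs_table(f)
  expect_identical(as.data.frame(back), as.data.frame(tab))
})
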