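# independent numerical oracles used across test files

# Klein-Nishina differential cross section per unit cos(theta), unnormalized
kn_dcs <- function(cos_theta, energy) {
  a <- energy / 0.51099895
  eps <- 1 / (1 + a * (1 - cos_theta))
  0.5 * eps^2 * (eps + 1 / eps - (1 - cos_theta^2))
}

# quadrature mean of a function of cos(theta) under the KN angular pdf
kn_mean <- function(f, energy) {
  num <- integrate(function(c) f(c) * kn_dcs(c, energy), -1, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(function(c) kn_dcs(c, energy), -1, 1,
                   rel.tol = 1e-10)$value
  num / den
}

# Bragg-additivity re-sum of a mixture coefficient from the element tables
bragg_sum <- function(composition, energy, process) {
  w <- composition / sum(composition)
  total <- 0
  for (s in names(w)) {
    tab <- element_table(s)
    v <- tab[[process]]
    if (all(v > 0)) {
      vi <- exp(approx(log(tab$energy_mev), log(v), log(energy))$y)
    } else {
      vi <- approx(tab$energy_mev, v, energy)$y
    }
    total <- total + w[[s]] * vi
  }
  total
}

# uniform isotropic flux fixture: segments of length L with uniform starts
# in a cylinder of radius R, height H; expected fluence everywhere deeper
# than L from the boundary is n * L / V
uniform_flux_segments <- function(n, L = 4, R = 25, H = 40) {
  rr <- sqrt(runif(n)) * R
  ph <- runif(n) * 2 * pi
  cz <- runif(n, -1, 1)
  phd <- runif(n) * 2 * pi
  s <- sqrt(1 - cz^2)
  data.frame(x = rr * cos(ph), y = rr * sin(ph), z = runif(n, -H / 2, H / 2),
             ux = s * cos(phd), uy = s * sin(phd), uz = cz,
             length = L, energy = 1, weight = 1, history = 0:(n - 1))
}

# coarse ring/disk cells (0.5 cm half-width) for estimator statistics
coarse_test_cells <- function(hw = 0.25) {
  g <- expand.grid(y = c(1, 3, 5, 10, 15, 20), z = c(-5, 0, 5))
  rings <- tibble::tibble(y = g$y, z = g$z, kind = "ring",
                          r_in = g$y - hw, r_out = g$y + hw,
                          z_min = g$z - hw, z_max = g$z + hw,
                          radial = g$z == 0, lattice = TRUE)
  disks <- tibble::tibble(y = 0, z = c(-5, 5), kind = "disk",
                          r_in = 0, r_out = 0.5,
                          z_min = c(-5, 5) - hw, z_max = c(-5, 5) + hw,
                          radial = FALSE, lattice = TRUE)
  cells <- rbind(rings, disks)
  cells$volume <- pi * (cells$r_out^2 - cells$r_in^2) *
    (cells$z_max - cells$z_min)
  cells
}
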