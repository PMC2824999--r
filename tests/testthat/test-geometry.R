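test_that("points locate to the expected nested regions", {
  pts <- data.frame(
    x = c(0, 0, 0, 0, 0, 0, 60),
    y = c(0, 0.030, 0.045, 0.045, 10, 0, 0),
    z = c(0, 0, 0, -0.3, 0, 49, 0))
  out <- locate_region(pts, phantom_dose())
  expect_equal(as.character(out$region),
               c("core", "air_gap", "capsule", "cable", "phantom",
                 "phantom", "exterior"))
})

test_that("axial and transverse boundary distances match the drawing", {
  d <- boundary_distance(c(0, 0, 0), c(0, 1, 0))
  expect_equal(d$distance, 0.025, tolerance = 1e-12)
  expect_equal(d$next_region, "air_gap")
  d <- boundary_distance(c(0, 0, 0), c(0, 0, 1))
  expect_equal(d$distance, 0.175, tolerance = 1e-12)
  expect_error(boundary_distance(c(0, 0, 0), c(0, 2, 0)), "unit vector")
})

test_that("ray tracing agrees with a fine marching oracle", {
  set.seed(71)
  ph <- phantom_dose()
  n_ray <- 150
  step <- 1e-4
  for (i in seq_len(n_ray)) {
    # start near the source where all surfaces live
    p <- runif(3, -0.5, 0.5)
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    d <- boundary_distance(p, u, ph)
    if (!is.finite(d$distance) || d$distance > 1.2) next
    # march until the region changes
    tt <- seq(step, d$distance + 50 * step, by = step)
    pts <- data.frame(x = p[1] + tt * u[1], y = p[2] + tt * u[2],
                      z = p[3] + tt * u[3])
    regs <- as.character(locate_region(pts, ph)$region)
    change <- which(regs != d$region)[1]
    expect_false(is.na(change))
    expect_lt(abs(tt[change] - d$distance), 2 * step)
  }
})

test_that("boundary distances telescope to the straight chord", {
  ph <- phantom_dose()
  set.seed(11)
  for (i in 1:25) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    p <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2), runif(1, -0.3, 0.3))
    total <- 0
    pos <- p
    for (k in 1:200) {
      d <- boundary_distance(pos, u, ph)
      if (!is.finite(d$distance)) break
      total <- total + d$distance
      pos <- pos + (d$distance + 1e-9) * u
      if (locate_region(data.frame(x = pos[1], y = pos[2], z = pos[3]),
                        ph)$region == "exterior") break
    }
    # chord of the 50 cm radius, 100 cm height cylinder from p along u
    a <- u[1]^2 + u[2]^2
    texit <- if (a > 0) {
      b <- 2 * (p[1] * u[1] + p[2] * u[2])
      cc <- p[1]^2 + p[2]^2 - 50^2
      tcyl <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
      if (abs(u[3]) > 0) min(tcyl, (sign(u[3]) * 50 - p[3]) / u[3]) else tcyl
    } else {
      (sign(u[3]) * 50 - p[3]) / u[3]
    }
    expect_lt(abs(total - texit), 1e-6)
  }
})

test_that("geometry is symmetric under z-reflection modulo the cable", {
  set.seed(3)
  pts <- data.frame(x = runif(300, -0.06, 0.06), y = runif(300, -0.06, 0.06),
                    z = runif(300, 0, 0.19))
  up <- locate_region(pts, phantom_dose())$region
  dn <- locate_region(transform(pts, z = -z), phantom_dose())$region
  expect_equal(as.character(up), as.character(dn))
  # rotation about z
  th <- runif(300, 0, 2 * pi)
  rot <- data.frame(x = pts$x * cos(th) - pts$y * sin(th),
                    y = pts$x * sin(th) + pts$y * cos(th), z = pts$z)
  expect_equal(as.character(locate_region(rot, phantom_dose())$region),
               as.character(up))
})

test_that("region volumes from rejection sampling match closed forms", {
  set.seed(9)
  n <- 2e5
  box <- c(0.06, 0.06, 0.45)   # encloses the whole source structure
  pts <- data.frame(x = runif(n, -box[1], box[1]),
                    y = runif(n, -box[2], box[2]),
                    z = runif(n, -box[3], box[3]))
  vbox <- prod(2 * box)
  reg <- locate_region(pts, phantom_dose())$region
  vol <- function(name) vbox * mean(reg == name)
  se <- function(name) vbox * sd(reg == name) / sqrt(n)
  v_core <- pi * 0.025^2 * 0.35
  v_gap <- pi * 0.035^2 * 0.37 - v_core
  v_caps <- pi * 0.050^2 * 0.40 - pi * 0.035^2 * 0.37
  v_cable <- pi * 0.050^2 * 0.20
  expect_lt(abs(vol("core") - v_core), 3 * se("core"))
  expect_lt(abs(vol("air_gap") - v_gap), 3 * se("air_gap"))
  expect_lt(abs(vol("capsule") - v_caps), 3 * se("capsule"))
  expect_lt(abs(vol("cable") - v_cable), 3 * se("cable"))
  # every point classifies into exactly one region (factor is complete)
  expect_false(anyNA(reg))
})

test_that("source photons sample the stated emission distribution", {
  set.seed(123)
  s <- sample_source_photons(1e5)
  n <- nrow(s)
  expect_lt(abs(mean(s$x)), 3 * sd(s$x) / sqrt(n))
  expect_lt(abs(mean(s$y)), 3 * sd(s$y) / sqrt(n))
  expect_lt(abs(mean(s$z)), 3 * sd(s$z) / sqrt(n))
  # all positions inside the active core
  expect_true(all(sqrt(s$x^2 + s$y^2) <= 0.025 & abs(s$z) <= 0.175))
  # two lines, equal weight: mean 1.25 MeV
  expect_true(all(s$energy %in% c(1.17, 1.33)))
  expect_lt(abs(mean(s$energy) - 1.25), 3 * sd(s$energy) / sqrt(n))
  # isotropy: z-component of direction uniform on [-1, 1]
  ks <- suppressWarnings(stats::ks.test(s$uz[1:10000], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sqrt(s$ux^2 + s$uy^2 + s$uz^2), rep(1, n), tolerance = 1e-9)
})
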