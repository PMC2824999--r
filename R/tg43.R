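ACTIVE_LENGTH <- 0.35    # cm

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Convert per-decay kerma to kerma rate per unit activity
#'
#' `1 Gy per decay = 3.6e5 cGy h^-1 Bq^-1`.
#'
#' @param kerma_per_decay kerma in Gy per disintegration.
#' @return kerma rate in cGy h^-1 Bq^-1.
#' @export
per_decay_to_activity_units <- function(kerma_per_decay) {
  kerma_per_decay * PER_DECAY_TO_CGY_H_BQ
}

#' Line-source geometry function G_L(r, theta)
#'
#' `G_L = beta / (L r sin(theta))` with `beta` the angle the active segment
#' of length `L` subtends at the field point; on the long axis it is the
#' continuous limit `1 / (r^2 - L^2/4)`.  Far from the source
#' `G_L -> 1/r^2`.
#'
#' @param r radial distance from the source centre, cm (> 0, vectorized).
#' @param theta polar angle from the source long axis, radians.
#' @param L active length, cm.
#' @return geometry function value, cm^-2.
#' @export
#' @examples
#' line_geometry_function(1, pi / 2)
line_geometry_function <- function(r, theta = pi / 2, L = ACTIVE_LENGTH) {
  n <- max(length(r), length(theta))
  r <- rep_len(r, n)
  theta <- rep_len(theta, n)
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  # field point in the (transverse, along) plane
  yt <- r * sin(theta)
  zt <- r * cos(theta)
  on_axis <- abs(yt) < 1e-9
  if (any(on_axis & abs(zt) <= L / 2 + 1e-12)) {
    stop("point lies on the active segment", call. = FALSE)
  }
  out <- numeric(n)
  # angle subtended by the segment ends at the field point
  a1 <- atan2(yt, zt - L / 2)
  a2 <- atan2(yt, zt + L / 2)
  beta <- abs(a2 - a1)
  out[!on_axis] <- (beta / (L * r * sin(theta)))[!on_axis]
  out[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  out
}

#' Minimum Compton-scattered (backscatter) photon energy
#'
#' Energy of a photon scattered through 180 degrees:
#' `E' = E / (1 + 2 E / m_e c^2)`.  For the 1.25 MeV mean gamma energy this
#' is 0.212 MeV, the low edge of the single-scatter continuum.
#'
#' @param energy incident photon energy, MeV (vectorized).
#' @return backscattered photon energy, MeV.
#' @export
#' @examples
#' backscatter_energy(1.25)
backscatter_energy <- function(energy) {
  stopifnot(all(energy > 0))
  energy / (1 + 2 * energy / MEC2)
}

#' Fit the air-kerma strength from transverse air-kerma data
#'
#' Air-kerma strength is obtained from the linear model
#' `k_air(y) * y^2 = S_K/A + b * y`: ordinary least squares of the
#' distance-squared-weighted air-kerma rate against distance.  The
#' intercept is S_K per unit activity and the slope `b` describes the
#' build-up of scattered photons in air.
#'
#' @param series tibble with columns `y` (cm) and `kerma_rate_per_activity`
#'   (cGy h^-1 Bq^-1); an optional `rel_1sigma` column propagates into the
#'   intercept uncertainty reported by [glance()].
#' @return an `sk_fit` object with elements `sk_per_A` (cGy cm^2 h^-1
#'   Bq^-1), `b`, and the underlying `lm` fit.
#' @export
fit_air_kerma_strength <- function(series) {
  stopifnot(all(c("y", "kerma_rate_per_activity") %in% names(series)))
  if (length(unique(series$y)) < 2) {
    stop("need at least 2 distinct distances", call. = FALSE)
  }
  d <- tibble::tibble(y = series$y,
                      ky2 = series$kerma_rate_per_activity * series$y^2)
  fit <- lm(ky2 ~ y, data = d)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  structure(list(sk_per_A = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 sk_se = unname(se[1]), b_se = unname(se[2]),
                 n = nrow(d), fit = fit, data = d),
            class = "sk_fit")
}

#' @export
print.sk_fit <- function(x, ...) {
  cat("<sk_fit> S_K/A = ", format(x$sk_per_A, digits = 4),
      " cGy cm^2 h^-1 Bq^-1 (se ", format(x$sk_se, digits = 2),
      "), b = ", format(x$b, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.sk_fit <- function(x, ...) {
  tibble::tibble(term = c("sk_per_A", "b"),
                 estimate = c(x$sk_per_A, x$b),
                 std.error = c(x$sk_se, x$b_se))
}

#' @importFrom generics glance
#' @export
glance.sk_fit <- function(x, ...) {
  tibble::tibble(sk_per_A = x$sk_per_A, b = x$b,
                 sk_rel_1sigma = x$sk_se / abs(x$sk_per_A),
                 r.squared = suppressWarnings(summary(x$fit)$r.squared),
                 n = x$n)
}

#' Dose rate constant
#'
#' Ratio of the dose rate to water at the TG-43 reference point (1 cm on
#' the transverse axis) to the air-kerma strength, in cGy h^-1 U^-1.
#' Uncertainties combine in quadrature.
#'
#' @param dose_rate_ref dose rate per unit activity at (y = 1 cm, z = 0),
#'   cGy h^-1 Bq^-1.
#' @param sk_per_A air-kerma strength per unit activity, cGy cm^2 h^-1
#'   Bq^-1.
#' @param rel_1sigma_dose,rel_1sigma_sk relative 1-sigma uncertainties.
#' @return tibble with `lambda` (cGy h^-1 U^-1) and `rel_1sigma`.
#' @export
dose_rate_constant <- function(dose_rate_ref, sk_per_A,
                               rel_1sigma_dose = 0, rel_1sigma_sk = 0) {
  if (dose_rate_ref <= 0 || sk_per_A <= 0) {
    stop("dose rate and S_K/A must be positive", call. = FALSE)
  }
  tibble::tibble(lambda = dose_rate_ref / sk_per_A,
                 rel_1sigma = sqrt(rel_1sigma_dose^2 + rel_1sigma_sk^2))
}

#' Radial dose function g_L(r)
#'
#' Removes the line-source geometry dependence from a transverse-axis dose
#' profile and normalizes at the reference radius:
#' `g_L(r) = [D(r) / D(r0)] * [G_L(r0, 90deg) / G_L(r, 90deg)]` with
#' `r0 = 1 cm`.  `g_L(r0) = 1` exactly by construction.
#'
#' @param profile tibble with columns `r` (cm) and `dose` (any fixed unit);
#'   an optional `rel_1sigma` column is propagated in quadrature against
#'   the reference radius.
#' @param L active length, cm.
#' @param r0 reference radius, cm (must be present in `profile$r`).
#' @return tibble with `r`, `g_L` and `rel_1sigma`.
#' @export
radial_dose_function <- function(profile, L = ACTIVE_LENGTH, r0 = 1) {
  stopifnot(all(c("r", "dose") %in% names(profile)))
  i0 <- which(abs(profile$r - r0) < 1e-9)
  if (length(i0) != 1) {
    stop("profile must contain the reference radius r0 = ", r0, " cm",
         call. = FALSE)
  }
  gl <- (profile$dose / profile$dose[i0]) *
    (line_geometry_function(r0, L = L) /
       line_geometry_function(profile$r, L = L))
  gl[i0] <- 1
  rel <- if ("rel_1sigma" %in% names(profile)) {
    r <- sqrt(profile$rel_1sigma^2 + profile$rel_1sigma[i0]^2)
    r[i0] <- 0
    r
  } else {
    rep(0, nrow(profile))
  }
  tibble::tibble(r = profile$r, g_L = gl, rel_1sigma = rel)
}

#' Cubic polynomial fit of the radial dose function
#'
#' Unweighted ordinary least squares of `g_L` on `{1, r, r^2, r^3}` (or up
#' to the requested order) over the supplied radii.
#'
#' @param gl tibble with columns `r` and `g_L`.
#' @param order polynomial order (default 3).
#' @return a `gl_fit` object; coefficients named `a0`, `a1`, ... with
#'   units cm^0, cm^-1, ...
#' @export
fit_radial_polynomial <- function(gl, order = 3) {
  stopifnot(all(c("r", "g_L") %in% names(gl)))
  if (nrow(gl) < order + 2) {
    stop("need at least order + 2 points", call. = FALSE)
  }
  X <- stats::poly(gl$r, degree = order, raw = TRUE)
  fit <- lm(gl$g_L ~ X)
  cf <- unname(coef(fit))
  if (anyNA(cf)) stop("rank-deficient polynomial fit", call. = FALSE)
  names(cf) <- paste0("a", 0:order)
  structure(list(coefficients = cf, order = order, fit = fit,
                 data = gl, residuals = unname(residuals(fit))),
            class = "gl_fit")
}

#' @export
print.gl_fit <- function(x, ...) {
  cat("<gl_fit> order-", x$order, " polynomial; coefficients:\n", sep = "")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' @export
predict.gl_fit <- function(object, r, ...) {
  drop(cbind(1, stats::poly(r, degree = object$order, raw = TRUE)) %*%
         object$coefficients)
}

#' @export
tidy.gl_fit <- function(x, ...) {
  se <- sqrt(diag(suppressWarnings(vcov(x$fit))))
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(se))
}

#' @export
glance.gl_fit <- function(x, ...) {
  tibble::tibble(r.squared = suppressWarnings(summary(x$fit)$r.squared),
                 max_abs_residual = max(abs(x$residuals)),
                 n = nrow(x$data), order = x$order)
}

#' Cartesian dose-rate table per unit air-kerma strength
#'
#' Divides the per-activity collision kerma rate in every lattice cell by
#' the air-kerma strength per activity, giving the away/along dose-rate
#' table in cGy h^-1 U^-1.
#'
#' @param cells finalized cell tibble from [run_simulation()] (must carry
#'   `kerma_rate_per_activity`); only `lattice` cells are used.
#' @param sk_per_A air-kerma strength per unit activity.
#' @param rel_1sigma_sk its relative 1-sigma uncertainty.
#' @return tibble with `y`, `z`, `dose_rate_per_sk` (cGy h^-1 U^-1) and
#'   `rel_1sigma`.
#' @export
build_dose_rate_table <- function(cells, sk_per_A, rel_1sigma_sk = 0) {
  stopifnot("kerma_rate_per_activity" %in% names(cells))
  if (sk_per_A <= 0) stop("S_K/A must be positive", call. = FALSE)
  lat <- cells[cells$lattice, ]
  tibble::tibble(y = lat$y, z = lat$z,
                 dose_rate_per_sk = lat$kerma_rate_per_activity / sk_per_A,
                 rel_1sigma = sqrt(lat$rel_1sigma^2 + rel_1sigma_sk^2))
}

#' Compare a solid phantom dose table against water
#'
#' Per-coordinate percent difference `100 (solid - water) / water` with
#' first-order propagated uncertainty, plus a flag marking coordinates
#' where the difference exceeds twice the combined uncertainty.
#'
#' @param water,solid tibbles on the same lattice with a value column
#'   (`dose_rate_per_sk`, `g_L` or `dose`) and `rel_1sigma`.
#' @param by join columns (default the shared coordinate columns).
#' @return tibble with the coordinates, `water`, `solid`, `pct_diff`,
#'   `pct_diff_1sigma` and `significant`.
#' @export
compare_phantoms <- function(water, solid, by = NULL) {
  value_col <- intersect(c("dose_rate_per_sk", "g_L", "dose"), names(water))
  if (length(value_col) == 0) {
    stop("no value column found", call. = FALSE)
  }
  value_col <- value_col[1]
  by <- by %||% intersect(c("y", "z", "r"), intersect(names(water),
                                                      names(solid)))
  w <- water[, c(by, value_col,
                 intersect("rel_1sigma", names(water)))]
  s <- solid[, c(by, value_col, intersect("rel_1sigma", names(solid)))]
  names(w)[names(w) == value_col] <- "water"
  names(s)[names(s) == value_col] <- "solid"
  names(w)[names(w) == "rel_1sigma"] <- "water_rel"
  names(s)[names(s) == "rel_1sigma"] <- "solid_rel"
  j <- dplyr::inner_join(w, s, by = by)
  if (nrow(j) != nrow(w) || nrow(j) != nrow(s)) {
    stop("lattice mismatch between the two tables", call. = FALSE)
  }
  if (!"water_rel" %in% names(j)) j$water_rel <- 0
  if (!"solid_rel" %in% names(j)) j$solid_rel <- 0
  j$pct_diff <- 100 * (j$solid - j$water) / j$water
  j$pct_diff_1sigma <- 100 * (j$solid / j$water) *
    sqrt(j$water_rel^2 + j$solid_rel^2)
  j$significant <- abs(j$pct_diff) > 2 * j$pct_diff_1sigma
  j$water_rel <- NULL
  j$solid_rel <- NULL
  j
}

#' Published radial dose function reference values
#'
#' Consensus Monte Carlo radial dose function table for the new-design
#' BEBIG Co-60 HDR source in water and the four solid phantom media, on the
#' 32 radii between 0.2 and 20 cm.  Shipped as plain-text package data.
#'
#' @return tibble with columns `r`, `water`, `pmma`, `polystyrene`, `rw1`,
#'   `solid_water`.
#' @export
gl_published <- function() {
  if (is.null(the$gl_published)) {
    the$gl_published <- tibble::as_tibble(
      read.table(system.file("extdata", "gl_published.csv",
                             package = "cobrachy", mustWork = TRUE),
                 header = TRUE, sep = ",", comment.char = "#"))
  }
  the$gl_published
}

#' Transverse-axis dose profile of a finalized cell table
#'
#' Pulls the radial-set cells (z = 0) out of a cell tibble in the shape
#' [radial_dose_function()] expects.
#'
#' @param cells finalized cell tibble carrying `radial` and
#'   `kerma_rate_per_activity` columns.
#' @return tibble with `r`, `dose`, `rel_1sigma`.
#' @export
transverse_profile <- function(cells) {
  stopifnot(all(c("radial", "kerma_rate_per_activity") %in% names(cells)))
  rad <- cells[cells$radial, ]
  tibble::tibble(r = rad$y, dose = rad$kerma_rate_per_activity,
                 rel_1sigma = rad$rel_1sigma)
}

#' Full TG-43 analysis of an air run and a phantom run
#'
#' Convenience wrapper chaining the individual steps: fits S_K/A from the
#' air-sphere point detectors, forms the dose-rate constant from the
#' reference cell, the radial dose function from the transverse profile,
#' its cubic fit, and the Cartesian dose-rate table.
#'
#' @param air `mc_result` of an air-sphere run with point detectors.
#' @param phantom `mc_result` of a dose-phantom run with cell tallies.
#' @return list with `sk`, `lambda`, `g_L`, `poly`, `dose_table`.
#' @export
tg43_analysis <- function(air, phantom) {
  sk <- fit_air_kerma_strength(air$detectors)
  gsk <- glance(sk)
  ref <- phantom$cells[phantom$cells$radial & abs(phantom$cells$y - 1) < 1e-9 &
                         abs(phantom$cells$z) < 1e-9, ]
  lam <- dose_rate_constant(ref$kerma_rate_per_activity, sk$sk_per_A,
                            ref$rel_1sigma, gsk$sk_rel_1sigma)
  gl <- radial_dose_function(transverse_profile(phantom$cells))
  pol <- fit_radial_polynomial(gl)
  tab <- build_dose_rate_table(phantom$cells, sk$sk_per_A,
                               gsk$sk_rel_1sigma)
  list(sk = sk, lambda = lam, g_L = gl, poly = pol, dose_table = tab)
}
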