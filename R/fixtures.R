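#' Synthetic tally archives with known analytic structure
#'
#' Builds a finalized cell table whose kerma field follows a chosen closed
#' form, multiplied by reproducible lognormal noise, so the TG-43 analysis
#' stage can be exercised and validated without running transport.
#'
#' Field models (evaluated at cell centres, `r = sqrt(y^2 + z^2)`):
#' * `"inverse_square"`: `A / r^2`;
#' * `"line_geometry"`: `A * G_L(r, theta)` -- a geometry-only field whose
#'   radial dose function is identically 1;
#' * `"line_geometry_attenuation"`: `A * G_L(r, theta) * exp(-mu r) *
#'   (b0 + b1 r + b2 r^2 + b3 r^3)`, an attenuation-plus-buildup model with
#'   closed-form `g_L(r) = exp(-mu (r - 1)) * P(r) / P(1)`.
#'
#' @param model field model name.
#' @param amplitude overall scale (kerma rate units).
#' @param mu attenuation coefficient (cm^-1) for the attenuation model.
#' @param buildup numeric length-4 polynomial coefficients `b0..b3`.
#' @param rel_sigma relative 1-sigma of the multiplicative lognormal noise
#'   (the reported per-cell uncertainty); 0 gives the exact field.
#' @param cells cell table, default [standard_tally_cells()].
#' @param seed optional RNG seed for reproducible noise.
#' @return an `mc_result`-shaped list (cells + meta) accepted by the
#'   analysis functions and [write_tally_archive()].
#' @export
#' @examples
#' fx <- fixture_field_archive("line_geometry", rel_sigma = 0)
#' radial_dose_function(transverse_profile_of(fx))
fixture_field_archive <- function(model = c("inverse_square", "line_geometry",
                                            "line_geometry_attenuation"),
                                  amplitude = 1, mu = 0.01,
                                  buildup = c(1, 0, 0, 0), rel_sigma = 0.01,
                                  cells = standard_tally_cells(),
                                  seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  r <- sqrt(cells$y^2 + cells$z^2)
  theta <- atan2(cells$y, cells$z)
  field <- switch(model,
    inverse_square = amplitude / r^2,
    line_geometry = amplitude * line_geometry_function(r, theta),
    line_geometry_attenuation = {
      P <- buildup[1] + buildup[2] * r + buildup[3] * r^2 + buildup[4] * r^3
      amplitude * line_geometry_function(r, theta) * exp(-mu * r) * P
    })
  if (any(field <= 0)) stop("field model produced non-positive values",
                            call. = FALSE)
  noise <- if (rel_sigma > 0) {
    sdlog <- sqrt(log(1 + rel_sigma^2))
    exp(rnorm(nrow(cells), -sdlog^2 / 2, sdlog))
  } else {
    1
  }
  cells$kerma_rate_per_activity <- field * noise
  cells$kerma_per_decay <- cells$kerma_rate_per_activity /
    PER_DECAY_TO_CGY_H_BQ
  cells$fluence_per_decay <- NA_real_
  cells$fluence_rel_1sigma <- NA_real_
  cells$rel_1sigma <- rel_sigma
  structure(list(
    cells = cells,
    meta = list(synthetic = TRUE, model = model, amplitude = amplitude,
                mu = mu, buildup = buildup, rel_sigma = rel_sigma,
                seed = seed, n_histories = NA,
                package_version = as.character(utils::packageVersion("cobrachy")))),
    class = "mc_result")
}

#' @rdname fixture_field_archive
#' @param result an `mc_result` (real or synthetic).
#' @export
transverse_profile_of <- function(result) {
  transverse_profile(result$cells)
}

#' Pencil-beam slab transmission experiment
#'
#' Samples free paths for a pencil beam entering a uniform slab and counts
#' the fraction that crosses without interacting; the expectation is
#' `exp(-thickness)` when thickness is expressed in mean free paths.
#'
#' @param thickness_mfp slab thickness in mean free paths.
#' @param n number of histories.
#' @param material slab material (default water).
#' @param energy photon energy, MeV.
#' @param seed optional RNG seed.
#' @return list with `fraction`, binomial `se` and `expected`.
#' @export
slab_transmission_experiment <- function(thickness_mfp, n,
                                         material = standard_material("water"),
                                         energy = 1.25, seed = NULL) {
  stopifnot(n >= 1, thickness_mfp >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- mu_total(material, energy)
  paths <- sample_free_path(material, energy, n)
  frac <- mean(paths > thickness_mfp / mu)
  list(fraction = frac,
       se = sqrt(max(frac * (1 - frac), 1 / n) / n),
       expected = exp(-thickness_mfp))
}

#' Constructed inputs with a known dose-rate constant
#'
#' Builds an exact inverse-square air-kerma series (zero build-up slope)
#' and a transverse reference kerma value such that the dose-rate constant
#' recovered by the analysis chain equals `lambda_target` exactly.
#'
#' @param lambda_target target dose-rate constant, cGy h^-1 U^-1.
#' @param sk_per_A air-kerma strength used for the construction.
#' @return list with `air_series` (tibble `y`, `kerma_rate_per_activity`)
#'   and `reference_dose_rate` (cGy h^-1 Bq^-1).
#' @export
known_ratio_pair <- function(lambda_target, sk_per_A = 3e-7) {
  stopifnot(lambda_target > 0)
  y <- c(25, 50, 75, 100)
  list(air_series = tibble::tibble(y = y,
                                   kerma_rate_per_activity = sk_per_A / y^2),
       reference_dose_rate = lambda_target * sk_per_A)
}
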