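#' Configure a Monte Carlo run
#'
#' Assembles everything a transport run needs: the phantom, the number of
#' primary photon histories, the tally lattice, optional transverse-axis
#' point detectors and fluence-spectrum positions, and the physics switches.
#' Identical configurations with the same seed give bit-identical results.
#'
#' Physics defaults: photoelectric absorption, free-electron Klein-Nishina
#' Compton scattering and pair production (back-to-back 511 keV annihilation
#' photons) are on; coherent (Rayleigh) scattering is off, since its strongly
#' forward-peaked deflections barely perturb kerma at these energies.
#' Photons are terminated below the 10 keV transport cutoff without local
#' deposition; secondary electrons are not transported, so the scored
#' quantity is collision kerma.
#'
#' @param phantom phantom medium key (`"water"`, `"pmma"`, `"polystyrene"`,
#'   `"solid_water"`, `"rw1"`, `"air"`, `"vacuum"`) for the standard dose
#'   cylinder, or a [phantom_spec()] object.
#' @param n_histories number of primary photons (>= 1).
#' @param seed optional RNG seed; `NULL` leaves the RNG state alone.
#' @param cells ring-cell tally table from [standard_tally_cells()], or
#'   `NULL` to disable cell tallies.
#' @param detectors numeric vector of transverse-axis point-detector
#'   distances (cm), or `NULL`.
#' @param spectrum numeric vector of transverse positions (cm) at which to
#'   score energy-binned fluence spectra, or `NULL`.
#' @param coherent,pair_production physics switches.
#' @param cutoff photon transport cutoff, MeV.
#' @param score_medium medium whose mass energy-absorption coefficient
#'   converts fluence to collision kerma in the cell tallies (kerma to
#'   water everywhere by default).
#' @return a `run_config` object.
#' @export
#' @examples
#' cfg <- run_config("water", n_histories = 1000, seed = 1)
run_config <- function(phantom = "water", n_histories = 1e5, seed = NULL,
                       cells = standard_tally_cells(), detectors = NULL,
                       spectrum = NULL, coherent = FALSE,
                       pair_production = TRUE, cutoff = 0.010,
                       score_medium = c("water", "air")) {
  if (is.character(phantom)) {
    phantom <- phantom_dose(phantom)
  }
  stopifnot(inherits(phantom, "phantom_spec"))
  if (!is.numeric(n_histories) || n_histories < 1) {
    stop("n_histories must be >= 1", call. = FALSE)
  }
  structure(list(phantom = phantom, n_histories = as.integer(n_histories),
                 seed = seed, cells = cells, detectors = detectors,
                 spectrum = spectrum, coherent = coherent,
                 pair_production = pair_production, cutoff = cutoff,
                 score_medium = match.arg(score_medium)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> ", x$phantom$medium, " ", x$phantom$shape,
      " (r=", x$phantom$radius, " cm), ",
      format(x$n_histories, big.mark = ","), " histories",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  invisible(x)
}

region_materials <- function(phantom) {
  lib <- material_library()
  list(lib$cobalt, lib$air, lib$steel316l, lib$steel316l, lib[[phantom$medium]])
}

#' Run the Monte Carlo simulation
#'
#' Analog photon transport of `n_histories` primary photons from the
#' encapsulated source through the configured phantom.  Track-length
#' estimators accumulate fluence and collision kerma in the ring-cell
#' lattice; next-event estimators accumulate air kerma at the point
#' detectors; spectra are scored in energy bins at the requested positions.
#' Statistical uncertainties are history-by-history 1-sigma values.
#'
#' @param config a [run_config()].
#' @return an `mc_result` list with tibbles `cells` (per-decay fluence,
#'   collision kerma rate per unit activity in cGy h^-1 Bq^-1,
#'   `rel_1sigma`), `detectors` (air-kerma rate per unit activity) and
#'   `spectrum` (normalized fluence per energy bin), plus run metadata.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]

  mats <- region_materials(config$phantom)
  fine <- lapply(mats, material_fine_grid, coherent = config$coherent,
                 pair = config$pair_production)
  tally <- if (!is.null(config$cells)) tally_spec_for_cpp(config$cells)
  det <- if (!is.null(config$detectors)) {
    cbind(0, config$detectors, 0)
  }
  spec <- if (!is.null(config$spectrum)) {
    sc <- spectrum_cells(config$spectrum)
    list(cells = as.matrix(sc[, c("r_in", "r_out", "z_min", "z_max",
                                  "volume")]),
         edges = spectrum_bin_edges())
  }

  raw <- cpp_run(config$n_histories, geom_for_cpp(config$phantom), fine,
                 config$coherent, config$pair_production, config$cutoff,
                 tally, det, spec,
                 muen_fine_grid(config$score_medium), muen_fine_grid("air"),
                 100000L)

  out <- list(config = config)
  n <- config$n_histories

  if (!is.null(tally)) {
    fin <- finalize_scores(raw$cells$kerma_sum, raw$cells$kerma_ssq, n)
    flu <- finalize_scores(raw$cells$fluence_sum, raw$cells$fluence_ssq, n)
    cells <- config$cells
    cells$fluence_per_decay <- flu$mean
    cells$fluence_rel_1sigma <- flu$rel_1sigma
    # MeV/g per decay -> Gy/decay -> cGy h^-1 Bq^-1
    cells$kerma_per_decay <- fin$mean * MEV_PER_G_TO_GY
    cells$kerma_rate_per_activity <- cells$kerma_per_decay *
      PER_DECAY_TO_CGY_H_BQ
    cells$rel_1sigma <- fin$rel_1sigma
    out$cells <- cells
  }

  if (!is.null(det)) {
    fin <- finalize_scores(raw$detectors$kerma_sum, raw$detectors$kerma_ssq, n)
    out$detectors <- tibble::tibble(
      y = config$detectors,
      fluence_per_decay = PHOTONS_PER_DECAY *
        raw$detectors$fluence_sum / n,
      kerma_per_decay = fin$mean * MEV_PER_G_TO_GY,
      kerma_rate_per_activity = fin$mean * MEV_PER_G_TO_GY *
        PER_DECAY_TO_CGY_H_BQ,
      rel_1sigma = fin$rel_1sigma)
  }

  if (!is.null(spec)) {
    edges <- spectrum_bin_edges()
    nb <- length(edges) - 1
    long <- tidyr::expand_grid(position = config$spectrum,
                               bin = seq_len(nb)) |>
      dplyr::arrange(.data$bin, .data$position)
    long$e_lo <- edges[long$bin]
    long$e_hi <- edges[long$bin + 1]
    long$fluence <- as.vector(raw$spectrum)
    long <- dplyr::arrange(long, .data$position, .data$bin)
    out$spectrum <- normalize_spectrum(long[long$fluence >= 0, ])
  }

  out$meta <- list(
    n_histories = n, seed = config$seed,
    phantom = config$phantom$medium, shape = config$phantom$shape,
    coherent = config$coherent, pair_production = config$pair_production,
    cutoff = config$cutoff, score_medium = config$score_medium,
    n_escaped = raw$n_escaped, n_absorbed = raw$n_absorbed,
    n_cutoff = raw$n_cutoff,
    elapsed_s = proc.time()[["elapsed"]] - t0,
    package_version = as.character(utils::packageVersion("cobrachy")))
  class(out) <- "mc_result"
  out
}

#' @export
print.mc_result <- function(x, ...) {
  m <- x$meta
  cat("<mc_result> ", m$phantom, " ", m$shape, ", ",
      format(m$n_histories, big.mark = ","), " histories (",
      sprintf("%.1f", m$elapsed_s), " s)\n", sep = "")
  if (!is.null(x$cells)) {
    cat("  cells: ", nrow(x$cells), "; max rel 1-sigma ",
        sprintf("%.2f%%", 100 * max(x$cells$rel_1sigma, na.rm = TRUE)),
        "\n", sep = "")
  }
  if (!is.null(x$detectors)) {
    cat("  point detectors at y = ",
        paste(x$detectors$y, collapse = ", "), " cm\n", sep = "")
  }
  invisible(x)
}

#' Sample photon free path lengths
#'
#' Exponential free paths with mean `1 / mu_total(material, energy)`.
#'
#' @param material a [build_material()] object.
#' @param energy photon energy, MeV.
#' @param n number of draws.
#' @return numeric vector of path lengths (cm).
#' @export
sample_free_path <- function(material, energy, n) {
  rexp(n, rate = mu_total(material, energy))
}

#' Sample Compton scattering events
#'
#' Draws scattering angles from the Klein-Nishina differential cross
#' section on free stationary electrons and returns the scattered photon
#' energy `E' = E / (1 + alpha (1 - cos theta))`, `alpha = E / m_e c^2`.
#' Every `E'` lies in `[E / (1 + 2 alpha), E]`.
#'
#' @param energy incident photon energy, MeV.
#' @param n number of samples.
#' @return tibble with `energy_out` (MeV) and `cos_theta`.
#' @export
#' @examples
#' compton_scatter(1.25, 5)
compton_scatter <- function(energy, n) {
  stopifnot(energy >= E_MIN)
  m <- cpp_compton_sample(energy, as.integer(n))
  tibble::tibble(energy_out = m[, 1], cos_theta = m[, 2])
}

#' Optical depth between two points
#'
#' Line integral of the linear attenuation coefficient (enabled processes)
#' from `from` to `to` through the nested geometry, as used by the
#' next-event point-detector estimator.
#'
#' @param from,to numeric length-3 positions (cm).
#' @param energy photon energy, MeV.
#' @param phantom a [phantom_spec()].
#' @param coherent,pair_production physics switches (must match the run).
#' @return dimensionless optical depth.
#' @export
optical_depth <- function(from, to, energy, phantom = phantom_dose(),
                          coherent = FALSE, pair_production = TRUE) {
  fine <- lapply(region_materials(phantom), material_fine_grid,
                 coherent = coherent, pair = pair_production)
  cpp_optical_depth(as.double(from), as.double(to), energy,
                    geom_for_cpp(phantom), fine)
}
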