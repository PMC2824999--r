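# transverse-axis radii at which the radial dose function is reported (cm)
RADIAL_R <- c(seq(0.2, 0.9, by = 0.1), 1, 1.2, 1.4, 1.5, 1.8, 2, 2.5, 3, 3.5,
              4, 4.5, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 18, 20)

# Cartesian away/along lattice of the dose-rate tables (cm)
LATTICE_Y <- c(0, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, 15)
LATTICE_Z <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, 15)
LATTICE_Z <- sort(unique(c(-LATTICE_Z, LATTICE_Z)))

TALLY_HW <- 0.025     # ring cell half-width, cm (0.5 mm cells)
DISK_R <- 0.05        # on-axis disk cell radius, cm

#' The standard ring-cell tally lattice
#'
#' Cells are symmetric rings about the source (z) axis with a 0.5 mm x
#' 0.5 mm rectangular cross-section in the y-z plane, centred at every
#' away/along coordinate of the Cartesian dose-rate lattice plus the
#' transverse-axis radii of the radial dose function grid.  On-axis (y = 0)
#' positions use small solid disk cells of 0.5 mm radius instead, since a
#' ring of zero radius has no volume; the three on-axis positions inside
#' the capsule/cable (z = 0, +-0.25 cm) are omitted.
#'
#' @param radial_r transverse radii (cm) scored at z = 0.
#' @param lattice_y,lattice_z away and along coordinates (cm) of the
#'   Cartesian lattice.
#' @return tibble of cells: centre `y`, `z`, `kind` (ring/disk), bounds
#'   `r_in`, `r_out`, `z_min`, `z_max`, `volume` (cm^3) and logical flags
#'   `radial` (radial dose function set) and `lattice`.
#' @export
standard_tally_cells <- function(radial_r = RADIAL_R, lattice_y = LATTICE_Y,
                                 lattice_z = LATTICE_Z) {
  ring <- function(y, z, radial, lattice) {
    tibble::tibble(y = y, z = z, kind = "ring",
                   r_in = y - TALLY_HW, r_out = y + TALLY_HW,
                   z_min = z - TALLY_HW, z_max = z + TALLY_HW,
                   radial = radial, lattice = lattice)
  }
  rad <- ring(radial_r, 0, TRUE, FALSE)
  lat <- tidyr::expand_grid(y = lattice_y, z = lattice_z)
  lat_ring <- ring(lat$y[lat$y > 0], lat$z[lat$y > 0], FALSE, TRUE)
  z_disk <- setdiff(lattice_z, c(-0.25, 0, 0.25))
  disk <- tibble::tibble(y = 0, z = z_disk, kind = "disk",
                         r_in = 0, r_out = DISK_R,
                         z_min = z_disk - TALLY_HW, z_max = z_disk + TALLY_HW,
                         radial = FALSE, lattice = TRUE)
  cells <- dplyr::bind_rows(rad, lat_ring, disk)
  # transverse lattice cells coincide with radial-set cells: merge flags
  cells <- cells |>
    dplyr::group_by(.data$r_in, .data$r_out, .data$z_min, .data$z_max) |>
    dplyr::summarise(y = .data$y[1], z = .data$z[1], kind = .data$kind[1],
                     radial = any(.data$radial), lattice = any(.data$lattice),
                     .groups = "drop") |>
    dplyr::mutate(volume = pi * (.data$r_out^2 - .data$r_in^2) *
                    (.data$z_max - .data$z_min)) |>
    dplyr::arrange(.data$y, .data$z) |>
    dplyr::select("y", "z", "kind", "r_in", "r_out", "z_min", "z_max",
                  "volume", "radial", "lattice")
  cells
}

# translate a cell table into the C++ tally spec: sorted boundary arrays and
# an (r-interval x z-interval) -> cell index map
tally_spec_for_cpp <- function(cells) {
  r_edges <- sort(unique(c(0, cells$r_in, cells$r_out)))
  z_edges <- sort(unique(c(cells$z_min, cells$z_max)))
  nr <- length(r_edges) - 1L
  nz <- length(z_edges) - 1L
  cellmap <- matrix(-1L, nr, nz)
  rmid <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  zmid <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  for (i in seq_len(nrow(cells))) {
    ir <- which(rmid > cells$r_in[i] & rmid < cells$r_out[i])
    iz <- which(zmid > cells$z_min[i] & zmid < cells$z_max[i])
    cellmap[ir, iz] <- i - 1L
  }
  list(r_edges = r_edges, z_edges = z_edges, cellmap = cellmap,
       volumes = cells$volume)
}

#' Score straight track segments into a cell lattice
#'
#' Direct access to the track-length estimator used by the transport core:
#' each segment contributes its in-cell path length divided by the cell
#' volume to fluence, and additionally `E * mu_en/rho(E)` per unit fluence
#' to collision kerma.  Useful for testing the estimator against fields
#' with known structure.
#'
#' @param cells cell table from [standard_tally_cells()].
#' @param segments data frame with columns `x,y,z` (start, cm), `ux,uy,uz`
#'   (unit direction), `length` (cm), `energy` (MeV), `weight`, `history`
#'   (0-based history index).
#' @param medium kerma conversion medium, `"water"` or `"air"`.
#' @return `cells` with per-history accumulators attached: `fluence_sum`,
#'   `fluence_ssq`, `kerma_sum`, `kerma_ssq` (kerma in MeV/g per history).
#' @export
score_track_segments <- function(cells, segments, medium = "water") {
  spec <- tally_spec_for_cpp(cells)
  m <- as.matrix(as.data.frame(segments)[, c("x", "y", "z", "ux", "uy", "uz",
                                             "length", "energy", "weight",
                                             "history")])
  storage.mode(m) <- "double"
  res <- cpp_score_segments(spec, m, muen_fine_grid(medium))
  cells$fluence_sum <- res$fluence_sum
  cells$fluence_ssq <- res$fluence_ssq
  cells$kerma_sum <- res$kerma_sum
  cells$kerma_ssq <- res$kerma_ssq
  cells
}

#' Finalize per-history accumulators
#'
#' Converts history-by-history sums and sums of squares into per-decay
#' means and relative 1-sigma uncertainties of the mean.  The factor 2
#' photons per disintegration is applied here.
#'
#' @param sum,sum_sq per-cell sums over histories of the per-history score
#'   and its square.
#' @param n_histories number of simulated primary photons (>= 2).
#' @return tibble with `mean` (per decay), `rel_1sigma`.
#' @export
finalize_scores <- function(sum, sum_sq, n_histories) {
  if (n_histories < 2) stop("need at least 2 histories", call. = FALSE)
  m <- sum / n_histories
  var_mean <- pmax(sum_sq - sum^2 / n_histories, 0) /
    (n_histories * (n_histories - 1))
  rel <- ifelse(m > 0, sqrt(var_mean) / m, NA_real_)
  tibble::tibble(mean = PHOTONS_PER_DECAY * m, rel_1sigma = rel)
}

#' Energy bin edges for fluence spectra
#'
#' Contiguous 20 keV bins over the transport energy range, with dedicated
#' 2 keV bins bracketing the 1.17 and 1.33 MeV gamma lines.
#'
#' @return numeric vector of ascending bin edges (MeV).
#' @export
spectrum_bin_edges <- function() {
  base <- seq(0.01, 1.41, by = 0.02)
  edges <- sort(unique(c(base, 1.169, 1.171, 1.329, 1.331)))
  setdiff(edges, c(1.17, 1.33))
}

# ring cells used for spectrum scoring; wider than dose cells for statistics
spectrum_cells <- function(positions, half_width = 0.25) {
  r1 <- pmax(positions - half_width, 0)
  r2 <- positions + half_width
  tibble::tibble(position = positions, r_in = r1, r_out = r2,
                 z_min = -half_width, z_max = half_width,
                 volume = pi * (r2^2 - r1^2) * 2 * half_width)
}

#' Normalize a fluence spectrum
#'
#' Divides per-bin fluence by the total so bins sum to one, independently
#' for every scoring position.
#'
#' @param spectrum tibble with columns `position`, `e_lo`, `e_hi`,
#'   `fluence`.
#' @return same tibble with `fluence` replaced by the normalized spectrum.
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(all(c("position", "fluence") %in% names(spectrum)))
  out <- spectrum |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(total = base::sum(.data$fluence)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    stop("empty spectrum tally: total fluence is zero", call. = FALSE)
  }
  out$fluence <- out$fluence / out$total
  out$total <- NULL
  out
}
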