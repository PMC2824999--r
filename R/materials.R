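PROCESSES <- c("photoelectric", "incoherent", "coherent", "pair")

#' Build a material from an elemental composition
#'
#' Combines per-element mass attenuation coefficient tables by Bragg
#' additivity: `mu/rho(mix) = sum_i w_i (mu/rho)_i` for every interaction
#' process, on the common energy grid.  Mass fractions whose sum deviates
#' from 1 by at most 1e-3 are renormalized; larger deviations are an error.
#'
#' @param composition named numeric vector of mass fractions, e.g.
#'   `c(H = 0.112, O = 0.888)`.
#' @param density bulk density in g/cm^3.
#' @param name optional display name.
#' @return A `material` object: composition, density and the mixture
#'   coefficient table (cm^2/g per process).
#' @export
#' @examples
#' water <- build_material(c(H = 0.112, O = 0.888), 0.998, "water")
#' mu_total(water, 1.25)
build_material <- function(composition, density, name = NULL) {
  stopifnot(is.numeric(composition), length(composition) >= 1)
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of mass fractions", call. = FALSE)
  }
  unknown <- setdiff(names(composition), element_properties()$symbol)
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(composition < 0) || any(composition > 1)) {
    stop("mass fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    stop("density must be a single positive number", call. = FALSE)
  }
  s <- sum(composition)
  if (abs(s - 1) > 1e-3) {
    stop("mass fractions sum to ", format(s), ", more than 1e-3 from 1",
         call. = FALSE)
  }
  composition <- composition / s

  tabs <- lapply(names(composition), element_table)
  grid <- tabs[[1]]$energy_mev
  mix <- tibble::tibble(energy_mev = grid)
  for (p in PROCESSES) {
    mix[[p]] <- Reduce(`+`, Map(function(tab, w) w * tab[[p]],
                                tabs, composition))
  }
  structure(
    list(name = name %||% paste(names(composition), collapse = "-"),
         composition = composition, density = density, table = mix),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, " (", format(x$density), " g/cm^3)\n", sep = "")
  comp <- paste0(names(x$composition), "=",
                 format(x$composition, digits = 4), collapse = ", ")
  cat("  mass fractions: ", comp, "\n", sep = "")
  invisible(x)
}

#' Linear attenuation coefficient of a material
#'
#' Log-log interpolation of the mixture table.  `processes` selects which
#' interaction channels contribute; by default all four.
#'
#' @param material a [build_material()] object.
#' @param energy photon energy, MeV (vectorized), within 0.010-1.40.
#' @param processes subset of
#'   `c("photoelectric", "incoherent", "coherent", "pair")`.
#' @param per_mass if `TRUE` return the mass coefficient mu/rho (cm^2/g)
#'   instead of the linear coefficient mu (cm^-1).
#' @return numeric vector, cm^-1 (or cm^2/g).
#' @export
mu_total <- function(material, energy, processes = PROCESSES,
                     per_mass = FALSE) {
  stopifnot(inherits(material, "material"))
  processes <- match.arg(processes, PROCESSES, several.ok = TRUE)
  if (any(energy < E_MIN - 1e-12) || any(energy > E_MAX + 1e-12)) {
    stop("energy outside [0.010, 1.40] MeV", call. = FALSE)
  }
  tab <- material$table
  out <- 0
  for (p in processes) {
    out <- out + interp_xs(tab$energy_mev, tab[[p]], energy)
  }
  if (per_mass) out else out * material$density
}

#' Interaction process probabilities
#'
#' Relative probabilities of the four photon interaction processes at each
#' energy, proportional to the per-process attenuation coefficients.
#'
#' @inheritParams mu_total
#' @return tibble with columns `energy_mev`, `photoelectric`, `incoherent`,
#'   `coherent`, `pair`; each row sums to 1.
#' @export
process_probabilities <- function(material, energy) {
  stopifnot(inherits(material, "material"))
  per <- lapply(PROCESSES, function(p) mu_total(material, energy, p))
  tot <- Reduce(`+`, per)
  out <- tibble::tibble(energy_mev = energy)
  for (i in seq_along(PROCESSES)) out[[PROCESSES[i]]] <- per[[i]] / tot
  out
}

#' Effective atomic number
#'
#' Power-law mean of atomic numbers weighted by electron fractions,
#' `(sum_i f_i Z_i^p)^(1/p)`.  The default exponent 2.94 is the Mayneord
#' convention for photoelectric-dominated contrast; other published
#' conventions use different exponents, so values are comparable only within
#' one convention.
#'
#' @param material a [build_material()] object.
#' @param exponent power-law exponent p.
#' @return dimensionless effective Z.
#' @export
effective_atomic_number <- function(material, exponent = 2.94) {
  stopifnot(inherits(material, "material"))
  props <- element_properties()
  idx <- match(names(material$composition), props$symbol)
  Z <- props$Z[idx]
  f <- material$composition * Z / props$A[idx]
  f <- f / sum(f)
  sum(f * Z^exponent)^(1 / exponent)
}

#' Standard materials of the source and phantom set
#'
#' Source materials (metallic cobalt, AISI 316L stainless steel), dry air,
#' liquid water and the four water-substitute solid phantoms (Solid Water,
#' RW1, PMMA, polystyrene) with their published elemental compositions and
#' densities.
#'
#' @return named list of `material` objects (plus `NULL` for `"vacuum"`).
#' @export
material_library <- function() {
  if (is.null(the$materials)) {
    the$materials <- list(
      water = build_material(c(H = 0.112, O = 0.888), 0.998, "water"),
      solid_water = build_material(
        c(H = 0.081, C = 0.672, N = 0.024, O = 0.199, Cl = 0.001, Ca = 0.023),
        1.015, "Solid Water"),
      rw1 = build_material(
        c(H = 0.132, C = 0.794, Mg = 0.009, O = 0.038, Cl = 0.027),
        0.970, "RW1"),
      pmma = build_material(c(H = 0.081, C = 0.600, O = 0.320), 1.190, "PMMA"),
      polystyrene = build_material(c(H = 0.077, C = 0.923), 1.060,
                                   "polystyrene"),
      cobalt = build_material(c(Co = 1.0), 8.9, "cobalt"),
      steel316l = build_material(
        c(C = 0.00026, Mn = 0.014, Si = 0.0042, P = 0.00019, S = 0.00003,
          Cr = 0.168, Mo = 0.0211, Ni = 0.1101, Fe = 0.6821),
        7.8, "AISI 316L"),
      # dry-air composition; the stated 40 % humidity changes coefficients
      # at these energies by far less than the simulation tolerances
      air = build_material(
        c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827),
        1.2e-3, "air"),
      vacuum = NULL)
  }
  the$materials
}

#' @rdname material_library
#' @param name material key, one of `names(material_library())`.
#' @export
standard_material <- function(name) {
  lib <- material_library()
  if (!name %in% names(lib)) {
    stop("unknown material '", name, "'; available: ",
         paste(names(lib), collapse = ", "), call. = FALSE)
  }
  lib[[name]]
}

# fine uniform-in-log(E) grid of linear coefficients (cm^-1) handed to the
# transport core; column 5 is the total over *enabled* processes
material_fine_grid <- function(material, coherent = FALSE, pair = TRUE,
                               n = 384) {
  if (is.null(material)) return(NULL)    # vacuum
  logE0 <- log(E_MIN)
  dlog <- (log(E_MAX) - logE0) / (n - 1)
  E <- pmin(pmax(exp(logE0 + dlog * (seq_len(n) - 1)), E_MIN), E_MAX)
  tab <- material$table
  m <- vapply(PROCESSES, function(p) {
    material$density * interp_xs(tab$energy_mev, tab[[p]], E)
  }, numeric(n))
  tot <- m[, "photoelectric"] + m[, "incoherent"] +
    (if (coherent) m[, "coherent"] else 0) + (if (pair) m[, "pair"] else 0)
  out <- cbind(m, total_enabled = tot)
  attr(out, "logE0") <- logE0
  attr(out, "dlog") <- dlog
  out
}

muen_fine_grid <- function(medium, n = 384) {
  logE0 <- log(E_MIN)
  dlog <- (log(E_MAX) - logE0) / (n - 1)
  E <- pmin(pmax(exp(logE0 + dlog * (seq_len(n) - 1)), E_MIN), E_MAX)
  v <- mu_en_over_rho(medium, E)
  attr(v, "logE0") <- logE0
  attr(v, "dlog") <- dlog
  v
}
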