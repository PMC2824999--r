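REGION_NAMES <- c("core", "air_gap", "capsule", "cable", "phantom", "exterior")

#' Dimensions of the encapsulated source model
#'
#' The source is a metallic cobalt cylinder of 0.5 mm diameter and 3.5 mm
#' length, surrounded by a 0.1 mm air gap and a 0.15 mm AISI 316L steel
#' capsule with flat ends; a 2 mm steel cable of the capsule radius is
#' attached at negative z.  The origin sits at the centre of the active
#' core, z along the source axis.
#'
#' @return named list of dimensions (cm) and region materials.
#' @export
source_model <- function() {
  list(core_radius = 0.025, core_half_length = 0.175,
       gap_outer_radius = 0.035, gap_outer_half_length = 0.185,
       capsule_outer_radius = 0.050, capsule_half_length = 0.200,
       cable_z = c(-0.400, -0.200),
       active_length = 0.35,
       materials = c(core = "cobalt", air_gap = "air",
                     capsule = "steel316l", cable = "steel316l"))
}

#' Phantom specifications
#'
#' Three standard phantoms surround the source, all centred on it:
#' * `phantom_dose()`: 100 cm diameter x 100 cm height cylinder, the
#'   full-scatter dose phantom (any medium);
#' * `phantom_air_sphere()`: 5 m diameter sphere of air (or vacuum) used
#'   for air-kerma strength;
#' * `phantom_spectrum_sphere()`: 100 cm radius sphere used for fluence
#'   spectra.
#'
#' @param shape `"cylinder"` or `"sphere"`.
#' @param medium material key from [material_library()] (includes
#'   `"vacuum"`).
#' @param radius radius in cm.
#' @param half_height half-height in cm (cylinders only).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c("cylinder", "sphere"), medium = "water",
                         radius = 50, half_height = 50) {
  shape <- match.arg(shape)
  lib <- material_library()
  if (!medium %in% names(lib)) {
    stop("unknown phantom medium '", medium, "'", call. = FALSE)
  }
  structure(list(shape = shape, medium = medium, radius = radius,
                 half_height = if (shape == "cylinder") half_height else radius),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
phantom_dose <- function(medium = "water") {
  phantom_spec("cylinder", medium, radius = 50, half_height = 50)
}

#' @rdname phantom_spec
#' @export
phantom_air_sphere <- function(medium = "air") {
  phantom_spec("sphere", medium, radius = 250)
}

#' @rdname phantom_spec
#' @export
phantom_spectrum_sphere <- function(medium = "water") {
  phantom_spec("sphere", medium, radius = 100)
}

geom_for_cpp <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  list(shape = if (phantom$shape == "cylinder") 0L else 1L,
       radius = phantom$radius, half_height = phantom$half_height)
}

#' Locate points in the nested source/phantom geometry
#'
#' Every point maps to exactly one region: the active core, the air gap,
#' the steel capsule, the cable, the phantom medium, or the exterior
#' vacuum.  Points on a surface resolve to the inner region.
#'
#' @param points data frame (or matrix) with columns/cols `x`, `y`, `z` (cm).
#' @param phantom a [phantom_spec()].
#' @return the input as a tibble with a `region` factor column appended.
#' @export
#' @examples
#' locate_region(data.frame(x = 0, y = c(0, 0.03, 10), z = 0), phantom_dose())
locate_region <- function(points, phantom = phantom_dose()) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  storage.mode(pts) <- "double"
  ids <- cpp_locate(pts, geom_for_cpp(phantom))
  out <- tibble::as_tibble(as.data.frame(points))
  out$region <- factor(REGION_NAMES[ids + 1L], levels = REGION_NAMES)
  out
}

#' Ray distance to the next region boundary
#'
#' Smallest positive distance along `direction` at which the ray leaves the
#' region containing `point`, and the region entered there.
#'
#' @param point numeric length-3 position (cm).
#' @param direction numeric length-3 unit vector.
#' @param phantom a [phantom_spec()].
#' @return tibble with `distance` (cm; `Inf` when the ray escapes to
#'   infinity), `region` and `next_region`.
#' @export
boundary_distance <- function(point, direction, phantom = phantom_dose()) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    stop("direction must be a unit vector", call. = FALSE)
  }
  res <- cpp_next_boundary(as.double(point), as.double(direction),
                           geom_for_cpp(phantom))
  tibble::tibble(
    distance = res$distance,
    region = REGION_NAMES[res$region + 1L],
    next_region = if (is.na(res$next_region)) NA_character_ else
      REGION_NAMES[res$next_region + 1L])
}

#' Sample primary photons from the source
#'
#' Emission positions are uniform over the active core volume, directions
#' isotropic, and the photon energy is 1.17 or 1.33 MeV with equal
#' probability (the two gamma lines; yield 2 photons per disintegration,
#' applied as a factor of 2 when tallies are finalized).
#'
#' @param n number of photons.
#' @return tibble with columns `x,y,z` (cm), `ux,uy,uz`, `energy` (MeV),
#'   `weight`.
#' @export
sample_source_photons <- function(n) {
  stopifnot(n >= 1)
  m <- cpp_sample_source(as.integer(n))
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3],
                 ux = m[, 4], uy = m[, 5], uz = m[, 6],
                 energy = m[, 7], weight = 1)
}
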