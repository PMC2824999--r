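#' Elements known to the cross-section library
#'
#' Atomic number and standard atomic mass for every element with a shipped
#' photon interaction table.  These cover the source (cobalt, AISI 316L
#' steel), air and the five phantom media.
#'
#' @return A tibble with columns `symbol`, `Z` and `A` (g/mol).
#' @export
element_properties <- function() {
  tibble::tribble(
    ~symbol, ~Z, ~A,
    "H",   1L,  1.008,
    "C",   6L,  12.011,
    "N",   7L,  14.007,
    "O",   8L,  15.999,
    "Mg", 12L,  24.305,
    "Si", 14L,  28.086,
    "P",  15L,  30.974,
    "S",  16L,  32.06,
    "Cl", 17L,  35.457,
    "Ar", 18L,  39.948,
    "Ca", 20L,  40.078,
    "Cr", 24L,  51.996,
    "Mn", 25L,  54.938,
    "Fe", 26L,  55.845,
    "Co", 27L,  58.933,
    "Ni", 28L,  58.693,
    "Mo", 42L,  95.95
  )
}

xs_file <- function(...) {
  system.file("extdata", "xs", ..., package = "cobrachy", mustWork = TRUE)
}

#' Read a delimited cross-section table
#'
#' The package's serialization for coefficient tables: tab-separated numeric
#' columns, `#` comment headers carrying provenance.  Written values use
#' shortest round-trip formatting so a write/read cycle is bit-exact.
#'
#' @param path file to read.
#' @return tibble of the numeric columns.
#' @export
read_xs_table <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               comment.char = "#"))
}

#' @rdname read_xs_table
#' @param tab table to write.
#' @param header optional provenance comment (without the leading `#`).
#' @export
write_xs_table <- function(tab, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  body <- apply(as.data.frame(lapply(tab, function(x) {
    if (is.numeric(x)) vapply(x, function(v) format(v, digits = 17), "") else x
  })), 1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Per-element mass attenuation coefficients
#'
#' Looks up the shipped table for one element: energy grid (MeV, strictly
#' ascending, spanning 0.010-1.40 MeV) and per-process mass attenuation
#' coefficients (cm^2/g) for the photoelectric effect, incoherent (Compton)
#' scattering, coherent (Rayleigh) scattering and pair production.  Pair
#' production is identically zero below the 1.022 MeV threshold.
#'
#' @param symbol element symbol, e.g. `"O"`.
#' @return tibble with columns `energy_mev`, `photoelectric`, `incoherent`,
#'   `coherent`, `pair`.
#' @export
#' @examples
#' element_table("O")
element_table <- function(symbol) {
  props <- element_properties()
  if (!symbol %in% props$symbol) {
    stop("unknown element: ", symbol, call. = FALSE)
  }
  key <- paste0("el_", symbol)
  if (is.null(the[[key]])) {
    the[[key]] <- read_xs_table(xs_file(paste0(symbol, ".tsv")))
  }
  the[[key]]
}

#' Mass energy-absorption coefficient table for air or water
#'
#' @param medium `"air"` or `"water"`.
#' @return tibble with columns `energy_mev` and `muen_over_rho` (cm^2/g).
#' @export
muen_table <- function(medium = c("water", "air")) {
  medium <- match.arg(medium)
  key <- paste0("muen_", medium)
  if (is.null(the[[key]])) {
    the[[key]] <- read_xs_table(xs_file(paste0("muen_", medium, ".tsv")))
  }
  the[[key]]
}

# log-log interpolation on an ascending grid; zero-valued stretches fall back
# to linear so the pair-production threshold stays exact
interp_xs <- function(Eg, v, E) {
  if (any(E < Eg[1] - 1e-12) || any(E > Eg[length(Eg)] + 1e-12)) {
    stop("energy outside table range [", Eg[1], ", ", Eg[length(Eg)],
         "] MeV", call. = FALSE)
  }
  E <- pmin(pmax(E, Eg[1]), Eg[length(Eg)])
  if (all(v > 0)) {
    exp(approx(log(Eg), log(v), log(E), rule = 2)$y)
  } else {
    out <- approx(Eg, v, E, rule = 2)$y
    pos <- v > 0
    if (any(pos)) {
      ok <- E >= Eg[which(pos)[1]]
      if (any(ok)) {
        out[ok] <- exp(approx(log(Eg[pos]), log(v[pos]), log(E[ok]),
                              rule = 2)$y)
      }
    }
    pmax(out, 0)
  }
}

#' Interpolated mass energy-absorption coefficient
#'
#' Log-log interpolation of the shipped air / water tables, used to convert
#' photon fluence to collision kerma.
#'
#' @param medium `"air"` or `"water"`.
#' @param energy photon energy in MeV (vectorized), within 0.010-1.40.
#' @return mu_en/rho in cm^2/g.
#' @export
#' @examples
#' mu_en_over_rho("water", c(1.17, 1.33))
mu_en_over_rho <- function(medium = c("water", "air"), energy) {
  medium <- match.arg(medium)
  tab <- muen_table(medium)
  if (any(energy < E_MIN - 1e-9) || any(energy > E_MAX + 1e-9)) {
    stop("energy outside [0.010, 1.40] MeV", call. = FALSE)
  }
  interp_xs(tab$energy_mev, tab$muen_over_rho, pmin(energy, E_MAX))
}
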