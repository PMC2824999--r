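# delimited-text tally archive: tallies.csv / detectors.csv / spectrum.csv
# plus meta.json, all round-tripping at full double precision

write_csv_exact <- function(df, path) {
  out <- as.data.frame(lapply(df, function(x) {
    if (is.double(x)) vapply(x, function(v) format(v, digits = 17), "") else x
  }), check.names = FALSE)
  names(out) <- names(df)
  # quote headers (they may contain commas), leave values bare
  writeLines(paste0('"', names(out), '"', collapse = ","), path)
  suppressWarnings(utils::write.table(out, path, sep = ",", quote = FALSE,
                                      row.names = FALSE, col.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

read_csv_plain <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a tally archive
#'
#' An archive is a directory of delimited text files: `tallies.csv` (cell
#' table), optionally `detectors.csv` and `spectrum.csv`, and `meta.json`
#' holding the run metadata (seed, histories, physics switches, package
#' version).  Values are written with shortest round-trip formatting, so
#' reading an archive back reproduces the in-memory doubles bit-exactly.
#'
#' @param result an `mc_result` from [run_simulation()] or
#'   [fixture_field_archive()].
#' @param dir archive directory (created if missing).
#' @return `dir`, invisibly (write); an `mc_result` (read).
#' @export
write_tally_archive <- function(result, dir) {
  stopifnot(inherits(result, "mc_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$cells)) {
    write_csv_exact(result$cells, file.path(dir, "tallies.csv"))
  }
  if (!is.null(result$detectors)) {
    write_csv_exact(result$detectors, file.path(dir, "detectors.csv"))
  }
  if (!is.null(result$spectrum)) {
    write_csv_exact(result$spectrum, file.path(dir, "spectrum.csv"))
  }
  meta <- result$meta
  meta$config <- NULL
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_tally_archive
#' @export
read_tally_archive <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a tally archive (missing meta.json): ", dir, call. = FALSE)
  }
  out <- list(meta = jsonlite::read_json(meta_path, simplifyVector = TRUE))
  tp <- file.path(dir, "tallies.csv")
  if (file.exists(tp)) {
    cells <- read_csv_plain(tp)
    for (col in intersect(c("radial", "lattice"), names(cells))) {
      cells[[col]] <- as.logical(cells[[col]])
    }
    out$cells <- cells
  }
  dp <- file.path(dir, "detectors.csv")
  if (file.exists(dp)) out$detectors <- read_csv_plain(dp)
  sp <- file.path(dir, "spectrum.csv")
  if (file.exists(sp)) out$spectrum <- read_csv_plain(sp)
  class(out) <- "mc_result"
  out
}

#' Read a run configuration file
#'
#' YAML key/value configuration mapping directly onto [run_config()]
#' arguments.  Recognized keys: `phantom`, `n_histories`, `seed`,
#' `detectors`, `spectrum`, `coherent`, `pair_production`, `cutoff`,
#' `score_medium`, `tally` (`"standard"` or `"none"`), and for non-default
#' phantoms the nested `phantom_spec: {shape, medium, radius, half_height}`.
#'
#' @param path YAML file.
#' @return a [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  phantom <- if (!is.null(y$phantom_spec)) {
    do.call(phantom_spec, y$phantom_spec)
  } else {
    y$phantom %||% "water"
  }
  cells <- if (identical(y$tally, "none")) NULL else standard_tally_cells()
  run_config(
    phantom = phantom,
    n_histories = y$n_histories %||% 1e5,
    seed = y$seed,
    cells = cells,
    detectors = if (!is.null(y$detectors)) as.numeric(y$detectors),
    spectrum = if (!is.null(y$spectrum)) as.numeric(y$spectrum),
    coherent = y$coherent %||% FALSE,
    pair_production = y$pair_production %||% TRUE,
    cutoff = y$cutoff %||% 0.010,
    score_medium = y$score_medium %||% "water")
}

config_echo <- function(config) {
  list(phantom = config$phantom$medium,
       phantom_shape = config$phantom$shape,
       phantom_radius = config$phantom$radius,
       phantom_half_height = config$phantom$half_height,
       n_histories = config$n_histories,
       seed = config$seed,
       detectors = config$detectors,
       spectrum = config$spectrum,
       coherent = config$coherent,
       pair_production = config$pair_production,
       cutoff_mev = config$cutoff,
       score_medium = config$score_medium,
       cell_half_width_cm = TALLY_HW,
       on_axis_disk_radius_cm = DISK_R)
}
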