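# ggplot2 views of results; all return the plot object unevaluated

#' Plot radial dose functions
#'
#' One curve per phantom column.  Accepts either a long tibble from
#' [radial_dose_function()] (columns `r`, `g_L`) or a wide table such as
#' [gl_published()].
#'
#' @param gl radial dose function table.
#' @return a ggplot object.
#' @export
plot_radial_dose_function <- function(gl) {
  if ("g_L" %in% names(gl)) {
    gl <- tibble::tibble(r = gl$r, value = gl$g_L, phantom = "simulated")
  } else {
    gl <- tidyr::pivot_longer(gl, -"r", names_to = "phantom",
                              values_to = "value")
  }
  ggplot2::ggplot(gl, ggplot2::aes(x = .data$r, y = .data$value,
                                   colour = .data$phantom)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "radial distance r (cm)",
                  y = expression(g[L](r)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gl_fit <- function(object, ...) {
  rr <- seq(min(object$data$r), max(object$data$r), length.out = 200)
  fitted <- tibble::tibble(r = rr, g_L = predict(object, rr))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$r, y = .data$g_L)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = fitted, colour = "steelblue") +
    ggplot2::labs(x = "radial distance r (cm)", y = expression(g[L](r)),
                  subtitle = paste0("order-", object$order,
                                    " polynomial fit")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mc_result <- function(object, ...) {
  stopifnot(!is.null(object$cells))
  cells <- object$cells[object$cells$lattice, ]
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$y, y = .data$z,
                                      fill = log10(.data$kerma_rate_per_activity))) +
    ggplot2::geom_tile(width = 0.4, height = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "away distance y (cm)", y = "along distance z (cm)",
                  fill = "log10 kerma rate") +
    ggplot2::theme_minimal()
}

#' Plot normalized fluence spectra
#'
#' @param spectrum tibble from [run_simulation()] (`position`, `e_lo`,
#'   `e_hi`, `fluence`).
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  spectrum$energy <- (spectrum$e_lo + spectrum$e_hi) / 2
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$energy, y = .data$fluence,
                               colour = factor(.data$position))) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "photon energy (MeV)", y = "normalized fluence",
                  colour = "position (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a phantom comparison report
#'
#' @param report tibble from [compare_phantoms()].
#' @return a ggplot object.
#' @export
plot_comparison <- function(report) {
  xvar <- if ("r" %in% names(report)) "r" else "y"
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data[[xvar]], y = .data$pct_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$pct_diff - .data$pct_diff_1sigma,
      ymax = .data$pct_diff + .data$pct_diff_1sigma), size = 0.2) +
    ggplot2::labs(x = paste(xvar, "(cm)"),
                  y = "difference vs water (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
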