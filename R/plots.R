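# ggplot2 visualisations for the main result types.

#' @export
autoplot.csp_profile <- function(object, n_mad = 4, ...) {
  sites <- map_binding_site(object, n_mad = n_mad)
  cutoff <- attr(sites, "cutoff")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$delta)) +
    ggplot2::geom_col(width = 0.8, fill = "grey40", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$broadened),
      ggplot2::aes(y = 0), shape = 4, colour = "firebrick", na.rm = TRUE
    ) +
    ggplot2::labs(
      x = "residue", y = expression(Delta * delta ~ "(ppm)"),
      title = sprintf("CSP at 1:%.3g endpoint (x = broadened)",
                      attr(object, "endpoint_ratio"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.itc_fit <- function(object, ...) {
  protocol <- thermo_protocol(object$data)
  ratio <- itc_heats(binding_params(
    n = max(object$n, 1e-6), kd = max(object$kd, 1e-12),
    dh = object$dh %||% 0
  ), protocol)$molar_ratio
  df <- tibble(
    molar_ratio = ratio,
    observed = object$data$heat_ucal,
    fitted = object$fitted %||% NA_real_,
    first = seq_along(ratio) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     shape = .data$first), size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       colour = "firebrick", na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = "molar ratio (ligand : macromolecule)",
      y = expression("injection heat (" * mu * "cal)"),
      title = sprintf("one-site fit: Kd = %.3g M, c = %.2g (%s)",
                      object$kd, object$c_value, object$verdict)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a heteronuclear NOE classification
#'
#' @param classified output of [hetnoe_classify()]
#' @param threshold the rigidity threshold to draw
#' @return a ggplot
#' @export
plot_hetnoe <- function(classified, threshold = 0.5) {
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data$residue, y = .data$ratio_i,
                               colour = .data$class)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(rigid = "steelblue4", flexible = "goldenrod3")
    ) +
    ggplot2::labs(x = "residue", y = expression(I[sat] / I[ref]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
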