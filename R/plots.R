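#' Plot a solubility profile
#'
#' Mean solubility against the solute-free organic fraction, with
#' one-standard-deviation error bars when replicate spreads are
#' available; multiple solutes/solvents are distinguished by colour.
#'
#' @param object A [solubility_profile()] result or a measurement tibble
#'   ([read_measurements()] / [generate_measured_profiles()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot solubility_profile
#' @export
autoplot.solubility_profile <- function(object, ...) {
  plot_profile(object)
}

#' @rdname autoplot.solubility_profile
#' @export
plot_profile <- function(object, ...) {
  stopifnot(is.data.frame(object), "organic_fraction" %in% names(object))
  xcol <- intersect(c("x_mean", "x_sat"), names(object))[1]
  if (is.na(xcol)) abort("no solubility column (x_mean or x_sat) to plot")
  grp <- intersect(c("organic_solvent", "name"), names(object))[1]
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$organic_fraction,
                                            y = .data[[xcol]]))
  if (!is.na(grp)) {
    p <- p + ggplot2::aes(colour = .data[[grp]])
  }
  if ("x_sd" %in% names(object) && any(!is.na(object$x_sd))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[xcol]] - .data$x_sd,
                   ymax = .data[[xcol]] + .data$x_sd),
      width = 0.02
    )
  }
  p + ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(x[2] * "* (solute-free organic mole fraction)"),
      y = "saturation mole fraction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a screening shortlist as a greenness / solubility trade-off
#'
#' Predicted log10 solubility against environmental index for every
#' shortlisted solvent, the reference solvent's solubility as a dashed
#' line (points above it are "better than reference"), and miscible
#' predictions pinned at the top of the axis with a distinct shape.
#'
#' @param object A `screening_report` from [screen_catalog()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_report
#' @export
autoplot.screening_report <- function(object, ...) {
  sl <- object$shortlist
  if (nrow(sl) == 0) abort("empty shortlist; nothing to plot")
  finite <- sl$log10_x_sat[is.finite(sl$log10_x_sat)]
  top <- if (length(finite)) max(finite) + 0.5 else 0.5
  sl$y <- ifelse(sl$miscible, top, sl$log10_x_sat)
  p <- ggplot2::ggplot(sl, ggplot2::aes(x = .data$ei, y = .data$y,
                                        shape = .data$miscible,
                                        colour = .data$better_than_reference)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "environmental index (EI)",
                  y = expression(log[10] ~ x^sat),
                  colour = "better than reference", shape = "miscible") +
    ggplot2::theme_minimal()
  if (is.finite(object$reference$log10_x_sat)) {
    p <- p + ggplot2::geom_hline(yintercept = object$reference$log10_x_sat,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot an EI ranking table
#'
#' Bar chart of the composite environmental index per system, both
#' variants side by side, ordered by the default ranking.
#'
#' @param data A ranked tibble from [ei_ranking_table()].
#' @return A ggplot object.
#' @export
plot_ei_ranking <- function(data) {
  stopifnot(all(c("system", "ei_default", "ei_no_pcop") %in% names(data)))
  long <- tidyr::pivot_longer(data, c("ei_default", "ei_no_pcop"),
                              names_to = "variant", values_to = "ei")
  long$variant <- ifelse(long$variant == "ei_default", "default",
                         "PCOP excluded")
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$system, .data$ei),
    y = .data$ei, fill = .data$variant
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "environmental index (EI)", fill = NULL) +
    ggplot2::theme_minimal()
}
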