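# Dose-response figures.  Observed replicate survival proportions are drawn
# as points over the fitted LL.2 curve; positive concentrations go on a log
# axis and the control is annotated at the left edge.

#' Plot one fitted dose-response curve
#'
#' @param object An `ll2_fit`.
#' @param n_grid Number of curve evaluation points (default 200).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ll2_fit <- function(object, n_grid = 200, ...) {
  if (!object$converged) abort("cannot plot a non-converged fit.")
  d <- object$data
  pos <- d$concentration[d$concentration > 0]
  grid <- exp(seq(log(min(pos)) - log(10), log(max(pos)) + log(2),
                  length.out = n_grid))
  curve <- tibble::tibble(
    concentration = grid,
    survival = ll2_survival(grid, object$b, object$e))
  obs <- tibble::tibble(
    concentration = pmax(d$concentration, min(grid)),
    survival = 1 - d$n_dead / d$n_exposed,
    control = d$concentration == 0)
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$concentration, y = .data$survival)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = obs, ggplot2::aes(shape = .data$control),
                        alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$e, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                labels = c("treated", "control"),
                                name = NULL) +
    ggplot2::labs(x = "Concentration (mg/L, nominal)",
                  y = "Survival fraction",
                  title = if (!is.na(object$compound[1]))
                    sprintf("%s at %s PSU", object$compound,
                            format(object$salinity))
                  else "LL.2 fit") +
    ggplot2::theme_minimal()
}

#' Dose-response curves for a whole analysis
#'
#' One panel per compound, colour by salinity: the layout of a standard
#' multi-compound acute-toxicity figure.
#'
#' @param object An `lc_analysis` from [run_full_analysis()].
#' @param n_grid Curve evaluation points per panel (default 100).
#' @param ... Unused.
#' @return A ggplot, faceted by compound (free x scales).
#' @export
autoplot.lc_analysis <- function(object, n_grid = 100, ...) {
  ok <- purrr::keep(object$fit_objects, "converged")
  if (!length(ok)) abort("no converged fits to plot.")
  layers <- purrr::map_dfr(ok, function(f) {
    pos <- f$data$concentration[f$data$concentration > 0]
    grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = n_grid))
    tibble::tibble(compound = f$compound, salinity = factor(f$salinity),
                   concentration = grid,
                   survival = ll2_survival(grid, f$b, f$e))
  })
  obs <- purrr::map_dfr(ok, function(f) {
    d <- f$data[f$data$concentration > 0, ]
    tibble::tibble(compound = f$compound, salinity = factor(f$salinity),
                   concentration = d$concentration,
                   survival = 1 - d$n_dead / d$n_exposed)
  })
  ggplot2::ggplot(layers,
                  ggplot2::aes(x = .data$concentration, y = .data$survival,
                               colour = .data$salinity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs, alpha = 0.5, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~compound, scales = "free_x") +
    ggplot2::labs(x = "Concentration (mg/L, nominal)",
                  y = "Survival fraction", colour = "Salinity (PSU)") +
    ggplot2::theme_minimal()
}
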