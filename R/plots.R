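#' Plot a fitted A/ci curve
#'
#' Observed points, the fitted piecewise model, the inflection point
#' (dashed), and optionally the operating point at ambient CO2 (blue dot).
#'
#' @param object An `aci_fit` from [fit_aci()].
#' @param ci_op Optional operating-point ci to mark, µmol mol^-1.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aci_fit
#' @export
autoplot.aci_fit <- function(object, ci_op = NULL, ...) {
  grid <- tibble::tibble(ci = seq(0, max(object$curve$ci) * 1.05,
                                  length.out = 400))
  grid$a <- predict_a(grid$ci, object$params)
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$ci, y = .data$a_n)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$a),
                       linewidth = 0.8, colour = "grey30") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(c[i] ~ "(" * mu * mol ~ mol^-1 * ")"),
      y = expression(A[N] ~ "(" * mu * mol ~ m^-2 ~ s^-1 * ")")
    ) +
    ggplot2::theme_classic()
  if (object$params$vpmax > object$params$vmax) {
    p <- p + ggplot2::geom_vline(xintercept = inflection_ci(object$params),
                                 linetype = "dashed", colour = "grey60")
  }
  if (!is.null(ci_op)) {
    op <- tibble::tibble(ci = ci_op, a = predict_a(ci_op, object$params))
    p <- p + ggplot2::geom_point(data = op, ggplot2::aes(y = .data$a),
                                 colour = "blue", size = 3)
  }
  p
}

#' Plot mean fitted curves with SE bands by genotype
#'
#' @param fits A [fit_aci_curves()] tibble (with `genotype` and `fit`).
#' @param ci_grid Grid of ci values for the band.
#' @return A ggplot object: mean fit line per genotype with an SE ribbon.
#' @export
plot_mean_curves <- function(fits, ci_grid = seq(0, 1000, by = 5)) {
  bands <- fits |>
    dplyr::group_by(.data$genotype) |>
    dplyr::group_modify(~ mean_curve_with_se(.x$fit, ci_grid)) |>
    dplyr::ungroup()
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$ci, y = .data$a_mean,
                                      colour = .data$genotype,
                                      fill = .data$genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$a_mean - .data$a_se,
                                      ymax = .data$a_mean + .data$a_se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = expression(c[i] ~ "(" * mu * mol ~ mol^-1 * ")"),
      y = expression(A[N] ~ "(" * mu * mol ~ m^-2 ~ s^-1 * ")"),
      colour = "genotype", fill = "genotype"
    ) +
    ggplot2::theme_classic()
}

#' Plot dry-down soil water trajectories
#'
#' Per-genotype mean rSWC (or daily water use) against day, with an SE
#' ribbon across pots.
#'
#' @param swc Output of [rswc_series()].
#' @param what `"rswc"` or `"water_use"`.
#' @return A ggplot object.
#' @export
plot_drydown <- function(swc, what = c("rswc", "water_use")) {
  what <- match.arg(what)
  d <- swc |>
    dplyr::filter(!is.na(.data[[what]])) |>
    dplyr::group_by(.data$genotype, .data$day) |>
    dplyr::summarise(
      m = mean(.data[[what]]),
      se = stats::sd(.data[[what]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ylab <- if (what == "rswc") "rSWC (%)" else expression(water ~ use ~ (g ~ d^-1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$m,
                                  colour = .data$genotype)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$se,
                                        ymax = .data$m + .data$se),
                           width = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "day of water withholding", y = ylab,
                  colour = "genotype") +
    ggplot2::theme_classic()
}

#' Plot stomatal density by genotype, surface, and leaf position
#'
#' @param dens Output of [density_from_counts()].
#' @return A ggplot object: bar chart of group means with SE bars, faceted
#'   by surface.
#' @export
plot_density <- function(dens) {
  d <- dens |>
    dplyr::group_by(.data$genotype, .data$surface, .data$leaf_position) |>
    dplyr::summarise(
      m = mean(.data$density),
      se = stats::sd(.data$density) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$leaf_position), y = .data$m,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$se,
                                        ymax = .data$m + .data$se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.2) +
    ggplot2::facet_wrap(~surface) +
    ggplot2::labs(x = "leaf position",
                  y = expression(stomatal ~ density ~ (mm^-2)),
                  fill = "genotype") +
    ggplot2::theme_classic()
}
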