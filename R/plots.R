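#' Plot binding modes on the theta-psi plane
#'
#' Scatter of analysed structures over the altitudinal/azimuthal angle plane
#' with the classification regions shaded.
#'
#' @param results Tibble with `theta`, `psi` and `mode_label` columns
#'   ([analyze_structure()] or [classify_mode()] output).
#' @param thresholds Class boundaries, see [mode_thresholds()].
#' @return A ggplot object.
#' @export
plot_mode_map <- function(results, thresholds = mode_thresholds()) {
  th <- thresholds
  regions <- tibble::tibble(
    label = c("symmetrical N-bound", "l-shaped N-bound",
              "bidentate top-hat", "monodentate top-hat", "side-on"),
    xmin = c(th$symmetrical[1], th$l_shaped[1], th$bidentate[1],
             th$monodentate[1], 0),
    xmax = c(th$symmetrical[2], th$l_shaped[2], th$bidentate[2],
             th$monodentate[2], 180),
    ymin = c(th$n_bound[1], th$n_bound[1], th$top_hat[1], th$top_hat[1],
             th$side_on[1]),
    ymax = c(th$n_bound[2], th$n_bound[2], th$top_hat[2], th$top_hat[2],
             th$side_on[2])
  )
  ggplot2::ggplot(results, ggplot2::aes(x = .data$psi, y = .data$theta)) +
    ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$label),
      inherit.aes = FALSE, alpha = 0.25
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$mode_label)) +
    ggplot2::coord_cartesian(xlim = c(0, 180), ylim = c(0, 180)) +
    ggplot2::labs(
      x = "azimuthal angle ψ (deg)",
      y = "altitudinal angle θ (deg)",
      fill = "region", colour = "assigned mode"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a distance time series
#'
#' @param series Series tibble (`time`, `value`, `metric`, `chain`), or
#'   several row-bound together.
#' @param cutoff Optional horizontal reference line (e.g. an H-bond cutoff),
#'   Angstrom.
#' @return A ggplot object.
#' @export
plot_distance_series <- function(series, cutoff = NULL) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = "distance (Å)") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Plot per-group binding-preference statistics
#'
#' Mean delta E with one-standard-deviation error bars per system and
#' oxidation state; positive values favour the N-bound orientation.
#'
#' @param summary Output of [summarize_delta()].
#' @return A ggplot object.
#' @export
plot_delta_e <- function(summary) {
  ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$system, y = .data$mean,
                 fill = .data$oxidation_state)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(y = "ΔE = E(top-hat) − E(N-bound), kcal/mol",
                  x = NULL, fill = "state") +
    ggplot2::theme_minimal()
}
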