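#' Plot control vs treated growth curves
#'
#' @param curves Long kinetic data as produced by [simulate_growth_curve()]
#'   (columns `time_min`, `od`, `well_role`, `replicate`).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves) {
  assert_columns(curves, c("time_min", "od", "well_role"), "curves")
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$time_min, y = .data$od,
    colour = .data$well_role,
    group = interaction(.data$well_role, .data$replicate)
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Time [min]", y = "OD", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked host-range summary plot
#'
#' @param summary Output of [summarize_host_range()] (with a `species`
#'   column).
#' @return A ggplot object.
#' @export
plot_host_range <- function(summary) {
  assert_columns(summary, c("sensitive_pct", "intermediate_pct",
    "insensitive_pct"), "summary")
  long <- summary |>
    tidyr::pivot_longer(
      dplyr::ends_with("_pct"),
      names_to = "label", values_to = "pct"
    ) |>
    dplyr::mutate(label = sub("_pct$", "", .data$label))
  x <- if ("species" %in% names(long)) "species" else NULL
  ggplot2::ggplot(long, ggplot2::aes(
    x = if (is.null(x)) "" else .data$species,
    y = .data$pct, fill = .data$label
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of strains", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Storage-stability line plot
#'
#' @param stability Output of [stability_percent()].
#' @return A ggplot object.
#' @export
plot_stability <- function(stability) {
  assert_columns(stability, c("month", "stability_pct"), "stability")
  ggplot2::ggplot(stability, ggplot2::aes(.data$month, .data$stability_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Storage time [months]", y = "Stability [% log titer]") +
    ggplot2::theme_minimal()
}

#' @rdname design_cocktail
#' @param object A `cocktail_design` object.
#' @export
autoplot.cocktail_design <- function(object, ...) {
  ggplot2::ggplot(object$strains, ggplot2::aes(
    x = .data$strain_id, y = .data$redundancy_depth, fill = .data$resilient
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "Receptor-distinct covering phages",
      fill = "Resilient to single\nphage loss"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
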