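# Lattice and profile graphics following the conventions of the field's
# map figures: per-species colours, black mixed nodes, white empty nodes;
# pink/white/green rank heat maps; profile track with dashed quadratic.

#' Plot a territory map
#'
#' @param territory A [classify_nodes()] result.
#' @param palette Optional named vector of species colours.
#' @return A ggplot object.
#' @export
plot_territory <- function(territory, palette = NULL) {
  fill <- dplyr::if_else(territory$class %in% c("pure", "majority"),
                         territory$species,
                         dplyr::if_else(territory$class == "mixed",
                                        ".mixed", ".empty"))
  dat <- territory |> mutate(fill = fill)
  species <- sort(unique(stats::na.omit(territory$species)))
  n_sp <- length(species)
  cols <- palette %||%
    setNames(grDevices::hcl.colors(max(n_sp, 3), "Dark 3")[seq_len(n_sp)],
             species)
  cols <- c(cols, ".mixed" = "black", ".empty" = "white")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$i, y = .data$j,
                                    fill = .data$fill)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = cols, breaks = species,
                               name = "species") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "lattice i", y = "lattice j")
}

#' Plot a trained map's species territories
#'
#' @param object A [blsom()] fit.
#' @param mode Territory mode, `"majority50"` or `"pure_only"`.
#' @param ... Passed to [plot_territory()].
#' @return A ggplot object.
#' @export
autoplot.blsom <- function(object, mode = "majority50", ...) {
  plot_territory(classify_nodes(object, mode), ...)
}

#' Plot a rank-based contribution heat map
#'
#' @param heatmap A [contribution_heatmap()] result.
#' @param title Optional title (e.g. the group label).
#' @return A ggplot object.
#' @export
plot_contribution <- function(heatmap, title = NULL) {
  dat <- heatmap |>
    mutate(rank_class = factor(dplyr::coalesce(.data$rank_class, "empty"),
                               levels = c("high", "moderate", "low",
                                          "empty")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$i, y = .data$j,
                                    fill = .data$rank_class)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(high = "#f4a6c0",
                                          moderate = "white",
                                          low = "#7fbf7f",
                                          empty = "grey95"),
                               name = "rank") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "lattice i", y = "lattice j", title = title)
}

#' Plot a sliding-window profile with its quadratic trend
#'
#' @param profile A [chromosome_profile()] result (one or more record x
#'   group tracks; tracks are facetted).
#' @param fits Optional [fit_quadratic()] result; computed if missing.
#' @param peaks Optional [call_peaks()] result to mark.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, fits = NULL, peaks = NULL) {
  fits <- fits %||% fit_quadratic(profile)
  curve <- profile |>
    left_join(fits, by = c("record_id", "group")) |>
    mutate(fitted = .data$a * .data$midpoint^2 + .data$b * .data$midpoint +
             .data$c)
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$midpoint / 1e6,
                                    y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$fitted),
                       linetype = "dashed", colour = "brown") +
    ggplot2::facet_grid(group ~ record_id, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "position (Mb)", y = "composition (%)")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(data = peaks,
                                 ggplot2::aes(colour = .data$class),
                                 size = 2)
  }
  p
}
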