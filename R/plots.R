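#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_col scale_fill_gradient2
#'   scale_fill_manual scale_fill_viridis_c labs theme_minimal coord_fixed autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

vd_map_theme <- function() {
  list(coord_fixed(), theme_minimal(), labs(x = "longitude", y = "latitude"))
}

#' Plot a trend map
#'
#' Tiles colored by Theil-Sen slope, significant cells marked with a dot.
#'
#' @param object A [grid_trends()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vd_trends <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(.data$lon, .data$lat)) +
    geom_tile(aes(fill = .data$slope)) +
    geom_point(data = dplyr::filter(d, .data$significant), size = 0.4) +
    scale_fill_gradient2(low = "#8c510a", mid = "#f5f5f5", high = "#01665e") +
    labs(fill = "slope / yr") +
    vd_map_theme()
}

#' @rdname autoplot.vd_trends
#' @export
plot_trend_map <- function(object, ...) autoplot.vd_trends(object, ...)

greenness_palette <- function() {
  c(
    greening_significant = "#1a9850", greening_nonsignificant = "#a6d96a",
    browning_significant = "#8c510a", browning_nonsignificant = "#fee08b",
    masked = "grey90"
  )
}

coincidence_palette <- function() {
  c(
    browning_and_drying = "#b2182b", browning_only = "#fdae61",
    drying_only = "#74add1", neither = "#e0e0e0", masked = "grey95"
  )
}

#' Plot a greenness category map
#'
#' @param object A [classify_greenness()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vd_greenness <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$lon, .data$lat, fill = .data$category)) +
    geom_tile() +
    scale_fill_manual(values = greenness_palette(), drop = FALSE) +
    vd_map_theme()
}

#' Plot a browning/drying coincidence map
#'
#' @param object A [coincidence_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vd_coincidence <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$lon, .data$lat, fill = .data$category)) +
    geom_tile() +
    scale_fill_manual(values = coincidence_palette(), drop = FALSE) +
    vd_map_theme()
}

#' Plot a drying agreement map
#'
#' Tiles colored by how many of the four water variables agree on drying.
#'
#' @param object A [classify_drying()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vd_drying <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$lon, .data$lat, fill = .data$agreement)) +
    geom_tile() +
    scale_fill_viridis_c(option = "B", direction = -1, limits = c(0, 4)) +
    labs(fill = "drying\nagreement") +
    vd_map_theme()
}

#' Plot a dominant-driver map
#'
#' @param object An [attribute_grid()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vd_attribution <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(label = dplyr::case_when(
      .data$status != "attributed" ~ NA_character_,
      .data$tie ~ "tie",
      TRUE ~ .data$dominant
    ))
  ggplot(d, aes(.data$lon, .data$lat, fill = .data$label)) +
    geom_tile() +
    labs(fill = "dominant driver") +
    vd_map_theme()
}

#' Bar chart of browning area by drying agreement
#'
#' @param summary A [browning_drying_summary()] (or multi-model mean) table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_browning_drying_bars <- function(summary, ...) {
  ggplot(summary, aes(factor(.data$agreement), .data$area_fraction,
                      fill = factor(.data$agreement))) +
    geom_col(show.legend = FALSE) +
    labs(
      x = "water variables agreeing on drying",
      y = "fraction of study area with significant browning"
    ) +
    theme_minimal()
}
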