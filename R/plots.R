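#' Plot communicated distance across the season
#'
#' Scatter of decoded distance (km) over the season with a LOESS smooth,
#' one panel per year. The smoother is a plotting aid only; inference on
#' distances goes through [monthly_distance_test()].
#'
#' @param vectors decoded dance tibble.
#' @param span LOESS span.
#' @return a ggplot object.
#' @export
plot_distance_season <- function(vectors, span = 0.1) {
  df <- vectors %>% mutate(date = as.Date(.data$date),
                           distance_km = .data$distance_m / 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$distance_km)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", span = span, se = FALSE,
                         formula = y ~ x, colour = "firebrick") +
    ggplot2::facet_wrap(~year, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Communicated distance (km)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wd_recruitment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$period, y = .data$point_pct)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo_pct,
                                          ymax = .data$hi_pct)) +
    ggplot2::labs(x = "Bloom period", y = "Recruitment (%)",
                  title = sprintf("%s, %d", object$crop[[1]], object$year[[1]])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wd_attractiveness <- function(object, ...) {
  est <- object$estimates %>%
    filter(.data$term %in% month.abb)
  est$term <- factor(est$term, levels = month.abb[month.abb %in% est$term])
  ggplot2::ggplot(est, ggplot2::aes(x = .data$term, y = .data$odds_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~crop) +
    ggplot2::labs(x = "Month", y = "Odds ratio vs other fields (log scale)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wd_month_test <- function(object, ...) {
  g <- object$groups
  nm <- names(g)[[1]]
  g$grp <- factor(g[[nm]], levels = g[[nm]])
  ggplot2::ggplot(g, ggplot2::aes(x = .data$grp, y = .data$median_km)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter),
                       vjust = -0.4, size = 3.5) +
    ggplot2::labs(x = NULL, y = "Median distance (km)",
                  subtitle = sprintf("chi2 = %.2f, df = %d, p = %.2g",
                                     object$chi2, object$df, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Map of fields with a recruitment grid overlay
#'
#' Renders the crop fields in the hive-centered plane and, optionally, a
#' 25 m recruitment grid from [grid_bin()] shaded by percent recruitment.
#'
#' @param fmap a [field_map()].
#' @param grid optional output of [grid_bin()].
#' @param cell_m grid cell size used (for tile sizing).
#' @return a ggplot object.
#' @export
plot_field_map <- function(fmap, grid = NULL, cell_m = 25) {
  polys <- purrr::map2(fmap$fields$polygon, seq_len(nrow(fmap$fields)),
                       function(p, i) {
                         tibble(east_m = p[, 1], north_m = p[, 2],
                                field_id = fmap$fields$field_id[[i]],
                                crop = fmap$fields$crop[[i]])
                       }) %>% bind_rows()
  g <- ggplot2::ggplot()
  if (!is.null(grid)) {
    g <- g + ggplot2::geom_tile(
      data = grid,
      ggplot2::aes(x = .data$east_min + cell_m / 2,
                   y = .data$north_min + cell_m / 2,
                   alpha = .data$percent),
      fill = "black", width = cell_m, height = cell_m)
  }
  g +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(x = .data$east_m, y = .data$north_m,
                                       group = .data$field_id,
                                       fill = .data$crop),
                          colour = "grey30", linewidth = 0.2, alpha = 0.6) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 17, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "East (m)", y = "North (m)", fill = "Crop",
                  alpha = "Recruitment (%)") +
    ggplot2::theme_minimal()
}
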