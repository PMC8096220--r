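#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_segment geom_point
#'   geom_col geom_errorbar scale_fill_gradient2 labs theme_minimal
#'   facet_wrap coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot an occupancy track with its pause calls
#'
#' Occupancy counts as vertical segments (minus strand drawn downward),
#' significant pause sites highlighted.
#'
#' @param object A `pause_calls` tibble.
#' @param track The [occupancy_track()] the calls came from.
#' @param region Optional `c(start, end)` window to restrict the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pause_calls <- function(object, track, region = NULL, ...) {
  tr <- as_tibble(track)
  calls <- as_tibble(object) %>% filter(.data$significant)
  if (!is.null(region)) {
    tr <- filter(tr, .data$pos >= region[1], .data$pos < region[2])
    calls <- filter(calls, .data$pos >= region[1], .data$pos < region[2])
  }
  tr <- mutate(tr, y = if_else(.data$strand == "+", .data$count, -.data$count))
  calls <- mutate(calls, y = if_else(.data$strand == "+", .data$count, -.data$count))
  ggplot(tr, aes(x = .data$pos, xend = .data$pos, y = 0, yend = .data$y)) +
    geom_segment(linewidth = 0.3, colour = "grey40") +
    geom_point(data = calls, aes(x = .data$pos, y = .data$y),
               colour = "firebrick", size = 1.5, inherit.aes = FALSE) +
    facet_wrap(~contig, scales = "free_x") +
    labs(x = "position (0-based)", y = "3'-end reads (+ up, - down)",
         title = "occupancy and significant pause sites") +
    theme_minimal()
}

#' Heatmap of a position-wise sequence enrichment matrix
#'
#' @param object An `enrichment_logo` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_logo <- function(object, ...) {
  df <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("base", "position", "log2_enrichment")
  df$position <- factor(df$position, levels = colnames(object))
  ggplot(df, aes(x = .data$position, y = .data$base,
                 fill = .data$log2_enrichment)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "position relative to the pause base (-1)", y = NULL,
         fill = "log2 fg/bg") +
    theme_minimal()
}

#' Dot-and-whisker plot of permutation feature importances
#'
#' @param object A `pause_rf` fit.
#' @param top Show at most this many features (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pause_rf <- function(object, top = 25L, ...) {
  imp <- tidy(object) %>% head(top) %>%
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot(imp, aes(x = .data$importance_mean, y = .data$feature,
                  colour = .data$significant)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$importance_mean - .data$importance_sd,
                      xmax = .data$importance_mean + .data$importance_sd),
                  width = 0.2) +
    labs(x = "permutation importance (drop in PR-AUC)", y = NULL,
         colour = "significant") +
    theme_minimal()
}
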