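# ggplot2 displays for the main result types.

#' @method autoplot multiplex_image
#' @export
autoplot.multiplex_image <- function(object, channels = NULL, ...) {
  chs <- names(object$channels)
  # conventional display: DAPI blue, T marker green, B marker red
  pick <- function(role, fallback) {
    if (!is.null(channels) && role %in% names(channels)) channels[[role]]
    else if (fallback %in% chs) fallback else NA_character_
  }
  ch_r <- pick("r", "B220"); ch_g <- pick("g", "CD3"); ch_b <- pick("b", "DAPI")
  norm <- function(ch) {
    if (is.na(ch)) return(matrix(0, object$height_px, object$width_px))
    m <- object$channels[[ch]]
    if (max(m) > 0) m / max(m) else m
  }
  col <- grDevices::rgb(norm(ch_r), norm(ch_g), norm(ch_b))
  df <- tidyr::expand_grid(y = seq_len(object$height_px),
                           x = seq_len(object$width_px))
  df$fill <- as.vector(matrix(col, object$height_px, object$width_px))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @method autoplot els_cormat
#' @export
autoplot.els_cormat <- function(object, ...) {
  df <- tidy(object)
  df$stars <- significance_stars(df$p.adjusted)
  df$stars[df$stars == "ns"] <- ""
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$estimate), colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  name = "Spearman r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Box-and-whisker comparison of a quantified endpoint across groups
#'
#' Boxes span the 25th-75th percentiles with whiskers to the minimum and
#' maximum, matching the summary reported by [run_comparison()].
#'
#' @param glands Per-field metrics tibble (needs `group` and the endpoint).
#' @param endpoint Endpoint column name (e.g. `"focus_score"`).
#' @return A ggplot object.
#' @export
plot_endpoint <- function(glands, endpoint = "focus_score") {
  if (!endpoint %in% names(glands)) {
    abort(sprintf("unknown endpoint '%s'.", endpoint))
  }
  ggplot2::ggplot(glands,
                  ggplot2::aes(.data$group, .data[[endpoint]],
                               fill = .data$group)) +
    ggplot2::geom_boxplot(coef = Inf, alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.6,
                         show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = endpoint) +
    ggplot2::theme_classic()
}
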