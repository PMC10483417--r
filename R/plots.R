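# ggplot2 presentations of the result types. These render the same views
# survey figures conventionally use: stacked kingdom compositions, BSR
# heatmaps, residual decompositions.

#' @describeIn summarize_kingdoms Stacked-bar kingdom composition per
#'   class/family.
#' @param object A `cazy_kingdom_summary`.
#' @param ... Unused.
#' @method autoplot cazy_kingdom_summary
#' @export
autoplot.cazy_kingdom_summary <- function(object, ...) {
  by <- attr(object, "by")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::any_of(KINGDOMS),
                              names_to = "kingdom", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[by]], y = .data$n,
                                     fill = .data$kingdom)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = by, y = "distinct CAZymes", fill = "kingdom") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn bsr_matrix Heatmap of the score-ratio matrix (rows =
#'   query).
#' @param object A `bsr_matrix`.
#' @method autoplot bsr_matrix
#' @export
autoplot.bsr_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$query,
                                   fill = .data$bsr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "BSR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' @describeIn chisq_decompose Signed explained-variance bars per cell.
#' @param object A `chisq_decomposition`.
#' @method autoplot chisq_decomposition
#' @export
autoplot.chisq_decomposition <- function(object, ...) {
  df <- tidy(object)
  df$cell <- if (length(unique(df$row)) > 1) {
    paste(df$row, df$col, sep = ":")
  } else {
    df$col
  }
  df$direction <- ifelse(df$residual >= 0, "over-represented",
                         "under-represented")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$cell,
                                                      -.data$explained_pct),
                                   y = .data$explained_pct,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "explained variance (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
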