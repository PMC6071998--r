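# ggplot2 views of the main result types. All take the tidy outputs, so they
# compose with the rest of the grammar.

#' @export
autoplot.girscan_pca <- function(object, labels = NULL, ...) {
  df <- pca_scores(object, labels)
  pct <- object$percent_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = paste0("PC1 (", format(pct[1], digits = 3), "%)"),
      y = paste0("PC2 (", format(pct[2], digits = 3), "%)")) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$population),
                            alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}

#' @export
autoplot.girscan_clusters <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2,
                        show.legend = FALSE) +
    ggplot2::labs(x = "number of clusters K", y = "BIC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ehh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos_bp, y = .data$ehh)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "focal_pos"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "EHH",
                  title = paste0(attr(object, "core"), " core at ",
                                 attr(object, "focal"))) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a per-SNP statistic
#'
#' @param tbl A per-SNP tibble with `chrom`, `pos_bp` and the plotted column.
#' @param y Column to plot (tidy-eval), e.g. `fst` or `pihs`.
#' @param threshold Optional horizontal threshold line (a single value or a
#'   tibble with `chrom` and `threshold` for per-chromosome lines).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(tbl, y, threshold = NULL) {
  y <- rlang::enquo(y)
  df <- tbl %>%
    filter(!is.na(!!y)) %>%
    arrange(.data$chrom, .data$pos_bp) %>%
    mutate(idx = dplyr::row_number(),
           stripe = factor(.data$chrom %% 2L))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = !!y,
                                        colour = .data$stripe)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "SNP (genome order)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    if (is.data.frame(threshold)) {
      seg <- df %>% group_by(.data$chrom) %>%
        summarise(x0 = min(.data$idx), x1 = max(.data$idx),
                  .groups = "drop") %>%
        left_join(threshold, by = "chrom")
      p <- p + ggplot2::geom_segment(
        data = seg, inherit.aes = FALSE,
        ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$threshold,
                     yend = .data$threshold),
        linetype = "dashed", colour = "red")
    } else {
      p <- p + ggplot2::geom_hline(yintercept = threshold,
                                   linetype = "dashed", colour = "red")
    }
  }
  p
}
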