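#' Plot enrichment results
#'
#' `autoplot()` methods give quick diagnostic views: a lollipop chart of the
#' most enriched sets (`cafet_result`, `fga_result`), a volcano plot for
#' differential expression (`cafet_de`) and a ranked score chart
#' (`cafet_scores`).
#'
#' @param object A result object.
#' @param n_top Number of sets to display (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @name cafet-autoplot
NULL

plot_set_lollipop <- function(df, value_col, ylab, n_top) {
  df <- df[!is.na(df[[value_col]]), , drop = FALSE]
  df <- head(df[order(df[[value_col]]), , drop = FALSE], n_top)
  df$neglog <- -log10(pmax(df[[value_col]], .Machine$double.xmin))
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neglog, y = .data$set_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$neglog,
                                       yend = .data$set_id),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::labs(x = ylab, y = NULL, colour = "significant") +
    ggplot2::theme_minimal()
}

#' @rdname cafet-autoplot
#' @export
autoplot.cafet_result <- function(object, n_top = 20, ...) {
  plot_set_lollipop(tidy(object), "fdr", expression(-log[10] ~ FDR), n_top)
}

#' @rdname cafet-autoplot
#' @export
autoplot.fga_result <- function(object, n_top = 20, ...) {
  plot_set_lollipop(tidy(object), "fdr", expression(-log[10] ~ FDR), n_top)
}

#' @rdname cafet-autoplot
#' @export
autoplot.cafet_de <- function(object, ...) {
  df <- tidy(object)
  df$signed_log2_fold <- ifelse(df$direction == "group1", 1, -1) *
    log2(pmin(df$fold_change, 2^30))
  df$neglog_p <- -log10(pmax(df$p_value, .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_log2_fold,
                                   y = .data$neglog_p,
                                   colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = expression(log[2] ~ "fold change (Group 1 / Group 2)"),
                  y = expression(-log[10] ~ p), colour = "DE") +
    ggplot2::theme_minimal()
}

#' @rdname cafet-autoplot
#' @param grouping Optional grouping tibble to colour samples by group.
#' @export
autoplot.cafet_scores <- function(object, grouping = NULL, ...) {
  df <- strip_result(object)
  if (!is.null(grouping)) {
    grouping <- as_grouping_tbl(grouping)
    df <- dplyr::left_join(df, grouping, by = "sample_id")
    df$group <- factor(df$group)
  } else {
    df$group <- factor(1)
  }
  df$sample_id <- factor(df$sample_id, levels = df$sample_id[order(df$score)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample (ranked)", y = "signature score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
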