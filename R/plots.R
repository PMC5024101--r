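# ggplot2 displays for the main result types

#' @describeIn run_discovery `autoplot()` draws the filter cascade as a
#'   waterfall of retained counts.
#' @param object A `linc_discovery` object.
#' @export
autoplot.linc_discovery <- function(object, ...) {
  st <- object$ledger$stages %>%
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$stage,
                                   y = .data$retained_count)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$retained_count),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts retained",
                  title = "lincRNA discovery cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' @describeIn linc_features `autoplot()` draws the length distribution and
#'   the cumulative AU curve.
#' @param object A `linc_features` object.
#' @export
autoplot.linc_features <- function(object, ...) {
  ggplot2::ggplot(object$au_curve,
                  ggplot2::aes(x = .data$au_fraction,
                               y = .data$cumulative_fraction,
                               colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "AU fraction", y = "cumulative fraction of transcripts",
                  colour = NULL, title = "Cumulative AU composition") +
    ggplot2::theme_minimal()
}

#' Histogram of tissue-specificity index values
#'
#' @param tsi Result of [compute_tsi()].
#' @param threshold Specificity threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_tsi_distribution <- function(tsi, threshold = 0.9) {
  ggplot2::ggplot(tsi %>% filter(.data$defined),
                  ggplot2::aes(x = .data$tsi)) +
    ggplot2::geom_histogram(bins = 30, fill = "#31a354") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "tissue specificity index (tau)", y = "lincRNAs",
                  title = "Tissue specificity") +
    ggplot2::theme_minimal()
}

#' Heatmap of tissue-specific lincRNA expression (row z-scores)
#'
#' @param expr FPKM tibble.
#' @param calls Result of [call_tissue_specific()].
#' @return A ggplot object.
#' @export
plot_specific_heatmap <- function(expr, calls) {
  z <- zscore_rows(expr, ids = calls$transcript_id)
  long <- as_tibble(as.data.frame.table(z, responseName = "zscore",
                                        stringsAsFactors = FALSE)) %>%
    rename(transcript_id = "Var1", tissue = "Var2") %>%
    mutate(tissue = factor(.data$tissue, levels = colnames(z)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue,
                                     y = .data$transcript_id,
                                     fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score",
                  title = "Tissue-specific lincRNAs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @describeIn build_interaction_network `autoplot()` draws the bipartite
#'   interaction graph.
#' @param object An `interaction_network` object.
#' @export
autoplot.interaction_network <- function(object, ...) {
  if (!nrow(object$edges)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty interaction network"))
  }
  set.seed(1L)  # layout only
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes %>% mutate(x = lay[, 1], y = lay[, 2])
  seg <- object$edges %>%
    left_join(nodes %>% select(node, xa = "x", ya = "y"),
              by = c(linc_id = "node")) %>%
    left_join(nodes %>% select(node, xb = "x", yb = "y"),
              by = c(mirna_id = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$type,
                                     size = .data$degree)) +
    ggplot2::scale_colour_manual(values = c(lincRNA = "#31a354",
                                            miRNA = "#de2d26")) +
    ggplot2::labs(title = "lincRNA-miRNA interaction network",
                  colour = NULL, size = "degree") +
    ggplot2::theme_void()
}
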