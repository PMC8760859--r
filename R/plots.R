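#' Volcano plot of a differential expression result
#'
#' log2 fold change against -log10 FDR, coloured by call (up = red,
#' down = green, ns = grey), with the calling thresholds drawn as dashed
#' lines.
#'
#' @param de A `de_result` from [de_analysis()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de) {
  stopifnot(inherits(de, "de_result"))
  tab <- de$table
  ggplot2::ggplot(
    tab,
    ggplot2::aes(.data$log2fc, -log10(pmax(.data$fdr, 1e-300)),
      colour = .data$call
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * log2(de$params$fc_min), linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(de$params$fdr_max), linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#1e8449", ns = "grey70")
    ) +
    ggplot2::labs(
      title = de$contrast$name,
      x = "log2 fold change", y = "-log10 FDR", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object A `de_result`.
#' @param ... Unused.
#' @export
autoplot.de_result <- function(object, ...) plot_volcano(object)

#' Bar chart of lncRNA class proportions
#'
#' @param results Classification tibble from [classify_lncrna()] or a
#'   proportions tibble from [class_proportions()].
#' @return A ggplot object.
#' @export
plot_class_proportions <- function(results) {
  props <- if ("fraction" %in% names(results)) {
    results
  } else {
    class_proportions(results)
  }
  ggplot2::ggplot(
    props,
    ggplot2::aes(
      factor(.data$class, levels = lncrna_classes()),
      .data$fraction
    )
  ) +
    ggplot2::geom_col(fill = "#2e86c1") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$fraction)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "fraction of lncRNAs") +
    ggplot2::theme_minimal()
}

#' Dot plot of top enriched terms
#'
#' @param results Tibble from [enrichment_test()].
#' @param k Number of terms shown (default 20).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, k = 20) {
  top <- top_terms(results, k)
  top$label <- if ("term_name" %in% names(top) && !all(is.na(top$term_name))) {
    top$term_name
  } else {
    top$term_id
  }
  ggplot2::ggplot(
    top,
    ggplot2::aes(
      .data$n_query_in_term / .data$n_term,
      stats::reorder(.data$label, -.data$p_value),
      size = .data$n_query_in_term, colour = -log10(.data$p_value)
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = "gene ratio (query hits / term size)", y = NULL,
      size = "hits", colour = "-log10 p"
    ) +
    ggplot2::theme_minimal()
}

#' qPCR group means with SEM error bars
#'
#' @param summary Tibble from [group_compare()].
#' @return A ggplot object; significant genes (p < 0.05) are starred.
#' @export
plot_qpcr <- function(summary) {
  assert_columns(
    summary, c("gene_id", "mean_1", "sem_1", "mean_2", "sem_2", "p_value"),
    "summary"
  )
  long <- dplyr::bind_rows(
    dplyr::transmute(
      summary,
      .data$gene_id, group = .data$group1,
      mean = .data$mean_1, sem = .data$sem_1, p_value = .data$p_value
    ),
    dplyr::transmute(
      summary,
      .data$gene_id, group = .data$group2,
      mean = .data$mean_2, sem = .data$sem_2, p_value = .data$p_value
    )
  )
  stars <- dplyr::filter(summary, .data$p_value < 0.05)
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$gene_id, .data$mean, fill = .data$group)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::geom_text(
      data = stars,
      ggplot2::aes(
        .data$gene_id, pmax(.data$mean_1 + .data$sem_1, .data$mean_2 + .data$sem_2),
        label = "*"
      ),
      inherit.aes = FALSE, vjust = -0.3, size = 5
    ) +
    ggplot2::labs(
      x = NULL, y = "relative expression (2^-ddCt, mean +/- SEM)", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
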