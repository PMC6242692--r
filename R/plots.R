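#' ROC curve plot for essentiality prediction
#'
#' @param roc Output of [roc_auc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(colour = "#2c6fbb", linewidth = 0.8) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Essentiality prediction (AUC = %.3f)", roc$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Gene rank plot of coding-strand medians
#'
#' Genes ranked by median coding-strand log2 fold-change, most depleted first,
#' with unscaled MAD error bars and the essentiality threshold line.
#'
#' @param scores Gene score tibble from [score_genes()], optionally with an
#'   `essential` label column for colouring.
#' @param threshold Essentiality threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_gene_ranks <- function(scores, threshold = -2) {
  dat <- scores |>
    filter(!is.na(.data$median_coding)) |>
    arrange(.data$median_coding) |>
    mutate(rank = dplyr::row_number())
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$median_coding))
  if ("essential" %in% names(dat) && !all(is.na(dat$essential))) {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$median_coding - .data$mad_coding,
        ymax = .data$median_coding + .data$mad_coding,
        colour = .data$essential
      ),
      size = 0.15
    )
  } else {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$median_coding - .data$mad_coding,
        ymax = .data$median_coding + .data$mad_coding
      ),
      size = 0.15, colour = "#2c6fbb"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Gene rank", y = "Median log2FC (coding-strand guides)",
      colour = "Annotated essential"
    ) +
    ggplot2::theme_minimal()
}

#' Coding-strand vs template-strand scatter
#'
#' One point per gene with both strand medians; sensitive genes (strong
#' depletion from the template strand) fall along the diagonal lower-left.
#'
#' @param scores Gene score tibble from [score_genes()].
#' @return A ggplot object.
#' @export
plot_strand_scatter <- function(scores) {
  dat <- scores |>
    filter(!is.na(.data$median_coding), !is.na(.data$median_template))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$median_coding, y = .data$median_template)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#2c6fbb") +
    ggplot2::geom_hline(yintercept = -2, linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = -2, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Median log2FC, coding strand", y = "Median log2FC, template strand"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of guide statistics
#'
#' log2 fold-change against BH-adjusted p-value, with the significance
#' threshold drawn as a dashed line.
#'
#' @param stats Guide statistics tibble (from [guide_stats()]).
#' @param padj_threshold Dashed-line threshold, default 1e-3.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, padj_threshold = 1e-3) {
  dat <- stats |> mutate(mlp = -log10(pmax(.data$padj, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc, y = .data$mlp)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6, colour = "grey30") +
    ggplot2::geom_hline(
      yintercept = -log10(padj_threshold),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 adjusted p-value") +
    ggplot2::theme_minimal()
}

#' Transduction estimate vs FDR plot
#'
#' Per-gene estimate of the capsid-production effect against its FDR; hits
#' (FDR below threshold) highlighted.
#'
#' @param stats Tibble from [host_factor_screen()].
#' @param fdr_threshold Dashed-line threshold, default 0.05.
#' @return A ggplot object.
#' @export
plot_transduction <- function(stats, fdr_threshold = 0.05) {
  dat <- stats |> mutate(mlp = -log10(pmax(.data$fdr, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$mlp, colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = -log10(fdr_threshold),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "#c0392b")) +
    ggplot2::labs(x = "Gene estimate (log2FC beyond growth trend)", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
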