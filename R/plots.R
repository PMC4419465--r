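# ggplot2 visualisations of the main result types.

#' MA plot of an enrichment or differential-binding result
#'
#' @param object A `damid_enrichment` or `damid_diffbind` tibble.
#' @param padj_threshold Highlight threshold for adjusted p.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.damid_enrichment <- function(object, padj_threshold = 0.05, ...) {
  d <- filter(as_tibble(object), tested, !is.na(padj))
  d$signif <- d$padj < padj_threshold
  ggplot2::ggplot(d, ggplot2::aes(x = log2(base_mean + 0.5), y = log2fc,
                                  colour = signif)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "deeppink3"),
                                 name = sprintf("padj < %g",
                                                padj_threshold)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 mean normalized count",
                  y = "log2 fold change (fusion / control)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.damid_enrichment
#' @export
autoplot.damid_diffbind <- function(object, ...) {
  d <- filter(as_tibble(object), tested)
  d$signif <- d$significant
  groups <- attr(object, "groups")
  ggplot2::ggplot(d, ggplot2::aes(x = log2(base_mean + 0.5), y = log2fc,
                                  colour = signif)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "deeppink3"),
                                 name = "significant") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 mean normalized count",
                  y = sprintf("log2 fold change (%s / %s)",
                              groups[2], groups[1])) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise sample correlations
#'
#' @param x Result of [correlation_and_cluster()].
#' @return A ggplot object (tile heatmap in dendrogram leaf order).
#' @export
plot_correlation_heatmap <- function(x) {
  r <- x$correlation
  ord <- x$order
  d <- as_tibble(as.data.frame(as.table(r)), .name_repair = "minimal")
  names(d) <- c("sample1", "sample2", "r")
  d$sample1 <- base::factor(d$sample1, levels = ord)
  d$sample2 <- base::factor(d$sample2, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(sample1, sample2, fill = r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "honeydew", high = "darkgreen",
                                 limits = c(min(r), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' PCA plot of samples
#'
#' @param object A `damid_pca` result.
#' @param components Two component indices to display.
#' @param colour_by Column of the stored sample metadata used for colour.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.damid_pca <- function(object, components = c(1, 2),
                               colour_by = "species", ...) {
  sc <- object$scores
  d <- tibble(sample = rownames(sc),
              x = sc[, components[1]], y = sc[, components[2]])
  ve <- round(100 * object$variance_explained[components], 1)
  if (!is.null(object$sample_info) &&
      colour_by %in% names(object$sample_info)) {
    d <- left_join(d, object$sample_info, by = "sample")
    p <- ggplot2::ggplot(d, ggplot2::aes(x, y,
                                         colour = .data[[colour_by]]))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x, y))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC%d (%g%%)", components[1], ve[1]),
                  y = sprintf("PC%d (%g%%)", components[2], ve[2])) +
    ggplot2::theme_minimal()
}

#' Bar plot of conservation category percentages
#'
#' @param distribution The `distribution` tibble from
#'   [conservation_distribution()].
#' @return A ggplot object.
#' @export
plot_conservation_categories <- function(distribution) {
  d <- mutate(distribution,
              label = ifelse(category == 1, "1 species (unique)",
                             sprintf("%d species", category)))
  ggplot2::ggplot(d, ggplot2::aes(label, percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of binding intervals") +
    ggplot2::theme_minimal()
}
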