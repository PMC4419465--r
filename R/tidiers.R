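# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment result
#'
#' @param x A `damid_enrichment`.
#' @param ... Ignored.
#' @return A plain tibble with one row per tested fragment.
#' @export
tidy.damid_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  filter(out, tested)
}

#' @rdname tidy.damid_enrichment
#' @export
glance.damid_enrichment <- function(x, ...) {
  d <- as_tibble(x)
  tibble(
    n_fragments = nrow(d),
    n_tested = sum(d$tested),
    n_signif_05 = sum(d$tested & !is.na(d$padj) & d$padj < 0.05 &
                        d$log2fc > 0),
    n_signif_01 = sum(d$tested & !is.na(d$padj) & d$padj < 0.01 &
                        d$log2fc > 0),
    median_dispersion = median(attr(x, "dispersions")$alpha)
  )
}

#' Tidy a differential-binding result
#'
#' @param x A `damid_diffbind`.
#' @param ... Ignored.
#' @return A plain tibble of tested consensus intervals.
#' @export
tidy.damid_diffbind <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  filter(out, tested)
}

#' @rdname tidy.damid_diffbind
#' @export
glance.damid_diffbind <- function(x, ...) {
  d <- as_tibble(x)
  tibble(
    n_intervals = nrow(d),
    n_significant = sum(d$significant, na.rm = TRUE),
    n_quantitative = sum(d$divergence_class == "quantitative",
                         na.rm = TRUE),
    n_qualitative = sum(d$divergence_class == "qualitative", na.rm = TRUE),
    fdr_level = attr(x, "fdr_level")
  )
}

#' Tidy a sample PCA
#'
#' @param x A `damid_pca`.
#' @param ... Ignored.
#' @return Tibble of sample scores in long-by-component layout.
#' @export
tidy.damid_pca <- function(x, ...) {
  sc <- x$scores
  out <- as_tibble(sc)
  out$sample <- rownames(sc)
  pivot_longer(out, -sample, names_to = "component", values_to = "score")
}

#' @rdname tidy.damid_pca
#' @export
glance.damid_pca <- function(x, ...) {
  tibble(n_components = length(x$variance_explained),
         pc1_variance = x$variance_explained[1],
         pc2_variance = x$variance_explained[2] %||% NA_real_)
}
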