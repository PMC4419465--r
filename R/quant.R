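# Jointly normalized quantitative comparison of binding across species and
# factors: consensus intervals over all samples, affinity scores (log2 of
# jointly normalized read counts), correlation clustering, PCA, and
# differential binding with quantitative/qualitative classification.

#' Build consensus intervals across samples
#'
#' Merges the union of all interval sets (single linkage on >= 1 bp
#' overlap) and keeps merged regions supported by at least `min_occupancy`
#' input sets.
#'
#' @param interval_sets List of interval tibbles on one coordinate system.
#' @param min_occupancy Minimum number of supporting sets (default 2).
#' @return Tibble of disjoint consensus intervals with a `support` column.
#' @export
build_consensus <- function(interval_sets, min_occupancy = 2L) {
  stopifnot(length(interval_sets) >= 2)
  pooled <- bind_rows(lapply(seq_along(interval_sets), function(i) {
    x <- validate_intervals(interval_sets[[i]])
    tibble(chrom = x$chrom, start = x$start, end = x$end, set = i)
  }))
  if (nrow(pooled) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  support = integer()))
  merged <- merge_intervals(select(pooled, chrom, start, end), gap = -1L)
  support <- vapply(merged$members,
                    function(i) length(unique(pooled$set[i])), integer(1))
  out <- tibble(chrom = merged$chrom, start = merged$start,
                end = merged$end, support = support)
  filter(out, support >= min_occupancy)
}

#' Binding affinity matrix over consensus intervals
#'
#' Counts extended reads per consensus interval for every sample, estimates
#' joint median-of-ratios size factors over all samples together, and scores
#' affinity as `log2(count / size_factor + 0.5)`.
#'
#' @param consensus Consensus intervals ([build_consensus()]).
#' @param reads Long read tibble with a `sample` column, on the common
#'   reference coordinates.
#' @param sample_info Tibble of sample metadata (`sample`, plus any of
#'   `species`, `factor`, `condition`, `replicate`).
#' @param extension_length Read extension in bp.
#' @param chrom_lengths Named chromosome lengths of the reference genome.
#' @return A `affinity_matrix` object: list with `affinity` (intervals x
#'   samples matrix), `counts` (raw counts), `size_factors`, `consensus`,
#'   `sample_info`.
#' @export
build_affinity_matrix <- function(consensus, reads, sample_info,
                                  extension_length = 200L, chrom_lengths) {
  if (nrow(consensus) == 0) abort("empty consensus interval set")
  stopifnot(nrow(sample_info) >= 2)
  counts <- matrix(0, nrow(consensus), nrow(sample_info),
                   dimnames = list(NULL, sample_info$sample))
  for (s in sample_info$sample) {
    rr <- filter(reads, .data$sample == s)
    ext <- extend_reads(select(rr, -sample), extension_length, chrom_lengths)
    hits <- interval_hits(consensus, ext)
    counts[, s] <- tabulate(hits$q, nbins = nrow(consensus))
  }
  sf <- estimate_size_factors(counts)
  affinity <- log2(sweep(counts, 2, sf, "/") + 0.5)
  structure(
    list(affinity = affinity, counts = counts, size_factors = sf,
         consensus = consensus, sample_info = sample_info),
    class = "affinity_matrix"
  )
}

#' Pairwise sample correlations and average-linkage clustering
#'
#' Pearson correlation of affinity scores over intervals, followed by
#' average-linkage hierarchical clustering on `1 - r`. Zero-variance
#' columns make the correlation undefined and are an error.
#'
#' @param x An `affinity_matrix`, or a numeric matrix (intervals x samples).
#' @return A list with `correlation` (samples x samples), `hclust`, and
#'   `order` (leaf order as sample labels).
#' @export
correlation_and_cluster <- function(x) {
  m <- if (inherits(x, "affinity_matrix")) x$affinity else x
  stopifnot(ncol(m) >= 2, nrow(m) >= 2)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    abort(paste("zero-variance sample(s):",
                paste(colnames(m)[sds == 0], collapse = ", ")))
  r <- cor(m)
  hc <- hclust(as.dist(1 - r), method = "average")
  list(correlation = r, hclust = hc, order = colnames(m)[hc$order])
}

#' PCA of samples on affinity scores
#'
#' Intervals are centered; components come from the singular value
#' decomposition of the centered sample x interval matrix. The sign of each
#' component is fixed so that its largest-magnitude interval loading is
#' positive.
#'
#' @param x An `affinity_matrix` or numeric matrix (intervals x samples).
#' @return A `damid_pca` object: list with `scores` (samples x components),
#'   `loadings`, `variance_explained` (fractions summing to <= 1),
#'   `sample_info` when available.
#' @export
pca_samples <- function(x) {
  info <- if (inherits(x, "affinity_matrix")) x$sample_info else NULL
  m <- if (inherits(x, "affinity_matrix")) x$affinity else x
  stopifnot(ncol(m) >= 3)
  sm <- t(m)                                 # samples x intervals
  centered <- sm - matrix(colMeans(sm), nrow(sm), ncol(sm), byrow = TRUE)
  if (all(abs(centered) < 1e-12)) abort("constant affinity matrix")
  sv <- svd(centered)
  k <- sum(sv$d > 1e-10)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  rownames(scores) <- rownames(sm)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, loadings = loadings, variance_explained = ve,
         centered = centered, sample_info = info),
    class = "damid_pca"
  )
}

#' Differential binding between two groups over consensus intervals
#'
#' Reuses the negative-binomial Wald machinery with joint size factors.
#' Intervals significant at the BH-adjusted FDR level are classified as
#' `quantitative` when they overlap a native called binding interval in both
#' groups' species and `qualitative` when called in exactly one.
#'
#' @param affinity An `affinity_matrix` (its raw counts are used).
#' @param group Group label per sample (length = number of samples); exactly
#'   two distinct values, each with >= 2 replicates.
#' @param fdr_level BH-adjusted significance level (FDR1 = 0.01,
#'   FDR5 = 0.05).
#' @param native_calls Optional named list (by group label) of native
#'   binding-interval tibbles on the reference coordinates, used for the
#'   divergence classification.
#' @return A `damid_diffbind` tibble: consensus coordinates, `base_mean`,
#'   `log2fc` (group2 vs group1), `pvalue`, `padj`, `significant`,
#'   `preferred_group`, `divergence_class`.
#' @export
differential_binding <- function(affinity, group, fdr_level = 0.01,
                                 native_calls = NULL) {
  stopifnot(inherits(affinity, "affinity_matrix"))
  counts <- affinity$counts
  lv <- unique(group)
  if (length(lv) != 2) abort("exactly two groups required")
  if (any(table(group) < 2)) abort("each group needs >= 2 replicates")
  # group2 plays the 'fusion' role so log2fc is group2 - group1
  condition <- ifelse(group == lv[2], "fusion", "control")
  sf <- affinity$size_factors
  disp <- estimate_dispersions(counts, sf, condition)
  res <- test_enrichment(counts, sf, disp, condition)
  out <- bind_cols(
    select(affinity$consensus, chrom, start, end),
    select(as_tibble(res), base_mean, log2fc, se, stat, pvalue, padj, tested)
  )
  out$padj <- ifelse(out$tested, out$padj, NA_real_)
  out$significant <- !is.na(out$padj) & out$padj < fdr_level
  out$preferred_group <- ifelse(out$significant,
                                ifelse(out$log2fc > 0, lv[2], lv[1]),
                                NA_character_)
  out$divergence_class <- NA_character_
  if (!is.null(native_calls)) {
    in1 <- overlaps_any(out, native_calls[[lv[1]]])
    in2 <- overlaps_any(out, native_calls[[lv[2]]])
    cls <- ifelse(in1 & in2, "quantitative",
                  ifelse(xor(in1, in2), "qualitative", NA_character_))
    out$divergence_class <- ifelse(out$significant, cls, NA_character_)
  }
  structure(out, groups = lv, fdr_level = fdr_level,
            class = c("damid_diffbind", class(tibble())))
}
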