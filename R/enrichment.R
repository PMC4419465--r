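# Negative-binomial differential enrichment of fusion versus Dam-only counts
# at GATC fragments, and merging of enriched fragments into binding
# intervals. The test is a two-group NB log-linear model with log size
# factors as offsets, a method-of-moments dispersion blended 50/50 with a
# 1/mu trend, and a Wald statistic on the fusion-vs-control coefficient.

#' Median-of-ratios size factors
#'
#' The reference for each fragment is the geometric mean of its counts over
#' samples, computed over fragments with all counts positive; a sample's size
#' factor is the median over those fragments of count/reference. Factors are
#' reported unscaled (no re-centering), so scaling one sample's counts by `c`
#' multiplies its factor by exactly `c`.
#'
#' @param counts A `fragment_counts` table, or a numeric matrix
#'   (fragments x samples).
#' @return Named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    abort("no fragment has positive counts in every sample")
  logm <- log(m[all_pos, , drop = FALSE])
  logref <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - logref)))
  setNames(sf, colnames(m))
}

#' Per-fragment negative-binomial dispersions
#'
#' Normalized counts (count / size factor) are pooled within condition; the
#' method-of-moments estimate is `alpha_hat = max(0, (s2 - mu)/mu^2)` with
#' `s2` the pooled within-condition variance and `mu` the grand mean. A
#' dispersion-mean trend `a0 + a1/mu` is fitted by least squares over
#' fragments with `alpha_hat > 0`, and the final dispersion is
#' `max(1e-8, (alpha_hat + trend(mu))/2)` (trend values floored at 0).
#'
#' @param counts A `fragment_counts` table or count matrix.
#' @param size_factors Named size factors (default: estimated from `counts`).
#' @param condition Condition label per sample; taken from [sample_info()]
#'   when `counts` carries metadata.
#' @return Tibble with one row per fragment: `mean` (grand mean of
#'   normalized counts), `alpha_mom`, `alpha_trend`, `alpha`.
#' @export
estimate_dispersions <- function(counts, size_factors = NULL,
                                 condition = NULL) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  if (is.null(condition)) {
    info <- sample_info(counts)
    if (is.null(info)) abort("condition labels required")
    condition <- info$condition
  }
  tab <- table(condition)
  if (any(tab < 2)) abort("need at least 2 replicates per condition")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  norm <- sweep(m, 2, size_factors, "/")
  mu <- rowMeans(norm)
  # pooled within-condition variance
  ss <- 0
  df <- 0
  for (cond in names(tab)) {
    sub <- norm[, condition == cond, drop = FALSE]
    dev <- sub - rowMeans(sub)
    ss <- ss + rowSums(dev^2)
    df <- df + ncol(sub) - 1L
  }
  s2 <- ss / df
  alpha_mom <- pmax(0, (s2 - mu) / mu^2)
  alpha_mom[!is.finite(alpha_mom)] <- 0
  use <- alpha_mom > 0 & mu > 0
  if (sum(use) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), alpha_mom[use])
    a <- fit$coefficients
  } else {
    a <- c(mean(alpha_mom[mu > 0]), 0)
  }
  alpha_trend <- pmax(0, a[1] + a[2] / mu)
  alpha_trend[!is.finite(alpha_trend)] <- 0
  alpha <- pmax(1e-8, 0.5 * alpha_mom + 0.5 * alpha_trend)
  tibble(mean = mu, alpha_mom = alpha_mom, alpha_trend = alpha_trend,
         alpha = alpha)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Raw p-values in `[0, 1]` (NA allowed, passed through).
#' @return Adjusted p-values, monotone in rank, capped at 1.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pp <- p[ok]
  n <- length(pp)
  o <- order(pp, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * pp[o]))
  out[ok[o]] <- adj
  out
}

# Vectorized IRLS for the two-group NB log-linear model.
# y: fragments x samples matrix; x: 0/1 fusion indicator per sample;
# offset: log size factor per sample; alpha: per-fragment dispersion.
# Returns list(b0, b1, se1, converged).
nb_two_group_irls <- function(y, x, offset, alpha, max_iter = 50L,
                              tol = 1e-8) {
  nf <- nrow(y)
  ns <- ncol(y)
  off <- matrix(offset, nf, ns, byrow = TRUE)
  xm <- matrix(x, nf, ns, byrow = TRUE)
  eps <- 0.1
  mu0 <- rowMeans((y / exp(off))[, x == 0, drop = FALSE]) + eps
  mu1 <- rowMeans((y / exp(off))[, x == 1, drop = FALSE]) + eps
  b0 <- log(mu0)
  b1 <- log(mu1) - log(mu0)
  conv <- rep(FALSE, nf)
  for (it in seq_len(max_iter)) {
    eta <- b0 %o% rep(1, ns) + (b1 %o% rep(1, ns)) * xm + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    sw <- rowSums(w)
    swx <- rowSums(w * xm)
    swz <- rowSums(w * z)
    swxz <- rowSums(w * xm * z)
    det <- sw * swx - swx^2          # x is 0/1 so sum(w x^2) = sum(w x)
    det[det <= 0] <- NA_real_
    nb0 <- (swx * swz - swx * swxz) / det
    nb1 <- (sw * swxz - swx * swz) / det
    nb0[is.na(nb0)] <- b0[is.na(nb0)]
    nb1[is.na(nb1)] <- b1[is.na(nb1)]
    nb0 <- pmin(pmax(nb0, -30), 30)
    nb1 <- pmin(pmax(nb1, -30), 30)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    conv <- conv | delta < tol
    b0 <- nb0
    b1 <- nb1
    if (all(conv)) break
  }
  eta <- b0 %o% rep(1, ns) + (b1 %o% rep(1, ns)) * xm + off
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  sw <- rowSums(w)
  swx <- rowSums(w * xm)
  det <- sw * swx - swx^2
  se1 <- sqrt(ifelse(det > 0, sw / det, Inf))
  list(b0 = b0, b1 = b1, se1 = se1, converged = conv)
}

#' Test fragments for differential enrichment (fusion vs Dam-only)
#'
#' Fits, per fragment, a two-group negative-binomial log-linear model with
#' log size factors as offsets and a fixed dispersion, by iteratively
#' reweighted least squares. The reported `log2fc` is the fusion-minus-
#' control coefficient in log2 units; the two-sided Wald p-value uses the
#' standard-normal tail. Fragments with all-zero counts are untested
#' (`tested = FALSE`, excluded from the BH denominator). Non-converged fits
#' are flagged and given p = 1.
#'
#' @param counts A `fragment_counts` table (with `sample_info` metadata), or
#'   a count matrix plus explicit `condition`.
#' @param size_factors Optional named size factors.
#' @param dispersions Optional per-fragment dispersions (numeric vector or
#'   the tibble from [estimate_dispersions()]).
#' @param condition Optional condition labels when `counts` is a matrix.
#' @return A `damid_enrichment` tibble: `frag_id`, `chrom`, `start`, `end`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `pvalue`, `padj`, `tested`,
#'   `converged`, with `size_factors` and `dispersions` attributes.
#' @export
test_enrichment <- function(counts, size_factors = NULL, dispersions = NULL,
                            condition = NULL) {
  is_tbl <- !is.matrix(counts)
  m <- if (is_tbl) count_matrix(counts) else counts
  if (is.null(condition)) {
    info <- sample_info(counts)
    if (is.null(info)) abort("condition labels required")
    condition <- info$condition
  }
  if (!all(c("fusion", "control") %in% condition))
    abort("both 'fusion' and 'control' conditions must be present")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(m, size_factors, condition)
  alpha <- if (is.data.frame(dispersions)) dispersions$alpha else dispersions
  if (length(alpha) == 1) alpha <- rep(alpha, nrow(m))
  x <- as.numeric(condition == "fusion")
  offset <- log(size_factors)
  tested <- rowSums(m) > 0
  fit <- nb_two_group_irls(m[tested, , drop = FALSE], x, offset,
                           alpha[tested])
  log2fc <- rep(NA_real_, nrow(m))
  se <- rep(NA_real_, nrow(m))
  stat <- rep(NA_real_, nrow(m))
  pval <- rep(NA_real_, nrow(m))
  converged <- rep(NA, nrow(m))
  log2fc[tested] <- fit$b1 / log(2)
  se[tested] <- fit$se1 / log(2)
  stat[tested] <- fit$b1 / fit$se1
  pval[tested] <- 2 * pnorm(-abs(stat[tested]))
  converged[tested] <- fit$converged
  pval[tested & !converged] <- 1
  padj <- bh_adjust(pval)
  base <- tibble(
    base_mean = rowMeans(sweep(m, 2, size_factors, "/")),
    log2fc = log2fc, se = se, stat = stat, pvalue = pval, padj = padj,
    tested = tested, converged = converged
  )
  out <- if (is_tbl) {
    bind_cols(select(as_tibble(counts), frag_id, chrom, start, end), base)
  } else {
    bind_cols(tibble(frag_id = seq_len(nrow(m))), base)
  }
  structure(out,
            size_factors = size_factors,
            dispersions = dispersions,
            class = c("damid_enrichment", class(tibble())))
}

#' Call binding intervals from enriched fragments
#'
#' Selects fragments with `log2fc > 0` and adjusted p below the threshold,
#' then merges same-chromosome selected fragments whose gap is at most
#' `merge_gap` bp. Each binding interval spans min start to max end of its
#' member fragments and records the member fragment ids, the minimum
#' adjusted p and the maximum log2 fold change.
#'
#' @param enrichment A `damid_enrichment` result with coordinates.
#' @param padj_threshold Adjusted-p cutoff (0.05 or 0.01 in routine use).
#' @param merge_gap Maximum gap in bp between merged fragments (default 100).
#' @param species,factor Optional labels stamped on the output.
#' @return A `binding_intervals` tibble: `chrom`, `start`, `end`,
#'   `n_fragments`, `frag_ids` (list-column), `min_padj`, `max_log2fc`,
#'   `species`, `factor`, `padj_threshold`. Sorted and non-overlapping.
#' @export
call_binding_intervals <- function(enrichment, padj_threshold = 0.05,
                                   merge_gap = 100L, species = NA_character_,
                                   factor = NA_character_) {
  sel <- filter(as_tibble(enrichment), tested, !is.na(padj),
                log2fc > 0, padj < padj_threshold)
  if (nrow(sel) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_fragments = integer(), frag_ids = list(),
                  min_padj = numeric(), max_log2fc = numeric())
  } else {
    merged <- merge_intervals(select(sel, chrom, start, end), gap = merge_gap)
    out <- tibble(
      chrom = merged$chrom, start = merged$start, end = merged$end,
      n_fragments = merged$n_members,
      frag_ids = lapply(merged$members, function(i) sel$frag_id[i]),
      min_padj = vapply(merged$members, function(i) min(sel$padj[i]),
                        numeric(1)),
      max_log2fc = vapply(merged$members, function(i) max(sel$log2fc[i]),
                          numeric(1))
    )
  }
  out$species <- species
  out$factor <- factor
  out$padj_threshold <- padj_threshold
  structure(out, class = c("binding_intervals", class(tibble())))
}
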