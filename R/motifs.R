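# PWM scanning with exact score p-values and alignment-based motif
# conservation. Weight scores are log2 odds against a 0-order background
# with a small pseudocount; match p-values come from the exact distribution
# of the weight score under the background, computed by dynamic programming
# on a discretized score grid.

DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param probs 4 x w matrix of per-position base probabilities (rows A, C,
#'   G, T); every column must sum to 1 within 1e-6.
#' @param name Motif name.
#' @param background Background base distribution (strictly positive,
#'   normalized internally).
#' @param pseudocount Pseudocount fraction used when forming log odds
#'   (default 0.01, applied as `pseudocount * background`).
#' @return A `pwm` object.
#' @export
pwm <- function(probs, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) abort("PWM must have 4 rows (A, C, G, T)")
  rownames(probs) <- DNA
  if (ncol(probs) < 1) abort("PWM width must be >= 1")
  if (any(abs(colSums(probs) - 1) > 1e-6))
    abort("PWM columns must sum to 1")
  if (any(background <= 0)) abort("background must be strictly positive")
  background <- background / sum(background)
  names(background) <- DNA
  structure(list(name = name, probs = probs, background = background,
                 pseudocount = pseudocount, width = ncol(probs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d, pseudocount %g)\n",
              x$name, x$width, x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' Read PWMs from MEME-minimal or 4-column probability text
#'
#' MEME minimal format: `MOTIF <name>` headers followed by a
#' `letter-probability matrix` block with one row per position (columns
#' A, C, G, T). The plain 4-column format is one whitespace-separated
#' probability row per position, the whole file being a single motif.
#'
#' @param path File path.
#' @param background,pseudocount Passed to [pwm()].
#' @return A list of `pwm` objects (possibly of length one).
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (any(grepl("^MOTIF\\b", lines))) {
    starts <- grep("^MOTIF\\b", lines)
    ends <- c(starts[-1] - 1L, length(lines))
    out <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      block <- lines[starts[i]:ends[i]]
      name <- strsplit(block[1], "\\s+")[[1]][2]
      rows <- grep("^[0-9.eE+-]+\\s", block, value = TRUE)
      rows <- rows[grepl("^[0-9.]", rows)]
      m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
      if (is.null(m) || ncol(m) != 4)
        abort("malformed letter-probability matrix")
      out[[i]] <- pwm(t(m), name = name, background = background,
                      pseudocount = pseudocount)
    }
    out
  } else {
    m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
    if (ncol(m) != 4) abort("expected 4 probability columns")
    list(pwm(t(m), name = sub("\\.[^.]*$", "", basename(path)),
             background = background, pseudocount = pseudocount))
  }
}

#' Log2-odds weight matrix of a PWM
#'
#' `w[b, i] = log2((p[b, i] + pseudocount * bg[b]) /
#' ((1 + pseudocount) * bg[b]))`. With a uniform column, uniform background
#' and zero pseudocount all weights are 0; increasing the pseudocount
#' shrinks every weight toward 0.
#'
#' @param x A `pwm` object.
#' @param background Optional override of the stored background.
#' @param pseudocount Optional override of the stored pseudocount.
#' @return 4 x w numeric matrix of log2 odds (rows A, C, G, T).
#' @export
log_odds <- function(x, background = NULL, pseudocount = NULL) {
  stopifnot(inherits(x, "pwm"))
  bg <- background %||% x$background
  pc <- pseudocount %||% x$pseudocount
  if (any(bg <= 0)) abort("background must be strictly positive")
  bg <- bg / sum(bg)
  w <- log2((x$probs + pc * bg) / ((1 + pc) * bg))
  rownames(w) <- DNA
  w
}

#' Exact score distribution of a weight matrix under the background
#'
#' Convolves the per-position score distributions on a discretized grid
#' (granularity `grid`), giving the exact distribution of the weight score
#' of a background-generated word up to grid rounding. For widths <= 8 it
#' equals exhaustive enumeration over all `4^w` words. The p-value of a
#' score `s` is `P(score >= s)`.
#'
#' @param w Log2-odds matrix ([log_odds()]); width at most 20.
#' @param background Background base distribution.
#' @param grid Score granularity (default 1e-3).
#' @return A `pwm_score_dist` object: list with `score` (grid midpoints),
#'   `prob`, `pval` (upper-tail), `grid`.
#' @export
score_distribution <- function(w, background = rep(0.25, 4), grid = 1e-3) {
  if (ncol(w) > 20) abort("PWM width over the exact-distribution limit (20)")
  bg <- background / sum(background)
  iw <- round(w / grid)                    # integer grid scores
  # DP over positions: dist[k] = P(sum of grid scores = dist_lo + k - 1)
  dist <- 1
  dist_lo <- 0
  for (j in seq_len(ncol(w))) {
    col_lo <- min(iw[, j])
    width_col <- max(iw[, j]) - col_lo + 1
    col <- numeric(width_col)
    for (b in 1:4) {
      k <- iw[b, j] - col_lo + 1
      col[k] <- col[k] + bg[b]
    }
    new_lo <- dist_lo + col_lo
    new <- numeric(length(dist) + width_col - 1)
    for (k in which(col > 0)) {
      idx <- seq_along(dist) + (k - 1)
      new[idx] <- new[idx] + dist * col[k]
    }
    dist <- new
    dist_lo <- new_lo
  }
  score <- (dist_lo + seq_along(dist) - 1) * grid
  pval <- rev(cumsum(rev(dist)))
  structure(list(score = score, prob = dist, pval = pmin(1, pval),
                 grid = grid),
            class = "pwm_score_dist")
}

#' @rdname score_distribution
#' @param dist A `pwm_score_dist`.
#' @param s Scores to look up.
#' @return For `score_pvalue()`, the upper-tail probability
#'   `P(score >= s)` for each element of `s`.
#' @export
score_pvalue <- function(dist, s) {
  idx <- findInterval(s - dist$grid / 2, dist$score) + 1L
  idx <- pmax(1L, pmin(idx, length(dist$pval) + 1L))
  out <- numeric(length(s))
  inside <- idx <= length(dist$pval)
  out[inside] <- dist$pval[idx[inside]]
  out[!inside] <- 0
  out
}

# encode an ACGTN sequence as integers 1..4 (N -> NA)
encode_dna <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], DNA)
  v
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# raw window scores on the encoded forward sequence for weight matrix w;
# windows containing N give NA
window_scores <- function(code, w) {
  L <- length(code)
  wd <- ncol(w)
  if (L < wd) return(numeric(0))
  nwin <- L - wd + 1
  sc <- numeric(nwin)
  na <- logical(nwin)
  for (j in seq_len(wd)) {
    b <- code[j:(j + nwin - 1)]
    na <- na | is.na(b)
    v <- w[cbind(b, j)]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc[na] <- NA_real_
  sc
}

#' Scan a sequence for PWM matches
#'
#' Scores every window on both strands (the reverse strand scores the
#' reverse-complemented window against the forward matrix) and reports
#' matches satisfying both the weight-score cutoff and the match p-value
#' cutoff. Offsets are 0-based on the forward strand; windows containing N
#' are skipped.
#'
#' @param seq A character string (or `DNAString`) over `ACGTN`.
#' @param x A `pwm`, or a log2-odds matrix (then `dist` must be supplied).
#' @param score_cutoff Minimum weight score (default 4).
#' @param p_cutoff Maximum match p-value (default 1e-4).
#' @param background Optional background override for scoring.
#' @param dist Optional precomputed `pwm_score_dist` (saves recomputation
#'   when scanning many sequences).
#' @return Tibble of matches: `offset` (0-based), `strand`, `score`,
#'   `p_value`.
#' @export
scan_sequence <- function(seq, x, score_cutoff = 4, p_cutoff = 1e-4,
                          background = NULL, dist = NULL) {
  if (!is.character(seq)) seq <- as.character(seq)
  if (inherits(x, "pwm")) {
    bg <- background %||% x$background
    w <- log_odds(x, background = bg)
  } else {
    w <- x
    bg <- background %||% rep(0.25, 4)
  }
  if (is.null(dist)) dist <- score_distribution(w, bg)
  # score with the grid-discretized matrix so window scores live exactly on
  # the DP grid of the p-value distribution
  w <- round(w / dist$grid) * dist$grid
  code <- encode_dna(seq)
  wd <- ncol(w)
  if (length(code) < wd)
    return(tibble(offset = integer(), strand = character(),
                  score = numeric(), p_value = numeric()))
  # reverse-strand: score the forward window with the reverse-complement
  # matrix (complement rows, reverse columns)
  w_rc <- w[4:1, wd:1, drop = FALSE]
  rownames(w_rc) <- DNA
  fwd <- window_scores(code, w)
  rev_ <- window_scores(code, w_rc)
  hits <- bind_rows(
    tibble(offset = seq_along(fwd) - 1L, strand = "+", score = fwd),
    tibble(offset = seq_along(rev_) - 1L, strand = "-", score = rev_)
  )
  hits <- filter(hits, !is.na(score), score >= score_cutoff)
  hits$p_value <- score_pvalue(dist, hits$score)
  hits <- filter(hits, p_value < p_cutoff)
  arrange(hits, offset, strand)
}

#' Shuffle PWM columns (control motif)
#'
#' Permutes the columns uniformly at random (Fisher-Yates via
#' `sample.int`), preserving the motif's composition, GC content and
#' length exactly.
#'
#' @param x A `pwm`.
#' @param seed Optional integer seed.
#' @return A `pwm` with permuted columns, name suffixed `_shuffled`.
#' @export
shuffle_pwm_columns <- function(x, seed = NULL) {
  stopifnot(inherits(x, "pwm"))
  with_seed(seed, {
    perm <- sample.int(x$width)
    pwm(x$probs[, perm, drop = FALSE], name = paste0(x$name, "_shuffled"),
        background = x$background, pseudocount = x$pseudocount)
  })
}

#' Extract interval sequences from a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param x Interval tibble.
#' @return Character vector of sequences, one per interval row.
#' @export
interval_sequences <- function(genome, x) {
  x <- validate_intervals(x)
  vapply(seq_len(nrow(x)), function(i) {
    as.character(Biostrings::subseq(genome[[x$chrom[i]]],
                                    start = x$start[i] + 1L,
                                    end = x$end[i]))
  }, character(1))
}

#' Wilcoxon rank-sum test
#'
#' `W` is the rank sum of `x` using midranks for ties. The two-sided
#' p-value is exact (by enumeration of rank assignments) when
#' `length(x) + length(y) <= 12` and there are no ties, and otherwise uses
#' the normal approximation with tie-corrected variance and a 0.5
#' continuity correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return One-row tibble: `statistic` (rank sum of `x`), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0
  if (n <= 12 && !ties) {
    # exact null distribution of the rank sum: counts of size-nx subsets of
    # {1..n} by sum (subset-sum DP)
    counts <- rank_sum_counts(n, nx)
    total <- choose(n, nx)
    lo_p <- sum(counts[seq_len(W - min_sum(nx) + 1)]) / total
    hi_p <- sum(counts[(W - min_sum(nx) + 1):length(counts)]) / total
    p <- min(1, 2 * min(lo_p, hi_p))
    tibble(statistic = W, p_value = p, method = "exact")
  } else {
    mu <- nx * (n + 1) / 2
    tie_tab <- table(r)
    tie_corr <- sum(tie_tab^3 - tie_tab) / ((n) * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_corr)
    if (v <= 0) return(tibble(statistic = W, p_value = 1,
                              method = "normal"))
    cc <- if (continuity) 0.5 else 0
    z <- (W - mu - sign(W - mu) * cc) / sqrt(v)
    tibble(statistic = W, p_value = min(1, 2 * pnorm(-abs(z))),
           method = "normal")
  }
}

min_sum <- function(nx) nx * (nx + 1) / 2

# counts[k] = number of size-nx subsets of {1..n} with sum = min_sum + k - 1
rank_sum_counts <- function(n, nx) {
  max_s <- sum((n - nx + 1):n)
  min_s <- min_sum(nx)
  # dp[j, s] = subsets of size j with sum s (s shifted by 0)
  dp <- matrix(0, nx + 1, max_s + 1)
  dp[1, 1] <- 1
  for (v in seq_len(n)) {
    for (j in min(nx, v):1) {
      src <- dp[j, seq_len(max_s + 1 - v)]
      dp[j + 1, (v + 1):(max_s + 1)] <- dp[j + 1, (v + 1):(max_s + 1)] + src
    }
  }
  dp[nx + 1, (min_s + 1):(max_s + 1)]
}

#' Compare motif density between two interval groups
#'
#' Counts PWM matches per interval in each group and compares the counts
#' with a two-sided Wilcoxon rank-sum test.
#'
#' @param seqs1,seqs2 Character vectors of interval sequences (e.g. from
#'   [interval_sequences()]).
#' @param x A `pwm`.
#' @param score_cutoff,p_cutoff Match cutoffs as in [scan_sequence()].
#' @param background Optional shared background; defaults to the 0-order
#'   base composition of the pooled scanned sequences.
#' @return List: `counts1`, `counts2`, `mean1`, `mean2`, `test` (the
#'   [wilcoxon_rank_sum()] row).
#' @export
motif_density_compare <- function(seqs1, seqs2, x, score_cutoff = 4,
                                  p_cutoff = 1e-4, background = NULL) {
  stopifnot(length(seqs1) >= 1, length(seqs2) >= 1)
  if (is.null(background)) {
    comp <- Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(c(seqs1, seqs2)))
    tot <- colSums(comp[, DNA, drop = FALSE])
    background <- (tot + 1) / sum(tot + 1)
  }
  w <- log_odds(x, background = background)
  dist <- score_distribution(w, background)
  count_in <- function(s) {
    nrow(scan_sequence(s, w, score_cutoff, p_cutoff,
                       background = background, dist = dist))
  }
  c1 <- vapply(seqs1, count_in, integer(1), USE.NAMES = FALSE)
  c2 <- vapply(seqs2, count_in, integer(1), USE.NAMES = FALSE)
  list(counts1 = c1, counts2 = c2, mean1 = mean(c1), mean2 = mean(c2),
       test = wilcoxon_rank_sum(c1, c2))
}

#' Scan a multiple alignment for PWM matches
#'
#' Each row is scanned on its ungapped sequence; every match's start is
#' mapped to its alignment column through the row's position map. A match
#' whose motif span covers gapped columns in its own row is flagged
#' (`spans_gap`).
#'
#' @param aln A `multiple_alignment` ([read_alignment()]).
#' @param x A `pwm`.
#' @param score_cutoff,p_cutoff Match cutoffs.
#' @param background Optional background; defaults to the composition of
#'   the ungapped alignment rows.
#' @return Tibble of matches: `species`, `offset` (ungapped, 0-based),
#'   `strand`, `score`, `p_value`, `column` (1-based alignment start
#'   column), `end_column`, `spans_gap`.
#' @export
scan_alignment <- function(aln, x, score_cutoff = 4, p_cutoff = 1e-4,
                           background = NULL) {
  aln <- validate_alignment(aln)
  seqs <- vapply(aln$seq, ungap, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(seqs))) abort("empty alignment row")
  if (is.null(background)) {
    comp <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs))
    tot <- colSums(comp[, DNA, drop = FALSE])
    background <- (tot + 1) / sum(tot + 1)
  }
  w <- log_odds(x, background = background)
  dist <- score_distribution(w, background)
  wd <- ncol(w)
  out <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    hits <- scan_sequence(seqs[i], w, score_cutoff, p_cutoff,
                          background = background, dist = dist)
    if (nrow(hits) == 0) next
    pm <- alignment_position_map(aln, i)
    col_start <- pm[hits$offset + 1L]
    col_end <- pm[hits$offset + wd]
    out[[i]] <- mutate(hits, species = aln$species[i], column = col_start,
                       end_column = col_end,
                       spans_gap = (col_end - col_start + 1L) > wd)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0)
    return(tibble(species = character(), offset = integer(),
                  strand = character(), score = numeric(),
                  p_value = numeric(), column = integer(),
                  end_column = integer(), spans_gap = logical()))
  select(res, species, offset, strand, score, p_value, column, end_column,
         spans_gap)
}

#' Positional conservation of motif matches in an alignment
#'
#' Groups matches by (alignment start column, strand). A group found in
#' more than one species is positionally conserved; a group containing all
#' alignment species is fully conserved. Each record carries the
#' nucleotide conservation rate over the motif's alignment columns.
#'
#' @param matches Output of [scan_alignment()].
#' @param aln The alignment that was scanned.
#' @return Tibble of conserved-motif records: `column`, `strand`,
#'   `species_set` (list-column), `n_species`, `positionally_conserved`,
#'   `all_species`, `perfectly_conserved` (all species, rate 1),
#'   `conservation_rate`.
#' @export
positional_conservation <- function(matches, aln) {
  aln <- validate_alignment(aln)
  n_total <- nrow(aln)
  if (nrow(matches) == 0)
    return(tibble(column = integer(), strand = character(),
                  species_set = list(), n_species = integer(),
                  positionally_conserved = logical(),
                  all_species = logical(), perfectly_conserved = logical(),
                  conservation_rate = numeric()))
  grp <- matches |>
    group_by(column, strand) |>
    summarise(species_set = list(sort(unique(species))),
              end_column = first(end_column), .groups = "drop")
  grp$n_species <- lengths(grp$species_set)
  grp$positionally_conserved <- grp$n_species > 1
  grp$all_species <- grp$n_species == n_total
  grp$conservation_rate <- vapply(seq_len(nrow(grp)), function(i) {
    nucleotide_conservation_rate(aln, grp$column[i]:grp$end_column[i])
  }, numeric(1))
  grp$perfectly_conserved <- grp$all_species & grp$conservation_rate == 1
  select(grp, column, strand, species_set, n_species,
         positionally_conserved, all_species, perfectly_conserved,
         conservation_rate)
}

#' Nucleotide conservation rate over alignment columns
#'
#' The fraction of columns in the range where every species has the
#' identical base with no gaps. A gap in any species makes a column
#' non-conserved.
#'
#' @param aln A `multiple_alignment`.
#' @param columns 1-based column indices (default: all columns).
#' @return Fraction in `[0, 1]`.
#' @export
nucleotide_conservation_rate <- function(aln, columns = NULL) {
  aln <- validate_alignment(aln)
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  columns <- columns %||% seq_len(ncol(mat))
  if (!length(columns)) abort("empty column range")
  if (any(columns < 1 | columns > ncol(mat)))
    abort("column range outside alignment")
  sub <- mat[, columns, drop = FALSE]
  cons <- apply(sub, 2, function(col) {
    !any(col == "-") && length(unique(col)) == 1
  })
  mean(cons)
}
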