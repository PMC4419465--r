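#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join inner_join anti_join distinct n row_number across
#'   rename pull if_else lag lead slice count first last bind_cols
#' @importFrom tidyr unnest pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap list_rbind
#' @importFrom stats pnorm pchisq rnbinom rpois runif rbinom median sd var cor
#'   hclust as.dist prcomp complete.cases setNames binom.test dnbinom optimize
#'   quantile rgeom rmultinom
#' @importFrom utils head tail combn
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Run configuration defaults
#'
#' Collects every numeric setting of the comparative DamID workflow in one
#' list: read-extension length, interval merge gap, enrichment significance
#' thresholds, differential-binding FDR levels, per-species-pair minimum match
#' fractions for interval translation, PWM match cutoffs, the promoter window
#' used for feature annotation, and the random seed propagated to all
#' stochastic operations.
#'
#' @param extension_length Read extension length in bp (average DamID fragment
#'   length); default 200.
#' @param merge_gap Maximum gap in bp between enriched GATC fragments merged
#'   into one binding interval; default 100.
#' @param padj_thresholds Adjusted-p thresholds for enrichment calling.
#' @param fdr_levels Named FDR levels for differential binding
#'   (FDR1 = 0.01, FDR5 = 0.05).
#' @param min_match Default minimum mapped fraction for interval translation.
#' @param min_match_distant Minimum mapped fraction used for a distant species
#'   pair.
#' @param pwm_score_cutoff Minimum PWM weight score (log2 odds) for a reported
#'   motif match.
#' @param pwm_p_cutoff Maximum match p-value for a reported motif match.
#' @param promoter_window Two non-negative integers: bp upstream and downstream
#'   of the TSS (in transcription orientation) forming the promoter window.
#' @param seed Integer random seed recorded in output headers.
#'
#' @return A named list of settings with class `damid_config`.
#' @export
damid_config <- function(extension_length = 200L,
                         merge_gap = 100L,
                         padj_thresholds = c(0.05, 0.01),
                         fdr_levels = c(FDR1 = 0.01, FDR5 = 0.05),
                         min_match = 0.7,
                         min_match_distant = 0.5,
                         pwm_score_cutoff = 4,
                         pwm_p_cutoff = 1e-4,
                         promoter_window = c(2000L, 500L),
                         seed = 1L) {
  stopifnot(
    extension_length > 0, merge_gap >= 0,
    all(padj_thresholds > 0 & padj_thresholds < 1),
    all(fdr_levels > 0 & fdr_levels < 1),
    min_match > 0, min_match <= 1,
    min_match_distant > 0, min_match_distant <= 1,
    pwm_p_cutoff > 0, pwm_p_cutoff <= 1,
    length(promoter_window) == 2, all(promoter_window >= 0)
  )
  structure(
    list(
      extension_length = as.integer(extension_length),
      merge_gap = as.integer(merge_gap),
      padj_thresholds = padj_thresholds,
      fdr_levels = fdr_levels,
      min_match = min_match,
      min_match_distant = min_match_distant,
      pwm_score_cutoff = pwm_score_cutoff,
      pwm_p_cutoff = pwm_p_cutoff,
      promoter_window = as.integer(promoter_window),
      seed = as.integer(seed)
    ),
    class = "damid_config"
  )
}

#' Read / write a flat key-value run configuration
#'
#' The configuration file is a flat YAML document whose keys mirror
#' [damid_config()].
#'
#' @param path File path.
#' @param config A `damid_config` list.
#' @return `read_config()` returns a `damid_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(damid_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Provenance header lines written at the top of output files.
provenance_header <- function(seed = NULL, params = NULL) {
  ver <- as.character(utils::packageVersion("damidcompare"))
  lines <- sprintf("# damidcompare %s", ver)
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %s", seed))
  if (!is.null(params) && length(params)) {
    kv <- paste(names(params), unlist(params), sep = "=", collapse = " ")
    lines <- c(lines, sprintf("# params: %s", kv))
  }
  lines
}

# ---- interval tibbles -------------------------------------------------------

#' Construct an interval tibble
#'
#' Genomic intervals are plain tibbles with columns `chrom`, `start`, `end`
#' (0-based half-open) and optionally `strand`, `name`, `score`. All package
#' functions that consume intervals accept any tibble with at least the three
#' coordinate columns.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param strand Optional strand (`"+"`, `"-"`, `"*"`).
#' @param name,score Optional label / score columns.
#' @return A tibble of validated intervals.
#' @export
intervals <- function(chrom, start, end, strand = NULL, name = NULL,
                      score = NULL) {
  x <- tibble(chrom = as.character(chrom),
              start = as.integer(start), end = as.integer(end))
  if (!is.null(strand)) x$strand <- as.character(strand)
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(score)) x$score <- as.numeric(score)
  validate_intervals(x)
}

#' @rdname intervals
#' @param x A tibble with `chrom`, `start`, `end` columns.
#' @export
validate_intervals <- function(x) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(paste0("interval table lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    abort("interval chrom names must be non-empty")
  if (any(x$start < 0)) abort("negative interval start coordinate")
  if (any(x$start >= x$end)) abort("interval start must be < end")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    abort("strand must be one of '+', '-', '*'")
  x
}

# IRanges view of an interval tibble (1-based closed, as IRanges expects).
as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# Overlap hits between two interval tibbles, honouring chromosomes.
# Returns a tibble (q, s, overlap_bp).
interval_hits <- function(query, subject, min_overlap = 1L) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(tibble(q = integer(), s = integer(), overlap_bp = integer()))
  common <- intersect(unique(query$chrom), unique(subject$chrom))
  out <- vector("list", length(common))
  for (i in seq_along(common)) {
    cc <- common[i]
    qi <- which(query$chrom == cc)
    si <- which(subject$chrom == cc)
    hits <- IRanges::findOverlaps(as_iranges(query[qi, ]),
                                  as_iranges(subject[si, ]),
                                  minoverlap = as.integer(min_overlap))
    qh <- qi[S4Vectors::queryHits(hits)]
    sh <- si[S4Vectors::subjectHits(hits)]
    ov <- pmin(query$end[qh], subject$end[sh]) -
      pmax(query$start[qh], subject$start[sh])
    out[[i]] <- tibble(q = qh, s = sh, overlap_bp = as.integer(ov))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0)
    return(tibble(q = integer(), s = integer(), overlap_bp = integer()))
  res
}

#' Test each query interval for overlap with any subject interval
#'
#' Half-open overlap semantics: intervals `[10,20)` and `[20,30)` do not
#' overlap. Implemented by a sorted sweep (via interval trees); agrees with a
#' brute-force double loop.
#'
#' @param query,subject Interval tibbles (`chrom`, `start`, `end`).
#' @param min_overlap Minimum shared bases (default 1).
#' @return A logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1L) {
  query <- validate_intervals(query)
  subject <- validate_intervals(subject)
  hits <- interval_hits(query, subject, min_overlap)
  seq_len(nrow(query)) %in% hits$q
}

#' Merge intervals within a gap (single linkage)
#'
#' Same-chromosome intervals whose gap (end of one to start of the next) is at
#' most `gap` bp are merged into one spanning interval. With `gap = 0`,
#' touching intervals merge but disjoint ones do not. Merging is idempotent
#' and independent of input order.
#'
#' @param x Interval tibble.
#' @param gap Maximum separation in bp.
#' @return A sorted tibble of disjoint intervals with a `n_members` column and
#'   a `members` list-column of input row indices.
#' @export
merge_intervals <- function(x, gap = 0L) {
  x <- validate_intervals(x)
  if (nrow(x) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_members = integer(), members = list()))
  ord <- order(x$chrom, x$start, x$end)
  xs <- x[ord, ]
  new_run <- xs$chrom != lag(xs$chrom, default = "") |
    xs$start > cummax_by_chrom(xs) + gap
  run <- cumsum(new_run)
  idx <- unname(split(seq_len(nrow(xs)), run))
  tibble(
    chrom = vapply(idx, function(i) xs$chrom[i[1L]], character(1)),
    start = vapply(idx, function(i) min(xs$start[i]), integer(1)),
    end = vapply(idx, function(i) max(xs$end[i]), integer(1)),
    n_members = lengths(idx),
    members = lapply(idx, function(i) ord[i])
  )
}

# Running max of interval ends within each chromosome, shifted by one row
# (i.e. the furthest end seen before the current row); -Inf at chrom starts.
cummax_by_chrom <- function(xs) {
  out <- numeric(nrow(xs))
  cur_chrom <- ""
  cur_max <- -Inf
  for (i in seq_len(nrow(xs))) {
    if (xs$chrom[i] != cur_chrom) {
      cur_chrom <- xs$chrom[i]
      cur_max <- -Inf
    }
    out[i] <- cur_max
    cur_max <- max(cur_max, xs$end[i])
  }
  out
}

#' Randomly relocate intervals within their chromosomes
#'
#' Each interval is re-placed uniformly at random on its own chromosome with
#' its length preserved, optionally avoiding a set of excluded regions
#' (rejection sampling). Used to build shuffled control interval sets.
#'
#' @param x Interval tibble.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param seed Optional integer seed.
#' @param exclude Optional interval tibble of regions placements must not
#'   overlap.
#' @param max_tries Rejection-sampling attempts per interval before erroring.
#' @return A tibble of shuffled intervals (same lengths, same chromosomes).
#' @export
shuffle_intervals <- function(x, chrom_lengths, seed = NULL, exclude = NULL,
                              max_tries = 1000L) {
  x <- validate_intervals(x)
  len <- x$end - x$start
  cl <- chrom_lengths[x$chrom]
  if (any(is.na(cl))) abort("interval chromosome absent from chrom_lengths")
  if (any(len > cl)) abort("interval longer than its chromosome")
  with_seed(seed, {
    starts <- integer(nrow(x))
    for (i in seq_len(nrow(x))) {
      ok <- FALSE
      for (k in seq_len(max_tries)) {
        s <- as.integer(floor(runif(1, 0, cl[i] - len[i] + 1)))
        if (!is.null(exclude)) {
          cand <- tibble(chrom = x$chrom[i], start = s, end = s + len[i])
          if (any(overlaps_any(cand, exclude))) next
        }
        ok <- TRUE
        starts[i] <- s
        break
      }
      if (!ok) abort("could not place interval outside excluded regions")
    }
    out <- x
    out$start <- starts
    out$end <- starts + len
    out
  })
}

# midpoint of half-open intervals
interval_midpoint <- function(x) as.integer(floor((x$start + x$end) / 2))

# Closest-base distance between interval rows and a second set of coordinates
# (vectors gs, ge). 0 iff overlapping; adjacent intervals have distance 1.
interval_distance <- function(s, e, gs, ge) {
  d <- pmax(gs - e, s - ge) + 1L
  pmax(0L, d)
}
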