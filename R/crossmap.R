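# Translation of intervals and reads between species coordinate systems
# through chain alignments, with a minimum-match filter: an interval maps
# only if at least `min_match` of its bases fall inside the ungapped blocks
# of exactly one chain; two or more qualifying chains reject the interval as
# ambiguous, matching liftOver's behaviour when multiple outputs are not
# permitted.

# Per-(interval, chain) aligned-base bookkeeping. Returns a tibble with one
# row per interval x overlapping chain: idx, chain_id, bases, dst_lo, dst_hi,
# reversed, dst_chrom.
chain_overlap_stats <- function(x, chains) {
  hits <- interval_hits(
    x,
    tibble(chrom = chains$src_chrom, start = chains$src_start,
           end = chains$src_end)
  )
  if (nrow(hits) == 0) {
    return(tibble(idx = integer(), chain_id = character(), bases = integer(),
                  dst_lo = integer(), dst_hi = integer(), reversed = logical(),
                  dst_chrom = character()))
  }
  b <- chains[hits$s, ]
  ov_start <- pmax(x$start[hits$q], b$src_start)
  ov_end <- pmin(x$end[hits$q], b$src_end)
  # destination coordinates of the overlapping piece, forward-strand
  piece_lo <- ifelse(b$reversed,
                     b$dst_end - (ov_end - b$src_start),
                     b$dst_start + (ov_start - b$src_start))
  piece_hi <- ifelse(b$reversed,
                     b$dst_end - (ov_start - b$src_start),
                     b$dst_start + (ov_end - b$src_start))
  per <- tibble(idx = hits$q, chain_id = b$chain_id,
                bases = as.integer(ov_end - ov_start),
                piece_lo = as.integer(piece_lo),
                piece_hi = as.integer(piece_hi),
                reversed = b$reversed, dst_chrom = b$dst_chrom)
  per |>
    group_by(idx, chain_id) |>
    summarise(bases = sum(bases), dst_lo = min(piece_lo),
              dst_hi = max(piece_hi), reversed = first(reversed),
              dst_chrom = first(dst_chrom), .groups = "drop")
}

#' Translate intervals through a chain map
#'
#' For each chain overlapping an interval, the mapped fraction is the number
#' of interval bases inside that chain's ungapped blocks divided by the
#' interval length. Chains reaching `min_match` are candidates: exactly one
#' candidate maps the interval (target = enclosing span of the mapped
#' pieces, orientation-normalized); two or more candidates reject it as
#' `multiple_chains`; none rejects it as `below_minMatch` when any chain
#' overlaps, else `no_chain`.
#'
#' @param x Interval tibble on the source genome.
#' @param chains A `chain_map` from [read_chain()].
#' @param min_match Minimum mapped fraction in `(0, 1]` (0.7 for close
#'   species pairs, 0.5 for a distant pair).
#' @return A mapping report: the input columns plus `status` (`mapped`,
#'   `below_minMatch`, `multiple_chains`, `no_chain`), `fraction`,
#'   `chain_id`, `dst_chrom`, `dst_start`, `dst_end`, `dst_strand`.
#' @export
translate_intervals <- function(x, chains, min_match = 0.7) {
  stopifnot(min_match > 0, min_match <= 1)
  x <- validate_intervals(x)
  stats <- chain_overlap_stats(x, chains)
  n <- nrow(x)
  width <- x$end - x$start
  status <- rep("no_chain", n)
  fraction <- rep(0, n)
  chain_id <- rep(NA_character_, n)
  dst_chrom <- rep(NA_character_, n)
  dst_start <- rep(NA_integer_, n)
  dst_end <- rep(NA_integer_, n)
  dst_strand <- rep(NA_character_, n)
  # chains whose overall span overlaps the interval (even in a gap between
  # blocks) leave it below_minMatch rather than no_chain
  spans <- chains |>
    group_by(chain_id) |>
    summarise(chrom = first(src_chrom), start = min(src_start),
              end = max(src_end), .groups = "drop")
  span_hits <- interval_hits(x, select(spans, chrom, start, end))
  status[unique(span_hits$q)] <- "below_minMatch"
  if (nrow(stats)) {
    stats$fraction <- stats$bases / width[stats$idx]
    best <- stats |>
      group_by(idx) |>
      summarise(best_frac = max(fraction), .groups = "drop")
    fraction[best$idx] <- best$best_frac
    cand <- filter(stats, fraction >= min_match)
    if (nrow(cand)) {
      ncand <- table(cand$idx)
      multi <- as.integer(names(ncand)[ncand >= 2])
      status[multi] <- "multiple_chains"
      single <- as.integer(names(ncand)[ncand == 1])
      one <- filter(cand, idx %in% single)
      status[one$idx] <- "mapped"
      fraction[one$idx] <- one$fraction
      chain_id[one$idx] <- one$chain_id
      dst_chrom[one$idx] <- one$dst_chrom
      dst_start[one$idx] <- one$dst_lo
      dst_end[one$idx] <- one$dst_hi
      src_strand <- if ("strand" %in% names(x)) x$strand else rep("+", n)
      flip <- c("+" = "-", "-" = "+", "*" = "-")
      dst_strand[one$idx] <- ifelse(one$reversed,
                                    flip[src_strand[one$idx]],
                                    src_strand[one$idx])
    }
  }
  out <- x
  out$status <- status
  out$fraction <- fraction
  out$chain_id <- chain_id
  out$dst_chrom <- dst_chrom
  out$dst_start <- dst_start
  out$dst_end <- dst_end
  out$dst_strand <- dst_strand
  out
}

#' Mapped intervals from a translation report, in target coordinates
#'
#' @param report Output of [translate_intervals()].
#' @return Interval tibble on the destination genome (mapped records only),
#'   retaining `name`/`score` columns and the source coordinates as
#'   `src_chrom`, `src_start`, `src_end`.
#' @export
mapped_intervals <- function(report) {
  m <- filter(report, status == "mapped")
  out <- tibble(chrom = m$dst_chrom, start = m$dst_start, end = m$dst_end,
                strand = m$dst_strand,
                src_chrom = m$chrom, src_start = m$start, src_end = m$end)
  for (col in intersect(c("name", "score"), names(m))) out[[col]] <- m[[col]]
  out
}

#' Translate reads to a target genome
#'
#' Each read is translated as an interval; unmapped reads are dropped and
#' tallied by status. Read strand flips when the chain orientation is
#' reversed.
#'
#' @param reads Read intervals (with optional `strand`, `sample` columns).
#' @param chains A `chain_map`.
#' @param min_match Minimum mapped fraction (reads are short, so 1.0 keeps
#'   only fully aligned reads; the default mirrors interval translation).
#' @return Translated reads on the target genome, with a `translation_summary`
#'   attribute (tibble of drop counts by status).
#' @export
translate_reads <- function(reads, chains, min_match = 0.7) {
  rep_ <- translate_intervals(reads, chains, min_match)
  summary <- count(as_tibble(rep_), status, name = "n")
  m <- filter(rep_, status == "mapped")
  out <- tibble(chrom = m$dst_chrom, start = m$dst_start, end = m$dst_end,
                strand = m$dst_strand)
  if ("sample" %in% names(m)) out$sample <- m$sample
  structure(out, translation_summary = summary)
}

#' Invert a chain map
#'
#' Swaps the source and target roles of every chain; `invert_chains()` is an
#' involution. Enables round-trip testing of translations.
#'
#' @param chains A `chain_map`.
#' @return The inverted `chain_map`.
#' @export
invert_chains <- function(chains) {
  out <- tibble(
    chain_id = chains$chain_id, score = chains$score,
    src_chrom = chains$dst_chrom, src_size = chains$dst_size,
    src_start = chains$dst_start, src_end = chains$dst_end,
    dst_chrom = chains$src_chrom, dst_size = chains$src_size,
    dst_start = chains$src_start, dst_end = chains$src_end,
    reversed = chains$reversed
  )
  validate_chain_map(out)
}
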