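# GATC fragment partition and per-fragment read quantification. The GATC
# fragment is the quantification unit of DamID: methylation by the Dam fusion
# is read out as sequencing coverage of the fragments between GATC sites.

#' Partition a genome at GATC sites
#'
#' Fragment boundaries are placed at the start coordinate of every exact
#' forward-strand GATC match (GATC is its own reverse complement, so one
#' strand suffices). Terminal fragments run from 0 to the first boundary and
#' from the last boundary to the chromosome end; chromosomes without a GATC
#' yield a single whole-chromosome fragment. Zero-length fragments (a GATC at
#' position 0) are suppressed. The 4-bp site belongs to the fragment it
#' starts.
#'
#' @param genome A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]).
#' @return A tibble with columns `frag_id` (stable 1-based index over the
#'   whole genome), `chrom`, `start`, `end`; per chromosome the fragments
#'   tile `[0, length)` exactly.
#' @export
gatc_fragment_map <- function(genome) {
  if (length(genome) == 0) abort("empty genome")
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    len <- Biostrings::width(genome)[i]
    m <- Biostrings::matchPattern("GATC", genome[[i]])
    bnd <- Biostrings::start(m) - 1L      # 0-based start of each GATC
    bnd <- bnd[bnd > 0L]                  # suppress zero-length lead fragment
    starts <- c(0L, bnd)
    ends <- c(bnd, len)
    out[[i]] <- tibble(chrom = names(genome)[i], start = starts, end = ends)
  }
  res <- bind_rows(out)
  res <- mutate(res, frag_id = row_number(), .before = 1)
  res
}

#' Extend reads to the average fragment length
#'
#' Each read is replaced by an interval of exactly `length` bp anchored at
#' its 5' end and extended in the 3' direction of its strand, then clamped to
#' `[0, chromosome length)`. Unstranded reads are treated as plus strand.
#'
#' @param reads Interval tibble of mapped reads (`chrom`, `start`, `end`,
#'   optional `strand`).
#' @param length Target length in bp (default 200, the average DamID fragment
#'   length).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A tibble of extended, clamped intervals (strand preserved).
#' @export
extend_reads <- function(reads, length = 200L, chrom_lengths) {
  reads <- validate_intervals(reads)
  if (any(length < reads$end - reads$start))
    abort("extension length shorter than a read")
  cl <- chrom_lengths[reads$chrom]
  if (any(is.na(cl))) abort("read chromosome absent from genome")
  strand <- if ("strand" %in% names(reads)) reads$strand else
    rep("+", nrow(reads))
  minus <- strand == "-"
  new_start <- ifelse(minus, reads$end - length, reads$start)
  new_end <- ifelse(minus, reads$end, reads$start + length)
  out <- reads
  out$start <- pmax(0L, as.integer(new_start))
  out$end <- pmin(as.integer(cl), as.integer(new_end))
  out$strand <- strand
  out
}

#' Count extended reads overlapping each GATC fragment
#'
#' A read contributes one count to every fragment it overlaps by at least one
#' base (coverage semantics), so the column sum is at least the number of
#' reads.
#'
#' @param fragments GATC fragment map from [gatc_fragment_map()].
#' @param reads Extended read intervals (clamped to chromosome bounds).
#' @return Integer count vector along `fragments$frag_id`.
#' @export
count_fragment_coverage <- function(fragments, reads) {
  counts <- integer(nrow(fragments))
  if (nrow(reads) == 0) return(counts)
  reads <- validate_intervals(reads)
  for (cc in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == cc)
    ri <- which(reads$chrom == cc)
    if (!length(ri)) next
    bnd <- fragments$start[fi]           # sorted fragment starts, first is 0
    n <- length(fi)
    i1 <- findInterval(reads$start[ri], bnd)
    i2 <- findInterval(reads$end[ri] - 1L, bnd)
    keep <- i1 >= 1L & i2 >= 1L & reads$end[ri] > reads$start[ri]
    i1 <- pmax(i1[keep], 1L)
    i2 <- pmin(i2[keep], n)
    inc <- tabulate(i1, nbins = n)
    dec <- tabulate(i2 + 1L, nbins = n + 1L)[seq_len(n)]
    counts[fi] <- counts[fi] + cumsum(inc - dec)
  }
  counts
}

#' Assemble the fragment x sample count table
#'
#' Extends each sample's reads, counts fragment coverage, and collates the
#' columns in the given sample order. Sample metadata (condition, factor,
#' species, replicate) travels with the table as the `sample_info` attribute.
#'
#' @param fragments GATC fragment map.
#' @param reads Long tibble of mapped reads with a `sample` column.
#' @param sample_info Tibble with one row per sample: `sample`, `condition`
#'   (`"fusion"` or `"control"`), `factor`, `species`, `replicate`.
#' @param extension_length Read extension length in bp.
#' @param chrom_lengths Named chromosome lengths.
#' @return A `fragment_counts` tibble: `frag_id`, `chrom`, `start`, `end`,
#'   then one integer column per sample. Access metadata with
#'   [sample_info()].
#' @export
assemble_count_table <- function(fragments, reads, sample_info,
                                 extension_length = 200L, chrom_lengths) {
  if (anyDuplicated(sample_info$sample)) abort("duplicate sample labels")
  if (!all(sample_info$condition %in% c("fusion", "control")))
    abort("condition must be 'fusion' or 'control'")
  if (!any(sample_info$condition == "fusion") ||
      !any(sample_info$condition == "control"))
    abort("need at least one fusion and one control sample")
  out <- fragments
  for (s in sample_info$sample) {
    rr <- filter(reads, .data$sample == s)
    ext <- extend_reads(select(rr, -sample), extension_length, chrom_lengths)
    out[[s]] <- count_fragment_coverage(fragments, ext)
  }
  structure(out, sample_info = sample_info,
            class = c("fragment_counts", class(tibble())))
}

#' @rdname assemble_count_table
#' @param x A `fragment_counts` table (or any object carrying the attribute).
#' @export
sample_info <- function(x) attr(x, "sample_info")

# count matrix (fragments x samples) from a fragment_counts tibble
count_matrix <- function(counts) {
  info <- sample_info(counts)
  m <- as.matrix(counts[, info$sample, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$frag_id
  m
}
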