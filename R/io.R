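# Readers and writers for the standard formats consumed and produced by the
# pipeline. All internal coordinates are 0-based half-open (BED convention);
# GFF3 (1-based inclusive) and UCSC chain files are converted at the boundary.

#' Read a genome FASTA file
#'
#' Sequences are case-folded to upper case and validated against the
#' `{A,C,G,T,N}` alphabet. Duplicate record names, empty sequences and
#' malformed headers are errors.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] keyed by record name.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(nm))) abort("FASTA record with empty name")
  if (anyDuplicated(nm)) abort("duplicate FASTA record names")
  if (any(Biostrings::width(x) == 0)) abort("empty FASTA sequence")
  chr <- toupper(as.character(x))
  if (any(grepl("[^ACGTN]", chr)))
    abort("FASTA sequence contains characters outside ACGTN")
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Named chromosome lengths of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  if (methods::is(genome, "XStringSet"))
    return(setNames(Biostrings::width(genome), names(genome)))
  setNames(nchar(genome), names(genome))
}

#' Read a BED3 / BED6 interval file
#'
#' Coordinates are 0-based half-open per the BED standard and validated
#' (`start < end`, non-negative). Input order is preserved. `#`-prefixed
#' header lines are skipped.
#'
#' @param path BED file path.
#' @param dialect `"BED3"` or `"BED6"`; the file must have exactly that many
#'   columns.
#' @return An interval tibble (`chrom`, `start`, `end` and, for BED6, `name`,
#'   `score`, `strand`).
#' @export
read_intervals <- function(path, dialect = c("BED3", "BED6")) {
  dialect <- match.arg(dialect)
  ncol_want <- if (dialect == "BED3") 3L else 6L
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (nrow(x) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    if (dialect == "BED6")
      out <- mutate(out, name = character(), score = numeric(),
                    strand = character())
    return(out)
  }
  if (ncol(x) != ncol_want)
    abort(sprintf("%s file must have %d columns, found %d",
                  dialect, ncol_want, ncol(x)))
  out <- tibble(chrom = x[[1]],
                start = as.integer(x[[2]]),
                end = as.integer(x[[3]]))
  if (any(is.na(out$start) | is.na(out$end)))
    abort("non-numeric BED coordinates")
  if (dialect == "BED6") {
    out$name <- x[[4]]
    out$score <- suppressWarnings(as.numeric(x[[5]]))
    out$strand <- x[[6]]
  }
  validate_intervals(out)
}

#' Write intervals to BED
#'
#' Writes BED3 (or BED6 when `name`, `score`, `strand` columns are present).
#' Optional provenance comment lines are written first.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @param header Optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, header = NULL) {
  x <- validate_intervals(x)
  bed6 <- all(c("name", "score", "strand") %in% names(x))
  cols <- if (bed6) {
    data.frame(x$chrom, x$start, x$end, x$name, x$score, x$strand)
  } else {
    data.frame(x$chrom, x$start, x$end)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(cols, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-fragment values as bedGraph
#'
#' Records are sorted by chromosome and start; overlapping fragments are an
#' error. Values round-trip through [read_bedgraph()] to 6 decimal places.
#'
#' @param x Interval tibble with a `value` column (one value per fragment).
#' @param path Output path.
#' @param header Optional `#` comment lines (provenance).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, header = NULL) {
  x <- validate_intervals(x)
  if (!"value" %in% names(x)) abort("bedGraph output needs a `value` column")
  x <- arrange(x, chrom, start)
  bad <- x$chrom == lag(x$chrom, default = "") &
    x$start < lag(x$end, default = -1L)
  if (any(bad)) abort("overlapping fragments in bedGraph output")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines('track type=bedGraph name="damidcompare"', con)
  if (nrow(x))
    writeLines(sprintf("%s\t%d\t%d\t%.6f", x$chrom, x$start, x$end, x$value),
               con)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#|^track", lines)]
  if (!length(lines))
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    value = as.numeric(vapply(parts, `[`, "", 4L))
  )
}

# ---- gene models ------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon features, converts to 0-based half-open coordinates,
#' selects the canonical transcript of each gene (the longest, by exonic
#' span), and derives introns as gaps between its sorted exons. Intron rank 1
#' is the 5'-most intron in transcription order (so on the minus strand the
#' genomic-rightmost intron has rank 1). The TSS is the 5' end of the gene
#' span on its strand.
#'
#' @param path GFF3 file path.
#' @return A nested tibble with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, and list-columns `exons` and `introns`
#'   (tibbles with `start`, `end`, and for introns `rank`).
#' @export
read_gff_genes <- function(path) {
  gff <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gff)
  type <- as.character(meta$type)
  id <- if ("ID" %in% names(meta)) as.character(meta$ID) else NA_character_
  parent <- if ("Parent" %in% names(meta)) {
    vapply(meta$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gff))
  df <- tibble(
    type = type, id = id, parent = parent,
    chrom = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff))
  )
  genes <- filter(df, type == "gene")
  mrnas <- filter(df, type == "mRNA")
  exons <- filter(df, type == "exon")
  if (nrow(genes) == 0) abort("no gene features in GFF3")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- filter(mrnas, parent == g$id)
    if (nrow(tx) == 0) {
      ex <- filter(exons, parent == g$id)
    } else {
      # canonical transcript = longest exonic span
      ex_by_tx <- lapply(tx$id, function(t) filter(exons, parent == t))
      span <- vapply(ex_by_tx, function(e) sum(e$end - e$start), numeric(1))
      ex <- ex_by_tx[[which.max(span)]]
    }
    if (nrow(ex) == 0) abort(sprintf("gene %s has no exons", g$id))
    ex <- arrange(ex, start)
    if (any(ex$start < g$start | ex$end > g$end))
      abort(sprintf("exon outside gene span for %s", g$id))
    if (nrow(ex) > 1 && any(ex$start[-1] < head(ex$end, -1)))
      abort(sprintf("overlapping exons in gene %s", g$id))
    intr <- if (nrow(ex) > 1) {
      tibble(start = head(ex$end, -1), end = ex$start[-1])
    } else {
      tibble(start = integer(), end = integer())
    }
    if (nrow(intr)) {
      intr$rank <- if (g$strand == "-") rev(seq_len(nrow(intr))) else
        seq_len(nrow(intr))
      intr <- arrange(intr, start)
    } else {
      intr$rank <- integer()
    }
    out[[i]] <- tibble(
      gene_id = g$id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end,
      tss = if (g$strand == "-") g$end - 1L else g$start,
      exons = list(select(ex, start, end)),
      introns = list(intr)
    )
  }
  bind_rows(out)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff_genes()]: emits gene, mRNA and exon features with
#' 1-based inclusive coordinates.
#'
#' @param genes Nested gene-model tibble as returned by [read_gff_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id), con)
    tx <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, tx, g$gene_id),
               con)
    ex <- g$exons[[1]]
    writeLines(sprintf("%s\t.\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                       g$chrom, ex$start + 1L, ex$end, g$strand, tx,
                       seq_len(nrow(ex)), tx), con)
  }
  invisible(path)
}

# ---- UCSC chain files -------------------------------------------------------

#' Read a UCSC chain file
#'
#' Parses the block structure of each chain and reconstructs absolute block
#' coordinates from the cumulative `size dt dq` triples. In UCSC usage the
#' "target" (tName) genome of a chain file named A-to-B is A, i.e. the genome
#' intervals are translated *from*; it is stored here as `src_*`, with the
#' query genome as `dst_*`. Reverse-strand query coordinates are normalized
#' to the forward strand; `reversed` flags the orientation.
#'
#' @param path Chain file path.
#' @return A `chain_map`: a tibble with one row per alignment block and
#'   columns `chain_id`, `score`, `src_chrom`, `src_size`, `src_start`,
#'   `src_end`, `dst_chrom`, `dst_size`, `dst_start`, `dst_end`, `reversed`.
#' @export
read_chain <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^chain\\b", lines[i])) abort("expected chain header line")
    h <- strsplit(lines[i], "\\s+")[[1]]
    if (length(h) < 12) abort("malformed chain header")
    score <- as.numeric(h[2])
    s_chrom <- h[3]; s_size <- as.integer(h[4]); s_strand <- h[5]
    s_start <- as.integer(h[6]); s_end <- as.integer(h[7])
    q_chrom <- h[8]; q_size <- as.integer(h[9]); q_strand <- h[10]
    q_start <- as.integer(h[11]); q_end <- as.integer(h[12])
    chain_id <- if (length(h) >= 13) h[13] else as.character(length(out) + 1L)
    if (s_strand != "+") abort("chain source strand must be '+'")
    i <- i + 1L
    sizes <- integer(); dts <- integer(); dqs <- integer()
    repeat {
      if (i > length(lines)) abort("chain missing terminal size-only line")
      f <- strsplit(lines[i], "\\s+")[[1]]
      sizes <- c(sizes, as.integer(f[1]))
      i <- i + 1L
      if (length(f) == 1) break
      if (length(f) != 3) abort("malformed chain block line")
      dts <- c(dts, as.integer(f[2]))
      dqs <- c(dqs, as.integer(f[3]))
    }
    n <- length(sizes)
    s_off <- s_start + c(0L, cumsum(sizes[-n] + dts))
    q_off <- q_start + c(0L, cumsum(sizes[-n] + dqs))
    if (s_off[n] + sizes[n] > s_end || q_off[n] + sizes[n] > q_end)
      abort("chain blocks extend past declared chain span")
    reversed <- q_strand == "-"
    if (reversed) {
      dst_start <- q_size - (q_off + sizes)
      dst_end <- q_size - q_off
    } else {
      dst_start <- q_off
      dst_end <- q_off + sizes
    }
    out[[length(out) + 1L]] <- tibble(
      chain_id = chain_id, score = score,
      src_chrom = s_chrom, src_size = s_size,
      src_start = s_off, src_end = s_off + sizes,
      dst_chrom = q_chrom, dst_size = q_size,
      dst_start = as.integer(dst_start), dst_end = as.integer(dst_end),
      reversed = reversed
    )
  }
  chains <- bind_rows(out)
  validate_chain_map(chains)
}

#' @rdname read_chain
#' @param chains A `chain_map` tibble.
#' @export
validate_chain_map <- function(chains) {
  chains <- as_tibble(chains)
  need <- c("chain_id", "score", "src_chrom", "src_size", "src_start",
            "src_end", "dst_chrom", "dst_size", "dst_start", "dst_end",
            "reversed")
  miss <- setdiff(need, names(chains))
  if (length(miss))
    abort(paste0("chain_map lacks column(s): ", paste(miss, collapse = ", ")))
  chains <- arrange(chains, chain_id, src_start)
  if (any(chains$src_start < 0 | chains$dst_start < 0))
    abort("negative chain block coordinate")
  if (any(chains$src_end > chains$src_size |
          chains$dst_end > chains$dst_size))
    abort("chain block outside chromosome bounds")
  by_chain <- split(seq_len(nrow(chains)), chains$chain_id)
  for (idx in by_chain) {
    if (length(idx) < 2) next
    s0 <- chains$src_start[idx]; s1 <- chains$src_end[idx]
    if (any(s0[-1] < head(s1, -1)))
      abort("chain blocks overlap on the source genome")
    d0 <- chains$dst_start[idx]; d1 <- chains$dst_end[idx]
    o <- order(d0)
    if (any(d0[o][-1] < head(d1[o], -1)))
      abort("chain blocks overlap on the destination genome")
  }
  structure(chains, class = c("chain_map", class(tibble())))
}

#' Write a chain map to UCSC chain format
#'
#' Inverse of [read_chain()]; reverse-orientation chains are written with
#' query coordinates back on the reverse strand.
#'
#' @param chains A `chain_map` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in unique(chains$chain_id)) {
    b <- arrange(filter(chains, chain_id == cid), src_start)
    rev <- b$reversed[1]
    if (rev) {
      # blocks in src order run right-to-left on the forward dst strand,
      # i.e. left-to-right in reverse-strand coordinates
      q0 <- b$dst_size[1] - b$dst_end
      q1 <- b$dst_size[1] - b$dst_start
    } else {
      q0 <- b$dst_start
      q1 <- b$dst_end
    }
    writeLines(sprintf("chain %g %s %d + %d %d %s %d %s %d %d %s",
                       b$score[1], b$src_chrom[1], b$src_size[1],
                       b$src_start[1], b$src_end[nrow(b)],
                       b$dst_chrom[1], b$dst_size[1],
                       if (rev) "-" else "+", q0[1], q1[nrow(b)], cid), con)
    sizes <- b$src_end - b$src_start
    if (nrow(b) > 1) {
      dt <- b$src_start[-1] - head(b$src_end, -1)
      dq <- q0[-1] - head(q1, -1)
      writeLines(sprintf("%d\t%d\t%d", head(sizes, -1), dt, dq), con)
    }
    writeLines(sprintf("%d", sizes[length(sizes)]), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- aligned FASTA ----------------------------------------------------------

#' Read / write a multiple alignment (aligned FASTA)
#'
#' An alignment is a tibble with columns `species` and `seq` (gapped, equal
#' lengths, alphabet `ACGTN-`). [alignment_position_map()] returns, for one
#' row, the alignment column of each ungapped position.
#'
#' @param path Aligned FASTA path.
#' @return A `multiple_alignment` tibble.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  aln <- tibble(species = sub("\\s.*$", "", names(x)),
                seq = unname(toupper(as.character(x))))
  validate_alignment(aln)
}

#' @rdname read_alignment
#' @param aln A `multiple_alignment` tibble.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(Biostrings::BStringSet(setNames(aln$seq, aln$species)), path)
}

#' @rdname read_alignment
#' @export
validate_alignment <- function(aln) {
  aln <- as_tibble(aln)
  if (!all(c("species", "seq") %in% names(aln)))
    abort("alignment needs `species` and `seq` columns")
  w <- nchar(aln$seq)
  if (length(unique(w)) > 1) abort("gapped sequences differ in length")
  if (any(grepl("[^ACGTN-]", aln$seq)))
    abort("alignment contains characters outside ACGTN-")
  structure(aln, class = c("multiple_alignment", class(tibble())))
}

#' @rdname read_alignment
#' @param row Row index of the alignment.
#' @return For `alignment_position_map()`, an integer vector: element `i` is
#'   the 1-based alignment column of ungapped position `i`.
#' @export
alignment_position_map <- function(aln, row) {
  chars <- strsplit(aln$seq[row], "")[[1]]
  which(chars != "-")
}

# strip gaps from one alignment row
ungap <- function(seq) gsub("-", "", seq, fixed = TRUE)
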