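# Cross-species conservation classification of binding intervals, gene and
# genomic-feature annotation, compensatory-turnover detection, and
# conservation enrichment tests by functional category. Conservation is
# single-linkage: >= 1 bp overlap with another species' translated interval
# set, with no reciprocal-fraction requirement.

#' Classify binding intervals by cross-species conservation
#'
#' All interval sets must be on the same (reference) coordinate system: the
#' reference species' native intervals plus each other species' translated
#' set. Each reference interval's species set is itself plus every species
#' whose translated set it overlaps; the category is the number of species.
#'
#' @param interval_sets Named list of interval tibbles on the reference
#'   coordinates, one per species. The first element is taken as the
#'   reference species unless `ref_species` says otherwise.
#' @param ref_species Name of the reference species within `interval_sets`.
#' @return A tibble of conservation records for the reference species'
#'   intervals: coordinates, `species_set` (list-column of species labels),
#'   `category` (1 = unique, up to N-way).
#' @export
classify_conservation <- function(interval_sets, ref_species = NULL) {
  stopifnot(is.list(interval_sets), !is.null(names(interval_sets)))
  ref_species <- ref_species %||% names(interval_sets)[1]
  ref <- validate_intervals(interval_sets[[ref_species]])
  others <- setdiff(names(interval_sets), ref_species)
  sets <- lapply(others, function(s) {
    ok <- overlaps_any(ref, interval_sets[[s]])
    ok
  })
  names(sets) <- others
  species_set <- lapply(seq_len(nrow(ref)), function(i) {
    c(ref_species, others[vapply(sets, `[`, NA, i)])
  })
  out <- select(ref, chrom, start, end)
  out$species_set <- species_set
  out$category <- lengths(species_set)
  out
}

#' Union-set conservation category distribution
#'
#' Pools the interval sets of all species (on common reference coordinates),
#' merges overlapping intervals from different species into single
#' representatives (single linkage), and reports for each representative the
#' set of species contributing to it. The category percentages are computed
#' over these de-duplicated representatives, so the denominator is "all
#' intervals identified across species".
#'
#' @param interval_sets Named list of interval tibbles on one coordinate
#'   system (native reference set plus translated sets).
#' @return A list with `representatives` (tibble: coordinates, `species_set`
#'   list-column, `category`) and `distribution` (tibble: `category`, `n`,
#'   `percent`; percents sum to 100).
#' @export
conservation_distribution <- function(interval_sets) {
  pooled <- bind_rows(lapply(names(interval_sets), function(s) {
    x <- validate_intervals(interval_sets[[s]])
    tibble(chrom = x$chrom, start = x$start, end = x$end, species = s)
  }))
  # gap -1 merges only intervals sharing >= 1 base (touching stay separate)
  merged <- merge_intervals(select(pooled, chrom, start, end), gap = -1L)
  reps <- tibble(
    chrom = merged$chrom, start = merged$start, end = merged$end,
    species_set = lapply(merged$members,
                         function(i) sort(unique(pooled$species[i])))
  )
  reps$category <- lengths(reps$species_set)
  dist <- reps |>
    count(category, name = "n") |>
    mutate(percent = 100 * n / sum(n))
  list(representatives = reps, distribution = dist)
}

#' Annotate intervals with their nearest gene
#'
#' Distance is the closest-base distance between the interval and the gene
#' span (0 iff overlapping, 1 when adjacent). Ties are broken
#' lexicographically by gene id and flagged in the `tie` column. Intervals on
#' chromosomes without genes are left unannotated (`gene_id = NA`).
#'
#' @param x Interval tibble.
#' @param genes Gene-model tibble ([read_gff_genes()]), or any tibble with
#'   `gene_id`, `chrom`, `start`, `end`.
#' @return `x` plus `gene_id`, `gene_distance`, `tie` columns.
#' @export
annotate_nearest_gene <- function(x, genes) {
  if (nrow(genes) == 0) abort("empty gene set")
  x <- validate_intervals(x)
  gene_id <- rep(NA_character_, nrow(x))
  gene_distance <- rep(NA_integer_, nrow(x))
  tie <- rep(FALSE, nrow(x))
  for (cc in unique(x$chrom)) {
    xi <- which(x$chrom == cc)
    gi <- which(genes$chrom == cc)
    if (!length(gi)) next
    # distances to every gene on the chromosome (gene counts are modest)
    dm <- outer(seq_along(xi), seq_along(gi), function(a, b) {
      interval_distance(x$start[xi[a]], x$end[xi[a]],
                        genes$start[gi[b]], genes$end[gi[b]])
    })
    ids <- genes$gene_id[gi]
    ord <- order(ids)
    for (k in seq_along(xi)) {
      d <- dm[k, ]
      dmin <- min(d)
      winners <- ids[d == dmin]
      gene_id[xi[k]] <- sort(winners)[1]
      gene_distance[xi[k]] <- dmin
      tie[xi[k]] <- length(winners) > 1
    }
  }
  if (any(tie))
    inform(sprintf("%d nearest-gene ties broken lexicographically", sum(tie)))
  x$gene_id <- gene_id
  x$gene_distance <- gene_distance
  x$tie <- tie
  x
}

# intron table (gene_id, chrom, strand, start, end, rank) from gene models
intron_table <- function(genes) {
  out <- genes |>
    select(gene_id, chrom, strand, introns) |>
    unnest(introns)
  if (!nrow(out))
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  rank = integer()))
  out
}

#' Annotate intervals with genomic feature class
#'
#' The interval midpoint decides the class with precedence
#' promoter > exon > intron > intergenic. The promoter window spans
#' `window[1]` bp upstream to `window[2]` bp downstream of the TSS in
#' transcription orientation (default 2000/500). Intronic intervals get the
#' rank of the containing intron (rank 1 = first intron in transcription
#' order). `tss_distance` is the distance from the midpoint to the nearest
#' TSS.
#'
#' @param x Interval tibble.
#' @param genes Gene models ([read_gff_genes()]).
#' @param promoter_window Upstream/downstream extents in bp.
#' @return `x` plus `feature`, `intron_rank`, `tss_distance` columns.
#' @export
annotate_features <- function(x, genes, promoter_window = c(2000L, 500L)) {
  x <- validate_intervals(x)
  mid <- interval_midpoint(x)
  up <- promoter_window[1]
  down <- promoter_window[2]
  promoters <- tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "-", genes$tss - down + 1L,
                   genes$tss - up),
    end = ifelse(genes$strand == "-", genes$tss + up + 1L,
                 genes$tss + down)
  ) |> mutate(start = pmax(0L, as.integer(start)), end = as.integer(end))
  exons <- genes |> select(gene_id, chrom, exons) |> unnest(exons)
  introns <- intron_table(genes)
  midpt <- tibble(chrom = x$chrom, start = mid, end = mid + 1L)
  in_prom <- overlaps_any(midpt, promoters)
  in_exon <- if (nrow(exons)) overlaps_any(midpt, exons) else
    rep(FALSE, nrow(x))
  feature <- rep("intergenic", nrow(x))
  intron_rank <- rep(NA_integer_, nrow(x))
  if (nrow(introns)) {
    hits <- interval_hits(midpt, introns)
    if (nrow(hits)) {
      hits <- hits[!duplicated(hits$q), ]
      feature[hits$q] <- "intron"
      intron_rank[hits$q] <- introns$rank[hits$s]
    }
  }
  feature[in_exon] <- "exon"
  feature[in_prom] <- "promoter"
  intron_rank[feature != "intron"] <- NA_integer_
  tssd <- rep(NA_integer_, nrow(x))
  for (cc in unique(x$chrom)) {
    xi <- which(x$chrom == cc)
    gi <- which(genes$chrom == cc)
    if (!length(gi)) next
    tssd[xi] <- vapply(mid[xi], function(p) min(abs(p - genes$tss[gi])),
                       numeric(1))
  }
  x$feature <- feature
  x$intron_rank <- intron_rank
  x$tss_distance <- as.integer(tssd)
  x
}

#' First-intron enrichment test
#'
#' Compares the observed number of intronic intervals in rank-1 introns with
#' the expectation proportional to the genomic length of rank-1 versus
#' higher-rank introns. Uses a one-degree chi-squared when both expected
#' counts are at least 5, else an exact binomial test.
#'
#' @param annotations Output of [annotate_features()].
#' @param genes Gene models.
#' @return One-row tibble: `n_intronic`, `n_first`, `expected_first_prop`,
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
intron_rank_enrichment <- function(annotations, genes) {
  introns <- intron_table(genes)
  if (!nrow(introns)) abort("gene models contain no introns")
  len1 <- sum((introns$end - introns$start)[introns$rank == 1])
  len_all <- sum(introns$end - introns$start)
  p1 <- len1 / len_all
  intr <- filter(annotations, feature == "intron")
  n <- nrow(intr)
  if (n == 0) {
    warn("no intronic intervals; first-intron test untestable")
    return(tibble(n_intronic = 0L, n_first = 0L, expected_first_prop = p1,
                  statistic = NA_real_, df = NA_integer_,
                  p_value = NA_real_, method = "untestable"))
  }
  k <- sum(intr$intron_rank == 1, na.rm = TRUE)
  e1 <- n * p1
  e2 <- n * (1 - p1)
  if (e1 >= 5 && e2 >= 5) {
    stat <- (k - e1)^2 / e1 + ((n - k) - e2)^2 / e2
    tibble(n_intronic = n, n_first = k, expected_first_prop = p1,
           statistic = stat, df = 1L,
           p_value = pchisq(stat, 1, lower.tail = FALSE),
           method = "chi-squared")
  } else {
    bt <- binom.test(k, n, p1)
    tibble(n_intronic = n, n_first = k, expected_first_prop = p1,
           statistic = NA_real_, df = NA_integer_, p_value = bt$p.value,
           method = "binomial")
  }
}

#' Detect compensatory binding-site turnover between two species
#'
#' Both interval sets must be annotated against the same gene models on the
#' reference coordinates (species B's intervals translated to species A's
#' genome). For every gene with at least one interval in each species, a
#' turnover event is emitted when no A-interval overlaps any translated
#' B-interval at that gene; a single overlap anywhere at the locus marks it
#' positionally conserved and cancels the event.
#'
#' @param a Intervals of species A on the reference, gene-annotated
#'   ([annotate_nearest_gene()] is applied when `gene_id` is absent).
#' @param b_translated Intervals of species B translated to the reference.
#' @param genes Gene models used for annotation.
#' @return Tibble of turnover events: `gene_id`, `n_intervals_a`,
#'   `n_intervals_b`.
#' @export
detect_turnover <- function(a, b_translated, genes) {
  if (!"gene_id" %in% names(a)) a <- annotate_nearest_gene(a, genes)
  if (!"gene_id" %in% names(b_translated))
    b_translated <- annotate_nearest_gene(b_translated, genes)
  shared <- intersect(a$gene_id, b_translated$gene_id)
  shared <- shared[!is.na(shared)]
  out <- list()
  for (g in shared) {
    ag <- filter(a, gene_id == g)
    bg <- filter(b_translated, gene_id == g)
    if (!any(overlaps_any(ag, bg))) {
      out[[length(out) + 1L]] <- tibble(
        gene_id = g, n_intervals_a = nrow(ag), n_intervals_b = nrow(bg))
    }
  }
  if (!length(out))
    return(tibble(gene_id = character(), n_intervals_a = integer(),
                  n_intervals_b = integer()))
  bind_rows(out)
}

#' Pearson chi-squared test of independence
#'
#' @param tab A 2-D contingency matrix of non-negative counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`, with the table and
#'   expected counts as attributes. Expected counts below 5 trigger a
#'   warning; a degenerate table (empty row or column) is an error.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("degenerate contingency table (empty row or column)")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warn("expected counts < 5; chi-squared approximation may be poor")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(
    tibble(statistic = stat, df = df,
           p_value = pchisq(stat, df, lower.tail = FALSE)),
    table = tab, expected = expected
  )
}

#' Conservation by functional category
#'
#' Cross-tabulates the conservation category of binding intervals against a
#' logical functional flag (CRM overlap, core-interval overlap, direct
#' target, ...) and tests independence with Pearson's chi-squared.
#'
#' @param records Conservation records ([classify_conservation()]) carrying
#'   the flag column.
#' @param flag Name of a logical column of `records`.
#' @return The [chisq_independence()] result (tibble with attributes).
#' @export
conservation_by_category <- function(records, flag) {
  if (!flag %in% names(records))
    abort(sprintf("flag column '%s' not present", flag))
  f <- records[[flag]]
  if (!is.logical(f)) abort("flag column must be logical")
  tab <- table(factor(f, levels = c(TRUE, FALSE)), records$category)
  chisq_independence(unclass(tab))
}

#' Common versus factor-unique binding and its conservation
#'
#' Partitions species A's intervals of two factors into common (overlapping
#' the other factor) and factor-unique classes, then measures, per class,
#' the fraction conserved in species B (overlap with the translated
#' same-class union from B). A 2 x 3 chi-squared of conserved/not x class is
#' attached.
#'
#' @param a_factor1,a_factor2 Interval tibbles of the two factors in species
#'   A (native coordinates).
#' @param b_factor1,b_factor2 Interval tibbles of the two factors in species
#'   B translated onto species A's coordinates.
#' @param factor_names Labels for the two factors.
#' @return Tibble with one row per class (`common`, `unique_<f1>`,
#'   `unique_<f2>`): `n`, `n_conserved`, `rate`; chi-squared as the `chisq`
#'   attribute.
#' @export
common_unique_analysis <- function(a_factor1, a_factor2, b_factor1,
                                   b_factor2,
                                   factor_names = c("factor1", "factor2")) {
  a1 <- validate_intervals(a_factor1)
  a2 <- validate_intervals(a_factor2)
  common1 <- overlaps_any(a1, a2)
  common2 <- overlaps_any(a2, a1)
  b_common1 <- overlaps_any(b_factor1, b_factor2)
  b_common2 <- overlaps_any(b_factor2, b_factor1)
  b_common <- bind_rows(b_factor1[b_common1, c("chrom", "start", "end")],
                        b_factor2[b_common2, c("chrom", "start", "end")])
  b_u1 <- b_factor1[!b_common1, c("chrom", "start", "end")]
  b_u2 <- b_factor2[!b_common2, c("chrom", "start", "end")]
  # merged representation of common binding: overlapping factor-1/factor-2
  # pairs collapse to one representative
  common_merged <- merge_intervals(
    bind_rows(a1[common1, c("chrom", "start", "end")],
              a2[common2, c("chrom", "start", "end")]), gap = -1L)
  classes <- list(
    common = select(common_merged, chrom, start, end),
    u1 = a1[!common1, c("chrom", "start", "end")],
    u2 = a2[!common2, c("chrom", "start", "end")]
  )
  refs <- list(common = b_common, u1 = b_u1, u2 = b_u2)
  rows <- imap(classes, function(x, cls) {
    cons <- if (nrow(x) && nrow(refs[[cls]])) overlaps_any(x, refs[[cls]])
    else rep(FALSE, nrow(x))
    tibble(class = cls, n = nrow(x), n_conserved = sum(cons),
           rate = if (nrow(x)) mean(cons) else NA_real_)
  }) |> list_rbind()
  rows$class <- c(common = "common",
                  u1 = paste0("unique_", factor_names[1]),
                  u2 = paste0("unique_", factor_names[2]))[rows$class]
  tab <- rbind(conserved = rows$n_conserved,
               not_conserved = rows$n - rows$n_conserved)
  colnames(tab) <- rows$class
  chisq <- if (all(colSums(tab) > 0) && all(rowSums(tab) > 0))
    chisq_independence(tab) else NULL
  structure(rows, chisq = chisq)
}

#' Map a gene set to reference-species orthologs
#'
#' Applies a (possibly many-to-many) ortholog table to a gene set and
#' de-duplicates the image; optionally reports the intersection with a
#' reference gene set.
#'
#' @param gene_set Character vector of gene ids.
#' @param ortholog_table Two-column tibble `from`, `to`.
#' @param reference_set Optional character vector of reference gene ids.
#' @return A list: `mapped` (character vector, de-duplicated image),
#'   `n_unmapped` (input genes with no ortholog), and when `reference_set`
#'   is given, `overlap` (intersection cardinality).
#' @export
map_targets_via_orthologs <- function(gene_set, ortholog_table,
                                      reference_set = NULL) {
  stopifnot(ncol(ortholog_table) >= 2)
  names(ortholog_table)[1:2] <- c("from", "to")
  if (nrow(ortholog_table) == 0) warn("empty ortholog mapping")
  hit <- filter(ortholog_table, from %in% gene_set)
  mapped <- unique(hit$to)
  n_unmapped <- length(setdiff(gene_set, ortholog_table$from))
  out <- list(mapped = mapped, n_unmapped = n_unmapped)
  if (!is.null(reference_set))
    out$overlap <- length(intersect(mapped, reference_set))
  out
}
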