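# Simulation of multi-species genomes related by a phylogeny, with gene
# models, CRMs, planted binding sites, truth chains/alignments derived from
# the recorded homology map (never inferred), and replicate DamID read sets.
#
# Homology bookkeeping: every node carries, besides its base vector, a
# strictly increasing numeric id per position. Ancestral positions have ids
# 1..L; inserted bases get fractional ids between their neighbours (with
# random jitter, so independent insertions on different branches never
# collide). Substitutions keep the id; deletions drop it. Chains and true
# alignments fall out of matching ids between species.

#' Phylogeny specification for the simulator
#'
#' @param newick Newick string (or an `ape::phylo` object) with branch
#'   lengths in expected neutral substitutions per site.
#' @param constraint_factor Relative substitution rate inside constrained
#'   (conserved-class) motifs, in `[0, 1]`; default 0.1.
#' @return A `phylogeny_spec`: list with the `ape::phylo` tree, `species`
#'   (tip labels) and `constraint_factor`.
#' @export
phylogeny_spec <- function(newick = "((mel:0.05,sim:0.05):0.15,yak:0.2);",
                           constraint_factor = 0.1) {
  tree <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    abort("tree must have non-negative branch lengths")
  stopifnot(constraint_factor >= 0, constraint_factor <= 1)
  structure(list(tree = tree, species = tree$tip.label,
                 constraint_factor = constraint_factor),
            class = "phylogeny_spec")
}

# JC69 substitution: each site changes with prob 3/4 (1 - exp(-4b/3)),
# uniformly to one of the other three bases. The transition matrix composes
# exactly along consecutive branches.
jc_substitute <- function(seq, b, rate_factor = 1) {
  if (b <= 0 || rate_factor <= 0) return(seq)
  p_change <- 0.75 * (1 - exp(-4 * b * rate_factor / 3))
  mut <- which(runif(length(seq)) < p_change)
  if (length(mut)) {
    shift <- sample.int(3L, length(mut), replace = TRUE)
    seq[mut] <- ((seq[mut] - 1L + shift) %% 4L) + 1L
  }
  seq
}

# One branch of sequence evolution: substitutions plus short indels outside
# protected ancestral positions. `protected` is a logical vector over
# ancestral ids.
evolve_branch <- function(seq, ids, b, protected,
                          indel_rate = 0.1, mean_indel = 3) {
  seq <- jc_substitute(seq, b)
  L <- length(seq)
  if (b <= 0 || L == 0) return(list(seq = seq, ids = ids))
  is_protected <- function(id) {
    ii <- id == floor(id) & id >= 1 & id <= length(protected)
    out <- logical(length(id))
    out[ii] <- protected[id[ii]]
    out
  }
  n_del <- rpois(1, 0.5 * indel_rate * b * L)
  n_ins <- rpois(1, 0.5 * indel_rate * b * L)
  drop <- logical(L)
  if (n_del > 0) {
    pos <- sample.int(L, n_del, replace = TRUE)
    len <- pmin(rgeom(n_del, 1 / mean_indel) + 1L, 50L)
    keep_ev <- rep(TRUE, n_del)
    for (k in seq_len(n_del)) {
      span <- pos[k]:min(L, pos[k] + len[k] - 1L)
      if (any(is_protected(ids[span])) || any(drop[span])) {
        keep_ev[k] <- FALSE
        next
      }
      drop[span] <- TRUE
    }
  }
  ins_ids <- numeric(0)
  ins_seq <- integer(0)
  if (n_ins > 0) {
    anchors <- sample.int(L, n_ins, replace = TRUE)
    lens <- pmin(rgeom(n_ins, 1 / mean_indel) + 1L, 50L)
    for (k in seq_len(n_ins)) {
      a <- anchors[k]
      if (is_protected(ids[a]) && a < L && is_protected(ids[a + 1L])) next
      lo <- ids[a]
      hi <- if (a < L) ids[a + 1L] else ids[a] + 1
      new_ids <- lo + (hi - lo) * sort(runif(lens[k]))
      ins_ids <- c(ins_ids, new_ids)
      ins_seq <- c(ins_seq, sample.int(4L, lens[k], replace = TRUE))
    }
  }
  final_ids <- c(ids[!drop], ins_ids)
  final_seq <- c(seq[!drop], ins_seq)
  o <- order(final_ids)
  list(seq = final_seq[o], ids = final_ids[o])
}

# place n non-overlapping intervals of the given lengths with at least
# min_gap between them, uniformly; returns start positions or errors
place_nonoverlapping <- function(total_len, lengths, min_gap) {
  n <- length(lengths)
  slack <- total_len - sum(lengths) - (n - 1) * min_gap
  if (slack < 0) abort("infeasible placement: too many features for length")
  cuts <- sort(runif(n, 0, slack))
  starts <- as.integer(floor(cuts)) +
    c(0L, cumsum(head(lengths, -1) + min_gap))
  starts
}

#' Simulate related genomes with annotations and truth chains
#'
#' Generates an ancestral i.i.d. uniform-composition sequence, places
#' non-overlapping genes (2-4 exons each) and candidate binding-site slots
#' in their introns and flanks, then evolves the sequence along the tree
#' with Jukes-Cantor substitutions and short indels (rate 10% of the
#' substitution rate, geometric lengths with mean 3) outside exons and
#' slots. Chains and per-locus alignments are emitted from the recorded
#' homology map, not inferred.
#'
#' @param phylo A `phylogeny_spec`.
#' @param length Ancestral genome length in bp (>= 100 kb recommended).
#' @param n_genes Number of genes.
#' @param n_crms Number of CRM intervals (placed over a random subset of
#'   slots).
#' @param slot_width Width in bp of each candidate site slot.
#' @param slot_spacing Spacing of the candidate-slot grid in bp; slots are
#'   jittered within +/- 200 bp, so neighbouring sites stay far enough
#'   apart for their called intervals not to merge.
#' @param seed Integer seed; fixed seed gives bytewise identical output.
#' @return A `sim_dataset`: list with `phylo`, `species`, `nodes` (per leaf:
#'   `seq` integer bases, `ids` homology ids), `ancestor`, `genes_anc`
#'   (tibble incl. exon offsets), `slots` (tibble), `crms_anc`, `params`.
#' @export
simulate_genomes <- function(phylo, length = 1e6, n_genes = 60,
                             n_crms = 40, slot_width = 80L,
                             slot_spacing = 2200L, seed = 1L) {
  stopifnot(inherits(phylo, "phylogeny_spec"))
  L <- as.integer(length)
  with_seed(seed, {
    anc_seq <- sample.int(4L, L, replace = TRUE)
    # gene placement
    gene_len <- as.integer(runif(n_genes, 3500, 7000))
    gene_start <- place_nonoverlapping(L - 4000L, gene_len, 2000L) + 2000L
    genes <- vector("list", n_genes)
    protected <- logical(L)
    for (g in seq_len(n_genes)) {
      gs <- gene_start[g]
      ge <- gs + gene_len[g]
      n_ex <- sample(2:4, 1)
      ex_len <- as.integer(runif(n_ex, 200, 450))
      # exons spread over the gene: first at the start, last at the end
      gaps <- diff(round(seq(0, gene_len[g] - sum(ex_len), length.out = n_ex + 1)))
      ex_start <- gs + cumsum(c(0L, head(ex_len, -1))) +
        as.integer(cumsum(gaps[seq_len(n_ex)]))
      ex_start[1] <- gs
      exons <- tibble(start = as.integer(ex_start),
                      end = as.integer(ex_start + ex_len))
      exons$end[n_ex] <- min(exons$end[n_ex], ge)
      strand <- sample(c("+", "-"), 1)
      genes[[g]] <- tibble(gene_id = sprintf("g%03d", g), chrom = "chr1",
                           strand = strand, start = gs, end = ge,
                           exons = list(exons))
      for (e in seq_len(nrow(exons)))
        protected[(exons$start[e] + 1L):exons$end[e]] <- TRUE
    }
    genes <- bind_rows(genes)
    # candidate slots on a global jittered grid, outside exons, each
    # assigned to its nearest gene
    grid <- seq(500L, L - 500L - slot_width, by = slot_spacing)
    cand <- as.integer(grid + runif(length(grid), -200, 200))
    all_exons <- genes |> select(gene_id, exons) |> unnest(exons)
    in_exon <- overlaps_any(
      tibble(chrom = "chr1", start = cand, end = cand + slot_width),
      tibble(chrom = "chr1", start = all_exons$start, end = all_exons$end))
    cand <- cand[!in_exon]
    near_gene <- vapply(cand, function(s) {
      d <- interval_distance(s, s + slot_width, genes$start, genes$end)
      genes$gene_id[which.min(d)]
    }, character(1))
    slots <- tibble(slot_id = seq_along(cand), gene_id = near_gene,
                    anc_start = cand,
                    anc_end = cand + as.integer(slot_width))
    for (i in seq_len(nrow(slots)))
      protected[(slots$anc_start[i] + 1L):slots$anc_end[i]] <- TRUE
    # CRMs over a random subset of slots
    crm_slots <- sample(slots$slot_id, min(n_crms, nrow(slots)))
    crms_anc <- tibble(
      crm_id = sprintf("crm%03d", seq_along(crm_slots)),
      slot_id = crm_slots,
      chrom = "chr1",
      start = pmax(0L, slots$anc_start[crm_slots] - 250L),
      end = pmin(L, slots$anc_end[crm_slots] + 250L)
    )
    # evolve along the tree (preorder from the root)
    tree <- phylo$tree
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    node_state <- list()
    node_state[[root]] <- list(seq = anc_seq, ids = as.numeric(seq_len(L)))
    ord <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    # preorder: repeatedly process edges whose parent state exists
    edges <- tree$edge
    elen <- tree$edge.length
    done <- logical(nrow(edges))
    while (!all(done)) {
      ready <- which(!done &
                       vapply(edges[, 1], function(p)
                         !is.null(node_state[p][[1]]), logical(1)))
      for (ei in ready) {
        parent <- edges[ei, 1]
        child <- edges[ei, 2]
        st <- node_state[[parent]]
        node_state[[child]] <- evolve_branch(st$seq, st$ids, elen[ei],
                                             protected)
        done[ei] <- TRUE
      }
    }
    nodes <- setNames(lapply(seq_len(n_tip), function(i) node_state[[i]]),
                      tree$tip.label)
    structure(
      list(phylo = phylo, species = tree$tip.label, nodes = nodes,
           ancestor = list(seq = anc_seq, ids = as.numeric(seq_len(L))),
           genes_anc = genes, slots = slots, crms_anc = crms_anc,
           protected = protected,
           params = list(length = L, n_genes = n_genes, n_crms = n_crms,
                         slot_width = slot_width, seed = seed)),
      class = "sim_dataset"
    )
  })
}

#' Leaf genome sequences of a simulated dataset
#'
#' @param dataset A `sim_dataset`.
#' @param species Species label (default: all).
#' @return A named [Biostrings::DNAStringSet]; each genome is one
#'   chromosome named `chr1`.
#' @export
sim_genomes <- function(dataset, species = NULL) {
  species <- species %||% dataset$species
  seqs <- vapply(species, function(s) {
    paste(DNA[dataset$nodes[[s]]$seq], collapse = "")
  }, character(1))
  out <- lapply(seqs, function(x) {
    g <- Biostrings::DNAStringSet(x)
    names(g) <- "chr1"
    g
  })
  names(out) <- species
  out
}

# Map an ancestral 0-based half-open interval into a species' coordinates.
# Returns c(start, end) or NULL when fully deleted. ids are sorted.
map_anc_interval <- function(ids, s, e) {
  i1 <- findInterval(s + 0.5, ids) + 1L
  i2 <- findInterval(e + 0.5, ids)
  if (i1 > i2) return(NULL)
  c(i1 - 1L, i2)
}

#' Truth chain between two simulated species
#'
#' Aligned blocks are maximal runs of positions sharing homology ids,
#' consecutive in both species. No inference is involved.
#'
#' @param dataset A `sim_dataset`.
#' @param from,to Species labels (chain maps `from` -> `to`).
#' @return A `chain_map` tibble.
#' @export
truth_chain <- function(dataset, from, to) {
  a <- dataset$nodes[[from]]
  b <- dataset$nodes[[to]]
  m <- match(a$ids, b$ids)
  has <- which(!is.na(m))
  if (!length(has)) abort("species share no homologous positions")
  # block breaks where either coordinate jumps
  brk <- c(TRUE, diff(has) != 1L | diff(m[has]) != 1L)
  run <- cumsum(brk)
  src_start <- tapply(has, run, min) - 1L
  src_end <- tapply(has, run, max)
  dst_start <- tapply(m[has], run, min) - 1L
  dst_end <- tapply(m[has], run, max)
  chains <- tibble(
    chain_id = "1", score = as.numeric(length(has)),
    src_chrom = "chr1", src_size = length(a$ids),
    src_start = as.integer(src_start), src_end = as.integer(src_end),
    dst_chrom = "chr1", dst_size = length(b$ids),
    dst_start = as.integer(dst_start), dst_end = as.integer(dst_end),
    reversed = FALSE
  )
  validate_chain_map(chains)
}

#' True multiple alignment of a reference interval
#'
#' Builds the gapped alignment of an interval (given in reference-species
#' coordinates) across species directly from the homology ids.
#'
#' @param dataset A `sim_dataset`.
#' @param ref_species Reference species whose coordinates define the locus.
#' @param start,end 0-based half-open interval on the reference genome.
#' @param species Species to include (default: all).
#' @return A `multiple_alignment` tibble.
#' @export
truth_alignment <- function(dataset, ref_species, start, end,
                            species = NULL) {
  species <- species %||% dataset$species
  ref <- dataset$nodes[[ref_species]]
  if (end > length(ref$ids) || start < 0 || start >= end)
    abort("interval outside reference genome")
  id_lo <- ref$ids[start + 1L]
  id_hi <- ref$ids[end]
  rows <- lapply(species, function(s) {
    nd <- dataset$nodes[[s]]
    i1 <- findInterval(id_lo - 1e-12, nd$ids) + 1L
    i2 <- findInterval(id_hi + 1e-12, nd$ids)
    if (i1 > i2) return(list(ids = numeric(0), seq = integer(0)))
    list(ids = nd$ids[i1:i2], seq = nd$seq[i1:i2])
  })
  names(rows) <- species
  cols <- sort(unique(unlist(lapply(rows, `[[`, "ids"))))
  aln <- vapply(rows, function(r) {
    chars <- rep("-", length(cols))
    hit <- match(r$ids, cols)
    chars[hit] <- DNA[r$seq]
    paste(chars, collapse = "")
  }, character(1))
  validate_alignment(tibble(species = species, seq = unname(aln)))
}

#' Gene models of a simulated species
#'
#' Ancestral gene and exon boundaries are mapped through the homology ids
#' (exons are indel-protected, so they map exactly); introns are re-derived
#' per species.
#'
#' @param dataset A `sim_dataset`.
#' @param species Species label.
#' @return Nested gene-model tibble in the format of [read_gff_genes()].
#' @export
sim_gene_models <- function(dataset, species) {
  ids <- dataset$nodes[[species]]$ids
  ga <- dataset$genes_anc
  out <- vector("list", nrow(ga))
  for (i in seq_len(nrow(ga))) {
    span <- map_anc_interval(ids, ga$start[i], ga$end[i])
    ex_anc <- ga$exons[[i]]
    ex <- bind_rows(lapply(seq_len(nrow(ex_anc)), function(e) {
      r <- map_anc_interval(ids, ex_anc$start[e], ex_anc$end[e])
      tibble(start = r[1], end = r[2])
    }))
    ex <- arrange(ex, start)
    intr <- if (nrow(ex) > 1) {
      tibble(start = head(ex$end, -1), end = ex$start[-1])
    } else tibble(start = integer(), end = integer())
    if (nrow(intr)) {
      intr$rank <- if (ga$strand[i] == "-") rev(seq_len(nrow(intr))) else
        seq_len(nrow(intr))
    } else intr$rank <- integer()
    out[[i]] <- tibble(
      gene_id = ga$gene_id[i], chrom = "chr1", strand = ga$strand[i],
      start = span[1], end = span[2],
      tss = if (ga$strand[i] == "-") span[2] - 1L else span[1],
      exons = list(ex), introns = list(intr)
    )
  }
  bind_rows(out)
}

#' CRM intervals of a simulated species
#'
#' @param dataset A `sim_dataset`.
#' @param species Species label.
#' @return Interval tibble of CRM locations in that species' coordinates.
#' @export
sim_crms <- function(dataset, species) {
  ids <- dataset$nodes[[species]]$ids
  ca <- dataset$crms_anc
  out <- vector("list", nrow(ca))
  for (i in seq_len(nrow(ca))) {
    r <- map_anc_interval(ids, ca$start[i], ca$end[i])
    if (is.null(r)) next
    out[[i]] <- tibble(chrom = "chr1", start = r[1], end = r[2],
                       name = ca$crm_id[i])
  }
  bind_rows(out)
}

#' Plant binding sites with known classes into a simulated dataset
#'
#' Each site consists of 1-`max_instances` PWM consensus-sampled motif
#' instances written into a reserved slot. Motif sequences are evolved
#' along the tree with substitutions only; conserved-class motifs evolve
#' at the phylogeny's constraint factor times the neutral rate, other
#' classes neutrally. Binding activity per species comes from the class:
#' conserved sites are active everywhere, unique sites in one species,
#' turnover sites occupy two distinct slots at the same gene, each active
#' in one species of a sampled pair.
#'
#' @param dataset A `sim_dataset` (modified copy returned).
#' @param pwm_obj A `pwm` used to sample motif instances.
#' @param n_sites Number of sites to plant.
#' @param class_mix Named fractions for `conserved`, `unique`, `turnover`
#'   (must sum to 1).
#' @param factor_mix Named fractions for `common`, `Dichaete`, `SoxN`.
#' @param fold_range Range of enrichment folds (uniform).
#' @param max_instances Maximum motif instances per site.
#' @param seed Integer seed.
#' @return A list: `dataset` (with motif bases written into every leaf) and
#'   `truth` (list of `sites` and `placements` tibbles).
#' @export
plant_sites <- function(dataset, pwm_obj, n_sites = 300,
                        class_mix = c(conserved = 0.3, unique = 0.5,
                                      turnover = 0.2),
                        factor_mix = c(common = 0.5, Dichaete = 0.3,
                                       SoxN = 0.2),
                        fold_range = c(4, 8), max_instances = 3L,
                        seed = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"), inherits(pwm_obj, "pwm"))
  if (abs(sum(class_mix) - 1) > 1e-8) abort("class_mix must sum to 1")
  if (abs(sum(factor_mix) - 1) > 1e-8) abort("factor_mix must sum to 1")
  species <- dataset$species
  tree <- dataset$phylo$tree
  cf <- dataset$phylo$constraint_factor
  w <- pwm_obj$width
  slot_w <- dataset$params$slot_width
  max_inst <- min(max_instances, (slot_w + 2) %/% (w + 2))
  lo_mat <- log_odds(pwm_obj)
  lo_dist <- score_distribution(lo_mat, pwm_obj$background)
  # planted instances are sampled from the PWM conditional on being
  # detectable at the standard match cutoffs (functional sites are
  # high-affinity)
  sample_instance <- function() {
    for (tries in seq_len(200)) {
      inst <- vapply(seq_len(w), function(p)
        sample.int(4L, 1, prob = pwm_obj$probs[, p]), integer(1))
      s <- paste(DNA[inst], collapse = "")
      if (nrow(scan_sequence(s, lo_mat, dist = lo_dist))) return(inst)
    }
    abort("could not sample a detectable motif instance")
  }
  with_seed(seed, {
    n_cls <- pmax(0L, round(n_sites * class_mix))
    n_cls[1] <- n_sites - sum(n_cls[-1])
    cls <- rep(names(class_mix), n_cls)
    n_turn <- sum(cls == "turnover")
    # turnover sites need two slots at the same gene
    by_gene <- split(dataset$slots$slot_id, dataset$slots$gene_id)
    pair_genes <- names(by_gene)[lengths(by_gene) >= 2]
    if (length(pair_genes) < n_turn)
      abort("not enough paired slots for turnover sites")
    turn_genes <- sample(pair_genes, n_turn)
    turn_slots <- lapply(turn_genes, function(g) sample(by_gene[[g]], 2))
    free <- setdiff(dataset$slots$slot_id, unlist(turn_slots))
    # a conserved site at a turnover gene would make the locus positionally
    # conserved and cancel the event, so conserved sites avoid those genes;
    # unique sites occupy distinct slots and cannot cancel it
    n_cons <- sum(cls == "conserved")
    n_uniq <- sum(cls == "unique")
    cons_pool <- setdiff(free, unlist(by_gene[turn_genes]))
    if (length(cons_pool) < n_cons)
      abort("not enough slots for conserved sites")
    cons_slots <- if (n_cons) sample(cons_pool, n_cons) else integer(0)
    uniq_pool <- setdiff(free, cons_slots)
    if (length(uniq_pool) < n_uniq) abort("not enough slots for sites")
    uniq_slots <- if (n_uniq) sample(uniq_pool, n_uniq) else integer(0)
    sites <- list()
    placements <- list()
    writes <- list()
    nodes <- dataset$nodes
    slot_tbl <- dataset$slots
    cons_i <- 0L
    uniq_i <- 0L
    turn_i <- 0L
    for (k in seq_len(n_sites)) {
      class_k <- cls[k]
      fold <- runif(1, fold_range[1], fold_range[2])
      factor_k <- sample(names(factor_mix), 1, prob = factor_mix)
      n_inst <- sample.int(max_inst, 1)
      if (class_k == "turnover") {
        turn_i <- turn_i + 1L
        slot_ids <- turn_slots[[turn_i]]
        pair <- sample(species, 2)
        active <- list(setNames(species %in% pair[1], species),
                       setNames(species %in% pair[2], species))
      } else if (class_k == "conserved") {
        cons_i <- cons_i + 1L
        slot_ids <- cons_slots[cons_i]
        active <- list(setNames(rep(TRUE, length(species)), species))
      } else {
        uniq_i <- uniq_i + 1L
        slot_ids <- uniq_slots[uniq_i]
        one <- sample(species, 1)
        active <- list(setNames(species == one, species))
      }
      rate_factor <- if (class_k == "conserved") cf else 1
      site_id <- sprintf("site%04d", k)
      sl1 <- slot_tbl[slot_tbl$slot_id == slot_ids[1], ]
      sites[[k]] <- tibble(
        site_id = site_id, slot_id = slot_ids[1], gene_id = sl1$gene_id,
        class = class_k, factor_class = factor_k, fold = fold,
        n_instances = n_inst,
        crm = any(slot_ids %in% dataset$crms_anc$slot_id),
        anc_start = sl1$anc_start,
        anc_end = sl1$anc_start + n_inst * (w + 2L)
      )
      for (j in seq_along(slot_ids)) {
        sl <- slot_tbl[slot_tbl$slot_id == slot_ids[j], ]
        anc_positions <- integer(0)
        inst_seqs <- list()
        for (m in seq_len(n_inst)) {
          inst <- sample_instance()
          if (runif(1) < 0.5) inst <- rev(5L - inst)   # reverse complement
          off <- sl$anc_start + (m - 1L) * (w + 2L)
          anc_positions <- c(anc_positions, off + seq_len(w))  # 1-based ids
          inst_seqs[[m]] <- inst
        }
        inst_cat <- unlist(inst_seqs)
        # evolve the motif bases along the tree at the constrained rate
        leaf_bases <- evolve_motif_on_tree(tree, inst_cat, rate_factor)
        writes[[length(writes) + 1L]] <- list(
          site_id = site_id, slot_id = sl$slot_id,
          anc_positions = anc_positions, leaf_bases = leaf_bases,
          anc_start = sl$anc_start,
          anc_end = sl$anc_start + n_inst * (w + 2L),
          active = active[[j]])
      }
    }
    # batch the homology lookups: one binary-search pass per species over
    # all planted positions (findInterval re-validates sortedness per call,
    # so per-slot lookups over megabase id vectors would dominate runtime)
    all_pos <- unlist(lapply(writes, `[[`, "anc_positions"))
    all_bases <- lapply(species, function(s)
      unlist(lapply(writes, function(wr) wr$leaf_bases[[s]])))
    names(all_bases) <- species
    bnd_start <- vapply(writes, `[[`, numeric(1), "anc_start")
    bnd_end <- vapply(writes, `[[`, numeric(1), "anc_end")
    for (s in species) {
      ids <- nodes[[s]]$ids
      idx <- findInterval(all_pos, ids)
      ok <- idx >= 1L & ids[pmax(idx, 1L)] == all_pos
      nodes[[s]]$seq[idx[ok]] <- all_bases[[s]][ok]
      # slot spans in species coordinates (0-based half-open)
      i1 <- findInterval(bnd_start + 0.5, ids) + 1L
      i2 <- findInterval(bnd_end + 0.5, ids)
      placements[[s]] <- tibble(
        site_id = vapply(writes, `[[`, character(1), "site_id"),
        slot_id = vapply(writes, `[[`, integer(1), "slot_id"),
        species = s,
        start = as.integer(i1 - 1L), end = as.integer(i2),
        active = vapply(writes, function(wr) unname(wr$active[s]),
                        logical(1)))
    }
    dataset$nodes <- nodes
    truth <- list(sites = bind_rows(sites),
                  placements = arrange(bind_rows(placements), site_id,
                                       slot_id, species))
    list(dataset = dataset, truth = truth)
  })
}

# Evolve a motif base vector along the tree (substitutions only) at
# rate_factor times the neutral rate; returns per-leaf base vectors.
evolve_motif_on_tree <- function(tree, bases, rate_factor) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  state <- list()
  state[[root]] <- bases
  edges <- tree$edge
  elen <- tree$edge.length
  done <- logical(nrow(edges))
  while (!all(done)) {
    ready <- which(!done & vapply(edges[, 1], function(p)
      !is.null(state[p][[1]]), logical(1)))
    for (ei in ready) {
      state[[edges[ei, 2]]] <- jc_substitute(state[[edges[ei, 1]]],
                                             elen[ei], rate_factor)
      done[ei] <- TRUE
    }
  }
  setNames(lapply(seq_len(n_tip), function(i) state[[i]]),
           tree$tip.label)
}

#' Simulate replicate DamID read sets for one species and factor
#'
#' Per GATC fragment of the species genome, the expected Dam-only control
#' intensity is uniform; the fusion intensity is
#' `background * (1 + (fold - 1) * k(d))` with the triangular kernel
#' `k(d) = max(0, 1 - d/spread)` and `d` the distance from the fragment
#' midpoint to the nearest active planted site of the factor (common-class
#' sites contribute to both factors). Per-replicate fragment counts are
#' negative binomial with dispersion `alpha`, scaled to the target depth;
#' reads (fixed length 50) are placed uniformly within their fragment with
#' random strand.
#'
#' @param dataset A `sim_dataset` (after [plant_sites()]).
#' @param truth Truth object from [plant_sites()].
#' @param species Species label.
#' @param factor `"Dichaete"` or `"SoxN"`.
#' @param depth Reads per sample (>= 10,000 recommended).
#' @param replicates Biological replicates per condition.
#' @param alpha NB dispersion (0 gives Poisson counts).
#' @param spread Kernel half-width in bp.
#' @param read_length Read length in bp.
#' @param include_control Also simulate Dam-only control replicates.
#' @param seed Integer seed.
#' @return List: `reads` (long tibble with `sample` column), `sample_info`.
#' @export
simulate_damid_reads <- function(dataset, truth, species,
                                 factor = "Dichaete", depth = 2e5,
                                 replicates = 3L, alpha = 0.1,
                                 spread = 500, read_length = 50L,
                                 include_control = TRUE, seed = 1L) {
  if (spread <= 0) abort("spread must be positive")
  genome <- sim_genomes(dataset, species)[[species]]
  frags <- gatc_fragment_map(genome)
  chrom_len <- chrom_lengths(genome)[["chr1"]]
  pl <- truth$placements |>
    inner_join(select(truth$sites, site_id, factor_class, fold),
               by = "site_id") |>
    filter(.data$species == !!species, active,
           factor_class %in% c("common", factor))
  mid <- interval_midpoint(frags)
  lam_fus <- rep(1, nrow(frags))
  if (nrow(pl)) {
    centers <- as.integer((pl$start + pl$end) / 2)
    o <- order(centers)
    centers <- centers[o]
    folds <- pl$fold[o]
    i <- findInterval(mid, centers)
    d_left <- ifelse(i >= 1, mid - centers[pmax(i, 1)], Inf)
    d_right <- ifelse(i < length(centers),
                      centers[pmin(i + 1, length(centers))] - mid, Inf)
    nearest <- ifelse(d_left <= d_right, pmax(i, 1),
                      pmin(i + 1, length(centers)))
    d <- pmin(d_left, d_right)
    kern <- pmax(0, 1 - d / spread)
    lam_fus <- 1 + (folds[nearest] - 1) * kern
  }
  lam_ctrl <- rep(1, nrow(frags))
  draw_sample <- function(lam, label) {
    mu <- depth * lam / sum(lam)
    counts <- if (alpha > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / alpha)
    } else rpois(length(mu), mu)
    total <- sum(counts)
    fr <- rep.int(seq_len(nrow(frags)), counts)
    start <- frags$start[fr] +
      floor(runif(total) * (frags$end[fr] - frags$start[fr]))
    tibble(chrom = "chr1", start = as.integer(start),
           end = pmin(as.integer(start) + read_length, chrom_len),
           strand = sample(c("+", "-"), total, replace = TRUE),
           sample = label)
  }
  with_seed(seed, {
    reads <- list()
    info <- list()
    for (r in seq_len(replicates)) {
      lbl <- sprintf("%s_%s_fusion_r%d", species, factor, r)
      reads[[length(reads) + 1L]] <- draw_sample(lam_fus, lbl)
      info[[length(info) + 1L]] <- tibble(
        sample = lbl, condition = "fusion", factor = factor,
        species = species, replicate = r)
    }
    if (include_control) {
      for (r in seq_len(replicates)) {
        lbl <- sprintf("%s_Dam_control_r%d", species, r)
        reads[[length(reads) + 1L]] <- draw_sample(lam_ctrl, lbl)
        info[[length(info) + 1L]] <- tibble(
          sample = lbl, condition = "control", factor = "none",
          species = species, replicate = r)
      }
    }
    list(reads = bind_rows(reads), sample_info = bind_rows(info))
  })
}

#' Simulate a complete comparative DamID experiment
#'
#' The default scenario mirrors the study design the package targets:
#' three species related 1:1:4 in branch length, a 1 Mb genome, 300
#' planted sites, one TF assayed in all species and a second TF in the two
#' close species, three fusion and three Dam-only replicates per species,
#' 200,000 reads per sample.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param phylo A `phylogeny_spec`.
#' @param length,n_genes,n_sites,depth,replicates,alpha,spread See the
#'   component generators.
#' @param pwm_obj PWM for planted motifs (default: [sox_pwm()]).
#' @param soxn_species Species in which the second factor is assayed.
#' @return List: `dataset`, `truth`, `reads` (all samples, long),
#'   `sample_info`, `config`.
#' @export
simulate_damid_experiment <- function(seed = 1L,
                                      phylo = phylogeny_spec(),
                                      length = 1e6,
                                      n_genes = round(length / 7500),
                                      n_sites = 300, depth = 2e5,
                                      replicates = 3L, alpha = 0.1,
                                      spread = 500,
                                      pwm_obj = sox_pwm(),
                                      soxn_species = c("mel", "sim")) {
  dataset <- simulate_genomes(phylo, length = length, n_genes = n_genes,
                              seed = seed)
  planted <- plant_sites(dataset, pwm_obj, n_sites = n_sites,
                         seed = seed + 1L)
  dataset <- planted$dataset
  truth <- planted$truth
  reads <- list()
  info <- list()
  i <- 2L
  for (s in dataset$species) {
    i <- i + 1L
    r <- simulate_damid_reads(dataset, truth, s, factor = "Dichaete",
                              depth = depth, replicates = replicates,
                              alpha = alpha, spread = spread,
                              include_control = TRUE, seed = seed + i)
    reads[[length(reads) + 1L]] <- r$reads
    info[[length(info) + 1L]] <- r$sample_info
    if (s %in% soxn_species) {
      i <- i + 1L
      r2 <- simulate_damid_reads(dataset, truth, s, factor = "SoxN",
                                 depth = depth, replicates = replicates,
                                 alpha = alpha, spread = spread,
                                 include_control = FALSE, seed = seed + i)
      reads[[length(reads) + 1L]] <- r2$reads
      info[[length(info) + 1L]] <- r2$sample_info
    }
  }
  list(dataset = dataset, truth = truth, reads = bind_rows(reads),
       sample_info = bind_rows(info),
       config = damid_config(seed = seed))
}

#' A group B Sox-like position weight matrix
#'
#' A 7-position matrix centred on the CAAAG core that group B Sox HMG
#' domains recognise, used as the default planted motif in simulations
#' (labelled synthetic; it is not a measured matrix).
#'
#' @param pseudocount Pseudocount passed to [pwm()].
#' @return A `pwm` object of width 7.
#' @export
sox_pwm <- function(pseudocount = 0.01) {
  probs <- matrix(c(
    # A     C     G     T
    0.40, 0.25, 0.15, 0.20,   # weak flank
    0.10, 0.65, 0.10, 0.15,   # C
    0.85, 0.05, 0.04, 0.06,   # A
    0.88, 0.04, 0.03, 0.05,   # A
    0.85, 0.04, 0.04, 0.07,   # A
    0.05, 0.06, 0.82, 0.07,   # G
    0.30, 0.10, 0.10, 0.50,   # T/A (factor-preference position)
    0.25, 0.35, 0.15, 0.25,   # weak flank
    0.35, 0.20, 0.20, 0.25,   # weak flank
    0.25, 0.25, 0.25, 0.25    # uniform flank
  ), nrow = 4)
  pwm(probs, name = "sox_synthetic", pseudocount = pseudocount)
}

#' Write a simulated dataset to disk
#'
#' Emits per-species FASTA genomes, GFF3 gene models, CRM BED files, truth
#' chains to the reference species, per-sample read BED files, the truth
#' table (TSV) and a YAML manifest recording the seed and parameters.
#' Round-tripping the files through the package readers reproduces the
#' in-memory objects.
#'
#' @param dataset A `sim_dataset`.
#' @param truth Truth object from [plant_sites()] (optional).
#' @param reads Long read tibble with `sample` column (optional).
#' @param dir Output directory (created if needed).
#' @param ref_species Reference species for chains (default: first).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, truth = NULL, reads = NULL, dir,
                          ref_species = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref_species <- ref_species %||% dataset$species[1]
  genomes <- sim_genomes(dataset)
  for (s in dataset$species) {
    write_fasta(genomes[[s]], file.path(dir, paste0(s, ".fa")))
    write_gff_genes(sim_gene_models(dataset, s),
                    file.path(dir, paste0(s, ".genes.gff3")))
    crm <- sim_crms(dataset, s)
    if (nrow(crm)) write_intervals(crm, file.path(dir, paste0(s, ".crm.bed")))
    if (s != ref_species) {
      write_chain(truth_chain(dataset, s, ref_species),
                  file.path(dir, sprintf("%s_to_%s.chain", s, ref_species)))
    }
  }
  if (!is.null(truth)) {
    readr::write_tsv(truth$sites, file.path(dir, "truth_sites.tsv"))
    readr::write_tsv(truth$placements, file.path(dir, "truth_placements.tsv"))
  }
  if (!is.null(reads)) {
    for (s in unique(reads$sample)) {
      rr <- filter(reads, sample == s)
      write_intervals(
        tibble(chrom = rr$chrom, start = rr$start, end = rr$end,
               name = ".", score = 0, strand = rr$strand),
        file.path(dir, paste0(s, ".reads.bed")))
    }
  }
  manifest <- c(list(package = "damidcompare",
                     species = dataset$species),
                dataset$params)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
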