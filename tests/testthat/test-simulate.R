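# The multi-species simulator: homology bookkeeping, Jukes-Cantor
# calibration, planted-site truth and read generation.

small_phylo <- function() phylogeny_spec("((mel:0.05,sim:0.05):0.1,yak:0.15);")

test_that("zero branch lengths give identical genomes and identity chains", {
  ph <- phylogeny_spec("((mel:0,sim:0):0,yak:0);")
  ds <- simulate_genomes(ph, length = 3e4, n_genes = 3, seed = 2)
  g <- sim_genomes(ds)
  expect_equal(as.character(g$mel[[1]]), as.character(g$sim[[1]]))
  expect_equal(as.character(g$mel[[1]]), as.character(g$yak[[1]]))
  ch <- truth_chain(ds, "mel", "yak")
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$src_start, 0L)
  expect_equal(ch$src_end, 3e4L)
  expect_equal(ch$dst_start, 0L)
})

test_that("pairwise identity matches the Jukes-Cantor closed form", {
  ph <- phylogeny_spec()
  ds <- simulate_genomes(ph, length = 2e5, n_genes = 12, seed = 5)
  for (pair in list(c("mel", "sim", 0.1), c("mel", "yak", 0.4))) {
    a <- ds$nodes[[pair[1]]]
    b <- ds$nodes[[pair[2]]]
    m <- match(a$ids, b$ids)
    has <- !is.na(m)
    ident <- mean(a$seq[has] == b$seq[m[has]])
    d <- as.numeric(pair[3])
    expected <- 0.25 + 0.75 * exp(-4 * d / 3)
    expect_equal(ident, expected, tolerance = 0.02 / expected)
  }
})

test_that("a fixed seed reproduces the dataset exactly", {
  ph <- small_phylo()
  d1 <- simulate_genomes(ph, length = 2e4, n_genes = 2, seed = 9)
  d2 <- simulate_genomes(ph, length = 2e4, n_genes = 2, seed = 9)
  expect_equal(d1$nodes, d2$nodes)
  expect_equal(d1$slots, d2$slots)
  p1 <- plant_sites(d1, sox_pwm(), n_sites = 6, seed = 10)
  p2 <- plant_sites(d2, sox_pwm(), n_sites = 6, seed = 10)
  expect_equal(p1$truth$sites, p2$truth$sites)
  expect_equal(p1$dataset$nodes, p2$dataset$nodes)
  r1 <- simulate_damid_reads(p1$dataset, p1$truth, "mel", depth = 2e4,
                             seed = 11)
  r2 <- simulate_damid_reads(p2$dataset, p2$truth, "mel", depth = 2e4,
                             seed = 11)
  expect_equal(r1$reads, r2$reads)
})

test_that("planted sites record their classes and translate onto orthologs", {
  ph <- small_phylo()
  ds <- simulate_genomes(ph, length = 1e5, n_genes = 10, seed = 13)
  pl <- plant_sites(ds, sox_pwm(), n_sites = 20,
                    class_mix = c(conserved = 0.5, unique = 0.3,
                                  turnover = 0.2), seed = 14)
  truth <- pl$truth
  # n sites recorded = n sites requested
  expect_equal(nrow(truth$sites), 20L)
  expect_equal(dplyr::n_distinct(truth$placements$site_id), 20L)

  # constraint factor 0: conserved-class motifs identical across species
  ph0 <- phylogeny_spec("((mel:0.05,sim:0.05):0.1,yak:0.15);",
                        constraint_factor = 0)
  ds0 <- simulate_genomes(ph0, length = 1e5, n_genes = 10, seed = 13)
  pl0 <- plant_sites(ds0, sox_pwm(), n_sites = 10,
                     class_mix = c(conserved = 1, unique = 0, turnover = 0),
                     seed = 14)
  g0 <- sim_genomes(pl0$dataset)
  wdt <- sox_pwm()$width
  # compare the motif bases only: the 2-bp spacers between instances are
  # ordinary genomic sequence and keep evolving neutrally
  motif_part <- function(seq, n_inst) {
    paste(vapply(seq_len(n_inst), function(m) {
      substr(seq, (m - 1L) * (wdt + 2L) + 1L, (m - 1L) * (wdt + 2L) + wdt)
    }, character(1)), collapse = "")
  }
  for (k in seq_len(nrow(pl0$truth$sites))) {
    site <- pl0$truth$sites[k, ]
    pc <- dplyr::filter(pl0$truth$placements, site_id == site$site_id)
    seqs <- vapply(seq_len(nrow(pc)), function(i) {
      s <- as.character(Biostrings::subseq(g0[[pc$species[i]]][[1]],
                                           pc$start[i] + 1L, pc$end[i]))
      motif_part(s, site$n_instances)
    }, character(1))
    expect_equal(length(unique(seqs)), 1L)
  }

  # every conserved site's placement translates through the truth chain to
  # overlap its orthologous placement
  cons <- dplyr::filter(truth$sites, class == "conserved")
  pls <- dplyr::filter(truth$placements, site_id %in% cons$site_id)
  ch <- truth_chain(pl$dataset, "sim", "mel")
  sim_pl <- dplyr::filter(pls, species == "sim")
  mel_pl <- dplyr::filter(pls, species == "mel")
  rep_ <- translate_intervals(
    tibble::tibble(chrom = "chr1", start = sim_pl$start, end = sim_pl$end),
    ch, 0.7)
  expect_true(all(rep_$status == "mapped"))
  ok <- overlaps_any(
    tibble::tibble(chrom = "chr1", start = rep_$dst_start,
                   end = rep_$dst_end),
    tibble::tibble(chrom = "chr1", start = mel_pl$start, end = mel_pl$end))
  expect_true(all(ok))

  # turnover sites: two placements at the same gene, non-overlapping in
  # orthologous position
  turn <- dplyr::filter(truth$sites, class == "turnover")
  for (sid in turn$site_id) {
    pp <- dplyr::filter(truth$placements, site_id == sid, active)
    expect_equal(nrow(pp), 2L)
    expect_equal(dplyr::n_distinct(pp$slot_id), 2L)
    expect_false(pp$species[1] == pp$species[2])
  }
})

test_that("class mix fractions must sum to one", {
  ph <- small_phylo()
  ds <- simulate_genomes(ph, length = 5e4, n_genes = 5, seed = 1)
  expect_error(plant_sites(ds, sox_pwm(), n_sites = 5,
                           class_mix = c(conserved = 0.5, unique = 0.2,
                                         turnover = 0.2)),
               "sum to 1")
})

test_that("read simulation concentrates fusion signal at planted sites", {
  ph <- small_phylo()
  ds <- simulate_genomes(ph, length = 1e5, n_genes = 10, seed = 17)
  pl <- plant_sites(ds, sox_pwm(), n_sites = 15, fold_range = c(8, 8),
                    class_mix = c(conserved = 1, unique = 0, turnover = 0),
                    factor_mix = c(common = 1, Dichaete = 0, SoxN = 0),
                    seed = 18)
  rd <- simulate_damid_reads(pl$dataset, pl$truth, "mel", depth = 1e5,
                             replicates = 2, alpha = 0.05, spread = 500,
                             seed = 19)
  # totals near the requested depth
  per <- dplyr::count(rd$reads, sample)
  expect_true(all(abs(per$n - 1e5) / 1e5 < 0.05))
  expect_equal(nrow(rd$sample_info), 4L)  # 2 fusion + 2 control

  g <- sim_genomes(pl$dataset)$mel
  frags <- gatc_fragment_map(g)
  fus <- dplyr::filter(rd$reads, grepl("fusion_r1", sample))
  ctl <- dplyr::filter(rd$reads, grepl("control_r1", sample))
  cf <- count_fragment_coverage(frags, fus)
  cc <- count_fragment_coverage(frags, ctl)
  mel_sites <- dplyr::filter(pl$truth$placements, species == "mel")
  centers <- (mel_sites$start + mel_sites$end) / 2
  mid <- (frags$start + frags$end) / 2
  d <- vapply(mid, function(x) min(abs(x - centers)), numeric(1))
  at_site <- d < 100
  far <- d > 1500
  ratio_site <- sum(cf[at_site]) / sum(cc[at_site])
  ratio_far <- sum(cf[far]) / sum(cc[far])
  # 8-fold sites: enrichment concentrates at the site, none far away
  expect_gt(ratio_site, 3)
  expect_lt(ratio_far, 1.3)
  expect_error(simulate_damid_reads(pl$dataset, pl$truth, "mel",
                                    spread = 0), "spread")
})

test_that("emitted datasets round-trip through the package readers", {
  ph <- small_phylo()
  ds <- simulate_genomes(ph, length = 4e4, n_genes = 4, seed = 21)
  pl <- plant_sites(ds, sox_pwm(), n_sites = 8, seed = 22)
  rd <- simulate_damid_reads(pl$dataset, pl$truth, "mel", depth = 5e3,
                             replicates = 1, seed = 23)
  dir <- withr::local_tempdir()
  write_dataset(pl$dataset, pl$truth, rd$reads, dir, ref_species = "mel")

  g <- read_fasta(file.path(dir, "sim.fa"))
  expect_equal(as.character(g[[1]]),
               as.character(sim_genomes(pl$dataset)$sim[[1]]))
  ch_file <- read_chain(file.path(dir, "sim_to_mel.chain"))
  ch_mem <- truth_chain(pl$dataset, "sim", "mel")
  expect_equal(ch_file$src_start, ch_mem$src_start)
  expect_equal(ch_file$dst_end, ch_mem$dst_end)
  genes_file <- read_gff_genes(file.path(dir, "mel.genes.gff3"))
  genes_mem <- sim_gene_models(pl$dataset, "mel")
  expect_equal(genes_file$start, genes_mem$start)
  expect_equal(genes_file$tss, genes_mem$tss)
  expect_equal(genes_file$introns[[1]], genes_mem$introns[[1]])
  mani <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(mani$seed, 21L)
  one <- rd$sample_info$sample[1]
  reads_back <- read_intervals(file.path(dir, paste0(one, ".reads.bed")),
                               "BED6")
  expect_equal(nrow(reads_back),
               sum(rd$reads$sample == one))
})

test_that("true alignments reproduce each species' sequence when ungapped", {
  ph <- small_phylo()
  ds <- simulate_genomes(ph, length = 5e4, n_genes = 5, seed = 25)
  g <- sim_genomes(ds)
  aln <- truth_alignment(ds, "mel", 1000L, 1400L)
  expect_s3_class(aln, "multiple_alignment")
  mel_row <- gsub("-", "", aln$seq[aln$species == "mel"])
  expect_equal(mel_row,
               as.character(Biostrings::subseq(g$mel[[1]], 1001L, 1400L)))
  # every row's ungapped sequence occurs in its species genome
  for (s in c("sim", "yak")) {
    row <- gsub("-", "", aln$seq[aln$species == s])
    if (nchar(row) > 20) {
      expect_equal(
        length(Biostrings::matchPattern(row, g[[s]][[1]])) >= 1, TRUE)
    }
  }
})
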