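# Conservation classification, gene/feature annotation, turnover and the
# category-association tests.

test_that("overlap queries use half-open semantics and match brute force", {
  q <- intervals("c", 10, 20)
  expect_true(overlaps_any(q, intervals("c", 19, 30)))
  expect_false(overlaps_any(q, intervals("c", 20, 30)))
  set.seed(9)
  for (i in 1:5) {
    n <- 100
    qs <- sample(0:900, n, TRUE)
    ss <- sample(0:900, n, TRUE)
    qx <- tibble::tibble(chrom = sample(c("a", "b"), n, TRUE), start = qs,
                         end = qs + sample(1:80, n, TRUE))
    sx <- tibble::tibble(chrom = sample(c("a", "b"), n, TRUE), start = ss,
                         end = ss + sample(1:80, n, TRUE))
    got <- overlaps_any(qx, sx)
    brute <- vapply(seq_len(n), function(k) {
      any(sx$chrom == qx$chrom[k] & sx$start < qx$end[k] &
            sx$end > qx$start[k])
    }, logical(1))
    expect_equal(got, brute)
  }
})

test_that("conservation classification unions species and de-duplicates", {
  same <- intervals("c", 100, 200)
  sets <- list(mel = same, sim = same, yak = same)
  rec <- classify_conservation(sets, "mel")
  expect_equal(rec$category, 3L)
  expect_setequal(rec$species_set[[1]], c("mel", "sim", "yak"))

  dist <- conservation_distribution(sets)
  expect_equal(nrow(dist$representatives), 1L)
  expect_equal(dist$distribution$percent, 100)
  expect_equal(dist$distribution$category, 3L)

  # overlap with neither -> unique; with one -> 2-way
  sets2 <- list(mel = intervals("c", c(100, 500), c(200, 600)),
                sim = intervals("c", 150, 250),
                yak = intervals("c", 900, 950))
  rec2 <- classify_conservation(sets2, "mel")
  expect_equal(rec2$category, c(2L, 1L))
  d2 <- conservation_distribution(sets2)
  expect_equal(sum(d2$distribution$percent), 100)
  expect_equal(sum(d2$distribution$n), 3L)  # {mel+sim}, {mel}, {yak}
})

test_that("nearest-gene annotation breaks ties lexicographically", {
  genes <- toy_genes()
  inside <- annotate_nearest_gene(intervals("chr1", 1200, 1250), genes)
  expect_equal(inside$gene_id, "gA")
  expect_equal(inside$gene_distance, 0L)

  # equidistant between gA (ends 9000) and gB (starts 12000)
  mid <- annotate_nearest_gene(intervals("chr1", 10450, 10550), genes)
  expect_equal(mid$gene_id, "gA")
  expect_true(mid$tie)

  # gene-free chromosome left unannotated
  off <- annotate_nearest_gene(intervals("chrZ", 0, 10), genes)
  expect_true(is.na(off$gene_id))
})

test_that("feature annotation follows promoter > exon > intron precedence", {
  genes <- toy_genes()
  # midpoint in first intron of gA, beyond the promoter window
  fa <- annotate_features(intervals("chr1", 1950, 2050), genes)
  expect_equal(fa$feature, "intron")
  expect_equal(fa$intron_rank, 1L)
  # midpoint 100 bp upstream of gA TSS
  fp <- annotate_features(intervals("chr1", 850, 950), genes)
  expect_equal(fp$feature, "promoter")
  # inside the promoter window the promoter outranks the intron
  fpi <- annotate_features(intervals("chr1", 1250, 1350), genes)
  expect_equal(fpi$feature, "promoter")
  # far from all genes
  fi <- annotate_features(intervals("chr1", 49000, 51000), genes)
  expect_equal(fi$feature, "intergenic")
  # minus-strand gene: genomic-rightmost intron is rank 1
  fb <- annotate_features(intervals("chr1", 15950, 16050), genes)
  expect_equal(fb$feature, "intron")
  expect_equal(fb$intron_rank, 1L)
  # and its second intron sits genomically left
  fb2 <- annotate_features(intervals("chr1", 12950, 13050), genes)
  expect_equal(fb2$intron_rank, 2L)
  # promoter of the minus-strand gene lies genomically right of its TSS
  fbp <- annotate_features(intervals("chr1", 20100, 20200), genes)
  expect_equal(fbp$feature, "promoter")
})

test_that("first-intron enrichment reproduces the chi-squared example", {
  # 50 intronic hits all in rank-1 introns covering 50% of intron length
  genes <- tibble::tibble(
    gene_id = "g", chrom = "c", strand = "+", start = 0L, end = 4000L,
    tss = 0L,
    exons = list(tibble::tibble(start = c(0L, 1100L, 2200L),
                                end = c(100L, 1200L, 4000L))),
    introns = list(tibble::tibble(start = c(100L, 1200L),
                                  end = c(1100L, 2200L), rank = 1:2)))
  ann <- tibble::tibble(chrom = "c", start = seq(150, 1050, length.out = 50),
                        end = seq(160, 1060, length.out = 50),
                        feature = "intron", intron_rank = 1L)
  res <- intron_rank_enrichment(ann, genes)
  expect_equal(res$statistic, 50, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$method, "chi-squared")

  # hits proportional to length: statistic ~ 0
  ann2 <- ann
  ann2$intron_rank <- rep(1:2, 25)
  expect_lt(intron_rank_enrichment(ann2, genes)$statistic, 1e-9)

  # a single intronic hit takes the binomial path
  res3 <- intron_rank_enrichment(ann[1, ], genes)
  expect_equal(res3$method, "binomial")
})

test_that("turnover requires shared gene and zero cross-species overlap", {
  genes <- toy_genes()
  a <- intervals("chr1", 1300, 1400)
  b_far <- intervals("chr1", 2500, 2600)
  ev <- detect_turnover(a, b_far, genes)
  expect_equal(ev$gene_id, "gA")

  # overlapping pair cancels the event
  b_over <- intervals("chr1", 1350, 1450)
  expect_equal(nrow(detect_turnover(a, b_over, genes)), 0L)

  # any overlap at the locus cancels, even with extra non-overlapping
  # intervals
  a2 <- intervals("chr1", c(1300, 5000), c(1400, 5100))
  expect_equal(nrow(detect_turnover(a2, b_over, genes)), 0L)

  # different genes: no shared locus, no event
  b_other <- intervals("chr1", 15300, 15400)
  expect_equal(nrow(detect_turnover(a, b_other, genes)), 0L)
})

test_that("Pearson chi-squared matches the hand computation and reference", {
  res <- chisq_independence(matrix(c(15, 30, 5, 50), 2))
  expect_equal(res$statistic, 9.09, tolerance = 0.01 / 9.09)
  expect_equal(res$df, 1L)
  expect_lt(chisq_independence(matrix(10, 2, 2))$statistic, 1e-12)
  expect_equal(chisq_independence(matrix(5 + 1:8, 2))$df, 3L)
  expect_error(chisq_independence(matrix(c(0, 0, 3, 4), 2)), "degenerate")

  set.seed(77)
  for (i in 1:1000) {
    tab <- matrix(rpois(sample(c(4, 6, 8), 1), 30) + 1, nrow = 2)
    ours <- chisq_independence(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("conservation-by-category cross-tabulates a logical flag", {
  rec <- tibble::tibble(category = rep(c(1L, 3L), c(40, 60)),
                        crm = rep(c(FALSE, TRUE, FALSE, TRUE),
                                  c(30, 10, 20, 40)))
  res <- conservation_by_category(rec, "crm")
  expect_equal(res$df, 1L)
  tab <- attr(res, "table")
  expect_equal(sum(tab), 100)
  expect_error(conservation_by_category(rec, "nope"), "not present")
})

test_that("common/unique partition degenerates correctly and tests classes", {
  a1 <- intervals("c", c(0, 500), c(100, 600))
  # identical factor sets: everything common
  res <- common_unique_analysis(a1, a1, a1, a1, c("D", "S"))
  expect_equal(res$n[res$class == "common"], 2L)
  expect_equal(res$n[res$class != "common"], c(0L, 0L))
  expect_equal(res$rate[res$class == "common"], 1)

  # disjoint factor sets: nothing common
  a2 <- intervals("c", c(1000, 2000), c(1100, 2100))
  res2 <- common_unique_analysis(a1, a2, a1, a2, c("D", "S"))
  expect_equal(res2$n[res2$class == "common"], 0L)
  expect_equal(res2$n[res2$class == "unique_D"], 2L)
})

test_that("ortholog mapping de-duplicates and counts the overlap", {
  tab <- tibble::tibble(from = c("m1", "m2", "m3"),
                        to = c("f1", "f1", "f2"))
  res <- map_targets_via_orthologs(c("m1", "m2"), tab)
  expect_equal(res$mapped, "f1")
  res2 <- map_targets_via_orthologs(c("m1", "m3", "mX"), tab,
                                    reference_set = c("f2", "f3"))
  expect_equal(res2$n_unmapped, 1L)
  expect_equal(res2$overlap, 1L)
})
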