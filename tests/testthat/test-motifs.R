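# PWM machinery: log odds, exact score distributions, scanning, shuffles,
# rank-sum statistics and alignment-based conservation.

test_that("log odds follow the pseudocount formula and shrink toward 0", {
  # uniform column, uniform background, zero pseudocount: all weights 0
  u <- pwm(matrix(0.25, 4, 1), pseudocount = 0)
  expect_equal(unname(log_odds(u)), matrix(0, 4, 1))
  # concentrated column: w[A] = log2(1.0025 / (1.01 * 0.25)) ~ 1.989
  p1 <- pwm(matrix(c(1, 0, 0, 0), 4), pseudocount = 0.01)
  expect_equal(unname(log_odds(p1)["A", 1]),
               log2((1 + 0.01 * 0.25) / (1.01 * 0.25)), tolerance = 1e-12)
  expect_equal(unname(log_odds(p1)["A", 1]), 1.989, tolerance = 1e-3)
  # doubling the pseudocount shrinks every |weight|
  w1 <- log_odds(p1, pseudocount = 0.01)
  w2 <- log_odds(p1, pseudocount = 0.02)
  expect_true(all(abs(w2) <= abs(w1) + 1e-12))
  expect_error(pwm(matrix(c(0.5, 0.5, 0.5, 0.5), 4)), "sum to 1")
})

test_that("score distribution equals exhaustive enumeration up to width 8", {
  grid <- 1e-3
  for (w in c(1, 2, 5, 8)) {
    set.seed(60 + w)
    probs <- matrix(rgamma(4 * w, 1), 4, w)
    probs <- sweep(probs, 2, colSums(probs), "/")
    pw <- pwm(probs)
    lo <- log_odds(pw)
    d <- score_distribution(lo, grid = grid)
    # enumerate all 4^w words on the same grid
    ig <- round(lo / grid)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- rowSums(matrix(ig[cbind(as.vector(words),
                                  rep(1:w, each = nrow(words)))],
                         nrow(words), w))
    # enumeration mass aligned onto the DP grid
    offset <- as.integer(round(d$score[1] / grid))
    expected <- numeric(length(d$prob))
    agg <- tapply(rep(0.25^w, nrow(words)), sc, sum)
    expected[as.integer(names(agg)) - offset + 1L] <- as.numeric(agg)
    expect_equal(d$prob, expected, tolerance = 1e-9)
    # upper-tail p at the maximum score equals the consensus word mass
    smax <- max(sc) * grid
    expect_equal(score_pvalue(d, smax), sum(0.25^w * (sc == max(sc))),
                 tolerance = 1e-9)
  }
  # width-1 uniform background: four point masses of 0.25
  d1 <- score_distribution(log_odds(pwm(matrix(c(.7, .1, .1, .1), 4))))
  expect_equal(sum(d1$prob > 1e-12), 2L)  # .7 and three tied .1 columns
  expect_equal(sum(d1$prob), 1, tolerance = 1e-12)
  expect_error(score_distribution(matrix(0, 4, 21)), "limit")
})

test_that("scanning reports both strands and skips N windows", {
  pm <- strong_pwm()
  hits <- scan_sequence("TTCAAAGTTAA", pm)
  expect_equal(hits$offset, 2L)
  expect_equal(hits$strand, "+")
  expect_gt(hits$score, 4)
  expect_lt(hits$p_value, 1e-4)
  # reverse complement of the consensus matches on the minus strand at the
  # same forward offset
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CAAAGTT")))
  hits2 <- scan_sequence(paste0("TT", rc, "AA"), pm)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$offset, 2L)
  expect_equal(hits2$score, hits$score)
  expect_equal(nrow(scan_sequence("NNNNNNNN", pm)), 0L)
  expect_equal(nrow(scan_sequence("ACG", pm)), 0L)
})

test_that("strand symmetry: a sequence and its reverse complement mirror", {
  set.seed(62)
  pm <- sox_pwm()
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h1 <- scan_sequence(s, pm, score_cutoff = 2, p_cutoff = 0.01)
    h2 <- scan_sequence(rc, pm, score_cutoff = 2, p_cutoff = 0.01)
    expect_equal(nrow(h1), nrow(h2))
    if (nrow(h1)) {
      mirrored <- sort(300 - 10 - h1$offset)
      expect_equal(sort(h2$offset), mirrored)
      expect_equal(sort(h1$score), sort(h2$score))
    }
  }
})

test_that("column shuffling preserves the column multiset and is seeded", {
  pm <- sox_pwm()
  s1 <- shuffle_pwm_columns(pm, seed = 3)
  s2 <- shuffle_pwm_columns(pm, seed = 3)
  expect_equal(s1$probs, s2$probs)
  cols <- function(p) apply(p$probs, 2, paste, collapse = ",")
  expect_setequal(cols(s1), cols(pm))
  one <- pwm(matrix(c(.7, .1, .1, .1), 4))
  expect_equal(shuffle_pwm_columns(one, seed = 1)$probs, one$probs)
})

test_that("interval shuffling preserves lengths and honours exclusions", {
  x <- intervals("c", c(0, 500), c(120, 620))
  cl <- c(c = 1000L)
  s1 <- shuffle_intervals(x, cl, seed = 5)
  s2 <- shuffle_intervals(x, cl, seed = 5)
  expect_equal(s1, s2)
  expect_equal(s1$end - s1$start, x$end - x$start)
  expect_true(all(s1$start >= 0 & s1$end <= 1000))
  # exclusion covering all but one placement forces the position
  excl <- intervals("c", 10, 1000)
  forced <- shuffle_intervals(intervals("c", 0, 10), c(c = 20L),
                              seed = 1, exclude = excl)
  expect_equal(forced$start, 0L)
  expect_error(shuffle_intervals(intervals("c", 0, 50), c(c = 20L)), "longer")
})

test_that("rank-sum test: exact enumeration, midranks, and approximation", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 3)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # all of group 1 above group 2, n = 5 each: two-sided p = 2/252
  r2 <- wilcoxon_rank_sum(6:10, 1:5)
  expect_equal(r2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # identical samples: ties force the normal path, p = 1
  r3 <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r3$p_value, 1)

  # exact path equals subset enumeration for all no-tie cases n <= 12
  set.seed(63)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    nx <- sample(2:(n - 2), 1)
    vals <- sample(1000, n)
    x <- vals[seq_len(nx)]
    y <- vals[-seq_len(nx)]
    got <- wilcoxon_rank_sum(x, y)
    r_all <- rank(c(x, y))
    W <- sum(r_all[seq_len(nx)])
    combos <- combn(n, nx)
    sums <- colSums(matrix(seq_len(n)[combos], nrow = nx))
    p_enum <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    expect_equal(got$p_value, p_enum, tolerance = 1e-12)
    # and agrees with the standard exact implementation
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }

  # the normal path agrees with the standard continuity-corrected
  # approximation on larger samples, with and without ties
  set.seed(64)
  for (i in 1:20) {
    x <- sample(50, 15, replace = i %% 2 == 0)
    y <- sample(60, 18, replace = i %% 2 == 0)
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$method, "normal")
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("motif density is higher in planted than in control sequences", {
  set.seed(65)
  pm <- strong_pwm()
  bgseq <- function() paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                            collapse = "")
  planted <- vapply(1:30, function(i) {
    s <- bgseq()
    for (k in 1:3) {
      pos <- sample(1:190, 1)
      substr(s, pos, pos + 6) <- "CAAAGTT"
    }
    s
  }, character(1))
  controls <- vapply(1:30, function(i) bgseq(), character(1))
  md <- motif_density_compare(planted, controls, pm,
                              background = rep(0.25, 4))
  expect_gt(md$mean1, md$mean2)
  expect_lt(md$test$p_value, 1e-6)

  # identical groups: p ~ 1
  md2 <- motif_density_compare(planted, planted, pm,
                               background = rep(0.25, 4))
  expect_gt(md2$test$p_value, 0.9)
})

test_that("alignment scanning maps matches to columns through gaps", {
  pm <- strong_pwm()
  aln <- validate_alignment(tibble::tibble(
    species = c("a", "b", "c"),
    seq = c("TTCAAAGTTAA", "TTCAAAGTTAA", "TTCAAAGTTAA")))
  m <- scan_alignment(aln, pm, background = rep(0.25, 4))
  expect_equal(nrow(m), 3L)
  expect_equal(unique(m$column), 3L)   # 1-based column of offset 2

  # gap inserted before the motif in one row: same column, shifted offset
  aln2 <- validate_alignment(tibble::tibble(
    species = c("a", "b"),
    seq = c("TT--CAAAGTTAA", "TTGGCAAAGTTAA")))
  m2 <- scan_alignment(aln2, pm, background = rep(0.25, 4))
  expect_equal(unique(m2$column), 5L)
  expect_equal(sort(m2$offset), c(2L, 4L))
  expect_false(any(m2$spans_gap))

  # gap inside the motif in one row: match persists on the ungapped row
  # sequence but its span covers gapped columns and is flagged
  aln3 <- validate_alignment(tibble::tibble(
    species = c("a", "b"),
    seq = c("TTCAA-AGTTAA", "TTCAATAGTTAA")))
  m3 <- scan_alignment(aln3, pm, background = rep(0.25, 4))
  row_a <- m3[m3$species == "a", ]
  expect_equal(nrow(row_a), 1L)
  expect_true(row_a$spans_gap)
})

test_that("positional conservation groups by column and strand", {
  pm <- strong_pwm()
  aln <- validate_alignment(tibble::tibble(
    species = c("a", "b", "c", "d"),
    seq = c("TTCAAAGTTAA", "TTCAAAGTTAA", "TTCAAAGTTAA", "TTCAAAGTTAA")))
  m <- scan_alignment(aln, pm, background = rep(0.25, 4))
  pc <- positional_conservation(m, aln)
  expect_equal(nrow(pc), 1L)
  expect_true(pc$positionally_conserved)
  expect_true(pc$all_species)
  expect_true(pc$perfectly_conserved)
  expect_equal(pc$conservation_rate, 1)

  # matches at different columns in different species are not conserved
  aln2 <- validate_alignment(tibble::tibble(
    species = c("a", "b"),
    seq = c("TTCAAAGTTAAAAAAAAAAAA", "TTTTTTTTTTTTCAAAGTTAA")))
  m2 <- scan_alignment(aln2, pm, background = rep(0.25, 4))
  pc2 <- positional_conservation(m2, aln2)
  expect_true(all(!pc2$positionally_conserved))

  # 2 of 4 species at one column: pairwise conserved, not all-species
  aln3 <- validate_alignment(tibble::tibble(
    species = c("a", "b", "c", "d"),
    seq = c("TTCAAAGTTAA", "TTCAAAGTTAA", "TTGGGGGGGAA", "TTGGGGGGGAA")))
  m3 <- scan_alignment(aln3, pm, background = rep(0.25, 4))
  pc3 <- positional_conservation(m3, aln3)
  expect_true(any(pc3$positionally_conserved & !pc3$all_species))
})

test_that("nucleotide conservation rate applies the gap rule", {
  aln <- validate_alignment(tibble::tibble(
    species = c("a", "b"), seq = c("ACGT", "ACGT")))
  expect_equal(nucleotide_conservation_rate(aln), 1)
  aln2 <- validate_alignment(tibble::tibble(
    species = c("a", "b"), seq = c("ACGT", "ACTT")))
  expect_equal(nucleotide_conservation_rate(aln2), 0.75)
  aln3 <- validate_alignment(tibble::tibble(
    species = c("a", "b"), seq = c("AC-T", "ACTT")))
  expect_equal(nucleotide_conservation_rate(aln3), 0.75)
  expect_equal(nucleotide_conservation_rate(aln3, columns = 3), 0)
  expect_error(nucleotide_conservation_rate(aln3, columns = 9), "outside")
})
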