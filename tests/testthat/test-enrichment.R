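# Size factors, dispersions, the NB Wald test, BH and interval calling.

unit_sf <- function(n) stats::setNames(rep(1, n), paste0("s", seq_len(n)))

test_that("median-of-ratios size factors match the hand computation", {
  m <- cbind(A = c(2, 4, 6), B = c(4, 8, 12))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-3)

  # identical samples get equal factors
  m2 <- cbind(A = c(5, 9, 3), B = c(5, 9, 3))
  expect_equal(unname(diff(estimate_size_factors(m2))), 0)

  # scaling one sample by c multiplies its factor by exactly c
  m3 <- cbind(A = c(5, 9, 3), B = 2.5 * c(5, 9, 3))
  sf3 <- estimate_size_factors(m3)
  expect_equal(unname(sf3["B"] / sf3["A"]), 2.5)

  expect_error(estimate_size_factors(cbind(A = c(0, 1), B = c(1, 0))),
               "positive")
})

test_that("dispersion estimation recovers the generating dispersion", {
  set.seed(3)
  mu <- exp(runif(5000, log(20), log(200)))
  cond <- rep(c("fusion", "control"), each = 3)
  # Poisson data: final dispersion collapses toward the floor
  y <- sapply(1:6, function(i) rpois(5000, mu))
  colnames(y) <- paste0("s", 1:6)
  expect_lte(median(estimate_dispersions(y, condition = cond)$alpha), 0.05)
  # NB alpha = 0.2
  y2 <- sapply(1:6, function(i) rnbinom(5000, mu = mu, size = 5))
  colnames(y2) <- paste0("s", 1:6)
  med <- median(estimate_dispersions(y2, condition = cond)$alpha)
  expect_gte(med, 0.1)
  expect_lte(med, 0.4)
  # constant counts: moment estimate exactly zero, trend floor applies
  y3 <- matrix(7, 10, 6, dimnames = list(NULL, paste0("s", 1:6)))
  d3 <- estimate_dispersions(y3, unit_sf(6), cond)
  expect_true(all(d3$alpha_mom == 0))
  expect_true(all(d3$alpha >= 1e-8))
  expect_error(estimate_dispersions(y3, unit_sf(6),
                                    c("fusion", rep("control", 5))),
               "2 replicates")
})

test_that("Benjamini-Hochberg step-up matches the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(21)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  # NA passthrough
  expect_equal(bh_adjust(c(0.1, NA, 0.5)),
               c(p.adjust(c(0.1, 0.5), "BH")[1], NA,
                 p.adjust(c(0.1, 0.5), "BH")[2]))
})

test_that("NB Wald test: null identity, strong enrichment, zero filter", {
  cond <- rep(c("fusion", "control"), each = 3)
  # fusion == control exactly: log2FC 0, p near 1
  y <- matrix(rep(c(30, 45, 60), 2), nrow = 1,
              dimnames = list(NULL, paste0("s", 1:6)))
  r <- test_enrichment(y, unit_sf(6), dispersions = 0.05, condition = cond)
  expect_equal(r$log2fc, 0, tolerance = 1e-6)
  expect_gt(r$pvalue, 0.99)

  # 10-fold enrichment at vanishing dispersion: log2FC ~ 3.32, tiny p
  y2 <- matrix(c(100, 100, 100, 10, 10, 10), nrow = 1,
               dimnames = list(NULL, paste0("s", 1:6)))
  r2 <- test_enrichment(y2, unit_sf(6), dispersions = 1e-8, condition = cond)
  expect_equal(r2$log2fc, log2(10), tolerance = 1e-4)
  expect_lt(r2$pvalue, 1e-6)

  # oracle: likelihood-ratio test by direct NB likelihood maximization on
  # this instance agrees on significance
  loglik <- function(mu_f, mu_c, alpha = 1e-8) {
    sum(dnbinom(c(100, 100, 100), mu = mu_f, size = 1 / alpha, log = TRUE)) +
      sum(dnbinom(c(10, 10, 10), mu = mu_c, size = 1 / alpha, log = TRUE))
  }
  l_alt <- loglik(100, 10)
  l_null <- loglik(55, 55)
  lrt_p <- pchisq(2 * (l_alt - l_null), df = 1, lower.tail = FALSE)
  expect_lt(lrt_p, 1e-6)

  # all-zero fragments untested and excluded from the BH denominator
  y3 <- rbind(c(100, 100, 100, 10, 10, 10), rep(0, 6), rep(0, 6))
  colnames(y3) <- paste0("s", 1:6)
  r3 <- test_enrichment(y3, unit_sf(6), dispersions = 0.05, condition = cond)
  expect_equal(r3$tested, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(r3$padj[2:3])))
  expect_equal(r3$padj[1], r3$pvalue[1])  # BH over a single tested fragment
})

test_that("interval calling applies the conjunction rule and merge gap", {
  enr <- structure(tibble::tibble(
    frag_id = 1:5, chrom = "c",
    start = c(0L, 150L, 400L, 600L, 800L),
    end = c(100L, 250L, 500L, 700L, 900L),
    base_mean = 50, log2fc = c(2, 2, 2, 2, -1), se = 0.1, stat = 5,
    pvalue = c(1e-5, 1e-5, 1e-5, 0.2, 1e-5),
    padj = c(1e-4, 1e-4, 1e-4, 0.2, 1e-4),
    tested = TRUE, converged = TRUE
  ), class = c("damid_enrichment", class(tibble::tibble())))
  calls <- call_binding_intervals(enr, 0.05, 100L)
  # gaps: 50 <= 100 merges, 150 > 100 does not; frag 4 fails padj,
  # frag 5 fails the log2fc > 0 side of the conjunction
  expect_equal(calls$start, c(0L, 400L))
  expect_equal(calls$end, c(250L, 500L))
  expect_equal(calls$n_fragments, c(2L, 1L))
  expect_equal(calls$frag_ids[[1]], 1:2)

  # adjacent fragments (gap 0) merge
  enr2 <- enr
  enr2$start <- c(0L, 100L, 400L, 600L, 800L)
  enr2$end <- c(100L, 200L, 500L, 700L, 900L)
  expect_equal(call_binding_intervals(enr2, 0.05, 100L)$n_fragments[1], 2L)
})

test_that("interval merging is idempotent, order-independent and disjoint", {
  set.seed(30)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    s <- sample(0:2000, n, replace = TRUE)
    x <- tibble::tibble(chrom = sample(c("a", "b"), n, TRUE),
                        start = s, end = s + sample(10:200, n, TRUE))
    gap <- sample(0:100, 1)
    m1 <- merge_intervals(x, gap)
    m2 <- merge_intervals(x[sample(n), ], gap)
    expect_equal(m1[, c("chrom", "start", "end")],
                 m2[, c("chrom", "start", "end")])
    again <- merge_intervals(m1[, c("chrom", "start", "end")], gap)
    expect_equal(again[, c("chrom", "start", "end")],
                 m1[, c("chrom", "start", "end")])
    # disjoint and sorted within chromosome
    per <- split(m1, m1$chrom)
    for (p in per) {
      if (nrow(p) > 1) expect_true(all(p$start[-1] > head(p$end, -1)))
    }
  }
})

test_that("tidiers summarise enrichment results", {
  cond <- rep(c("fusion", "control"), each = 3)
  set.seed(5)
  y <- matrix(rnbinom(600, mu = 50, size = 10), ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  r <- test_enrichment(y, condition = cond)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "damid_enrichment"))
  gl <- glance(r)
  expect_equal(gl$n_fragments, 100L)
  expect_lte(gl$n_signif_05, 5L)
})
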