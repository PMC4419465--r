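# Shared fixtures. The end-to-end simulated experiment is expensive, so it
# is built lazily once per test run and shared by the tests that need it.

fixture_env <- new.env(parent = emptyenv())

# A small two-block chain used across liftover tests:
# src [0,150) -> dst [0,150) and src [180,300) -> dst [150,270).
two_block_chain <- function() {
  validate_chain_map(tibble::tibble(
    chain_id = "1", score = 1000,
    src_chrom = "chrS", src_size = 400L,
    src_start = c(0L, 180L), src_end = c(150L, 300L),
    dst_chrom = "chrT", dst_size = 400L,
    dst_start = c(0L, 150L), dst_end = c(150L, 270L),
    reversed = FALSE
  ))
}

# identity chain over [0, size)
identity_chain <- function(size = 1000L, chrom = "c", dst_chrom = "d") {
  validate_chain_map(tibble::tibble(
    chain_id = "1", score = size, src_chrom = chrom, src_size = size,
    src_start = 0L, src_end = size, dst_chrom = dst_chrom,
    dst_size = size, dst_start = 0L, dst_end = size, reversed = FALSE
  ))
}

# Random single-chain map on one chromosome: alternating aligned blocks and
# gaps; optionally reversed orientation.
random_chain <- function(n_blocks = 5, reversed = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample(20:80, n_blocks, replace = TRUE)
  src_gap <- sample(0:50, n_blocks - 1, replace = TRUE)
  dst_gap <- sample(0:50, n_blocks - 1, replace = TRUE)
  src_start <- cumsum(c(10L, head(sizes, -1) + src_gap))
  dst_start <- cumsum(c(5L, head(sizes, -1) + dst_gap))
  src_size <- max(src_start + sizes) + 10L
  dst_size <- max(dst_start + sizes) + 10L
  if (reversed) {
    # forward-normalized dst coordinates decrease along src order: place
    # blocks n..1 at ascending forward positions, then read off per block
    rev_sizes <- rev(sizes)
    offs <- cumsum(c(5L, head(rev_sizes, -1) + dst_gap))
    dst_start_fwd <- rev(offs)
    dst_size <- max(dst_start_fwd + sizes) + 10L
    return(validate_chain_map(tibble::tibble(
      chain_id = "1", score = sum(sizes), src_chrom = "A",
      src_size = src_size, src_start = src_start,
      src_end = src_start + sizes, dst_chrom = "B", dst_size = dst_size,
      dst_start = dst_start_fwd, dst_end = dst_start_fwd + sizes,
      reversed = TRUE
    )))
  }
  validate_chain_map(tibble::tibble(
    chain_id = "1", score = sum(sizes), src_chrom = "A",
    src_size = src_size, src_start = src_start, src_end = src_start + sizes,
    dst_chrom = "B", dst_size = dst_size, dst_start = dst_start,
    dst_end = dst_start + sizes, reversed = FALSE
  ))
}

# Gene models built in code (no files): one plus-strand and one minus-strand
# gene, both long enough that their introns lie outside the default
# 2000/500 bp promoter window.
toy_genes <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      gene_id = "gA", chrom = "chr1", strand = "+",
      start = 1000L, end = 9000L, tss = 1000L,
      exons = list(tibble::tibble(start = c(1000L, 4000L, 8800L),
                                  end = c(1200L, 4200L, 9000L))),
      introns = list(tibble::tibble(start = c(1200L, 4200L),
                                    end = c(4000L, 8800L), rank = c(1L, 2L)))
    ),
    tibble::tibble(
      gene_id = "gB", chrom = "chr1", strand = "-",
      start = 12000L, end = 20000L, tss = 19999L,
      exons = list(tibble::tibble(start = c(12000L, 15000L, 19800L),
                                  end = c(12200L, 15200L, 20000L))),
      introns = list(tibble::tibble(start = c(12200L, 15200L),
                                    end = c(15000L, 19800L), rank = c(2L, 1L)))
    )
  )
}

# Strong consensus PWM (width 7) whose consensus CAAAGTT passes the default
# weight-score and p-value cutoffs under uniform background.
strong_pwm <- function() {
  m <- matrix(0.02, 4, 7)
  cons <- match(strsplit("CAAAGTT", "")[[1]], c("A", "C", "G", "T"))
  m[cbind(cons, 1:7)] <- 0.94
  pwm(m, name = "strong")
}

# Lazily built full simulated experiment plus the derived pipeline objects
# shared by the acceptance tests (one seed, built once).
pipeline_fixture <- function() {
  if (!is.null(fixture_env$pipe)) return(fixture_env$pipe)
  ex <- simulate_damid_experiment(seed = 101L)
  genomes <- sim_genomes(ex$dataset)
  call_species <- function(sp, fac = "Dichaete") {
    g <- genomes[[sp]]
    frags <- gatc_fragment_map(g)
    info <- dplyr::filter(ex$sample_info, species == sp,
                          factor %in% c(fac, "none"))
    reads <- dplyr::filter(ex$reads, sample %in% info$sample)
    ct <- assemble_count_table(frags, reads, info, 200L, chrom_lengths(g))
    call_binding_intervals(test_enrichment(ct), 0.05, 100L,
                           species = sp, factor = fac)
  }
  calls <- lapply(stats::setNames(ex$dataset$species, ex$dataset$species),
                  call_species)
  translated <- lapply(c("sim", "yak"), function(sp) {
    ch <- truth_chain(ex$dataset, sp, "mel")
    mapped_intervals(translate_intervals(
      calls[[sp]][, c("chrom", "start", "end")], ch, 0.7))
  })
  names(translated) <- c("sim", "yak")
  fixture_env$pipe <- list(ex = ex, genomes = genomes, calls = calls,
                           translated = translated)
  fixture_env$pipe
}
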