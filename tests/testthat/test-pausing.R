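# Pausing indices, read-through ratio, expression filter, and the paired
# signed-rank comparison.

regions_for <- function(start, end, strand = "+") {
  define_regions(make_genes("g", "c", start, end, strand))
}

test_that("window counts are strand-matched and zero off-track", {
  r <- regions_for(1000, 2000)
  empty <- make_track(character(), character(), integer(), numeric())
  wc <- window_counts(empty, r)
  expect_true(all(unlist(wc[, -1]) == 0))
  # value 3 exactly at the TES base: tesr counts it, rt does not
  tr <- make_track("c", "+", 1999, 3)
  wc <- window_counts(tr, r)
  expect_equal(wc$tesr_count, 3)
  expect_equal(wc$rt_count, 0)
  # antisense-only signal counts nothing
  anti <- make_track("c", "-", c(1050, 1950), c(5, 5))
  expect_true(all(unlist(window_counts(anti, r)[, -1]) == 0))
})

test_that("TPP index is the TESr/GB density ratio", {
  r <- regions_for(0, 1250)   # tssr 150, gb 1000, tesr 100
  counts <- data.frame(gene_id = "g", tssr_count = 0, gb_count = 5,
                       tesr_count = 50, tss200_count = 0, rt_count = 0)
  expect_equal(tpp_index(counts, r, pseudocount = 0), 100)  # 0.5 / 0.005
  counts$gb_count <- 0; counts$tesr_count <- 10
  expect_equal(tpp_index(counts, r, pseudocount = 1), 100)  # 0.1 / 0.001
  # uniform density gives 1.0 at pseudocount 0
  dens <- 0.4
  counts2 <- data.frame(gene_id = "g", tssr_count = 150 * dens,
                        gb_count = 1000 * dens, tesr_count = 100 * dens,
                        tss200_count = 0, rt_count = 0)
  expect_equal(tpp_index(counts2, r, pseudocount = 0), 1.0)
  expect_equal(ppp_index(counts2, r, pseudocount = 0), 1.0)
  # raw-sum variant has no length correction
  expect_equal(tpp_index(counts2, r, pseudocount = 0, variant = "rawsum"),
               100 * dens / (1000 * dens))
  # ineligible gene yields NA
  rshort <- define_regions(make_genes("g", "c", 0, 120, "+"))
  expect_true(is.na(tpp_index(counts, rshort, 0)))
})

test_that("PPP index mirrors TPP with the TSS-proximal window", {
  g <- make_genes("g", "c", 0, 750, "+")
  r <- define_regions(g)   # tssr 150, gb 500, tesr 100
  counts <- data.frame(gene_id = "g", tssr_count = 30, gb_count = 10,
                       tesr_count = 0, tss200_count = 0, rt_count = 0)
  expect_equal(ppp_index(counts, r, pseudocount = 0), 10)  # 0.2 / 0.02
  counts$tssr_count <- 0
  expect_equal(ppp_index(counts, r, pseudocount = 0), 0)
})

test_that("read-through ratio supports both denominators", {
  counts <- data.frame(gene_id = "g", tssr_count = 0, gb_count = 40,
                       tesr_count = 0, tss200_count = 80, rt_count = 20)
  expect_equal(readthrough_ratio(counts), 0.25)
  expect_equal(readthrough_ratio(counts, "genebody"), 0.5)
  counts$rt_count <- 80
  expect_equal(readthrough_ratio(counts), 1.0)
  counts$tss200_count <- 0
  expect_true(is.na(readthrough_ratio(counts)))   # zero denominator drops
})

test_that("expression filter uses a strict threshold", {
  rec <- data.frame(tss200_count = c(11, 10, 9))
  out <- filter_expressed(rec, threshold = 10)
  expect_equal(out$passes_filter, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(filter_expressed(rec[0, , drop = FALSE])), 0L)
})

test_that("signed-rank test matches exhaustive enumeration", {
  # all-zero differences
  expect_warning(w <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(w$p_value, 1)
  # n = 6, all differences one-sided: p = 2/64
  w6 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
  expect_equal(w6$p_value, 2 / 64)
  # n = 5 mixed-sign case against the brute-force oracle
  a <- c(1, 2, 3, 4, 0); b <- c(0, 0, 0, 0, 5)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, brute_signed_rank_p(a, b))
  # random fixtures, n <= 12, including ties in |d|
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    x <- sample(-5:5, n, replace = TRUE)
    y <- sample(-5:5, n, replace = TRUE)
    if (all(x == y)) next
    got <- suppressWarnings(wilcoxon_signed_rank(x, y)$p_value)
    expect_equal(got, brute_signed_rank_p(x, y),
                 label = sprintf("rep %d", rep))
  }
})

test_that("large-n path agrees with the continuity-corrected normal test", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  got <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(got$method, "normal_approximation")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("condition comparison pairs by gene id and reports medians", {
  a <- setNames(c(5, 4, 3, 9), c("g1", "g2", "g3", "gX"))
  b <- setNames(c(1, 2, 1, 7), c("g2", "g3", "g4", "g1"))
  cc <- compare_conditions(a, b)
  expect_equal(cc$n_pairs, 3L)      # g1, g2, g3 overlap
  expect_equal(cc$median_a, 4)
  expect_equal(cc$median_b, 2)  # b-values of g1, g2, g3 are 7, 1, 2
  expect_error(compare_conditions(setNames(1, "a"), setNames(1, "b")),
               "no overlapping genes")
})

test_that("indices are invariant to global track rescaling; the filter is not", {
  g <- simulate_genome(sim_genome_config(n_rdh = 6, n_snrna = 2,
                                         n_snorna = 0, n_protein = 2),
                       seed = 2)
  truth <- sim_truth(g$genes)
  aln <- simulate_proseq(g, truth, reads_per_gene = 2000, seed = 4)
  tr <- three_prime_pileup(aln)
  r <- define_regions(g$genes, contig_lengths = g$contigs)
  raw <- pausing_stats(tr, r, pseudocount = 0)
  sc <- scale_track(tr, structure(list(mode = "spike_coverage", value = 0.37),
                                  class = "normalization_factor"))
  scaled <- pausing_stats(sc, r, pseudocount = 0,
                          filter_threshold = 10 * 0.37)
  expect_equal(scaled$tpp_index, raw$tpp_index)
  expect_equal(scaled$ppp_index, raw$ppp_index)
  expect_equal(scaled$readthrough_ratio, raw$readthrough_ratio)
  # the expression filter depends on the scale
  plain_scaled <- pausing_stats(sc, r, pseudocount = 0)
  expect_true(sum(plain_scaled$passes_filter) <= sum(raw$passes_filter))
})

test_that("median TPP increases with the simulated TES-pause weight", {
  g <- simulate_genome(sim_genome_config(n_rdh = 10, n_snrna = 0,
                                         n_snorna = 0, n_protein = 0,
                                         n_rrna = 0),
                       seed = 3)
  r <- define_regions(g$genes, contig_lengths = g$contigs)
  med_for <- function(w3, seed) {
    truth <- sim_truth(g$genes, spike_fraction = 0.01)
    truth$params$w5 <- 0.1
    truth$params$rho <- 0.05
    truth$params$w3 <- w3
    truth$params$wgb <- 1 - 0.1 - 0.05 - w3
    aln <- simulate_proseq(g, truth, reads_per_gene = 1500, seed = seed)
    tbl <- pausing_stats(three_prime_pileup(aln), r, pseudocount = 0)
    median(tbl$tpp_index, na.rm = TRUE)
  }
  meds <- sapply(c(0.05, 0.2, 0.5), function(w3)
    mean(sapply(1:20, function(s) med_for(w3, s))))
  expect_true(meds[1] < meds[2])
  expect_true(meds[2] < meds[3])
})
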