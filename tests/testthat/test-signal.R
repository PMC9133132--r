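# 3'-end pileup construction, normalization factors, and track I/O.

test_that("the last-base rule places the 3' end by read orientation", {
  tr_plus <- three_prime_pileup(make_aln("c", 100, 130, "+"))
  expect_equal(window_sum(tr_plus, "c", 129, 130, "+"), 1)
  expect_equal(track_total(tr_plus), 1)
  tr_minus <- three_prime_pileup(make_aln("c", 100, 130, "-"))
  expect_equal(window_sum(tr_minus, "c", 100, 101, "-"), 1)
  # additivity of identical alignments
  two <- three_prime_pileup(make_aln("c", c(100, 100), c(130, 130), "+"))
  expect_equal(window_sum(two, "c", 129, 130, "+"), 2)
  expect_equal(track_total(two), 2)
})

test_that("mapq and degenerate-span filters exclude records", {
  aln <- make_aln("c", c(0, 10, 20), c(5, 15, 20), "+", mapq = c(60, 5, 60))
  tr <- three_prime_pileup(aln, min_mapq = 10)
  expect_equal(track_total(tr), 1)          # low-mapq and end<=start dropped
  expect_equal(attr(tr, "n_skipped"), 1L)
  empty <- three_prime_pileup(make_aln(character(), integer(), integer(),
                                       character()))
  expect_equal(track_total(empty), 0)
})

test_that("streaming pileup equals the naive per-read oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 2000
    aln <- make_aln(sample(c("c1", "c2"), n, TRUE),
                    start <- sample(0:5000, n, TRUE),
                    start + sample(25:50, n, TRUE),
                    sample(c("+", "-"), n, TRUE),
                    mapq = sample(c(0, 30, 60), n, TRUE))
    tr <- three_prime_pileup(aln, min_mapq = 10)
    oracle <- naive_pileup(aln, min_mapq = 10)
    expect_equal(track_total(tr), oracle$n_used)   # conservation
    df <- as.data.frame(tr)
    got <- setNames(df$value, paste(df$contig, df$strand, df$pos))
    expect_equal(got[order(names(got))],
                 oracle$counts[order(names(oracle$counts))])
  }
})

test_that("strand flip is an involution and is applied before the 3' rule", {
  aln <- make_aln("c", c(100, 200), c(130, 240), c("+", "-"))
  flipped <- three_prime_pileup(aln, flip_strand = TRUE)
  # + read recorded on -, 3' end at alignment start
  expect_equal(window_sum(flipped, "c", 100, 101, "-"), 1)
  expect_equal(window_sum(flipped, "c", 239, 240, "+"), 1)
  plain <- three_prime_pileup(aln)
  # flipping the input strands then flipping again reproduces plain
  aln2 <- aln; aln2$strand <- ifelse(aln2$strand == "+", "-", "+")
  double <- three_prime_pileup(aln2, flip_strand = TRUE)
  expect_equal(as.data.frame(double), as.data.frame(plain))
})

test_that("spike factor follows exogenous-genome coverage arithmetic", {
  aln <- make_aln("dmel", rep(0, 1000), rep(50, 1000), "+")
  f <- spike_normalization_factor(aln, "dmel", 100000, reference_coverage = 1)
  expect_equal(unname(f$evidence["spike_coverage"]), 0.5)
  expect_equal(f$value, 2.0)
  # identical spike alignments in two samples give identical factors
  f2 <- spike_normalization_factor(aln, "dmel", 100000)
  expect_equal(f2$value, f$value)
  expect_error(
    spike_normalization_factor(make_aln("chr1", 0, 50, "+"), "dmel", 1e5),
    "spike-in absent")
})

test_that("doubling the spike share at fixed sample reads halves the factor", {
  g <- simulate_genome(sim_genome_config(n_rdh = 6, n_snrna = 0,
                                         n_snorna = 0, n_protein = 0),
                       seed = 5)
  t1 <- sim_truth(g$genes, spike_fraction = 0.1)
  t2 <- sim_truth(g$genes, spike_fraction = 2 * 0.1 / (1 + 0.1))  # doubled
  # spike_fraction f gives n_spike = f/(1-f) * n_gene; doubling that odds
  # ratio doubles spike reads at fixed gene reads
  a1 <- simulate_proseq(g, t1, reads_per_gene = 3000, seed = 9)
  a2 <- simulate_proseq(g, t2, reads_per_gene = 3000, seed = 9)
  f1 <- spike_normalization_factor(a1, g$spike_contig, 50000)
  f2 <- spike_normalization_factor(a2, g$spike_contig, 50000)
  expect_equal(f2$value / f1$value, 0.5, tolerance = 0.05)
})

test_that("rRNA-million factor counts 3' ends in the rRNA interval", {
  iv <- data.frame(contig = "chrUn", start = 1000L, end = 2000L)
  aln <- make_aln("chrUn", rep(1400, 2e6), rep(1450, 2e6), "+")
  f <- suppressWarnings(rrna_normalization_factor(aln, iv))
  expect_equal(f$value, 0.5)                       # 1e6 / 2e6
  tr <- make_track("chrUn", "+", 1500, 1e6)
  expect_equal(rrna_normalization_factor(tr, iv)$value, 1.0)
  expect_error(rrna_normalization_factor(make_track("chrUn", "+", 10, 5), iv),
               "rRNA denominator empty")
})

test_that("the default rRNA interval is the GRCh38 rDNA scaffold window", {
  expect_equal(RRNA_INTERVAL_DEFAULT$contig, "chrUn_GL000220v1")
  expect_equal(RRNA_INTERVAL_DEFAULT$start, 105424L)
  expect_equal(RRNA_INTERVAL_DEFAULT$end, 118780L)
})

test_that("scaling is linear, refuses double application, and commutes with interval sums", {
  set.seed(31)
  pos <- sample(0:2000, 300)
  tr <- three_prime_pileup(make_aln("c", pos, pos + 30, "+"))
  ident <- scale_track(tr, structure(list(mode = "none", value = 1.0),
                                     class = "normalization_factor"))
  expect_equal(as.data.frame(ident), as.data.frame(tr))
  f2 <- structure(list(mode = "spike_coverage", value = 2.0),
                  class = "normalization_factor")
  sc <- scale_track(tr, f2)
  expect_equal(track_total(sc), 2 * track_total(tr))
  expect_equal(sc$library_units, "spike_normalized")
  expect_error(scale_track(sc, f2), "refusing to scale twice")
  for (win in list(c(0, 500), c(500, 1500), c(1900, 2100))) {
    expect_equal(window_sum(sc, "c", win[1], win[2], "+"),
                 2 * window_sum(tr, "c", win[1], win[2], "+"))
  }
})

test_that("bedGraph export and re-import reproduce the track exactly", {
  set.seed(17)
  n <- 500
  aln <- make_aln("chr9", s <- sample(0:3000, n, TRUE), s + 40,
                  sample(c("+", "-"), n, TRUE))
  tr <- three_prime_pileup(aln)
  prefix <- withr::local_tempfile()
  paths <- write_bedgraph(tr, prefix)
  back <- read_bedgraph(paths[["plus"]], paths[["minus"]])
  expect_equal(as.data.frame(back), as.data.frame(tr), ignore_attr = TRUE)
  # minus-strand values are written negative only in the export layer
  mf <- read.table(paths[["minus"]], sep = "\t")
  expect_true(all(mf$V4 < 0))
})

test_that("SAM/BAM and BED alignment readers agree", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:10000",
    "r1\t0\tchrT\t101\t60\t30M\t*\t0\t0\t*\t*",
    "r2\t16\tchrT\t201\t60\t25M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  a <- read_alignments(sam)
  expect_equal(nrow(a), 2L)   # unmapped record excluded
  expect_equal(a$start, c(100L, 200L))
  expect_equal(a$end, c(130L, 225L))
  expect_equal(a$strand, c("+", "-"))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrT\t100\t130\tr1\t60\t+", "chrT\t200\t225\tr2\t60\t-"), bed)
  b <- read_alignments(bed)
  expect_equal(a[, c("contig", "start", "end", "strand")],
               b[, c("contig", "start", "end", "strand")])
})
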