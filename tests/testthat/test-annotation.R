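# Gene model loading, transcript collapsing, and analysis-window geometry.

test_that("gene-bed loader applies the strand rule for TSS/TES", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t500\t900\tgeneA\t0\t-\tRDH", path)
  g <- load_gene_models(path, "gene-bed")
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 500L)
  expect_equal(g$end, 900L)
  expect_equal(tss(g), 899L)
  expect_equal(tes(g), 500L)
  expect_equal(g$gene_class, "RDH")
})

test_that("GTF loader shifts 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0(
    "chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\t",
    'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'),
    path)
  g <- load_gene_models(path, "gtf")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_equal(g$gene_id, "t1")
  expect_equal(g$gene_class, "protein_coding")
})

test_that("gene-bed and GTF loaders agree on a dual-format fixture", {
  genes <- data.frame(
    gene_id = c("tA", "tB", "tC"), chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 5000L, 20L), end = c(700L, 6200L, 800L),
    strand = c("+", "-", "+"),
    gene_class = c("RDH", "snRNA", "protein_coding"),
    stringsAsFactors = FALSE)
  bed <- write_gene_bed(genes, withr::local_tempfile(fileext = ".bed"))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(sprintf(
    '%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_class "%s";',
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id,
    genes$gene_id, genes$gene_class), gtf)
  a <- load_gene_models(bed, "gene-bed")
  b <- load_gene_models(gtf, "gtf")
  b <- b[match(a$gene_id, b$gene_id), ]
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("malformed records and invalid strands are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tg1\t0\t+\tRDH", "chr1\t5\t50"), path)
  expect_error(load_gene_models(path, "gene-bed"), "line 2")
  writeLines("chr1\t0\t100\tg1\t0\t.\tRDH", path)
  expect_error(load_gene_models(path, "gene-bed"), "strand")
  writeLines(c("chr1\t0\t100\tg1\t0\t+\tRDH",
               "chr1\t200\t300\tg1\t0\t+\tRDH"), path)
  expect_error(load_gene_models(path, "gene-bed"), "duplicate")
})

test_that("transcripts sharing a TSS collapse into one unit", {
  g <- make_genes(c("b", "a"), "chr1", c(100, 100), c(500, 700), "+",
                  c("protein_coding", "RDH"))
  merged <- collapse_shared_ends(g)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 700L)
  expect_equal(merged$gene_id, "a")      # lexicographically first member
  expect_equal(merged$gene_class, "RDH") # class priority
})

test_that("transcripts with no shared end are retained unchanged", {
  g <- make_genes(c("a", "b"), "chr1", c(100, 600), c(500, 900), "+")
  merged <- collapse_shared_ends(g)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$start, c(100L, 600L))
})

test_that("collapsing is transitive across shared-end chains", {
  # A shares TSS with B; B shares TES with C; A and C otherwise distinct
  g <- make_genes(c("A", "B", "C"), "chr1",
                  c(100, 100, 300), c(500, 800, 800), "+")
  merged <- collapse_shared_ends(g)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 800L)
  # same ends on opposite strands or contigs do not merge
  g2 <- make_genes(c("A", "B"), "chr1", c(100, 100), c(500, 700),
                   c("+", "-"))
  expect_equal(nrow(collapse_shared_ends(g2)), 2L)
})

test_that("collapse_shared_ends is idempotent on random gene sets", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 20
    starts <- sample(seq(0, 5000, by = 50), n, replace = TRUE)
    g <- make_genes(sprintf("g%02d", 1:n),
                    sample(c("c1", "c2"), n, TRUE), starts,
                    starts + sample(c(100, 200, 300), n, TRUE),
                    sample(c("+", "-"), n, TRUE))
    once <- collapse_shared_ends(g)
    twice <- collapse_shared_ends(once)
    expect_equal(as.data.frame(twice), as.data.frame(once))
  }
  expect_equal(nrow(collapse_shared_ends(make_genes(character(), character(),
                                                    integer(), integer(),
                                                    character()))), 0L)
})

test_that("analysis windows follow the printed read-through geometry", {
  g <- make_genes("g", "chr1", 1000, 2000, "+")
  r <- define_regions(g)
  expect_equal(c(r$rt_start, r$rt_end), c(2000L, 2200L))
  expect_equal(c(r$tssr_start, r$tssr_end), c(1000L, 1150L))
  expect_equal(c(r$tesr_start, r$tesr_end), c(1900L, 2000L))
  expect_equal(c(r$tss200_start, r$tss200_end), c(1000L, 1200L))
  expect_true(r$eligible)

  gm <- make_genes("g", "chr1", 1000, 2000, "-")
  rm_ <- define_regions(gm)
  expect_equal(c(rm_$rt_start, rm_$rt_end), c(800L, 1000L))
  expect_equal(c(rm_$tssr_start, rm_$tssr_end), c(1850L, 2000L))
  expect_equal(c(rm_$tesr_start, rm_$tesr_end), c(1000L, 1100L))
})

test_that("degenerate geometries are flagged ineligible, not shrunk", {
  short <- define_regions(make_genes("s", "chr1", 0, 120, "+"))
  expect_false(short$eligible)
  expect_match(short$reason, "min_gene_length")
  # long enough for the length floor but gene body would be negative
  gbneg <- define_regions(make_genes("s", "chr1", 0, 200, "+"))
  expect_false(gbneg$eligible)
  expect_match(gbneg$reason, "gene body")
})

test_that("windows clipped at contig bounds are flagged", {
  g <- make_genes("g", "chr1", 100, 600, "+")
  r <- define_regions(g, contig_lengths = c(chr1 = 650L))
  expect_true(r$clipped)
  expect_equal(r$rt_end, 650L)
  r2 <- define_regions(make_genes("g", "chr1", 100, 600, "-"))
  expect_equal(r2$rt_start, 0L)   # clipped at the left edge
  expect_true(r2$clipped)
})

test_that("tssr, gb, tesr tile the transcript with no gap or overlap", {
  set.seed(7)
  for (rep in 1:20) {
    len <- sample(300:3000, 1)
    start <- sample(0:5000, 1)
    strand <- sample(c("+", "-"), 1)
    r <- define_regions(make_genes("g", "c", start, start + len, strand))
    stopifnot(r$eligible)
    covered <- sort(c(seq(r$tssr_start, r$tssr_end - 1),
                      seq(r$gb_start, r$gb_end - 1),
                      seq(r$tesr_start, r$tesr_end - 1)))
    expect_equal(covered, seq(start, start + len - 1))
    expect_equal(length(covered),
                 (r$tssr_end - r$tssr_start) + (r$gb_end - r$gb_start) +
                 (r$tesr_end - r$tesr_start))
  }
})

test_that("define_regions is strand-symmetric under genome reflection", {
  set.seed(11)
  pivot <- 100000L
  for (rep in 1:10) {
    len <- sample(300:2000, 1)
    start <- sample(1000:5000, 1)
    g <- make_genes("g", "c", start, start + len, "+")
    # reflect about the pivot and flip strand
    gr <- make_genes("g", "c", pivot - (start + len), pivot - start, "-")
    r <- define_regions(g)
    rr <- define_regions(gr)
    for (w in c("tssr", "gb", "tesr", "tss200", "rt")) {
      expect_equal(rr[[paste0(w, "_start")]],
                   pivot - r[[paste0(w, "_end")]])
      expect_equal(rr[[paste0(w, "_end")]],
                   pivot - r[[paste0(w, "_start")]])
    }
  }
})

test_that("region sets export as BED6 with window-name suffixes", {
  g <- make_genes(c("g1", "g2"), "chr1", c(1000, 4000), c(2000, 5000), "+")
  path <- withr::local_tempfile(fileext = ".bed")
  regions_to_bed(define_regions(g), path)
  bed <- read.table(path, sep = "\t")
  expect_equal(nrow(bed), 10L)
  expect_true("g1:tesr" %in% bed$V4)
  expect_true(all(bed$V3 > bed$V2))
})
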