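# Ground-truthed synthetic data for every pipeline stage: a small genome
# with classed gene clusters and a spike-in contig, PRO-seq-like alignments
# drawn from a per-gene pausing/read-through mixture, IP/input count pairs,
# and two-channel nuclear-body images with a controlled association
# fraction.
#
# All randomness flows from a single master seed through named substreams,
# so identical seed + config give identical outputs.

.substream <- function(seed, stream) {
  offsets <- c(genome = 104L, reads = 224L, images = 350L,
               sequence = 479L, counts = 611L)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stream]]
}

#' Default synthetic genome configuration
#'
#' Two host contigs each carrying one cluster of replication-dependent
#' histone (RDH)-like genes plus dispersed snRNA, snoRNA and protein-coding
#' genes, a Drosophila-like spike-in contig, and a Pol-I-like rRNA contig
#' with a single heavily transcribed rRNA gene that ignores the
#' alpha-amanitin preset.
#'
#' @param n_rdh,n_snrna,n_snorna,n_protein,n_other,n_rrna per-class gene
#'   counts (RDH genes are split between the two clusters; at most one rRNA
#'   gene, on the rRNA contig).
#' @param rdh_length,snrna_length,snorna_length,protein_length,other_length
#'   length ranges in nt, `c(min, max)`.
#' @param host_contig_length,spike_contig_length,rrna_contig_length contig
#'   sizes in nt.
#' @return a config list consumed by [simulate_genome()].
#' @export
sim_genome_config <- function(n_rdh = 30L, n_snrna = 10L, n_snorna = 10L,
                              n_protein = 20L, n_other = 0L, n_rrna = 1L,
                              rdh_length = c(450L, 700L),
                              snrna_length = c(350L, 600L),
                              snorna_length = c(350L, 600L),
                              protein_length = c(1000L, 3000L),
                              other_length = c(600L, 1500L),
                              host_contig_length = 120000L,
                              spike_contig_length = 50000L,
                              rrna_contig_length = 20000L) {
  list(n = c(RDH = n_rdh, snRNA = n_snrna, snoRNA = n_snorna,
             protein_coding = n_protein, other_noncoding = n_other,
             rRNA = n_rrna),
       length_range = list(RDH = rdh_length, snRNA = snrna_length,
                           snoRNA = snorna_length,
                           protein_coding = protein_length,
                           other_noncoding = other_length),
       host_contig_length = host_contig_length,
       spike_contig_length = spike_contig_length,
       rrna_contig_length = rrna_contig_length,
       cluster_intervals = data.frame(
         contig = c("chrA", "chrB"),
         start = c(10000L, 15000L), end = c(55000L, 60000L),
         stringsAsFactors = FALSE))
}

# place genes sequentially inside [lo, hi) with random gaps; returns starts
.place_genes <- function(lengths, lo, hi, min_gap = 500L) {
  starts <- integer(length(lengths))
  cur <- lo
  for (i in seq_along(lengths)) {
    cur <- cur + min_gap + sample.int(400L, 1L)
    if (cur + lengths[i] > hi)
      stop("gene placement exceeds contig interval; reduce gene number or ",
           "lengths")
    starts[i] <- cur
    cur <- cur + lengths[i]
  }
  starts
}

#' Simulate a small annotated genome
#'
#' RDH-like genes are clustered inside two designated intervals (one per
#' host contig); other classes are dispersed downstream of the clusters.
#' The spike contig carries no genes; the rRNA contig carries one rRNA gene
#' whose body doubles as the rRNA normalization interval.
#'
#' @param config from [sim_genome_config()].
#' @param seed master seed.
#' @return a `sim_genome` list: `contigs` (named lengths), `genes`
#'   (a `gene_models` data.frame), `cluster_intervals`, `rrna_interval`,
#'   `spike_contig`, `seed`.
#' @export
simulate_genome <- function(config = sim_genome_config(), seed = 1L) {
  set.seed(.substream(seed, "genome"))
  contigs <- c(chrA = config$host_contig_length,
               chrB = config$host_contig_length,
               spikeA = config$spike_contig_length,
               rRNA1 = config$rrna_contig_length)
  genes <- list()
  mk <- function(prefix, n, contig, starts, lengths, strands, cls)
    data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
               chrom = contig, start = starts, end = starts + lengths,
               strand = strands, gene_class = cls, stringsAsFactors = FALSE)
  rlen <- function(cls, n) {
    r <- config$length_range[[cls]]
    if (n == 0) integer() else as.integer(r[1] + sample.int(r[2] - r[1] + 1L, n, replace = TRUE) - 1L)
  }
  # RDH genes inside the two cluster intervals
  n_rdh <- config$n[["RDH"]]
  if (n_rdh > 0) {
    n1 <- ceiling(n_rdh / 2); n2 <- n_rdh - n1
    ci <- config$cluster_intervals
    for (k in seq_len(2)) {
      nk <- if (k == 1) n1 else n2
      if (nk == 0) next
      lens <- rlen("RDH", nk)
      starts <- .place_genes(lens, ci$start[k], ci$end[k])
      genes[[length(genes) + 1]] <-
        mk(paste0("rdh", c("A", "B")[k]), nk, ci$contig[k], starts, lens,
           sample(c("+", "-"), nk, replace = TRUE), "RDH")
    }
  }
  # dispersed genes downstream of the cluster on alternating host contigs
  disp <- c("snRNA", "snoRNA", "protein_coding", "other_noncoding")
  pre <- c(snRNA = "snr", snoRNA = "sno", protein_coding = "pcg",
           other_noncoding = "onc")
  cursor <- c(chrA = 56000L, chrB = 61000L)
  for (cls in disp) {
    n <- config$n[[cls]]
    if (n == 0) next
    contig_of <- rep(c("chrA", "chrB"), length.out = n)
    for (ct in c("chrA", "chrB")) {
      nk <- sum(contig_of == ct)
      if (nk == 0) next
      lens <- rlen(cls, nk)
      starts <- .place_genes(lens, cursor[[ct]],
                             config$host_contig_length - 1000L)
      cursor[[ct]] <- max(starts + lens)
      genes[[length(genes) + 1]] <-
        mk(paste0(pre[[cls]], substr(ct, 4, 4)), nk, ct, starts, lens,
           sample(c("+", "-"), nk, replace = TRUE), cls)
    }
  }
  # one heavily transcribed Pol-I-like gene on the rRNA contig
  rrna_iv <- data.frame(contig = "rRNA1", start = 2000L, end = 12000L,
                        stringsAsFactors = FALSE)
  if (config$n[["rRNA"]] > 0)
    genes[[length(genes) + 1]] <-
      data.frame(gene_id = "rrna001", chrom = "rRNA1", start = 2000L,
                 end = 12000L, strand = "+", gene_class = "rRNA",
                 stringsAsFactors = FALSE)
  models <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               gene_class = character(), stringsAsFactors = FALSE)
  models <- models[order(models$chrom, models$start), , drop = FALSE]
  validate_gene_models(models)
  structure(list(contigs = contigs, genes = new_gene_models(models),
                 cluster_intervals = config$cluster_intervals,
                 rrna_interval = rrna_iv, spike_contig = "spikeA",
                 seed = seed),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$contigs), "contigs,", nrow(x$genes),
      "genes (seed", x$seed, ")\n")
  invisible(x)
}

#' Write the synthetic genome as FASTA and gene-bed annotation
#'
#' Sequences are repeat-free uniform random nucleotides, generated
#' deterministically from the genome's seed.
#'
#' @param genome a `sim_genome`.
#' @param fasta_path,bed_path output paths (NULL to skip either).
#' @export
write_genome <- function(genome, fasta_path = NULL, bed_path = NULL) {
  if (!is.null(fasta_path)) {
    set.seed(.substream(genome$seed, "sequence"))
    seqs <- Biostrings::DNAStringSet(vapply(genome$contigs, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), ""))
    names(seqs) <- names(genome$contigs)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  if (!is.null(bed_path)) {
    g <- genome$genes
    utils::write.table(
      data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
                 g$gene_class),
      bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(genome)
}

.class_weights_default <- data.frame(
  gene_class = c("RDH", "snRNA", "snoRNA", "protein_coding",
                 "other_noncoding", "rRNA"),
  w5  = c(0.20, 0.20, 0.20, 0.30, 0.30, 0.02),
  w3  = c(0.40, 0.25, 0.10, 0.05, 0.05, 0.02),
  rho = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.01),
  stringsAsFactors = FALSE)

#' Condition presets and per-gene simulation parameters
#'
#' Builds the per-gene mixture parameters for one simulated condition. Each
#' read's 3' end is drawn from a four-component mixture in transcript
#' coordinates: uniform over the promoter-proximal window (weight `w5`),
#' uniform over the gene body (`wgb`), a discretized Gaussian pause centred
#' `pause3_offset` nt upstream of the TES (`w3`), and a geometric
#' read-through tail past the TES with mean `rt_decay` nt (`rho`).
#'
#' Presets:
#' \describe{
#'   \item{WT}{class-specific baseline weights; RDH genes have the strongest
#'     TES-proximal pause.}
#'   \item{EAF1_mut}{RDH genes lose most of the TES pause (w3 to 0.05*w3)
#'     and double their read-through fraction.}
#'   \item{NELF_KD}{RDH w3 halved; snRNA w3 mildly reduced (x0.85); other
#'     classes untouched.}
#'   \item{alpha_amanitin}{expected read counts of all non-rRNA genes
#'     multiplied by `amanitin_suppression` (default 0.1); the Pol-I-like
#'     rRNA gene is untouched.}
#' }
#'
#' @param genes a `gene_models` data.frame (e.g. from a `sim_genome`).
#' @param condition one of `"WT"`, `"NELF_KD"`, `"EAF1_mut"`,
#'   `"alpha_amanitin"`.
#' @param reads_per_gene expected read count per gene (scalar; the rRNA gene
#'   gets 10x this, rRNA being far more heavily transcribed).
#' @param spike_fraction fraction of all reads on the spike contig (default
#'   0.1: spike-in cells added at 10 percent of the sample cell number).
#' @param pause3_offset,pause_width TES-pause centre (nt upstream of TES)
#'   and Gaussian width.
#' @param rt_decay mean of the geometric read-through tail in nt.
#' @param amanitin_suppression read-count factor for non-rRNA genes under
#'   the alpha_amanitin preset.
#' @return a `sim_truth` list: `params` (per-gene data.frame with
#'   reads_expected, w5, wgb, w3, rho, pause3_offset, pause_width, rt_decay,
#'   suppression), `condition_name`, `spike_fraction`.
#' @export
sim_truth <- function(genes, condition = c("WT", "NELF_KD", "EAF1_mut",
                                           "alpha_amanitin"),
                      reads_per_gene = 1000, spike_fraction = 0.1,
                      pause3_offset = 35L, pause_width = 10L,
                      rt_decay = 50, amanitin_suppression = 0.1) {
  condition <- match.arg(condition)
  cw <- .class_weights_default
  idx <- match(genes$gene_class, cw$gene_class)
  p <- data.frame(gene_id = genes$gene_id, gene_class = genes$gene_class,
                  reads_expected = ifelse(genes$gene_class == "rRNA",
                                          10 * reads_per_gene,
                                          reads_per_gene),
                  w5 = cw$w5[idx], w3 = cw$w3[idx], rho = cw$rho[idx],
                  pause3_offset = pause3_offset, pause_width = pause_width,
                  rt_decay = rt_decay, suppression = 1,
                  stringsAsFactors = FALSE)
  rdh <- p$gene_class == "RDH"
  if (condition == "EAF1_mut") {
    p$w3[rdh] <- 0.05 * p$w3[rdh]
    p$rho[rdh] <- 2 * p$rho[rdh]
  } else if (condition == "NELF_KD") {
    p$w3[rdh] <- 0.5 * p$w3[rdh]
    sn <- p$gene_class == "snRNA"
    p$w3[sn] <- 0.85 * p$w3[sn]
  } else if (condition == "alpha_amanitin") {
    p$suppression[p$gene_class != "rRNA"] <- amanitin_suppression
  }
  p$wgb <- 1 - p$w5 - p$w3 - p$rho
  structure(list(params = p, condition_name = condition,
                 spike_fraction = spike_fraction),
            class = "sim_truth")
}

.validate_sim_params <- function(p) {
  s <- p$w5 + p$wgb + p$w3 + p$rho
  if (any(abs(s - 1) > 1e-9))
    stop("mixture weights must sum to 1 (gene ",
         p$gene_id[which(abs(s - 1) > 1e-9)[1]], ")")
  if (any(p$w5 < 0 | p$wgb < 0 | p$w3 < 0 | p$rho < 0))
    stop("negative mixture weight")
  invisible(p)
}

#' Simulate PRO-seq-like alignments
#'
#' Draws each read's 3' end from the per-gene mixture in `truth` (see
#' [sim_truth()]), attaches a read body of uniform 25-50 nt ending at the 3'
#' end, adds spike-contig reads at the truth's spike fraction, and returns
#' coordinate-sorted BED6-compatible alignments.
#'
#' Per-gene read numbers: with `reads_per_gene` set, exactly that many reads
#' per gene (scaled by the preset's suppression factor); otherwise Poisson
#' around `reads_expected * suppression`, or a multinomial split of
#' `n_reads` proportional to those expectations.
#'
#' @param genome a `sim_genome`.
#' @param truth a `sim_truth`.
#' @param n_reads optional total gene-read count (multinomial allocation).
#' @param reads_per_gene optional exact per-gene read count (scalar or
#'   per-gene vector), overriding `n_reads`.
#' @param seed master seed.
#' @return alignment data.frame (contig, start, end, strand, mapq), sorted,
#'   with the per-gene read counts in the `reads_per_gene` attribute.
#' @export
simulate_proseq <- function(genome, truth, n_reads = NULL,
                            reads_per_gene = NULL, seed = 1L) {
  p <- truth$params
  .validate_sim_params(p)
  genes <- genome$genes
  stopifnot(identical(p$gene_id, genes$gene_id))
  if (!is.null(n_reads) && n_reads <= 0) stop("n_reads must be > 0")
  set.seed(.substream(seed, "reads"))
  lambda <- p$reads_expected * p$suppression
  n_g <- if (!is.null(reads_per_gene)) {
    as.integer(round(rep_len(reads_per_gene, nrow(p)) * p$suppression))
  } else if (!is.null(n_reads)) {
    as.integer(stats::rmultinom(1, n_reads, lambda / sum(lambda)))
  } else {
    stats::rpois(nrow(p), lambda)
  }
  parts <- vector("list", nrow(p) + 1L)
  for (i in seq_len(nrow(p))) {
    n <- n_g[i]
    if (n == 0) next
    L <- genes$end[i] - genes$start[i]
    tssr_len <- min(150L, L)
    tesr_len <- min(100L, L)
    gb0 <- min(tssr_len, L - 1L); gb1 <- max(L - tesr_len, gb0 + 1L)
    comp <- sample.int(4L, n, replace = TRUE,
                       prob = c(p$w5[i], p$wgb[i], p$w3[i], p$rho[i]))
    t <- integer(n)
    k <- comp == 1L
    t[k] <- sample.int(tssr_len, sum(k), replace = TRUE) - 1L
    k <- comp == 2L
    t[k] <- gb0 + sample.int(gb1 - gb0, sum(k), replace = TRUE) - 1L
    k <- comp == 3L
    t[k] <- pmin(pmax(as.integer(round(stats::rnorm(
      sum(k), L - 1L - p$pause3_offset[i], p$pause_width[i]))), 0L), L - 1L)
    k <- comp == 4L
    t[k] <- L - 1L + 1L + stats::rgeom(sum(k), prob = 1 / p$rt_decay[i])
    plus <- genes$strand[i] == "+"
    pos <- if (plus) genes$start[i] + t else genes$end[i] - 1L - t
    clen <- genome$contigs[[genes$chrom[i]]]
    pos <- pmin(pmax(pos, 0L), clen - 1L)
    rl <- sample(25:50, n, replace = TRUE)
    start <- if (plus) pmax(pos - rl + 1L, 0L) else pos
    end <- if (plus) pos + 1L else pmin(pos + rl, clen)
    parts[[i]] <- data.frame(contig = genes$chrom[i], start = start,
                             end = end, strand = genes$strand[i],
                             stringsAsFactors = FALSE)
  }
  n_gene_reads <- sum(n_g)
  f <- truth$spike_fraction
  n_spike <- round(f / (1 - f) * n_gene_reads)
  if (n_spike > 0) {
    clen <- genome$contigs[[genome$spike_contig]]
    pos <- sample.int(clen, n_spike, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_spike, replace = TRUE)
    rl <- sample(25:50, n_spike, replace = TRUE)
    plus <- strand == "+"
    start <- ifelse(plus, pmax(pos - rl + 1L, 0L), pos)
    end <- ifelse(plus, pos + 1L, pmin(pos + rl, clen))
    parts[[nrow(p) + 1L]] <- data.frame(contig = genome$spike_contig,
                                        start = start, end = end,
                                        strand = strand,
                                        stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  aln$mapq <- 60L
  aln <- aln[order(aln$contig, aln$start, aln$end), , drop = FALSE]
  rownames(aln) <- NULL
  attr(aln, "reads_per_gene") <- stats::setNames(n_g, p$gene_id)
  aln
}

#' Write alignments as sorted BED6
#'
#' @param alignments alignment data.frame.
#' @param path output file.
#' @export
write_alignments_bed <- function(alignments, path) {
  a <- alignments[order(alignments$contig, alignments$start,
                        alignments$end), , drop = FALSE]
  utils::write.table(
    data.frame(a$contig, a$start, a$end,
               sprintf("read%07d", seq_len(nrow(a))), a$mapq, a$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate an IP/input per-gene count pair with class-restricted enrichment
#'
#' Input counts are Poisson around `mean_count` per gene; IP counts are
#' Poisson around `mean_count * effect` for genes of `enriched_class` (the
#' nuclear-body-proximal genes) and `mean_count` otherwise.
#'
#' @param genes a `gene_models` data.frame.
#' @param enriched_class gene class receiving the enrichment spike.
#' @param effect IP fold-enrichment for that class (default 4).
#' @param mean_count expected input count per gene.
#' @param seed master seed.
#' @return list: `ip_counts`, `input_counts` (named), `truth` data.frame
#'   with the per-gene enrichment flag.
#' @export
simulate_ip_input <- function(genes, enriched_class = "RDH", effect = 4,
                              mean_count = 200, seed = 1L) {
  set.seed(.substream(seed, "counts"))
  enriched <- genes$gene_class == enriched_class
  input <- stats::rpois(nrow(genes), mean_count)
  ip <- stats::rpois(nrow(genes), mean_count * ifelse(enriched, effect, 1))
  list(ip_counts = stats::setNames(ip, genes$gene_id),
       input_counts = stats::setNames(input, genes$gene_id),
       truth = data.frame(gene_id = genes$gene_id, enriched = enriched,
                          stringsAsFactors = FALSE))
}

.add_blob <- function(img, x, y, sigma, amplitude) {
  r <- ceiling(4 * sigma)
  rows <- max(1L, round(y) + 1L - r):min(nrow(img), round(y) + 1L + r)
  cols <- max(1L, round(x) + 1L - r):min(ncol(img), round(x) + 1L + r)
  dy <- (rows - 1L) - y
  dx <- (cols - 1L) - x
  img[rows, cols] <- img[rows, cols] +
    amplitude * exp(-outer(dy^2, dx^2, `+`) / (2 * sigma^2))
  img
}

.dart_throw <- function(n, lo, hi, min_sep, avoid = NULL, avoid_dist = 0,
                        max_tries = 20000L) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible packing: cannot place ", n,
           " blobs with the requested separation")
    x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
    if (length(xs) &&
        min((xs - x)^2 + (ys - y)^2) < min_sep^2) next
    if (!is.null(avoid) && nrow(avoid) &&
        min((avoid$x - x)^2 + (avoid$y - y)^2) < avoid_dist^2) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  data.frame(x = xs, y = ys)
}

#' Simulate two-channel nuclear-body images with known association fraction
#'
#' Anchor-channel Gaussian blobs are placed uniformly at random (with a
#' margin and a minimum mutual separation). A fraction `f` of anchors
#' receives a partner blob displaced by a random vector of length uniform in
#' [0, 2*sigma] (overlapping); the remaining partner blobs are placed at
#' least 10*sigma from any anchor. Poisson noise is added on top of a flat
#' background.
#'
#' @param n_frames number of frames.
#' @param frame_size frame side length in pixels.
#' @param n_anchors anchor (and partner) blobs per frame.
#' @param sigma blob Gaussian width in pixels.
#' @param f ground-truth association fraction in [0, 1].
#' @param amplitude blob peak intensity (photon counts).
#' @param background flat background intensity.
#' @param noise add Poisson noise (default TRUE).
#' @param seed master seed.
#' @return a `sim_images` list of frames; each frame has `channels` (named
#'   list: anchor, partner) and `truth` (blob table with channel, x, y,
#'   associated flag).
#' @export
simulate_images <- function(n_frames = 1L, frame_size = 256L,
                            n_anchors = 30L, sigma = 2, f = 0.5,
                            amplitude = 100, background = 2, noise = TRUE,
                            seed = 1L) {
  stopifnot(f >= 0, f <= 1, sigma > 0, n_anchors >= 1)
  set.seed(.substream(seed, "images"))
  margin <- 6 * sigma
  frames <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    anchors <- .dart_throw(n_anchors, margin, frame_size - 1 - margin,
                           min_sep = 8 * sigma)
    n_assoc <- round(f * n_anchors)
    assoc_idx <- if (n_assoc > 0) sample.int(n_anchors, n_assoc) else integer()
    theta <- stats::runif(n_assoc, 0, 2 * pi)
    rad <- stats::runif(n_assoc, 0, 2 * sigma)
    partners_assoc <- data.frame(
      x = anchors$x[assoc_idx] + rad * cos(theta),
      y = anchors$y[assoc_idx] + rad * sin(theta))
    n_bg <- n_anchors - n_assoc
    partners_bg <- if (n_bg > 0)
      .dart_throw(n_bg, margin, frame_size - 1 - margin,
                  min_sep = 4 * sigma, avoid = anchors,
                  avoid_dist = 10 * sigma)
    else data.frame(x = numeric(), y = numeric())
    ach <- matrix(0, frame_size, frame_size)
    pch <- matrix(0, frame_size, frame_size)
    for (i in seq_len(n_anchors))
      ach <- .add_blob(ach, anchors$x[i], anchors$y[i], sigma, amplitude)
    for (i in seq_len(nrow(partners_assoc)))
      pch <- .add_blob(pch, partners_assoc$x[i], partners_assoc$y[i],
                       sigma, amplitude)
    for (i in seq_len(nrow(partners_bg)))
      pch <- .add_blob(pch, partners_bg$x[i], partners_bg$y[i],
                       sigma, amplitude)
    if (noise) {
      ach <- matrix(stats::rpois(length(ach), ach + background),
                    frame_size, frame_size)
      pch <- matrix(stats::rpois(length(pch), pch + background),
                    frame_size, frame_size)
    }
    truth <- rbind(
      data.frame(channel = "anchor", x = anchors$x, y = anchors$y,
                 associated = seq_len(n_anchors) %in% assoc_idx),
      data.frame(channel = "partner",
                 x = c(partners_assoc$x, partners_bg$x),
                 y = c(partners_assoc$y, partners_bg$y),
                 associated = rep(c(TRUE, FALSE),
                                  c(nrow(partners_assoc),
                                    nrow(partners_bg)))))
    frames[[fr]] <- list(channels = list(anchor = ach, partner = pch),
                         truth = truth)
  }
  structure(frames, class = "sim_images",
            truth_f = f, sigma = sigma, amplitude = amplitude,
            background = background)
}

#' Write simulated frames as multi-page TIFF files
#'
#' One TIFF per channel per frame, intensities rescaled to [0, 1].
#'
#' @param frames a `sim_images` object.
#' @param dir output directory.
#' @export
write_images_tiff <- function(frames, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF export requires the tiff package")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (fr in seq_along(frames)) {
    for (ch in names(frames[[fr]]$channels)) {
      m <- frames[[fr]]$channels[[ch]]
      tiff::writeTIFF(m / max(m, 1),
                      file.path(dir, sprintf("frame%02d_%s.tiff", fr, ch)))
    }
  }
  invisible(dir)
}
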