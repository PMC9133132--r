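# Independent brute-force oracles and tiny fixture builders shared by the
# test files. Oracles deliberately use a different algorithmic route than
# the package implementation.

# naive per-read 3'-end pileup: one environment entry per (contig, strand,
# pos), incremented read by read
naive_pileup <- function(alignments, min_mapq = 10L, flip_strand = FALSE) {
  env <- new.env(hash = TRUE)
  n_used <- 0L
  for (i in seq_len(nrow(alignments))) {
    if (alignments$end[i] <= alignments$start[i]) next
    if (alignments$mapq[i] < min_mapq) next
    s <- alignments$strand[i]
    if (flip_strand) s <- if (s == "+") "-" else "+"
    pos <- if (s == "+") alignments$end[i] - 1L else alignments$start[i]
    key <- paste(alignments$contig[i], s, pos)
    env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    n_used <- n_used + 1L
  }
  vals <- mget(ls(env), envir = env)
  list(counts = unlist(vals), n_used = n_used)
}

# naive interval sum over a pileup environment result
naive_window_sum <- function(naive, contig, start, end, strand) {
  tot <- 0
  for (key in names(naive$counts)) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    if (parts[1] != contig || parts[2] != strand) next
    pos <- as.integer(parts[3])
    if (pos >= start && pos < end) tot <- tot + naive$counts[[key]]
  }
  tot
}

# exhaustive two-sided signed-rank p-value over all 2^n sign assignments
brute_signed_rank_p <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    t <- sum(r[bits])
    if (abs(t - mu) >= abs(t_obs - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# recursive scanline-free flood fill (8-connected) over a logical mask
flood_fill_labels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# minimal gene_models builder for fixtures
make_genes <- function(gene_id, chrom, start, end, strand,
                       gene_class = "protein_coding") {
  df <- data.frame(gene_id = gene_id,
                   chrom = rep_len(chrom, length(gene_id)),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(strand, length(gene_id)),
                   gene_class = rep_len(gene_class, length(gene_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

# alignment row builder
make_aln <- function(contig, start, end, strand, mapq = 60L) {
  n <- max(length(contig), length(start), length(end), length(strand))
  data.frame(contig = rep_len(contig, n),
             start = as.integer(rep_len(start, n)),
             end = as.integer(rep_len(end, n)),
             strand = rep_len(strand, n),
             mapq = as.integer(rep_len(mapq, n)),
             stringsAsFactors = FALSE)
}

# track with given single-position values
make_track <- function(contig, strand, pos, value,
                       library_units = "raw_reads") {
  track_from_positions(
    data.frame(contig = contig, strand = strand, pos = as.integer(pos),
               value = value, stringsAsFactors = FALSE),
    library_units = library_units)
}

write_gene_bed <- function(df, path) {
  utils::write.table(
    data.frame(df$chrom, df$start, df$end, df$gene_id, 0L, df$strand,
               df$gene_class),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  path
}
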