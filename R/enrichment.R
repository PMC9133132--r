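# Per-gene IP/input enrichment (ChIP-style and in situ biotinylation-seq
# tracks) and fixed-window locus signal (4C-style quantification).

#' Counts-per-million normalization
#'
#' @param counts per-gene raw counts (named numeric).
#' @param library_total total mapped reads in the library.
#' @return per-gene CPM, same names.
#' @export
cpm_normalize <- function(counts, library_total) {
  if (library_total <= 0) stop("library_total must be > 0")
  counts * 1e6 / library_total
}

#' Per-gene IP vs input enrichment
#'
#' Both the ratio (IP + pseudocount)/(input + pseudocount) and the plain
#' difference IP - input (which may be negative) are reported; which is the
#' more informative display depends on the dynamic range of the track.
#'
#' @param ip,input per-gene CPM vectors named by gene id.
#' @param pseudocount added to both terms of the ratio (default 1 CPM).
#' @return data.frame: gene_id, ip_cpm, input_cpm, ratio, difference.
#' @export
per_gene_enrichment <- function(ip, input, pseudocount = 1) {
  if (is.null(names(ip)) || is.null(names(input)))
    stop("ip and input must be named by gene id")
  common <- intersect(names(ip), names(input))
  if (length(common) == 0) stop("disjoint gene sets between ip and input")
  ipc <- ip[common]; inc <- input[common]
  data.frame(gene_id = common, ip_cpm = unname(ipc),
             input_cpm = unname(inc),
             ratio = unname((ipc + pseudocount) / (inc + pseudocount)),
             difference = unname(ipc - inc),
             stringsAsFactors = FALSE)
}

#' Per-gene signal from a coverage-style track
#'
#' Sums track values over each gene's full span; strand-agnostic by default
#' (IP tracks are unstranded).
#'
#' @param track a `signal_track`.
#' @param genes a `gene_models` data.frame.
#' @param stranded match the gene strand instead of summing both strands.
#' @return named numeric vector of per-gene totals.
#' @export
gene_signal <- function(track, genes, stranded = FALSE) {
  v <- vapply(seq_len(nrow(genes)), function(i)
    window_sum(track, genes$chrom[i], genes$start[i], genes$end[i],
               strand = if (stranded) genes$strand[i] else NULL), 0)
  stats::setNames(v, genes$gene_id)
}

#' Built-in histone locus window presets
#'
#' The two replication-dependent histone gene clusters of the human genome,
#' as fixed quantification windows (GRCh38 coordinates):
#' cluster 1 on chromosome 6 (27130000-27150000 and 27801000-27903000) and
#' cluster 2 on chromosome 1 (149780000-149890000).
#'
#' @param name `"histone_cluster_1"` or `"histone_cluster_2"`.
#' @return data.frame with locus_name, contig, start, end.
#' @export
histone_locus_preset <- function(name = c("histone_cluster_1",
                                          "histone_cluster_2")) {
  name <- match.arg(name)
  switch(name,
    histone_cluster_1 = data.frame(
      locus_name = "histone_cluster_1", contig = "chr6",
      start = c(27130000L, 27801000L), end = c(27150000L, 27903000L),
      stringsAsFactors = FALSE),
    histone_cluster_2 = data.frame(
      locus_name = "histone_cluster_2", contig = "chr1",
      start = 149780000L, end = 149890000L,
      stringsAsFactors = FALSE))
}

#' Total signal over a set of locus windows
#'
#' Strand-agnostic sum of track values across all listed intervals (e.g. the
#' total 4C contact signal of a histone locus).
#'
#' @param track a `signal_track`.
#' @param intervals data.frame with contig, start, end (0-based half-open)
#'   and optionally locus_name; or the name of a built-in preset (see
#'   [histone_locus_preset()]).
#' @return a `locus_signal` list: locus_name, intervals, total_signal.
#' @export
window_signal <- function(track, intervals) {
  if (is.character(intervals)) intervals <- histone_locus_preset(intervals)
  stopifnot(all(intervals$end > intervals$start))
  tot <- sum(vapply(seq_len(nrow(intervals)), function(i)
    window_sum(track, intervals$contig[i], intervals$start[i],
               intervals$end[i]), 0))
  nm <- if ("locus_name" %in% names(intervals)) intervals$locus_name[1]
        else "locus"
  structure(list(locus_name = nm, intervals = intervals,
                 total_signal = tot), class = "locus_signal")
}

#' @export
print.locus_signal <- function(x, ...) {
  cat("locus_signal '", x$locus_name, "': total ", format(x$total_signal),
      " over ", nrow(x$intervals), " window(s)\n", sep = "")
  invisible(x)
}

#' Write per-gene enrichment records as TSV
#' @param records data.frame from [per_gene_enrichment()].
#' @param path output file.
#' @export
write_enrichment <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
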