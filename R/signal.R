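# Strand-specific single-nucleotide 3'-end pileup tracks and normalization.
#
# A signal_track stores, per (contig, strand), sorted unique positions and
# their values. Raw tracks hold integer read counts; normalized tracks hold
# scaled values. PRO-seq maps the 3' end of the nascent RNA -- the active
# position of the engaged polymerase -- so only the 3'-most aligned base of
# each read contributes.

#' Read alignments from BED6 or SAM/BAM
#'
#' Returns a plain alignment table (contig, start, end, strand, mapq) in
#' 0-based half-open coordinates. BED6 files carry the mapping quality in the
#' score column. SAM/BAM input is read through Rsamtools/GenomicAlignments;
#' unmapped, secondary and supplementary records are excluded and the aligned
#' span (soft clips excluded) is used.
#'
#' @param path alignment file.
#' @param format `"bed"`, `"sam"` or `"bam"`; default guesses from the file
#'   extension.
#' @return data.frame with columns contig, start, end, strand, mapq.
#' @export
read_alignments <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) ext else "bed"
  }
  format <- match.arg(format, c("bed", "sam", "bam"))
  if (format == "bed") return(.read_alignments_bed(path))
  .read_alignments_bam(path, sam = format == "sam")
}

.read_alignments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end", "name",
                                        "mapq", "strand"))
  data.frame(contig = df$contig, start = as.integer(df$start),
             end = as.integer(df$end), strand = df$strand,
             mapq = as.integer(df$mapq), stringsAsFactors = FALSE)
}

.read_alignments_bam <- function(path, sam = FALSE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("SAM/BAM input requires the Rsamtools and GenomicAlignments packages")
  if (sam) path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flags, what = "mapq"))
  data.frame(
    contig = as.character(GenomicAlignments::seqnames(ga)),
    start  = BiocGenerics::start(ga) - 1L,
    end    = BiocGenerics::end(ga),
    strand = as.character(BiocGenerics::strand(ga)),
    mapq   = S4Vectors::mcols(ga)$mapq,
    stringsAsFactors = FALSE)
}

.track_key <- function(contig, strand) paste0(contig, "|", strand)

new_signal_track <- function(index, sample_id = "sample",
                             library_units = "raw_reads",
                             scale_applied = 1, n_alignments = NA_integer_) {
  structure(list(sample_id = sample_id, index = index,
                 library_units = library_units,
                 scale_applied = scale_applied,
                 n_alignments = n_alignments),
            class = "signal_track")
}

#' Build a 3'-end pileup track from alignments
#'
#' Each accepted alignment contributes +1 at its 3'-most aligned base in read
#' orientation: position end-1 for a plus-strand alignment, position start
#' for a minus-strand alignment. With `flip_strand`, the recorded strand of
#' every alignment is inverted before the 3'-end rule is applied (support for
#' library dialects sequencing the reverse complement of the nascent RNA).
#'
#' Alignments below `min_mapq`, or with end <= start (counted, skipped), are
#' excluded. An empty stream yields an empty track.
#'
#' @param alignments data.frame as from [read_alignments()].
#' @param min_mapq minimum mapping quality (default 10).
#' @param flip_strand invert the alignment strand before taking the 3' end.
#' @param sample_id label stored on the track.
#' @return a `signal_track`.
#' @export
three_prime_pileup <- function(alignments, min_mapq = 10L,
                               flip_strand = FALSE, sample_id = "sample") {
  aln <- alignments
  bad_strand <- !aln$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("unknown strand symbol '", aln$strand[which(bad_strand)[1]], "'")
  degenerate <- aln$end <= aln$start
  n_skipped <- sum(degenerate)
  aln <- aln[!degenerate & aln$mapq >= min_mapq, , drop = FALSE]
  strand <- aln$strand
  if (flip_strand) strand <- ifelse(strand == "+", "-", "+")
  pos <- ifelse(strand == "+", aln$end - 1L, aln$start)
  key <- .track_key(aln$contig, strand)
  index <- lapply(split(pos, key), function(p) {
    tab <- sort(unique(p))
    val <- as.numeric(tabulate(match(p, tab), nbins = length(tab)))
    list(pos = as.integer(tab), val = val, cum = cumsum(val))
  })
  tr <- new_signal_track(index, sample_id = sample_id,
                         n_alignments = nrow(aln))
  attr(tr, "n_skipped") <- n_skipped
  tr
}

#' Total signal in a track
#' @param track a `signal_track`.
#' @export
track_total <- function(track) {
  sum(vapply(track$index, function(z) sum(z$val), 0))
}

#' Sum of track values over a half-open interval
#'
#' @param track a `signal_track`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"`, `"-"`, or `NULL` for strand-agnostic summation.
#' @export
window_sum <- function(track, contig, start, end, strand = NULL) {
  strands <- if (is.null(strand)) c("+", "-") else strand
  tot <- 0
  for (s in strands) {
    z <- track$index[[.track_key(contig, s)]]
    if (is.null(z) || end <= start) next
    i0 <- findInterval(start - 0.5, z$pos)   # positions < start
    i1 <- findInterval(end - 0.5, z$pos)     # positions < end
    if (i1 > i0)
      tot <- tot + z$cum[i1] - (if (i0 > 0) z$cum[i0] else 0)
  }
  tot
}

#' Compute a spike-in normalization factor from exogenous-genome coverage
#'
#' Coverage is total aligned bases on the spike contigs divided by the spike
#' genome length; the factor is `reference_coverage / coverage`, so samples
#' with more spike signal are scaled down.
#'
#' @param alignments alignment data.frame (base lengths are needed, so a
#'   pileup track is not sufficient).
#' @param spike_contigs character vector of spike contig names.
#' @param spike_genome_length spike genome length in nt.
#' @param reference_coverage coverage that maps to factor 1 (default 1.0,
#'   absolute units; pass another sample's measured coverage to make that
#'   sample the reference).
#' @return a `normalization_factor` list: mode, value, evidence.
#' @export
spike_normalization_factor <- function(alignments, spike_contigs,
                                       spike_genome_length,
                                       reference_coverage = 1.0) {
  stopifnot(spike_genome_length > 0)
  sp <- alignments[alignments$contig %in% spike_contigs, , drop = FALSE]
  if (nrow(sp) == 0) stop("spike-in absent: no alignments on spike contigs")
  coverage <- sum(sp$end - sp$start) / spike_genome_length
  structure(list(mode = "spike_coverage",
                 value = reference_coverage / coverage,
                 evidence = c(spike_coverage = coverage,
                              spike_alignments = nrow(sp))),
            class = "normalization_factor")
}

#' Default rRNA interval used for alpha-amanitin sample normalization
#'
#' The rRNA-derived reads used as the denominator are those whose 3' end maps
#' to chrUn_GL000220v1:105424-118780 (a 45S rDNA-bearing scaffold of GRCh38).
#'
#' @export
RRNA_INTERVAL_DEFAULT <- data.frame(
  contig = "chrUn_GL000220v1", start = 105424L, end = 118780L,
  stringsAsFactors = FALSE)

#' Compute an rRNA-million normalization factor
#'
#' For samples in which Pol II is inhibited (alpha-amanitin), spike-in and
#' library-size normalization are confounded by the global loss of Pol II
#' signal; Pol I rRNA reads are used instead. The factor is 1e6 divided by
#' the number of alignments whose 3' end falls inside `rrna_interval`.
#'
#' @param x a `signal_track` or an alignment data.frame.
#' @param rrna_interval data.frame with contig, start, end (0-based
#'   half-open); default [RRNA_INTERVAL_DEFAULT].
#' @return a `normalization_factor`.
#' @export
rrna_normalization_factor <- function(x, rrna_interval = RRNA_INTERVAL_DEFAULT) {
  stopifnot(nrow(rrna_interval) >= 1, rrna_interval$end > rrna_interval$start)
  if (inherits(x, "signal_track")) {
    n <- sum(vapply(seq_len(nrow(rrna_interval)), function(i)
      window_sum(x, rrna_interval$contig[i], rrna_interval$start[i],
                 rrna_interval$end[i]), 0))
  } else {
    pos <- ifelse(x$strand == "+", x$end - 1L, x$start)
    n <- 0L
    for (i in seq_len(nrow(rrna_interval)))
      n <- n + sum(x$contig == rrna_interval$contig[i] &
                   pos >= rrna_interval$start[i] & pos < rrna_interval$end[i])
  }
  if (n == 0) stop("rRNA denominator empty: no reads in the rRNA interval")
  structure(list(mode = "rrna_million", value = 1e6 / n,
                 evidence = c(rrna_reads = n)),
            class = "normalization_factor")
}

#' Apply a normalization factor to a track
#'
#' Every value is multiplied by `factor$value`; positions are unchanged.
#' Scaling an already-normalized track is refused.
#'
#' @param track a raw `signal_track`.
#' @param factor a `normalization_factor`.
#' @return the scaled `signal_track` with `library_units` updated.
#' @export
scale_track <- function(track, factor) {
  if (track$library_units != "raw_reads")
    stop("track already normalized (", track$library_units,
         "); refusing to scale twice")
  track$index <- lapply(track$index, function(z) {
    z$val <- z$val * factor$value
    z$cum <- cumsum(z$val)
    z
  })
  track$scale_applied <- factor$value
  track$library_units <- switch(factor$mode,
    spike_coverage = "spike_normalized",
    rrna_million = "rrna_normalized",
    none = "raw_reads")
  track
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track '", x$sample_id, "': ", length(x$index),
      " contig/strand lane(s), total signal ",
      format(track_total(x)), " (", x$library_units, ")\n", sep = "")
  invisible(x)
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat("normalization_factor [", x$mode, "]: ", format(x$value), "\n", sep = "")
  invisible(x)
}

#' Convert a track to a position-level data.frame
#'
#' @param x a `signal_track`.
#' @param ... unused.
#' @return data.frame with contig, strand, pos, value.
#' @method as.data.frame signal_track
#' @export
as.data.frame.signal_track <- function(x, ...) {
  if (length(x$index) == 0)
    return(data.frame(contig = character(), strand = character(),
                      pos = integer(), value = numeric()))
  parts <- lapply(names(x$index), function(k) {
    cs <- strsplit(k, "|", fixed = TRUE)[[1]]
    z <- x$index[[k]]
    data.frame(contig = cs[1], strand = cs[2], pos = z$pos, value = z$val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out[order(out$contig, out$strand, out$pos), , drop = FALSE]
}

#' Write a track as a pair of bedGraph files
#'
#' Plus- and minus-strand lanes go to separate files; minus-strand values are
#' written negative, a display convention applied only in this export layer.
#'
#' @param track a `signal_track`.
#' @param prefix output path prefix; files are `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph`.
#' @return invisibly, the two file paths.
#' @export
write_bedgraph <- function(track, prefix) {
  df <- as.data.frame(track)
  paths <- c(plus = paste0(prefix, "_plus.bedGraph"),
             minus = paste0(prefix, "_minus.bedGraph"))
  for (s in c("+", "-")) {
    d <- df[df$strand == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = if (nrow(d)) d$contig else character(),
      ranges = IRanges::IRanges(start = d$pos + 1L, width = 1L),
      score = if (s == "-") -d$value else d$value)
    rtracklayer::export(gr, paths[[if (s == "+") "plus" else "minus"]],
                        format = "bedGraph")
  }
  invisible(paths)
}

#' Read a plus/minus bedGraph pair back into a track
#'
#' Inverse of [write_bedgraph()]: minus-file scores are negated back to
#' positive values and ranges are expanded to single positions.
#'
#' @param plus_path,minus_path bedGraph files for the two strands.
#' @param sample_id label for the track.
#' @param library_units units label to restore (bedGraph does not carry it).
#' @return a `signal_track`.
#' @export
read_bedgraph <- function(plus_path, minus_path, sample_id = "sample",
                          library_units = "raw_reads") {
  read_one <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0)
      return(data.frame(contig = character(), strand = character(),
                        pos = integer(), value = numeric()))
    w <- BiocGenerics::width(gr)
    pos <- unlist(lapply(seq_along(gr), function(i)
      seq.int(BiocGenerics::start(gr)[i] - 1L, length.out = w[i])))
    val <- rep(S4Vectors::mcols(gr)$score, w)
    if (strand == "-") val <- -val
    data.frame(contig = rep(as.character(GenomicRanges::seqnames(gr)), w),
               strand = strand, pos = as.integer(pos), value = val,
               stringsAsFactors = FALSE)
  }
  df <- rbind(read_one(plus_path, "+"), read_one(minus_path, "-"))
  df <- df[df$value != 0, , drop = FALSE]
  track_from_positions(df, sample_id = sample_id,
                       library_units = library_units)
}

#' Build a track directly from per-position values
#'
#' Used by track readers and by simulations that produce coverage-style
#' values directly (e.g. locus-enrichment tracks).
#'
#' @param df data.frame with contig, strand, pos, value (values at duplicate
#'   positions are summed).
#' @param sample_id,library_units track metadata.
#' @return a `signal_track`.
#' @export
track_from_positions <- function(df, sample_id = "sample",
                                 library_units = "raw_reads") {
  key <- .track_key(df$contig, df$strand)
  index <- lapply(split(df[, c("pos", "value")], key), function(d) {
    v <- rowsum(d$value, d$pos)
    pos <- as.integer(rownames(v))
    o <- order(pos)
    list(pos = pos[o], val = as.numeric(v[o]), cum = cumsum(as.numeric(v[o])))
  })
  new_signal_track(index, sample_id = sample_id,
                   library_units = library_units,
                   n_alignments = NA_integer_)
}

#' Write a manifest row describing exported tracks
#'
#' @param entries data.frame with sample_id, plus_file, minus_file,
#'   normalization mode, factor, evidence.
#' @param path TSV output path.
#' @export
write_track_manifest <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
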