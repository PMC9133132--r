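# Anchor-centred meta-gene matrices and mean profiles.
#
# Rows are genes, columns are bins of transcript-oriented offsets around the
# anchor (TSS or TES). Minus-strand rows are stored already flipped, so
# offset +x always means downstream in transcript orientation.

#' Build an anchor-centred signal matrix
#'
#' Row g, bin j holds the strand-matched track signal in the j-th bin of the
#' oriented window `[-upstream, +downstream)` around gene g's anchor (offset
#' 0 is the anchor base itself). Parts of a window beyond contig edges
#' contribute zero.
#'
#' @param track a `signal_track`.
#' @param genes a `gene_models` data.frame.
#' @param anchor `"TES"` or `"TSS"`.
#' @param upstream,downstream window extent in nt; their sum must be
#'   divisible by `binsize`.
#' @param binsize bin width in nt (default 10).
#' @return a `metagene_matrix`: list with `values` (genes x bins), `offsets`
#'   (bin start offsets), `anchors` (gene_id, anchor position, strand).
#' @export
anchor_matrix <- function(track, genes, anchor = c("TES", "TSS"),
                          upstream = 500L, downstream = 500L,
                          binsize = 10L) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0) stop("no genes supplied")
  if ((upstream + downstream) %% binsize != 0)
    stop("upstream + downstream must be divisible by binsize")
  apos <- if (anchor == "TES") tes(genes) else tss(genes)
  nbin <- (upstream + downstream) %/% binsize
  offs <- seq.int(-upstream, downstream - binsize, by = binsize)
  vals <- matrix(0, nrow(genes), nbin,
                 dimnames = list(genes$gene_id, offs))
  for (i in seq_len(nrow(genes))) {
    plus <- genes$strand[i] == "+"
    for (j in seq_len(nbin)) {
      o0 <- offs[j]; o1 <- offs[j] + binsize
      if (plus) { s <- apos[i] + o0; e <- apos[i] + o1 }
      else      { s <- apos[i] - o1 + 1L; e <- apos[i] - o0 + 1L }
      vals[i, j] <- window_sum(track, genes$chrom[i], max(s, 0L), e,
                               strand = genes$strand[i])
    }
  }
  structure(list(values = vals, offsets = offs, binsize = binsize,
                 anchor = anchor,
                 anchors = data.frame(gene_id = genes$gene_id,
                                      position = apos,
                                      strand = genes$strand,
                                      stringsAsFactors = FALSE)),
            class = "metagene_matrix")
}

#' Mean meta-gene profile from an anchor matrix
#'
#' With `per_gene_norm = "row_sum"` each row is divided by its total before
#' averaging (rows with zero total are dropped, and their count is reported
#' in the `n_dropped` attribute); with `"none"`, a plain column mean.
#'
#' @param matrix a `metagene_matrix`.
#' @param per_gene_norm `"none"` or `"row_sum"`.
#' @return named numeric profile (one value per bin), with attributes
#'   `offsets` and `n_dropped`.
#' @export
mean_profile <- function(matrix, per_gene_norm = c("none", "row_sum")) {
  per_gene_norm <- match.arg(per_gene_norm)
  v <- matrix$values
  if (nrow(v) == 0) stop("empty metagene matrix")
  n_dropped <- 0L
  if (per_gene_norm == "row_sum") {
    tot <- rowSums(v)
    n_dropped <- sum(tot == 0)
    v <- v[tot > 0, , drop = FALSE]
    if (nrow(v) == 0) stop("all rows have zero total signal")
    v <- v / rowSums(v)
  }
  prof <- colMeans(v)
  attr(prof, "offsets") <- matrix$offsets
  attr(prof, "n_dropped") <- n_dropped
  prof
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat("metagene_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "bins of", x$binsize, "nt, anchored at", x$anchor, "\n")
  invisible(x)
}

#' Plot a mean meta-gene profile
#'
#' @param x a `metagene_matrix`.
#' @param per_gene_norm passed to [mean_profile()].
#' @param ... further arguments to [graphics::plot()].
#' @method plot metagene_matrix
#' @export
plot.metagene_matrix <- function(x, per_gene_norm = "none", ...) {
  prof <- mean_profile(x, per_gene_norm)
  graphics::plot(x$offsets + x$binsize / 2, prof, type = "l",
                 xlab = sprintf("offset from %s (nt)", x$anchor),
                 ylab = "mean signal", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(prof)
}

#' Write a metagene matrix (and its profile) as TSV
#'
#' @param matrix a `metagene_matrix`.
#' @param path matrix TSV path; the profile goes to `<path>.profile.tsv`.
#' @param per_gene_norm passed to [mean_profile()].
#' @export
write_metagene <- function(matrix, path, per_gene_norm = "none") {
  m <- data.frame(gene_id = rownames(matrix$values), matrix$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- mean_profile(matrix, per_gene_norm)
  utils::write.table(
    data.frame(offset = matrix$offsets, mean_signal = as.numeric(prof)),
    paste0(path, ".profile.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
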