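# Per-gene pausing statistics: TES-proximal pausing (TPP) index,
# promoter-proximal pausing (PPP) index, and read-through ratio, plus the
# spike-normalized expression filter and paired class-wise condition
# comparisons.
#
# Both indices are density ratios: window signal per nt over gene-body signal
# per nt, with a pseudocount on the gene-body count so sparse gene bodies
# give large but finite indices. A raw-sum variant (no length correction) is
# provided as well.

#' Sum track signal over each gene's analysis windows
#'
#' Counting is strand-matched to the gene strand. Windows on contigs absent
#' from the track count zero.
#'
#' @param track a `signal_track`.
#' @param regions a `region_set` from [define_regions()].
#' @return data.frame: gene_id plus tssr_count, gb_count, tesr_count,
#'   tss200_count, rt_count.
#' @export
window_counts <- function(track, regions) {
  one <- function(nm) {
    vapply(seq_len(nrow(regions)), function(i)
      window_sum(track, regions$chrom[i],
                 regions[[paste0(nm, "_start")]][i],
                 regions[[paste0(nm, "_end")]][i],
                 strand = regions$strand[i]), 0)
  }
  data.frame(gene_id = regions$gene_id,
             tssr_count = one("tssr"), gb_count = one("gb"),
             tesr_count = one("tesr"), tss200_count = one("tss200"),
             rt_count = one("rt"), stringsAsFactors = FALSE)
}

.density_index <- function(win_count, win_len, gb_count, gb_len, pseudocount,
                           variant) {
  if (variant == "density")
    (win_count / win_len) / ((gb_count + pseudocount) / gb_len)
  else
    win_count / (gb_count + pseudocount)
}

#' TES-proximal pausing (TPP) index
#'
#' Signal density in the TES-proximal window (ending at and including the
#' TES) divided by gene-body signal density, i.e. how strongly the
#' polymerase dwells just upstream of the transcript end relative to
#' elongation through the body. The pseudocount (default 1) is added to the
#' gene-body count only, keeping the index finite on sparse gene bodies.
#'
#' @param counts window-count data.frame from [window_counts()].
#' @param regions the matching `region_set` (provides window lengths).
#' @param pseudocount added to the denominator count (default 1).
#' @param variant `"density"` (per-nt densities; default) or `"rawsum"`
#'   (plain count ratio, no length correction).
#' @return numeric vector of indices, NA for ineligible genes.
#' @export
tpp_index <- function(counts, regions, pseudocount = 1,
                      variant = c("density", "rawsum")) {
  variant <- match.arg(variant)
  stopifnot(identical(counts$gene_id, regions$gene_id))
  out <- .density_index(counts$tesr_count,
                        regions$tesr_end - regions$tesr_start,
                        counts$gb_count,
                        regions$gb_end - regions$gb_start,
                        pseudocount, variant)
  out[!regions$eligible] <- NA_real_
  out
}

#' Promoter-proximal pausing (PPP) index
#'
#' As [tpp_index()], with the TSS-proximal window in place of the
#' TES-proximal window.
#'
#' @inheritParams tpp_index
#' @export
ppp_index <- function(counts, regions, pseudocount = 1,
                      variant = c("density", "rawsum")) {
  variant <- match.arg(variant)
  stopifnot(identical(counts$gene_id, regions$gene_id))
  out <- .density_index(counts$tssr_count,
                        regions$tssr_end - regions$tssr_start,
                        counts$gb_count,
                        regions$gb_end - regions$gb_start,
                        pseudocount, variant)
  out[!regions$eligible] <- NA_real_
  out
}

#' Transcription read-through ratio
#'
#' Signal in the 200 nt past the TES over signal in the 200 nt from the TSS
#' (`mode = "tss200"`, the default) or over the gene-body count
#' (`mode = "genebody"`). A zero denominator yields NA and the gene is
#' dropped from ratio summaries.
#'
#' @param counts window-count data.frame from [window_counts()].
#' @param mode denominator choice.
#' @return numeric vector of ratios.
#' @export
readthrough_ratio <- function(counts, mode = c("tss200", "genebody")) {
  mode <- match.arg(mode)
  den <- if (mode == "tss200") counts$tss200_count else counts$gb_count
  ifelse(den > 0, counts$rt_count / den, NA_real_)
}

#' Compute the full per-gene pausing table for one sample
#'
#' Runs [window_counts()] and attaches TPP, PPP, read-through ratio and the
#' expression-filter flag.
#'
#' @param track a `signal_track` (spike-normalized if the filter is to be
#'   interpreted on the paper's scale).
#' @param regions a `region_set`.
#' @param pseudocount gene-body pseudocount for the indices.
#' @param rt_mode read-through denominator, see [readthrough_ratio()].
#' @param variant index variant, see [tpp_index()].
#' @param filter_threshold threshold for [filter_expressed()].
#' @return a `pausing_table` data.frame: gene_id, gene_class, the five window
#'   counts, tpp_index, ppp_index, readthrough_ratio, eligible,
#'   passes_filter.
#' @export
pausing_stats <- function(track, regions, pseudocount = 1,
                          rt_mode = "tss200", variant = "density",
                          filter_threshold = 10) {
  counts <- window_counts(track, regions)
  out <- data.frame(gene_id = regions$gene_id,
                    gene_class = regions$gene_class,
                    counts[, -1, drop = FALSE],
                    stringsAsFactors = FALSE)
  out$tpp_index <- tpp_index(counts, regions, pseudocount, variant)
  out$ppp_index <- ppp_index(counts, regions, pseudocount, variant)
  out$readthrough_ratio <- readthrough_ratio(counts, rt_mode)
  out$eligible <- regions$eligible
  out <- filter_expressed(out, threshold = filter_threshold)
  class(out) <- c("pausing_table", "data.frame")
  out
}

#' Flag genes passing the expression filter
#'
#' A gene passes when its (normalized) TSS..TSS+200 signal strictly exceeds
#' `threshold` (default 10, the 10-fold spike-normalized signal cut used for
#' read-through summaries). Non-passing genes are retained in the table but
#' excluded from ratio and boxplot-style summaries.
#'
#' @param records data.frame carrying a `tss200_count` column.
#' @param threshold strict lower bound.
#' @return the records with `passes_filter` set.
#' @export
filter_expressed <- function(records, threshold = 10) {
  records$passes_filter <- records$tss200_count > threshold
  records
}

#' Two-sided Wilcoxon signed-rank test, exact for small n
#'
#' Zero differences are dropped before ranking (signed-rank convention).
#' For n <= 15 remaining pairs the p-value is computed by exhaustive
#' enumeration of all 2^n sign assignments of the ranked absolute
#' differences (so ties in |d| are handled exactly); above that, a normal
#' approximation with continuity correction and tie-corrected variance.
#'
#' @param a,b paired numeric vectors.
#' @return list: statistic (sum of positive ranks), n_pairs (nonzero pairs),
#'   p_value, method.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, n_pairs = 0L, p_value = 1,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= 15) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    t_all <- as.vector(signs %*% r)
    p <- mean(abs(t_all - mu) >= abs(t_obs - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    sigma <- sqrt(sum(r^2) / 4)        # tie-corrected null SD
    z <- (abs(t_obs - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approximation"
  }
  list(statistic = t_obs, n_pairs = n, p_value = p, method = method)
}

#' Compare a per-gene statistic between two conditions
#'
#' Pairs values by gene id and applies the two-sided Wilcoxon signed-rank
#' test (see [wilcoxon_signed_rank()]). NA values drop the pair.
#'
#' @param values_a,values_b named numeric vectors (names are gene ids), or
#'   plain vectors with `paired_by` giving the ids.
#' @param paired_by gene ids when the vectors are unnamed (recycled for
#'   both).
#' @param gene_class optional label stored on the result.
#' @return a `class_comparison` list: gene_class, n_pairs, median_a,
#'   median_b, statistic, p_value, test_name.
#' @export
compare_conditions <- function(values_a, values_b, paired_by = NULL,
                               gene_class = NA_character_) {
  if (!is.null(paired_by)) {
    names(values_a) <- paired_by
    names(values_b) <- paired_by
  }
  if (is.null(names(values_a)) || is.null(names(values_b)))
    stop("values must be named by gene id (or supply paired_by)")
  common <- intersect(names(values_a), names(values_b))
  a <- values_a[common]; b <- values_b[common]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("no overlapping genes between conditions")
  w <- wilcoxon_signed_rank(a, b)
  structure(list(gene_class = gene_class, n_pairs = length(a),
                 median_a = stats::median(a), median_b = stats::median(b),
                 statistic = w$statistic, p_value = w$p_value,
                 test_name = "two-sided Wilcoxon signed-rank",
                 method = w$method),
            class = "class_comparison")
}

#' Class-wise comparison of a pausing statistic between two samples
#'
#' For each gene class, pairs eligible, filter-passing genes present in both
#' tables and runs [compare_conditions()] on the chosen statistic.
#'
#' @param table_a,table_b `pausing_table`s for the two conditions.
#' @param stat column to compare (`"tpp_index"`, `"ppp_index"` or
#'   `"readthrough_ratio"`).
#' @param classes gene classes to test (default: all present in both).
#' @param require_filter restrict to filter-passing genes (default TRUE).
#' @return data.frame, one row per class: n_pairs, median_a, median_b,
#'   statistic, p_value.
#' @export
compare_classes <- function(table_a, table_b, stat = "tpp_index",
                            classes = NULL, require_filter = TRUE) {
  use <- function(tb) {
    keep <- tb$eligible & !is.na(tb[[stat]])
    if (require_filter) keep <- keep & tb$passes_filter
    tb[keep, , drop = FALSE]
  }
  ta <- use(table_a); tb <- use(table_b)
  if (is.null(classes))
    classes <- intersect(unique(ta$gene_class), unique(tb$gene_class))
  rows <- lapply(classes, function(cl) {
    va <- stats::setNames(ta[[stat]][ta$gene_class == cl],
                          ta$gene_id[ta$gene_class == cl])
    vb <- stats::setNames(tb[[stat]][tb$gene_class == cl],
                          tb$gene_id[tb$gene_class == cl])
    cc <- compare_conditions(va, vb, gene_class = cl)
    data.frame(gene_class = cl, n_pairs = cc$n_pairs,
               median_a = cc$median_a, median_b = cc$median_b,
               statistic = cc$statistic, p_value = cc$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Boxplot-style per-class summary of a pausing statistic
#'
#' Median and quartiles per gene class over eligible, filter-passing genes.
#'
#' @param tbl a `pausing_table`.
#' @param stat column to summarize.
#' @param require_filter restrict to filter-passing genes.
#' @return data.frame: gene_class, n, q1, median, q3.
#' @export
class_summary <- function(tbl, stat = "tpp_index", require_filter = TRUE) {
  keep <- tbl$eligible & !is.na(tbl[[stat]])
  if (require_filter) keep <- keep & tbl$passes_filter
  tbl <- tbl[keep, , drop = FALSE]
  rows <- lapply(split(tbl[[stat]], tbl$gene_class), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  })
  out <- do.call(rbind, rows)
  out <- data.frame(gene_class = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf(
    "class_comparison%s: n = %d pairs, medians %.4g vs %.4g, W = %.1f, p = %.3g (%s)\n",
    if (is.na(x$gene_class)) "" else paste0(" [", x$gene_class, "]"),
    x$n_pairs, x$median_a, x$median_b, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Write a pausing table as TSV
#' @param tbl a `pausing_table`.
#' @param path output file.
#' @export
write_pausing_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
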