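# Gene models and analysis windows.
#
# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# TSS is the first transcribed base (start on "+", end-1 on "-"); TES is the
# final transcribed base, inclusive (end-1 on "+", start on "-").

#' Recognized gene classes, in merge-priority order
#'
#' Replication-dependent histone (RDH) genes first: when transcripts of mixed
#' classes are collapsed into one unit, the unit keeps the highest-priority
#' class among its members.
#'
#' @export
GENE_CLASSES <- c("RDH", "snRNA", "snoRNA", "rRNA", "protein_coding",
                  "other_noncoding")

new_gene_models <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

validate_gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand",
                  "gene_class") %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand symbol '", df$strand[which(bad)[1]], "' for gene ",
         df$gene_id[which(bad)[1]])
  if (any(df$start >= df$end))
    stop("start >= end for gene ", df$gene_id[which(df$start >= df$end)[1]])
  bad <- !df$gene_class %in% GENE_CLASSES
  if (any(bad))
    stop("unknown gene_class '", df$gene_class[which(bad)[1]], "'")
  invisible(df)
}

#' Load gene models from a GTF file or a gene-bed table
#'
#' Coordinates are converted to the internal 0-based half-open convention
#' (GTF input is 1-based inclusive and is shifted; gene-bed input is already
#' 0-based half-open, as in BED).
#'
#' The gene-bed dialect is a 7-column tab-separated table:
#' chrom, start, end, gene_id, score, strand, gene_class.
#'
#' For GTF input, one model is built per `transcript` feature (all features
#' if the file has no `type` column). The class label is taken from a
#' `gene_class` attribute if present, otherwise mapped from `gene_biotype`
#' (snRNA/snoRNA/rRNA/protein_coding kept as such, other biotypes to
#' `other_noncoding`), and can be overridden by `class_table`.
#'
#' @param path path to the annotation file.
#' @param format `"gene-bed"` or `"gtf"`.
#' @param class_table optional data.frame with columns `gene_id`,
#'   `gene_class`, overriding per-gene class labels.
#' @return a `gene_models` data.frame: gene_id, chrom, start, end, strand,
#'   gene_class.
#' @export
load_gene_models <- function(path, format = c("gene-bed", "gtf"),
                             class_table = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(format,
    "gene-bed" = .load_gene_bed(path),
    "gtf"      = .load_gtf(path))
  if (!is.null(class_table)) {
    idx <- match(df$gene_id, class_table$gene_id)
    hit <- !is.na(idx)
    df$gene_class[hit] <- class_table$gene_class[idx[hit]]
  }
  validate_gene_models(df)
  new_gene_models(df)
}

.load_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7))
    stop("malformed gene-bed record at line ", which(nf < 7)[1],
         ": expected 7 tab-separated fields, got ", nf[which(nf < 7)[1]])
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed gene-bed record at line ",
         which(is.na(start) | is.na(end))[1], ": non-integer coordinate")
  data.frame(
    gene_id    = vapply(fields, `[`, "", 4L),
    chrom      = vapply(fields, `[`, "", 1L),
    start      = start,
    end        = end,
    strand     = vapply(fields, `[`, "", 6L),
    gene_class = vapply(fields, `[`, "", 7L),
    stringsAsFactors = FALSE)
}

.biotype_to_class <- function(biotype) {
  out <- rep("other_noncoding", length(biotype))
  keep <- c("snRNA", "snoRNA", "rRNA", "protein_coding", "RDH")
  out[biotype %in% keep] <- biotype[biotype %in% keep]
  out[is.na(biotype)] <- "protein_coding"
  out
}

.load_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "transcript"))
    gr <- gr[md$type == "transcript"]
  md <- S4Vectors::mcols(gr)
  id <- if ("transcript_id" %in% names(md) && !all(is.na(md$transcript_id)))
    as.character(md$transcript_id) else as.character(md$gene_id)
  cls <- if ("gene_class" %in% names(md)) as.character(md$gene_class)
         else if ("gene_biotype" %in% names(md))
           .biotype_to_class(as.character(md$gene_biotype))
         else rep("protein_coding", length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("unknown strand symbol '*' for transcript ", id[strand == "*"][1])
  data.frame(
    gene_id    = id,
    chrom      = as.character(GenomicRanges::seqnames(gr)),
    start      = BiocGenerics::start(gr) - 1L,   # GTF is 1-based inclusive
    end        = BiocGenerics::end(gr),
    strand     = strand,
    gene_class = cls,
    stringsAsFactors = FALSE)
}

#' Transcription start / end site of each gene model
#'
#' Both are positions of single bases in 0-based coordinates: the TSS is the
#' first transcribed base and the TES the last transcribed base.
#'
#' @param models a `gene_models` data.frame.
#' @return integer vector, one position per model.
#' @export
tss <- function(models) {
  ifelse(models$strand == "+", models$start, models$end - 1L)
}

#' @rdname tss
#' @export
tes <- function(models) {
  ifelse(models$strand == "+", models$end - 1L, models$start)
}

#' Collapse transcripts sharing a TSS or a TES into single units
#'
#' Transcripts on the same chromosome and strand that share an identical TSS
#' or an identical TES are merged (transitively) into one transcription unit
#' spanning min(start)..max(end). The merged unit keeps the lexicographically
#' first member gene_id and the highest-priority gene class among members
#' (RDH > snRNA > snoRNA > rRNA > protein_coding > other_noncoding).
#'
#' @param models a `gene_models` data.frame.
#' @return a `gene_models` data.frame of collapsed units.
#' @export
collapse_shared_ends <- function(models) {
  n <- nrow(models)
  if (n == 0) return(new_gene_models(models))
  # union-find; sharing an identical start or identical end within a
  # chrom+strand group is equivalent to sharing a TSS or TES on either strand
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  key_s <- paste(models$chrom, models$strand, models$start)
  key_e <- paste(models$chrom, models$strand, models$end)
  for (key in list(key_s, key_e)) {
    groups <- split(seq_len(n), key)
    for (g in groups)
      if (length(g) > 1) for (k in seq_along(g)[-1]) union_(g[1], g[k])
  }
  root <- vapply(seq_len(n), find, 1L)
  merged <- lapply(split(seq_len(n), root), function(idx) {
    m <- models[idx, , drop = FALSE]
    data.frame(
      gene_id    = sort(m$gene_id)[1],
      chrom      = m$chrom[1],
      start      = min(m$start),
      end        = max(m$end),
      strand     = m$strand[1],
      gene_class = GENE_CLASSES[min(match(m$gene_class, GENE_CLASSES))],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  new_gene_models(out)
}

#' Derive per-gene analysis windows
#'
#' For each gene, defines in transcript orientation (mirrored on the minus
#' strand), all 0-based half-open:
#' \describe{
#'   \item{tssr}{`tssr_len` nt starting at the TSS (promoter-proximal pause
#'     window).}
#'   \item{tesr}{`tesr_len` nt ending at, and including, the TES
#'     (TES-proximal pause window).}
#'   \item{gb}{the gene body between tssr and tesr; excludes both pause
#'     windows so a pause peak cannot inflate its own denominator.}
#'   \item{tss200}{`tss200_len` nt starting at the TSS (read-through ratio
#'     denominator).}
#'   \item{rt}{`rt_len` nt starting one base past the TES (read-through
#'     window).}
#' }
#' Genes shorter than `min_gene_length`, or whose gene body would be shorter
#' than `min_gb_length`, are flagged ineligible (with a reason) rather than
#' silently shrunk. Windows extending past contig bounds (when
#' `contig_lengths` is given, and always at coordinate 0) are clipped and
#' flagged, not fatal.
#'
#' @param models a `gene_models` data.frame.
#' @param tssr_len,tesr_len,tss200_len,rt_len window lengths in nt.
#' @param min_gene_length,min_gb_length eligibility thresholds in nt.
#' @param contig_lengths optional named integer vector of contig lengths used
#'   to clip windows on the right.
#' @return a `region_set` data.frame with one row per gene: interval columns
#'   `<win>_start`/`<win>_end`, plus `eligible`, `reason`, `clipped`.
#' @export
define_regions <- function(models, tssr_len = 150L, tesr_len = 100L,
                           tss200_len = 200L, rt_len = 200L,
                           min_gene_length = 150L, min_gb_length = 50L,
                           contig_lengths = NULL) {
  s <- models$start; e <- models$end
  plus <- models$strand == "+"
  len <- e - s

  win <- function(p_start, p_end, m_start, m_end)
    cbind(start = ifelse(plus, p_start, m_start),
          end   = ifelse(plus, p_end,   m_end))
  tssr   <- win(s, s + tssr_len,            e - tssr_len, e)
  tesr   <- win(e - tesr_len, e,            s, s + tesr_len)
  gb     <- win(s + tssr_len, e - tesr_len, s + tesr_len, e - tssr_len)
  tss200 <- win(s, s + tss200_len,          e - tss200_len, e)
  rt     <- win(e, e + rt_len,              s - rt_len, s)

  eligible <- rep(TRUE, nrow(models))
  reason <- rep(NA_character_, nrow(models))
  short <- len < min_gene_length
  reason[short] <- sprintf("gene length %d < min_gene_length %d",
                           len[short], as.integer(min_gene_length))
  gb_short <- !short & (gb[, "end"] - gb[, "start"]) < min_gb_length
  reason[gb_short] <- sprintf("gene body %d nt < min_gb_length %d",
                              pmax(gb[gb_short, "end"] - gb[gb_short, "start"], 0L),
                              as.integer(min_gb_length))
  eligible[short | gb_short] <- FALSE

  out <- data.frame(gene_id = models$gene_id, chrom = models$chrom,
                    strand = models$strand, gene_class = models$gene_class,
                    stringsAsFactors = FALSE)
  clipped <- rep(FALSE, nrow(models))
  bound <- if (is.null(contig_lengths)) rep(NA_integer_, nrow(models))
           else unname(contig_lengths[models$chrom])
  wins <- list(tssr = tssr, gb = gb, tesr = tesr, tss200 = tss200, rt = rt)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    lo <- pmax(w[, "start"], 0L)
    hi <- ifelse(is.na(bound), w[, "end"], pmin(w[, "end"], bound))
    hi <- pmax(hi, lo)
    clipped <- clipped | (lo != w[, "start"]) | (hi != w[, "end"])
    out[[paste0(nm, "_start")]] <- as.integer(lo)
    out[[paste0(nm, "_end")]]   <- as.integer(hi)
  }
  out$eligible <- eligible
  out$reason <- reason
  out$clipped <- clipped
  class(out) <- c("region_set", "data.frame")
  out
}

#' Export a region set as BED6
#'
#' One BED record per window per gene, named `<gene_id>:<window>`.
#'
#' @param regions a `region_set`.
#' @param path output file path.
#' @export
regions_to_bed <- function(regions, path) {
  wins <- c("tssr", "gb", "tesr", "tss200", "rt")
  recs <- do.call(rbind, lapply(wins, function(nm) {
    data.frame(chrom = regions$chrom,
               start = regions[[paste0(nm, "_start")]],
               end = regions[[paste0(nm, "_end")]],
               name = paste0(regions$gene_id, ":", nm),
               score = 0L, strand = regions$strand,
               stringsAsFactors = FALSE)
  }))
  recs <- recs[recs$end > recs$start, , drop = FALSE]
  utils::write.table(recs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x), "transcription units on",
      length(unique(x$chrom)), "contig(s)\n")
  tab <- table(factor(x$gene_class, levels = GENE_CLASSES))
  cat(paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = ", "), "\n")
  NextMethod()
}
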