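# End-to-end convenience wrapper tying the modules together.

#' Run the PRO-seq pausing pipeline on one simulated condition
#'
#' Simulates alignments for the given condition preset, builds the 3'-end
#' pileup, applies spike-in (or, for the alpha-amanitin preset,
#' rRNA-million) normalization, and computes the per-gene pausing table.
#'
#' @param genome a `sim_genome` from [simulate_genome()].
#' @param condition condition preset name, see [sim_truth()].
#' @param reads_per_gene exact reads per gene (see [simulate_proseq()]).
#' @param seed master seed.
#' @param normalization `"spike"`, `"rrna"` or `"none"`.
#' @param pseudocount,rt_mode,variant,filter_threshold passed to
#'   [pausing_stats()].
#' @param truth optional pre-built `sim_truth` overriding `condition`.
#' @param regions optional pre-built `region_set` (defaults to
#'   [define_regions()] on the genome's genes).
#' @return list: `table` (a `pausing_table`), `track` (the normalized
#'   `signal_track`), `regions`, `truth`, `alignments`.
#' @export
run_proseq_pipeline <- function(genome, condition = "WT",
                                reads_per_gene = 1000, seed = 1L,
                                normalization = c("spike", "rrna", "none"),
                                pseudocount = 1, rt_mode = "tss200",
                                variant = "density", filter_threshold = 10,
                                truth = NULL, regions = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(truth))
    truth <- sim_truth(genome$genes, condition = condition)
  aln <- simulate_proseq(genome, truth, reads_per_gene = reads_per_gene,
                         seed = seed)
  track <- three_prime_pileup(aln, sample_id = truth$condition_name)
  if (normalization == "spike") {
    nf <- spike_normalization_factor(aln, genome$spike_contig,
                                     genome$contigs[[genome$spike_contig]])
    track <- scale_track(track, nf)
  } else if (normalization == "rrna") {
    nf <- rrna_normalization_factor(aln, genome$rrna_interval)
    track <- scale_track(track, nf)
  }
  if (is.null(regions))
    regions <- define_regions(genome$genes,
                              contig_lengths = genome$contigs)
  tbl <- pausing_stats(track, regions, pseudocount = pseudocount,
                       rt_mode = rt_mode, variant = variant,
                       filter_threshold = filter_threshold)
  list(table = tbl, track = track, regions = regions, truth = truth,
       alignments = aln)
}
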