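Package: polpause
Title: Quantification of RNA Polymerase II Pausing at Transcript Ends from PRO-seq Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested pipeline for quantifying RNA polymerase II
    pausing at the 3' ends of genes from PRO-seq (precision nuclear run-on
    sequencing) data. Converts alignments into strand-specific single-nucleotide
    3'-end pileup tracks, applies spike-in (exogenous Drosophila) or rRNA-read
    normalization, computes per-gene TES-proximal and promoter-proximal pausing
    indices and the transcription read-through ratio, compares conditions per
    gene class with an exact Wilcoxon signed-rank test, and builds anchor-centred
    meta-gene profiles. Companion modules quantify per-gene IP/input enrichment
    (CPM normalized) and locus-window signal, and analyse nuclear-body
    colocalization in multi-channel fluorescence images (particle detection,
    mask-overlap association, centroid distances, anchor-averaged images).
    A ground-truthed synthetic-data generator drives every stage so the whole
    pipeline is exercisable without raw sequencing or microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    Rsamtools,
    GenomicAlignments,
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
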