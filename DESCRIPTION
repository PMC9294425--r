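Package: ORFpi
Title: ORF Prediction from the 3-nt Periodicity of Population Nucleotide Diversity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts open reading frames (including small ORFs) genome-wide
    from population SNP data, exploiting the elevated per-site nucleotide
    diversity (pi) at wobble (third codon) positions inside coding sequence.
    Provides metagene diversity profiling with a multitaper harmonic F-test
    for 3-nt periodicity, frame-wise one-sided Student's t-tests on diversity
    and on trained codon usage, Fisher combination of p-values, classification
    of predicted ORFs against a reference annotation (uORF, dORF, truncated,
    extended, and related categories), accuracy/recall/F-score evaluation, and
    a synthetic genome/diversity simulator with truth manifests for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    parallel,
    data.table,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Genetics, Annotation, GenePrediction, SNP
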