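Package: protannotate
Title: Proteogenomic Genome Reannotation from Peptide Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteogenomic reannotation of compact (bacterial) genomes from
    shotgun-proteomics peptide evidence. Builds a six-frame stop-to-stop ORF
    database, filters peptide-spectrum matches at a target-decoy FDR,
    classifies peptides against the annotated proteome and the six-frame
    database (genome search-specific peptides, GSSPs), infers identified
    proteins, and calls novel genes and N-terminal gene-model revisions with
    noncanonical start-codon support. Also provides signal-peptide refutation
    by MS coverage, PTM-site confidence filtering, TMT-style differential
    expression, and a synthetic-data generator with a planted ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
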