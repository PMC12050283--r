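Package: eccforge
Title: Detection, Unification and Differential Analysis of Extrachromosomal
    Circular DNA from Rolling-Circle Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for extrachromosomal circular DNA (eccDNA)
    analysis from rolling-circle-amplified nanopore concatemer reads. Includes
    a synthetic-data generator (annotated toy genome, planted circular
    templates, concatemer read simulation with truth tables, zero-inflated
    Poisson count matrices), an eccDNA caller based on tandem repeat-unit
    decomposition with linear/genomic-tandem exclusion and read-support
    filtering, multiple-fragment circle detection (Nfullpass/Nfragment),
    cross-sample locus identity unification, genomic-feature classification
    (ecGenes, ecTEs, full-length ecRepeatUnits), and GMPR-normalized
    earth-mover's-distance permutation testing for exclusive and differential
    features.
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
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
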