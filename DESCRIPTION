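Package: charrpanel
Title: Design and Evaluation of SNP Genotyping Arrays for Salmonid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating high-density SNP genotyping
    arrays from multi-platform variant discovery data, motivated by array
    design for Arctic charr (Salvelinus alpinus). Implements family-based
    candidate QC (missingness, Mendelian-error detection, segregation
    distortion), population minor-allele-frequency filtering, quality filters
    on high-coverage variant calls, cross-platform SNP validation,
    strand-ambiguity screening, spacing-aware tiered panel selection with
    71-mer probe construction, sdY-based genotypic sexing, and post-genotyping
    evaluation (Axiom-style marker classification, cross-group sharing, genome
    coverage and gene representation). A seeded synthetic-data module
    generates every pipeline input: genome, annotation, true variants,
    platform call sets, family genotypes, and simulated array runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    stringi,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
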