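Package: yindelscreen
Title: Screening Phylogenetically Informative Y-Chromosomal InDels
Version: 0.1.0
Authors@R: person("Forensic Genomics", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers clade-defining insertion/deletion polymorphisms on the
    male-specific Y chromosome from multi-sample VCF data. Samples are assigned
    to Y-haplogroups by descending a labeled haplogroup tree on derived-state
    defining markers; per-clade derived-allele frequencies are obtained by
    direct counting; bi-allelic InDels are screened for clade-exactness (derived
    in every member of one clade and in nobody else), assigned to their subclade
    via lowest common ancestors, and deduplicated against markers that already
    define tree nodes. A seeded cohort simulator with a planted-variant truth
    table makes every stage of the pipeline verifiable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
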