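Package: dlatyper
Title: Sequence-Based DLA Class II Typing, Haplotype Inference and
    Case-Control Association
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sequence-based typing of the canine major
    histocompatibility complex (DLA) class II loci DRB1, DQA1 and DQB1
    from direct-sequencing consensus reads containing IUPAC ambiguity
    codes. Implements heterozygote allele deconvolution against a
    reference allele library, Clark-style three-locus haplotype phasing
    anchored on homozygous individuals, case-control association
    statistics for allele, haplotype and homozygosity features (odds
    ratio with Haldane-Anscombe zero-cell correction, Woolf logit
    confidence interval, two-sided Wald test), a desk-scale genome-wide
    association stage (quality-control filters, 1-df allelic chi-square,
    Bonferroni correction, genomic inflation factor), and a seeded
    synthetic-data generator so the whole pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
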