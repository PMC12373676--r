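Package: sexCAPS
Title: Discovery and In-Silico Validation of CAPS Sex Markers from
    Male/Female Transcript Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for identifying Y-linked transcripts in dioecious
    species from male and female sample cohorts, and for turning them into
    PCR-based sex genotyping assays. Candidate Y transcripts are selected
    with a comparative k-mer sieve (k-mers present in every male sample and
    absent from every female sample) followed by male-bias and strict-TPM
    expression filters; candidates are paired with their X-chromosome
    gametologs by local alignment, ranked by X/Y divergence, and scanned
    for allele-differential restriction sites flanked by conserved primer
    windows. The package designs degenerate common primers and
    allele-specific probes, and validates the resulting CAPS
    (Cleaved Amplified Polymorphic Sequence) and TaqMan-style assays in
    silico via PCR simulation, restriction digestion, gel band prediction
    and genotype calling. Seeded synthetic-data generators with planted
    ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
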