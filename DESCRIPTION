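Package: allelepam
Title: Allele-Specific CRISPR Targeting via Variant-Derived PAM Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects protospacer-adjacent motifs (PAMs) that are created by a
    single-nucleotide variant (substitution, single-base insertion or deletion)
    and exist exclusively on the variant allele, so that CRISPR-Cas cleavage is
    allele specific.  Ships a registry of 23 Cas enzymes covering 26 degenerate
    PAM motifs with their protospacer orientation and spacer lengths, scans both
    strands of a variant's local context, rejects candidates whose reference
    allele carries any PAM (including off-target PAMs such as NAG for SpCas9)
    of the same enzyme at the locus, suggests spacer (gRNA) sequences, and
    summarises targetability over cohorts of variants.  Includes TSV batch and
    VCF+FASTA readers, TSV/JSON writers, a command-line interface, and a seeded
    synthetic-variant generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
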