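Package: msimmr
Title: Microsatellite Instability, Hypermutation and Mismatch-Repair Lesion
    Calling from Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for classifying advanced prostate cancers as
    hypermutated from somatic mutation burden, calling microsatellite
    instability (MSI) both from targeted-sequencing repeat-length histograms
    (unstable-locus-fraction scoring against a normal-control baseline) and
    from five-marker mononucleotide PCR fragment profiles, detecting
    mismatch-repair (MMR) gene lesions (frameshifts, split-read structural
    rearrangements, exon-level copy losses) with a bi-allelic inactivation
    verdict per gene, and integrating all calls into patient-level cohort
    summaries (prevalence with cohort overlap, multi-site concordance, and a
    mechanism cross-tabulation linking hypermutation, MSI and MMR lesions).
    Includes a fully parameterised synthetic-data generator that emits every
    input the pipeline consumes - PCR-stutter repeat-length histograms,
    germline-contaminated somatic variant tables, clipped-read structural
    variant evidence, exon depth ratios and five-marker PCR profiles -
    alongside a machine-readable truth sidecar for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
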