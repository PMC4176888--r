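# msimmr

Hypermutation, microsatellite instability and mismatch-repair lesion
calling for advanced prostate cancer, at desk scale, with a synthetic-data
generator for validation by parameter recovery.

## The problem

A subset of advanced prostate cancers is *hypermutated* — carrying
hundreds of protein-altering somatic mutations — and this phenotype is
driven by loss of DNA mismatch repair (MMR), most often through complex
structural rearrangements of *MSH2*/*MSH6* rather than the *MLH1*
promoter silencing typical of colorectal cancer. Establishing that
mechanism for a cohort requires several coordinated analyses:

- **Burden classification.** Somatic calls are filtered (tumor variant
  allele fraction ≥ 10%; common dbSNP-style variants removed; anything at
  ≥ 40% allele balance in a germline sample removed) and a specimen is
  hypermutated when its protein-altering count strictly exceeds 300.
- **MSI by NGS** (mSINGS-style). For each of up to 146 mononucleotide
  microsatellite loci on a targeted panel, the number of distinct repeat
  alleles (read support ≥ 5% of locus depth) is compared with a
  normal-control baseline; loci under 30× are excluded; a locus is
  unstable when its allele count exceeds baseline mean + 3 SD, and the
  specimen is MSI-high when the unstable fraction exceeds
  0.20: `fraction_unstable = n_unstable / n_evaluated > 0.20`.
- **MSI by PCR.** The five-marker mononucleotide panel (NR-21, BAT-26,
  BAT-25, NR-24, MONO-27): instability in ≥ 2 of 5 markers is
  MSI-positive.
- **MMR lesions.** Split-read clip points are clustered (window 10 bp,
  ≥ 4 supporting reads per breakpoint) into inversions, deletions and
  translocations; exon depth ratios are thresholded (≤ 0.70 loss,
  ≤ 0.15 homozygous loss) and merged into segments; mosaic *MSH6*
  homopolymer-tract frameshifts — artifacts of MSI itself — are excluded;
  and each gene receives a zygosity verdict (homozygous loss alone, or
  ≥ 2 distinct events ⇒ biallelic).
- **Cohort reporting.** Patient-level prevalence with PDX↔autopsy
  overlap collapsed, multi-site concordance, and a mechanism audit
  checking that every hypermutated patient is MSI-positive with at least
  one MMR lesion.

Quantitative assay support (the 0–200 quasi-continuous IHC score and
standard-curve qPCR quantitation of *MLH1* promoter methylation with
methyl/ALUC4 ratios) is included as well.

Raw-data processing (alignment, somatic calling, consequence annotation)
is out of scope: the package consumes small plain-text tables (TSV, BED,
VCF, JSON) and is aimed at method development, teaching, and validating
caller logic against generated truth.

## Worked example

Simulate an MMR-deficient specimen with a planted *MSH2* inversion plus a
full-gene copy loss, and run every caller:

```r
library(msimmr)

cfg      <- sim_config(seed = 11)
panel    <- msi_panel()                      # 146 mononucleotide loci
baseline <- train_baseline(simulate_controls(10, panel, cfg))

truth <- specimen_truth("patient-A [liver]", "MSI-high",
                        hypermutated = TRUE, true_burden = 420,
                        lesions = list(
                          lesion_rearrangement("MSH2", "inversion",
                                               partner_label = "fusion-1"),
                          lesion_copy_loss("MSH2")))
sim   <- simulate_specimen(truth, panel, cfg)
calls <- analyze_specimen(sim, baseline)

calls$msi_ngs
#> <msi_result> MSI-high: 72/146 loci unstable (fraction 0.493)
calls$msi_pcr
#> <msi_pcr_result> MSI-positive: 5/5 markers unstable
calls$burden
#> <burden_result> patient-A [liver]: 420 protein-altering of 504 passing (hypermutated)
calls$lesions
#> <gene_lesion_set>
#>   gene n_events zygosity_verdict
#> 1 MSH2        2        biallelic
#> 2 MSH6        0             none
#> 3 MLH1        0             none
```

Reading the output: 72 of the 146 evaluated loci exceeded their
normal-control allele-count baseline (the generator destabilized 73), so
the unstable fraction 0.493 > 0.20 gives MSI-high; the filtered variant
table recovers the planted burden of 420 protein-altering mutations
exactly (contaminants are removed by the VAF/common/germline filters), and
420 > 300 gives hypermutated; the recovered inversion breakpoint
(`calls$rearrangements`, chr2:47681386, 12 supporting reads) falls inside
*MSH2* and, together with the exon 1–16 copy-loss segment
(`calls$cnv$segments`), yields two distinct inactivating events — a
biallelic *MSH2* verdict, the expected mechanism for a hypermutated
MSI-high tumor.

A whole cohort mirroring the modeled study design (15 PDX lines + 50
autopsy patients, 5 cross-cohort links) runs through
`simulate_cohort(reference_cohort_manifest(), cfg)` followed by
`analyze_cohort()`, which reports the 7/60 unique-patient prevalence,
multi-site concordance, and the mechanism cross-tabulation.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "msimmr.R", package = "msimmr")` with subcommands
`simulate`, `msi-train`, `msi-call`, `pcr-call` and `burden`.

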