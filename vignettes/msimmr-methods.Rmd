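---
title: "Methods: MSI, hypermutation and MMR lesion calling at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI, hypermutation and MMR lesion calling at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimmr)
```

# Scope

`msimmr` is a desk-scale re-analysis pipeline for the mismatch-repair
(MMR)-deficient, hypermutated subtype of advanced prostate cancer. It links
six analyses: a synthetic-data generator; microsatellite-instability (MSI)
calling from targeted-sequencing repeat-length histograms; MSI calling from
five-marker PCR fragment profiles; hypermutation classification from somatic
mutation burden; MMR-gene lesion detection (frameshifts, split-read
rearrangements, exon copy losses) with a bi-allelic inactivation verdict;
and patient-level cohort reporting. "Desk scale" means every input is a
small plain-text table: read alignment, somatic calling from raw reads and
consequence annotation are upstream of this package and out of scope.

# The synthetic-data generator

The generator is first-class, tested code, not a fixture: it emits every
input the callers consume, together with a truth sidecar, so that each
caller can be validated by parameter recovery. All randomness flows from
`sim_config(seed)`; per-specimen streams are derived deterministically from
the seed and the specimen id, so one seed reproduces a cohort byte for
byte.

## Stutter model

PCR replication slippage at mononucleotide runs dominantly deletes repeat
units. We model the number of units `k` a read slips below its true allele
as geometric,

$$P(k) = (1 - p)\,p^{k}, \qquad k = 0, 1, 2, \ldots$$

truncated at 12 units and renormalized (`stutter_pmf()`). The default
`stutter_prob` p = 0.02 puts about 2% of reads one unit short of the
allele — visible as a stutter shoulder but safely below the 5% allele
support threshold at typical depths, which is what makes a normal baseline
with near-unit allele counts realistic. The closed form is exported so
tests can compare empirical histograms against it (three-standard-error
bounds at depth 10^4; chi-square goodness-of-fit across seeds).

## MSI allele shifts

A destabilized locus gains one or two novel allele modes at
`reference - k` with `k ~ 1 + Poisson(msi_shift_mean)` (default mean 1.5),
each carrying roughly 20–40% of reads and its own stutter tail. An
MMR-deficient specimen destabilizes exactly
`round(msi_locus_fraction * n_loci)` loci (default 0.5 of 146, i.e. 73);
the destabilized set is recorded in the truth sidecar. The 0.5 default
reflects the strong multi-locus instability expected of bi-allelically
MMR-inactivated tumors, comfortably above the 0.20 decision bound — the
generator tests detection of a clear phenotype, not the assay's limiting
dilution.

## Somatic variant tables

A specimen's table contains exactly `true_burden` protein-altering somatic
variants (planted lesion frameshifts and, in MSI-high specimens, the two
mosaic MSH6 homopolymer-tract frameshifts count toward this total, as they
would in an exome), about 20% as many synonymous passengers, and three
contaminant classes the filters must remove: germline records drawn with
normal-sample allele balance ≥ 0.40, common-variant-flagged records, and
sub-10%-VAF records. `contamination_germline_rate` (default 0.3) sets the
germline share of the table. Because contaminants are constructed to fail
exactly one filter each, the filtered protein-altering count equals
`true_burden` exactly, for every seed — the burden-recovery property is
deterministic by design.

## Structural-variant and copy-number evidence

Rearrangements are emitted as minimal clipped-read records (clip point,
side, strand, partner coordinates), `sv_support = 12` reads per breakpoint,
noiseless by default (`sv_jitter = 0`) plus a handful of scattered
singleton reads. Orientation encodes type: opposite partner strands mean
inversion, crossed chromosomes translocation, colinear same-strand pairs
deletion. Copy losses scale exon depth ratios to Normal(0.5, 0.05)
(heterozygous) or Normal(0.03, 0.01) (homozygous) against a Normal(1.0,
0.05) neutral background — values chosen so that the caller's thresholds
separate states by many standard deviations.

## PCR profiles

Each of the five mononucleotide markers (NR-21, BAT-26, BAT-25, NR-24,
MONO-27; modal repeat lengths encoded by the names) gets a normal trace
with a main peak and a two-unit geometric stutter shoulder. Unstable
markers add a novel tumor allele 3–6 units below the normal mode at
50–90% of the main intensity.

## What the generator does not emulate

Base-level sequencing error, quality scores, insertion-type stutter,
capture GC bias, tumor purity and subclonal structure, real mSINGS
baseline dispersion, and electropherogram artifacts are all absent.
Passing recovery tests therefore demonstrates the callers' logic —
thresholds, boundary semantics, bookkeeping — under the stated noise
model, not clinical performance on real data.

# MSI by NGS

The scorer follows the unstable-locus-fraction approach for targeted
panels. Per locus, the statistic is the number of distinct repeat lengths
holding at least `support_fraction = 0.05` of the locus depth
(`count_alleles()`). A baseline over ≥ 2 normal controls stores the mean
and standard deviation of that count per locus (`train_baseline()`);
controls below `min_depth = 30` reads at a locus are dropped from that
locus, and loci with fewer than two passing controls are untrainable. The
SD is the population form (divide by n): the control set is treated as the
reference population itself, and with sane control numbers the difference
is small but worth pinning for reproducibility.

A tumour locus below 30× is depth-filtered (excluded from numerator and
denominator); otherwise it is unstable when its allele count strictly
exceeds `mean + 3·SD` — "statistically greater" operationalized as a
three-sigma exceedance, with ties stable. The specimen is MSI-high when
the unstable fraction strictly exceeds 0.20; fewer than
`min_evaluable = 20` evaluated loci gives an indeterminate call (the
clinically used minimum is not published; 20 loci keeps the fraction's
granularity below the decision bound).

# MSI by PCR

A marker is unstable when its tumor trace has a peak (≥ 10% of the trace
maximum) at least `shift_min = 3` repeat units from the normal modal
allele; the specimen is MSI-positive with two or more unstable markers of
five. The kit's interpretive rules are proprietary, so the shift is
measured from the normal *mode*: measuring from every above-threshold
normal peak would let the stutter shoulder (which legitimately extends
2–3 units below the allele) mask any 3-unit novel allele, contradicting
the intended boundary behaviour (a novel peak one unit from the mode is
stutter; four units away is instability). Both parameters are exposed.

# Hypermutation

`filter_somatic()` retains variants with tumor VAF ≥ 0.10 (inclusive:
"at least 10%"), no common-variant flag (the dbSNP-v137-minus-disease
check arrives as a precomputed boolean; shipping dbSNP is out of desk
scale), and maximum germline allele balance < 0.40 (records at 40% or
more removed). The filter preserves order, is idempotent, and rejects
malformed fractions with a logged reason rather than silently keeping
them. `classify_burden()` counts protein-altering records and calls
hypermutation strictly above 300 — a burden of exactly 300 is negative.
Whether indels or only SNVs contribute is not specified upstream; all
protein-altering records count here. In PDX mode (no matched normal) the
germline filter is disabled, only the common-variant flag applies, and
the count is reported without a threshold verdict, because the 300
definition presumes matched-normal subtraction.

# MMR lesions

`cluster_breakpoints()` groups clip points by chromosome and clip side,
merges points within `window = 10` bp, takes the modal position as the
breakpoint, and pairs clusters through their modal partner coordinates
(reciprocally, within the same window); both sides must reach
`min_support = 4` reads. On noiseless input the modal position equals the
planted position exactly; with jitter up to `window/2` the recovered
position stays within the window. `call_exon_cnv()` thresholds exon depth
ratios at `loss_max = 0.70` and `homozygous_max = 0.15` and merges runs of
at least `min_consecutive = 2` like-state exons into segments; the
thresholds sit between the generator's planted means (0.5 / 0.03) and the
neutral band (1.0) by several SDs, and a single-exon dip is still called
per-exon but not segmented. Negative ratios are input errors.

Zygosity: frameshift/nonsense variants (after artifact exclusion),
gene-splitting rearrangements (one breakpoint inside the gene suffices;
one rearrangement counts once per gene), and copy-loss segments are
pooled per gene. A homozygous loss alone is biallelic; otherwise ≥ 2
events are biallelic, 1 monoallelic, 0 none. The two mosaic MSH6
homopolymer-tract frameshifts are excluded by coordinate catalog,
independent of the specimen's MSI status — whether such exclusion should
be status-dependent is unresolved upstream, and the catalog-wide rule is
the simpler, order-independent choice.

# Assay scores

The IHC score is `sum(intensity × percent of cells)` over intensity levels
0/1/2, range 0–200, nuclear staining only; duplicate cores are averaged,
invalid cores dropped, and a sample with no valid core is missing.
Methylation quantitation fits `Cq = a + b·log10(quantity)` by least
squares on calibrator dilutions, inverts it per assay, and reports
methyl/ALUC4 and unmethyl/ALUC4 ratios with the s.e.m. over paired
replicates when available. A methyl assay with no amplification or with a
Cq more than one cycle beyond the last standard is reported as
"not detected" with ratio 0 (the upstream report is binary non-detection
without a numeric cutoff, so the curve's reach defines detectability);
Cq more than one cycle outside the standard range is flagged as
extrapolation. The noiseless round trip (quantities → line → quantities)
is exact to < 1e-9 relative error.

# Cohort reporting

`unique_prevalence()` collapses PDX↔autopsy links by union (invariant to
link direction and entry order) and counts a unique patient as
hypermutated if any linked entry is; discordant linked pairs are counted
once, as hypermutated, and flagged. Percentages are reported both exactly
and rounded to one decimal with round-half-even — 7/60 prints as 11.7
here, while upstream reports of the same fraction print 11.6 and 12;
emitting both forms avoids the ambiguity. `concordance()` computes
per-patient all-sites-agree flags and a rate over multi-site patients
(vacuously 1 with the multi-site count shown). `mechanism_table()` audits
the expected pattern — every hypermutated patient should be MSI-positive
(by either assay) and carry at least one MMR lesion — reporting
violations rather than erroring, and marking incomplete rows.

The reference cohort fixture (`reference_cohort_manifest()`) mirrors the
modeled study: 15 PDX lines (3 hypermutated), 50 autopsy patients (5
hypermutated, with the published burdens and multi-site specimen lists for
the 11 characterized patients), five cross-cohort links, structured
lesions per characterized entry including a lymph-node-private MLH1
frameshift. The 39 uncharacterized autopsy patients and all PDX burdens
are synthetic (deterministic, sub- or supra-threshold as appropriate); a
copy-loss event on chromosome 2 outside the three modeled MMR genes is
not representable and is omitted.

# Problem sizes and runtime

Test and acceptance runs use the full 146-locus panel at mean depth 200
for MSI recovery (100 MSI-high + 100 microsatellite-stable specimens),
a 5-locus panel for the 100-seed burden-recovery loop (the variant table
does not depend on panel size), and the full 65-entry / 81-specimen
reference cohort for the end-to-end run. These sizes were chosen so the
whole suite completes in about two minutes on one CPU while keeping every
statistical check at its stated strength.

# Known limitations

Single tumor clone, no purity model; mononucleotide repeats only; the
split-read clusterer pairs clusters greedily and is not designed for
overlapping events closer than the window; the CNV caller assumes
pre-normalized depth ratios; PCR scoring assumes a single-allele normal
(germline-heterozygous markers would need a multi-mode normal model); and
generator noise parameters are free knobs, not calibrated to any empirical
panel's stutter distribution.
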