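#' Simulate normal-control histogram tables
#'
#' Controls are microsatellite-stable specimens used to train the per-locus
#' baseline; they share the panel and noise parameters of the tumour
#' specimens.
#'
#' @param n_controls Number of controls (default 10).
#' @param panel Panel from [msi_panel()].
#' @param config A [sim_config()].
#' @return Long-format histogram table covering all controls.
#' @export
simulate_controls <- function(n_controls = 10L, panel = msi_panel(),
                              config = sim_config()) {
  .assert(n_controls >= 2L, "need >= 2 controls to train a baseline")
  do.call(rbind, lapply(seq_len(n_controls), function(i)
    simulate_histograms(sprintf("CTRL_%02d", i), panel,
                        unstable_loci = character(), config = config)))
}

#' Run every caller on one simulated specimen
#'
#' Applies, in order: MSI-by-NGS scoring against the supplied baseline,
#' the five-marker PCR call, somatic filtering plus burden classification,
#' and lesion detection (breakpoint clustering, exon CNV, artifact-excluded
#' zygosity assessment on the filtered variants).
#'
#' @param sim A [simulate_specimen()] result.
#' @param baseline A [train_baseline()] result.
#' @param burden_threshold Hypermutation threshold (default 300).
#' @param pdx_mode Tumor-only filtering for the burden step.
#' @return List of class `specimen_calls`: `msi_ngs` (`msi_result`),
#'   `msi_pcr` (`msi_pcr_result`), `burden` (`burden_result`), `lesions`
#'   (`gene_lesion_set`), `rearrangements`, `cnv`.
#' @export
analyze_specimen <- function(sim, baseline, burden_threshold = 300L,
                             pdx_mode = FALSE) {
  .assert(inherits(sim, "sim_specimen"), "sim must be a sim_specimen")
  msi_ngs <- msi_call_specimen(sim$histograms, baseline)
  msi_pcr <- call_msi_pcr(sim$pcr)
  filtered <- filter_somatic(sim$variants, pdx_mode = pdx_mode)
  burden <- classify_burden(filtered, threshold = burden_threshold,
                            specimen_id = sim$truth$specimen_id,
                            n_input = nrow(sim$variants), pdx_mode = pdx_mode)
  rearr <- cluster_breakpoints(sim$split_reads)
  cnv <- call_exon_cnv(sim$exon_depth)
  lesions <- gene_lesions(variants = filtered, rearrangements = rearr,
                          cnv_segments = cnv$segments)
  structure(list(msi_ngs = msi_ngs, msi_pcr = msi_pcr, burden = burden,
                 lesions = lesions, rearrangements = rearr, cnv = cnv),
            class = "specimen_calls")
}

#' Run the full pipeline over a simulated cohort
#'
#' Trains the MSI baseline on freshly simulated controls, analyzes every
#' specimen, aggregates calls to the entry (patient / PDX line) level with
#' the any-site rule, and assembles the prevalence, concordance and
#' mechanism reports.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config The [sim_config()] used for the cohort (controls are drawn
#'   from a shifted seed of the same configuration).
#' @param n_controls Controls for baseline training (default 10).
#' @param burden_threshold Hypermutation threshold (default 300).
#' @return List of class `cohort_report`: `specimen_calls` (one row per
#'   specimen), `entry_calls` (one row per entry), `mechanism`
#'   ([mechanism_table()]), `prevalence` ([unique_prevalence()]),
#'   `concordance_hyper` ([concordance()] on hypermutation status) and the
#'   per-specimen `details` list.
#' @export
analyze_cohort <- function(cohort, config = sim_config(), n_controls = 10L,
                           burden_threshold = 300L) {
  .assert(inherits(cohort, "sim_cohort"), "cohort must be a sim_cohort")
  ctrl_config <- config
  ctrl_config$seed <- .derive_seed(config$seed, "cohort-controls")
  panel <- msi_panel(config$n_loci)
  baseline <- train_baseline(simulate_controls(n_controls, panel, ctrl_config))
  details <- lapply(cohort$specimens, analyze_specimen, baseline = baseline,
                    burden_threshold = burden_threshold)
  specs <- cohort$manifest$specimens
  specimen_calls <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    d <- details[[specs$specimen_id[i]]]
    data.frame(
      specimen_id = specs$specimen_id[i], entry_id = specs$entry_id[i],
      site = specs$site[i],
      msi_ngs = d$msi_ngs$call, fraction_unstable = d$msi_ngs$fraction_unstable,
      msi_pcr = d$msi_pcr$call, n_pcr_unstable = d$msi_pcr$n_unstable,
      burden = d$burden$n_protein_altering,
      hypermutated = d$burden$hypermutated,
      n_mmr_events = nrow(d$lesions$events),
      verdict = .best_verdict(d$lesions$verdicts$zygosity_verdict),
      stringsAsFactors = FALSE)
  }))
  rownames(specimen_calls) <- NULL
  entry_calls <- do.call(rbind, lapply(split(specimen_calls,
                                             specimen_calls$entry_id),
                                       function(g) data.frame(
    entry_id = g$entry_id[1], n_sites = nrow(g),
    hypermutated = any(g$hypermutated),
    msi_ngs = if (any(g$msi_ngs == "MSI-high")) "MSI-high" else g$msi_ngs[1],
    msi_pcr = if (any(g$msi_pcr == "MSI-positive")) "MSI-positive" else g$msi_pcr[1],
    n_mmr_events = max(g$n_mmr_events),
    verdict = .best_verdict(g$verdict),
    stringsAsFactors = FALSE)))
  rownames(entry_calls) <- NULL
  mech <- mechanism_table(data.frame(
    patient_id = entry_calls$entry_id,
    hypermutated = entry_calls$hypermutated,
    msi_ngs = entry_calls$msi_ngs, msi_pcr = entry_calls$msi_pcr,
    n_mmr_events = entry_calls$n_mmr_events,
    verdict = entry_calls$verdict, stringsAsFactors = FALSE))
  prev <- unique_prevalence(cohort$manifest,
                            data.frame(entry_id = entry_calls$entry_id,
                                       hypermutated = entry_calls$hypermutated,
                                       stringsAsFactors = FALSE))
  conc <- concordance(data.frame(patient_id = specimen_calls$entry_id,
                                 specimen_id = specimen_calls$specimen_id,
                                 call = specimen_calls$hypermutated,
                                 stringsAsFactors = FALSE))
  structure(list(specimen_calls = specimen_calls, entry_calls = entry_calls,
                 mechanism = mech, prevalence = prev,
                 concordance_hyper = conc, details = details,
                 baseline = baseline),
            class = "cohort_report")
}

.best_verdict <- function(v) {
  for (lvl in c("biallelic", "monoallelic")) if (lvl %in% v) return(lvl)
  "none"
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(paste0("<cohort_report> %d specimens, %d entries; prevalence ",
                     "%d/%d (%.1f%%); mechanism violations: %d\n"),
              nrow(x$specimen_calls), nrow(x$entry_calls),
              x$prevalence$numerator, x$prevalence$denominator,
              x$prevalence$percent, attr(x$mechanism, "n_violations")))
  invisible(x)
}
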