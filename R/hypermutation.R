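#' Somatic-variant filtering for burden estimation
#'
#' Retains exactly the variants that satisfy all of: tumor variant allele
#' fraction at least `vaf_min` (inclusive — "at least 10%"), not flagged as a
#' common (dbSNP-style) variant, and a maximum germline allele balance
#' strictly below `germline_ab_max` (records at 40% or more in any germline
#' sample are removed). Input order is preserved and the filter is
#' idempotent. Records whose fractions fall outside [0,1] are rejected and
#' reported via `attr(, "rejected")`.
#'
#' In PDX mode (no matched normal available) the germline-allele-balance
#' filter is disabled and only the common-variant flag is applied, mirroring
#' comparison of tumor-only calls against a database of common germline
#' variants.
#'
#' @param variants `data.frame` with at least `tumor_vaf`,
#'   `normal_allele_balance`, `common_variant`.
#' @param vaf_min Minimum tumor VAF (default 0.10, inclusive).
#' @param germline_ab_max Germline allele-balance rejection bound
#'   (default 0.40; records `>=` this value are removed).
#' @param pdx_mode Disable the germline filter (tumor-only specimens).
#' @return Filtered `data.frame` (order preserved) with attribute `rejected`
#'   listing malformed records and reasons.
#' @export
filter_somatic <- function(variants, vaf_min = 0.10, germline_ab_max = 0.40,
                           pdx_mode = FALSE) {
  if (nrow(variants) == 0L) {
    attr(variants, "rejected") <- variants
    return(variants)
  }
  ok_frac <- function(x) !is.na(x) & x >= 0 & x <= 1
  valid <- ok_frac(variants$tumor_vaf) &
    (pdx_mode | ok_frac(variants$normal_allele_balance))
  rejected <- variants[!valid, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "fraction outside [0,1]"
    message(sprintf("filter_somatic: rejected %d malformed record(s)",
                    nrow(rejected)))
  }
  v <- variants[valid, , drop = FALSE]
  keep <- v$tumor_vaf >= vaf_min & !v$common_variant
  if (!pdx_mode) keep <- keep & v$normal_allele_balance < germline_ab_max
  out <- v[keep, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Classify a specimen's mutation burden
#'
#' Counts protein-altering variants among the (already filtered) somatic
#' calls and classifies the specimen as hypermutated when that count
#' strictly exceeds `threshold` (the ">300 protein-altering mutations"
#' definition; a burden of exactly 300 is not hypermutated). In PDX mode the
#' count is a novel-SNV-style tally from tumor-only filtering and is reported
#' without applying the threshold (`hypermutated = NA`), since the threshold
#' is defined for matched-normal burden.
#'
#' @param variants Filtered variant `data.frame` (see [filter_somatic()]);
#'   must contain `protein_altering`.
#' @param threshold Burden threshold (default 300, strict `>`).
#' @param specimen_id Label carried into the result.
#' @param n_input Optional pre-filter record count for bookkeeping.
#' @param pdx_mode Report the count without thresholding.
#' @return Object of class `burden_result`: list with `specimen_id`,
#'   `n_input`, `n_pass`, `n_protein_altering`, `hypermutated`.
#' @export
classify_burden <- function(variants, threshold = 300L, specimen_id = NA_character_,
                            n_input = nrow(variants), pdx_mode = FALSE) {
  n_pass <- nrow(variants)
  n_pa <- sum(variants$protein_altering)
  hyper <- if (pdx_mode) NA else n_pa > threshold
  structure(list(specimen_id = specimen_id, n_input = n_input,
                 n_pass = n_pass, n_protein_altering = n_pa,
                 hypermutated = hyper),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result> %s: %d protein-altering of %d passing (%s)\n",
              x$specimen_id, x$n_protein_altering, x$n_pass,
              if (is.na(x$hypermutated)) "tumor-only count"
              else if (x$hypermutated) "hypermutated" else "not hypermutated"))
  invisible(x)
}

#' Patient-level hypermutation classification across specimens
#'
#' Aggregates per-specimen burden results by patient: a patient is
#' hypermutated if any site is (any-site rule), and carries a concordance
#' flag that is `TRUE` when all of the patient's sites agree
#' (single-specimen patients are trivially concordant).
#'
#' @param burden_df `data.frame` with `specimen_id`, `n_protein_altering`,
#'   `hypermutated`.
#' @param specimen_patient `data.frame` mapping `specimen_id` to
#'   `patient_id`; every specimen must be mapped.
#' @return `data.frame` with one row per patient: `patient_id`, `n_sites`,
#'   `hypermutated`, `concordant`, `max_burden`.
#' @export
classify_cohort <- function(burden_df, specimen_patient) {
  missing <- setdiff(burden_df$specimen_id, specimen_patient$specimen_id)
  .assert(length(missing) == 0L,
          sprintf("specimen(s) with unknown patient: %s",
                  paste(missing, collapse = ", ")))
  m <- merge(burden_df, specimen_patient, by = "specimen_id")
  out <- do.call(rbind, lapply(split(m, m$patient_id), function(g) {
    data.frame(patient_id = g$patient_id[1], n_sites = nrow(g),
               hypermutated = any(g$hypermutated),
               concordant = length(unique(g$hypermutated)) == 1L,
               max_burden = max(g$n_protein_altering),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
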