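#' Unique-patient hypermutation prevalence with cohort overlap collapsed
#'
#' PDX lines derived from autopsy patients describe the same patient twice;
#' linked entries are collapsed into one unique patient (a patient is
#' hypermutated if any linked entry is) before counting. The collapse is a
#' union over link pairs, so the result does not depend on link direction or
#' on entry ordering.
#'
#' @param manifest A [cohort_manifest()].
#' @param calls `data.frame` with `entry_id` and `hypermutated`; every
#'   manifest entry must have a call.
#' @return List of class `prevalence_result`: `numerator` (unique
#'   hypermutated patients), `denominator` (unique patients),
#'   `percent_exact`, `percent` (one decimal, round-half-even) and
#'   `discordant_links` (unique patients whose linked entries disagree —
#'   counted as hypermutated, flagged).
#' @examples
#' m <- reference_cohort_manifest()
#' calls <- data.frame(entry_id = m$entries$entry_id,
#'                     hypermutated = m$entries$hypermutated)
#' unique_prevalence(m, calls) # 7 of 60
#' @export
unique_prevalence <- function(manifest, calls) {
  entries <- manifest$entries
  missing <- setdiff(entries$entry_id, calls$entry_id)
  .assert(length(missing) == 0L,
          sprintf("entries without a call: %s", paste(missing, collapse = ", ")))
  # union-find over link pairs
  parent <- setNames(entries$entry_id, entries$entry_id)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in which(!is.na(entries$link))) {
    a <- find(entries$entry_id[i]); b <- find(entries$link[i])
    .assert(!is.na(b), sprintf("unresolvable link for %s", entries$entry_id[i]))
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  key <- vapply(entries$entry_id, find, character(1))
  hyper <- setNames(calls$hypermutated[match(entries$entry_id, calls$entry_id)],
                    entries$entry_id)
  groups <- split(hyper, key)
  num <- sum(vapply(groups, any, logical(1)))
  den <- length(groups)
  discordant <- names(groups)[vapply(groups, function(g)
    length(unique(g)) > 1L, logical(1))]
  structure(list(numerator = num, denominator = den,
                 percent_exact = 100 * num / den,
                 percent = round(100 * num / den, 1),
                 discordant_links = discordant),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf("<prevalence_result> %d/%d unique patients hypermutated (%.1f%%)\n",
              x$numerator, x$denominator, x$percent))
  invisible(x)
}

#' Multi-site call concordance per patient
#'
#' A patient's sites are concordant when every specimen carries the same
#' call. The cohort rate is computed over multi-site patients only; with no
#' multi-site patients it is vacuously 1 (with `n_multisite = 0` so the
#' vacuity is visible).
#'
#' @param calls `data.frame` with `patient_id`, `specimen_id` and `call`
#'   (any atomic call — logical hypermutation status, MSI call, ...).
#' @return List: `per_patient` (`patient_id`, `n_sites`, `concordant`),
#'   `rate`, `n_multisite`.
#' @export
concordance <- function(calls) {
  per <- do.call(rbind, lapply(split(calls, calls$patient_id), function(g)
    data.frame(patient_id = g$patient_id[1], n_sites = nrow(g),
               concordant = length(unique(g$call)) == 1L,
               stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  multi <- per[per$n_sites > 1L, , drop = FALSE]
  rate <- if (nrow(multi)) mean(multi$concordant) else 1.0
  list(per_patient = per, rate = rate, n_multisite = nrow(multi))
}

#' Mechanism cross-tabulation: hypermutation, MSI and MMR lesions
#'
#' One row per patient linking the burden classification, both MSI calls and
#' the MMR lesion evidence, with a consistency audit: a hypermutated patient
#' lacking MSI (by both assays) or lacking any MMR lesion violates the
#' expected mechanism and is flagged (a report, not an error). Lesion-positive
#' but MSI-negative, non-hypermutated patients (the monoallelic-carrier
#' pattern) are not violations. Rows with missing inputs are marked
#' incomplete and excluded from the audit.
#'
#' @param calls `data.frame` with one row per patient: `patient_id`,
#'   `hypermutated` (logical), `msi_ngs` (`"MSI-high"` etc.), `msi_pcr`
#'   (`"MSI-positive"` etc.), `n_mmr_events` (integer), `verdict` (best
#'   per-gene zygosity verdict, informational).
#' @return `data.frame` `mechanism_table` with added `msi`, `incomplete` and
#'   `violation` columns; total violations in `attr(, "n_violations")`.
#' @export
mechanism_table <- function(calls) {
  if (nrow(calls) == 0L) {
    out <- cbind(calls, msi = logical(), incomplete = logical(),
                 violation = logical())
    attr(out, "n_violations") <- 0L
    return(out)
  }
  incomplete <- is.na(calls$hypermutated) | is.na(calls$msi_ngs) |
    is.na(calls$msi_pcr) | is.na(calls$n_mmr_events)
  msi <- calls$msi_ngs == "MSI-high" | calls$msi_pcr == "MSI-positive"
  violation <- ifelse(incomplete, NA,
                      calls$hypermutated & (!msi | calls$n_mmr_events == 0L))
  out <- cbind(calls, msi = msi, incomplete = incomplete,
               violation = violation)
  attr(out, "n_violations") <- sum(violation, na.rm = TRUE)
  out
}
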