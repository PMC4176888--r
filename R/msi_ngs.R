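#' Build a single-locus histogram from a long-format histogram table
#'
#' @param tab Long-format table (`specimen_id`, `locus_id`, `repeat_length`,
#'   `read_count`) as emitted by [simulate_histograms()].
#' @param locus_id Locus to extract.
#' @param specimen_id Optional specimen filter (required if `tab` holds
#'   several specimens).
#' @return A `length_histogram`.
#' @export
hist_from_table <- function(tab, locus_id, specimen_id = NULL) {
  if (!is.null(specimen_id)) tab <- tab[tab$specimen_id == specimen_id, ]
  .assert(length(unique(tab$specimen_id)) <= 1L,
          "tab holds several specimens; pass specimen_id")
  rows <- tab[tab$locus_id == locus_id, ]
  counts <- setNames(as.integer(rows$read_count), rows$repeat_length)
  counts <- counts[order(as.integer(names(counts)))]
  structure(list(locus_id = locus_id, counts = counts,
                 depth = sum(rows$read_count)),
            class = "length_histogram")
}

#' Count distinct supported alleles at a microsatellite locus
#'
#' The per-locus instability statistic: the number of distinct repeat lengths
#' whose read count reaches `support_fraction` of the locus depth. MSI
#' manifests as an allele count exceeding what normal controls show.
#'
#' @param hist A `length_histogram` with depth > 0.
#' @param support_fraction Minimum fraction of locus depth a repeat length
#'   must carry to count as an allele (default 0.05).
#' @return Integer allele count.
#' @examples
#' h <- structure(list(locus_id = "L", counts = c(`24` = 30L, `25` = 70L),
#'                     depth = 100L), class = "length_histogram")
#' count_alleles(h) # 2
#' @export
count_alleles <- function(hist, support_fraction = 0.05) {
  .assert(hist$depth > 0, "count_alleles undefined at zero depth; filter first")
  .assert(is.numeric(support_fraction) && support_fraction > 0 &&
            support_fraction < 1, "support_fraction must be in (0,1)")
  sum(hist$counts >= support_fraction * hist$depth)
}

#' Train the per-locus normal-control baseline
#'
#' For every locus, computes the mean and population standard deviation of
#' the supported-allele count across normal controls. A control whose depth
#' at a locus is below `min_depth` is dropped from that locus's baseline;
#' loci with fewer than two passing controls are untrainable and excluded
#' from evaluation.
#'
#' @param control_tab Long-format histogram table covering >= 2 control
#'   specimens.
#' @param support_fraction Passed to [count_alleles()].
#' @param min_depth Minimum locus depth for a control to contribute
#'   (default 30).
#' @return Object of class `msi_baseline`: a `data.frame` with `locus_id`,
#'   `mean_allele_count`, `sd_allele_count`, `n_controls`; untrainable loci
#'   are recorded in `attr(, "untrainable")`.
#' @export
train_baseline <- function(control_tab, support_fraction = 0.05,
                           min_depth = 30L) {
  ids <- unique(control_tab$specimen_id)
  .assert(length(ids) >= 2L, "need >= 2 control specimens")
  loci <- unique(control_tab$locus_id)
  rows <- lapply(loci, function(loc) {
    counts <- vapply(ids, function(sid) {
      h <- hist_from_table(control_tab, loc, sid)
      if (h$depth < min_depth) NA_integer_ else count_alleles(h, support_fraction)
    }, integer(1))
    counts <- counts[!is.na(counts)]
    if (length(counts) < 2L) return(NULL)
    data.frame(locus_id = loc, mean_allele_count = mean(counts),
               sd_allele_count = .pop_sd(counts),
               n_controls = length(counts), stringsAsFactors = FALSE)
  })
  trained <- do.call(rbind, rows)
  untrainable <- setdiff(loci, trained$locus_id)
  structure(trained, class = c("msi_baseline", "data.frame"),
            untrainable = untrainable,
            support_fraction = support_fraction, min_depth = min_depth)
}

# population SD (divide by n): the controls are treated as the full
# reference population, not a sample from one
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Evaluate one locus against its baseline
#'
#' A locus is `filtered-low-depth` below `min_depth`; otherwise it is
#' `unstable` when its supported-allele count strictly exceeds
#' `mean + k_sd * sd` of the control baseline (ties are stable).
#'
#' @param hist A `length_histogram`.
#' @param baseline_row The matching row of a [train_baseline()] result.
#' @param min_depth Depth filter (default 30).
#' @param k_sd Number of baseline standard deviations defining "statistically
#'   greater" (default 3).
#' @param support_fraction Passed to [count_alleles()].
#' @return One of `"unstable"`, `"stable"`, `"filtered-low-depth"`.
#' @export
evaluate_locus <- function(hist, baseline_row, min_depth = 30L, k_sd = 3,
                           support_fraction = 0.05) {
  .assert(identical(hist$locus_id, baseline_row$locus_id),
          sprintf("locus/baseline mismatch: %s vs %s", hist$locus_id,
                  baseline_row$locus_id))
  if (hist$depth < min_depth) return("filtered-low-depth")
  n <- count_alleles(hist, support_fraction)
  cutoff <- baseline_row$mean_allele_count + k_sd * baseline_row$sd_allele_count
  if (n > cutoff) "unstable" else "stable"
}

#' Specimen-level MSI call from per-locus statuses
#'
#' The unstable-locus fraction is computed over evaluated loci only
#' (depth-filtered loci are excluded from numerator and denominator); the
#' specimen is MSI-high when the fraction strictly exceeds `msi_threshold`.
#' Fewer than `min_evaluable` evaluated loci yields an indeterminate call.
#'
#' @param statuses Character vector of per-locus statuses from
#'   [evaluate_locus()], named by locus.
#' @param msi_threshold MSI-high decision bound (default 0.20, strict `>`).
#' @param min_evaluable Minimum evaluated loci for a confident call
#'   (default 20).
#' @return Object of class `msi_result`: list with `status` (the per-locus
#'   vector), `n_evaluated`, `n_unstable`, `fraction_unstable`, `call`.
#' @export
call_specimen <- function(statuses, msi_threshold = 0.20, min_evaluable = 20L) {
  .assert(all(statuses %in% c("unstable", "stable", "filtered-low-depth")),
          "invalid locus status")
  n_eval <- sum(statuses != "filtered-low-depth")
  n_unst <- sum(statuses == "unstable")
  frac <- if (n_eval > 0L) n_unst / n_eval else NA_real_
  call <- if (n_eval < min_evaluable) "indeterminate"
          else if (frac > msi_threshold) "MSI-high" else "MSI-negative"
  structure(list(status = statuses, n_evaluated = n_eval, n_unstable = n_unst,
                 fraction_unstable = frac, call = call),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("<msi_result> %s: %d/%d loci unstable (fraction %.3f)\n",
              x$call, x$n_unstable, x$n_evaluated,
              if (is.na(x$fraction_unstable)) NaN else x$fraction_unstable))
  invisible(x)
}

#' Call MSI for one specimen from its histogram table
#'
#' Convenience wrapper: evaluates every baseline-trained locus and issues the
#' specimen-level call. Untrainable loci are skipped entirely; trained loci
#' absent from the specimen table have zero depth and are depth-filtered.
#'
#' @param specimen_tab Long-format histogram table for one specimen.
#' @param baseline A [train_baseline()] result.
#' @param min_depth,k_sd,support_fraction,msi_threshold,min_evaluable See
#'   [evaluate_locus()] and [call_specimen()].
#' @return An `msi_result`.
#' @export
msi_call_specimen <- function(specimen_tab, baseline, min_depth = 30L,
                              k_sd = 3, support_fraction = 0.05,
                              msi_threshold = 0.20, min_evaluable = 20L) {
  # baseline loci absent from the specimen have depth 0 and are depth-filtered
  loci <- baseline$locus_id
  statuses <- vapply(loci, function(loc) {
    h <- hist_from_table(specimen_tab, loc)
    evaluate_locus(h, baseline[baseline$locus_id == loc, ], min_depth, k_sd,
                   support_fraction)
  }, character(1))
  names(statuses) <- loci
  call_specimen(statuses, msi_threshold, min_evaluable)
}
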