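#' Quasi-continuous IHC protein-expression score
#'
#' Score = sum over staining intensity levels (0 = none, 1 = faint, 2 =
#' strong nuclear staining) of intensity times the percentage of cells at
#' that intensity; range 0 (no expression) to 200 (all cells at maximal
#' intensity). Unscored cells count as intensity 0.
#'
#' @param intensity_percents Named numeric vector with names among
#'   `"0"`, `"1"`, `"2"` giving percent of cells at each intensity;
#'   percents must be non-negative and sum to at most 100.
#' @return Score in \[0, 200\].
#' @examples
#' ihc_score(c(`1` = 50, `2` = 30)) # 110
#' @export
ihc_score <- function(intensity_percents) {
  .assert(all(names(intensity_percents) %in% c("0", "1", "2")),
          "intensity levels must be 0, 1 or 2")
  .assert(all(intensity_percents >= 0), "percents must be non-negative")
  .assert(sum(intensity_percents) <= 100 + 1e-9,
          "percents must sum to at most 100")
  sum(as.numeric(names(intensity_percents)) * intensity_percents)
}

#' Score a sample over duplicate tissue cores
#'
#' Tissue cores are run in duplicate; valid cores are scored with
#' [ihc_score()] and averaged. Damaged or missing cores (`NULL` or all-`NA`
#' entries) are dropped, and a sample with no valid core is reported as
#' missing (`NA`).
#'
#' @param cores List of per-core intensity-percent vectors.
#' @return Mean core score, or `NA` if no core is valid.
#' @export
ihc_score_sample <- function(cores) {
  valid <- Filter(function(co) !is.null(co) && length(co) && !all(is.na(co)),
                  cores)
  if (!length(valid)) return(NA_real_)
  mean(vapply(valid, ihc_score, numeric(1)))
}

#' Absolute methylation quantitation from a qPCR standard curve
#'
#' Fits the standard curve `Cq = a + b * log10(quantity)` by least squares
#' on the calibrator dilutions, inverts it for each sample assay
#' (methyl-MLH1, unmethyl-MLH1 and the ALUC4 input-DNA control), and reports
#' absolute quantities plus the methyl/ALUC4 and unmethyl/ALUC4 ratios.
#' With two or more replicates per assay the standard error of the mean is
#' reported for each ratio (replicates paired by order). A sample whose Cq
#' lies more than one cycle beyond the standard range is flagged as an
#' extrapolation; a methyl assay with no Cq (no amplification) or a Cq
#' beyond the last standard + 1 cycle is reported as methylation
#' not detected, with ratio 0.
#'
#' @param standards `data.frame` with `log10_quantity` and `cq` (>= 2
#'   distinct quantities).
#' @param samples `data.frame` with `assay` (one of `"methyl-MLH1"`,
#'   `"unmethyl-MLH1"`, `"ALUC4"`) and `cq` (`NA` = no amplification).
#' @return Object of class `methylation_result`: list with `curve`
#'   (intercept, slope), `quantities` (per assay: mean quantity, n
#'   replicates, extrapolated flag), `ratios` (`methyl_ratio`,
#'   `unmethyl_ratio`, with `sem` where computable) and `methyl_detected`.
#' @export
quantify_methylation <- function(standards, samples) {
  .assert(length(unique(standards$log10_quantity)) >= 2L,
          "need >= 2 distinct standard quantities")
  .assert(all(standards$cq > 0, na.rm = TRUE) &&
            all(samples$cq > 0, na.rm = TRUE), "Cq values must be > 0")
  fit <- stats::lm(cq ~ log10_quantity, data = standards)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  .assert(is.finite(b) && abs(b) > 1e-12, "singular standard curve fit")
  cq_range <- range(standards$cq)
  invert <- function(cq) 10^((cq - a) / b)
  assays <- c("methyl-MLH1", "unmethyl-MLH1", "ALUC4")
  per_assay <- lapply(assays, function(as_name) {
    cq <- samples$cq[samples$assay == as_name]
    cq_obs <- cq[!is.na(cq)]
    q <- invert(cq_obs)
    list(assay = as_name, n = length(cq_obs),
         quantities = q,
         mean_quantity = if (length(q)) mean(q) else 0,
         extrapolated = any(cq_obs < cq_range[1] - 1 | cq_obs > cq_range[2] + 1))
  })
  names(per_assay) <- assays
  methyl_cq <- samples$cq[samples$assay == "methyl-MLH1"]
  methyl_detected <- length(methyl_cq) > 0 && any(!is.na(methyl_cq)) &&
    all(methyl_cq[!is.na(methyl_cq)] <= cq_range[2] + 1)
  ratio_of <- function(num) {
    den <- per_assay[["ALUC4"]]
    if (den$n == 0L || den$mean_quantity == 0) return(list(value = NA_real_, sem = NA_real_))
    value <- num$mean_quantity / den$mean_quantity
    sem <- NA_real_
    if (num$n >= 2L && num$n == den$n) {
      reps <- num$quantities / den$quantities
      sem <- stats::sd(reps) / sqrt(length(reps))
    }
    list(value = value, sem = sem)
  }
  mr <- ratio_of(per_assay[["methyl-MLH1"]])
  ur <- ratio_of(per_assay[["unmethyl-MLH1"]])
  if (!methyl_detected && per_assay[["ALUC4"]]$n > 0L) mr$value <- 0
  structure(list(
    curve = c(intercept = a, slope = b),
    quantities = per_assay,
    ratios = list(methyl_ratio = mr$value, methyl_ratio_sem = mr$sem,
                  unmethyl_ratio = ur$value, unmethyl_ratio_sem = ur$sem),
    methyl_detected = methyl_detected
  ), class = "methylation_result")
}

#' @export
print.methylation_result <- function(x, ...) {
  cat(sprintf(paste0("<methylation_result> methyl/ALUC4 = %s%s, ",
                     "unmethyl/ALUC4 = %s\n"),
              format(x$ratios$methyl_ratio, digits = 4),
              if (!x$methyl_detected) " (methylation not detected)" else "",
              format(x$ratios$unmethyl_ratio, digits = 4)))
  invisible(x)
}
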