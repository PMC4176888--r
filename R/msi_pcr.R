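#' Score one PCR marker for instability
#'
#' A marker is unstable when its tumor profile contains a peak — a fragment
#' length carrying at least `intensity_fraction` of the tumor's maximum
#' intensity — located at least `shift_min` repeat units away from the
#' normal modal allele. Shifts smaller than `shift_min` lie within the
#' stutter window around the normal allele and never count. A profile with
#' an empty tumor or normal trace is unevaluable (`NA`).
#'
#' @param profile A `marker_profile` (see [simulate_pcr_profile()]), or any
#'   list with named numeric `tumor` and `normal` intensity vectors (names =
#'   fragment length).
#' @param shift_min Minimum repeat-unit shift distinguishing a novel allele
#'   from stutter (default 3).
#' @param intensity_fraction Peak-calling threshold as a fraction of the
#'   trace maximum (default 0.10).
#' @return `TRUE`, `FALSE`, or `NA` if unevaluable.
#' @export
marker_unstable <- function(profile, shift_min = 3L, intensity_fraction = 0.10) {
  .assert(all(profile$tumor >= 0) && all(profile$normal >= 0),
          "intensities must be non-negative")
  if (!length(profile$tumor) || !length(profile$normal) ||
      max(profile$tumor) == 0 || max(profile$normal) == 0) return(NA)
  tp <- as.integer(names(profile$tumor)[
    profile$tumor >= intensity_fraction * max(profile$tumor)])
  normal_mode <- as.integer(names(profile$normal)[which.max(profile$normal)])
  any(abs(tp - normal_mode) >= shift_min)
}

#' Five-marker MSI call from PCR fragment profiles
#'
#' Applies the pentaplex mononucleotide rule: a specimen showing instability
#' in two or more of the five markers is MSI-positive. Fewer than two
#' evaluable markers yields an indeterminate call.
#'
#' @param profiles List of `marker_profile`s (typically the five-element list
#'   from [simulate_pcr_specimen()]).
#' @param shift_min,intensity_fraction Passed to [marker_unstable()].
#' @return Object of class `msi_pcr_result`: list with `call`
#'   (`"MSI-positive"`, `"MSI-negative"` or `"indeterminate"`), `n_unstable`,
#'   `n_evaluable` and the per-marker logical vector `unstable`.
#' @export
call_msi_pcr <- function(profiles, shift_min = 3L, intensity_fraction = 0.10) {
  unstable <- vapply(profiles, marker_unstable, logical(1),
                     shift_min = shift_min,
                     intensity_fraction = intensity_fraction)
  names(unstable) <- vapply(profiles, function(p) p$marker, character(1))
  n_eval <- sum(!is.na(unstable))
  n_unst <- sum(unstable, na.rm = TRUE)
  call <- if (n_eval < 2L) "indeterminate"
          else if (n_unst >= 2L) "MSI-positive" else "MSI-negative"
  structure(list(call = call, n_unstable = n_unst, n_evaluable = n_eval,
                 unstable = unstable),
            class = "msi_pcr_result")
}

#' @export
print.msi_pcr_result <- function(x, ...) {
  cat(sprintf("<msi_pcr_result> %s: %d/%d markers unstable\n", x$call,
              x$n_unstable, x$n_evaluable))
  invisible(x)
}
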