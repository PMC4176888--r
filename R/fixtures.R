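#' Cohort manifest constructor
#'
#' A manifest describes a cohort for simulation and reporting: one row per
#' *entry* (a patient or a PDX line), the specimens (sites) belonging to each
#' entry, cross-cohort links (a PDX line to its source autopsy patient), and
#' the planted MMR lesions per entry.
#'
#' @param entries `data.frame` with `entry_id`, `cohort` (`"PDX"` or
#'   `"autopsy"`), `link` (linked `entry_id` or `NA`), `msi_status`,
#'   `hypermutated`, `true_burden`.
#' @param specimens `data.frame` with `specimen_id`, `entry_id`, `site`;
#'   specimen ids must be unique.
#' @param lesions Named list: `entry_id` -> list of lesion objects (see
#'   [lesion_frameshift()]).
#' @return Object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(entries, specimens, lesions = list()) {
  .assert(!anyDuplicated(specimens$specimen_id), "duplicate specimen ids")
  .assert(!anyDuplicated(entries$entry_id), "duplicate entry ids")
  bad_link <- setdiff(entries$link[!is.na(entries$link)], entries$entry_id)
  .assert(length(bad_link) == 0L,
          sprintf("unresolvable link(s): %s", paste(bad_link, collapse = ", ")))
  bad_spec <- setdiff(specimens$entry_id, entries$entry_id)
  .assert(length(bad_spec) == 0L,
          sprintf("specimen references unknown entry: %s",
                  paste(bad_spec, collapse = ", ")))
  structure(list(entries = entries, specimens = specimens, lesions = lesions),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d entries (%d PDX, %d autopsy), %d specimens\n",
              nrow(x$entries), sum(x$entries$cohort == "PDX"),
              sum(x$entries$cohort == "autopsy"), nrow(x$specimens)))
  invisible(x)
}

# structured lesion sets for the characterized cohort entries; 'Chr2 copy
# losses' outside the MMR genes (LuCaP 81) are not representable in the
# MMR-only gene model and are omitted
.reference_lesions <- function() {
  msh2_147 <- list(
    lesion_rearrangement("MSH2", "inversion", partner_label = "C2orf61 343kb"),
    lesion_rearrangement("MSH2", "inversion", partner_label = "KCNK12 74kb"),
    lesion_rearrangement("MSH2", "inversion", partner_label = "KCNK12 40kb"))
  msh2_145 <- list(
    lesion_copy_loss("MSH2", exons = 8:16),
    lesion_rearrangement("MSH6", "translocation", partner_chrom = "chr12",
                         partner_label = "TESC"))
  list(
    "LuCaP 58" = list(lesion_copy_loss("MSH6", exons = 8:10),
                      lesion_frameshift("MSH6", exon = 10,
                                        hgvs = "c.3799_3800del")),
    "LuCaP 73" = list(lesion_copy_loss("MSH2"), lesion_copy_loss("MSH6"),
                      lesion_rearrangement("MSH2", "inversion",
                                           partner_label = "FBXO11")),
    "LuCaP 147" = msh2_147,
    "05-165" = msh2_147,
    "LuCaP 145" = msh2_145,
    "05-144" = msh2_145,
    "03-130" = list(lesion_rearrangement("MSH2", "translocation",
                                         partner_chrom = "chr18"),
                    lesion_copy_loss("MSH2"),
                    lesion_frameshift("MSH6", exon = 4, hgvs = "c.2690del"),
                    lesion_copy_loss("MSH6")),
    "06-134" = list(lesion_copy_loss("MLH1", zygosity = "hom")),
    "00-010" = list(lesion_frameshift("MSH2", exon = 14,
                                      hgvs = "c.2364_2365insTACA")),
    "05-123" = list(lesion_frameshift("MSH2", exon = 7,
                                      hgvs = "c.1124_1125insG"),
                    lesion_frameshift("MSH2", exon = 7, hgvs = "c.1082del"),
                    lesion_frameshift("MLH1", exon = 12, hgvs = "c.1310del",
                                      site_private = "lymph node"))
  )
}

#' Reference cohort manifest (15 PDX lines + 50 autopsy patients)
#'
#' The default fixture reproduces the study design of the cohort the
#' pipeline models: 15 PDX lines of which 3 are hypermutated/MSI-high
#' (LuCaP 58, 73, 147), and 50 rapid-autopsy patients of which 5 are
#' hypermutated (05-165, 03-130, 06-134, 00-010, 05-123) with their exome
#' mutation burdens (855, 647, 314, 673, 807) and multi-site specimen lists;
#' six characterized non-hypermutated patients carry their published burdens
#' (149, 57, 46, 47, 37, 69). Five PDX lines link to their source autopsy
#' patients — LuCaP 147 to 05-165 (both hypermutated), LuCaP 145 to 05-144,
#' LuCaP 78/81/92 to 98-328/98-362/99-069 — so collapsing the overlap yields
#' 60 unique patients, 7 of them hypermutated. The remaining 39 autopsy
#' patients were not individually characterized; they appear here as
#' synthetic microsatellite-stable single-site entries with deterministic
#' sub-threshold burdens. PDX burdens are likewise synthetic (hypermutated
#' lines well above, others well below the threshold) since the published
#' PDX counts are tumor-only novel-SNV tallies. Characterized entries carry
#' their structured MMR lesions for the generator to plant.
#'
#' @return A [cohort_manifest()].
#' @export
reference_cohort_manifest <- function() {
  pdx_ids <- c("LuCaP 58", "LuCaP 73", "LuCaP 147", "LuCaP 23.1", "LuCaP 35",
               "LuCaP 70", "LuCaP 77", "LuCaP 78", "LuCaP 81", "LuCaP 86.2",
               "LuCaP 92", "LuCaP 96", "LuCaP 105", "LuCaP 141", "LuCaP 145")
  pdx_hyper <- pdx_ids %in% c("LuCaP 58", "LuCaP 73", "LuCaP 147")
  pdx_link <- rep(NA_character_, length(pdx_ids))
  pdx_link[match(c("LuCaP 147", "LuCaP 78", "LuCaP 81", "LuCaP 92",
                   "LuCaP 145"), pdx_ids)] <-
    c("05-165", "98-328", "98-362", "99-069", "05-144")
  pdx <- data.frame(
    entry_id = pdx_ids, cohort = "PDX", link = pdx_link,
    msi_status = ifelse(pdx_hyper, "MSI-high", "MSS"),
    hypermutated = pdx_hyper,
    true_burden = ifelse(pdx_hyper, 600L + 40L * seq_along(pdx_ids),
                         40L + 5L * seq_along(pdx_ids)),
    stringsAsFactors = FALSE)

  det <- data.frame(
    entry_id = c("05-165", "03-130", "06-134", "00-010", "05-123",
                 "01-095", "05-144", "05-214", "05-116", "00-029", "00-090"),
    burden = c(855L, 647L, 314L, 673L, 807L, 149L, 57L, 46L, 47L, 37L, 69L),
    hyper = c(rep(TRUE, 5), rep(FALSE, 6)), stringsAsFactors = FALSE)
  filler_ids <- c("98-328", "98-362", "99-069", sprintf("AP-%02d", 1:36))
  autopsy <- data.frame(
    entry_id = c(det$entry_id, filler_ids), cohort = "autopsy",
    link = NA_character_,
    msi_status = c(ifelse(det$hyper, "MSI-high", "MSS"),
                   rep("MSS", length(filler_ids))),
    hypermutated = c(det$hyper, rep(FALSE, length(filler_ids))),
    true_burden = c(det$burden,
                    30L + ((seq_along(filler_ids) * 13L) %% 150L)),
    stringsAsFactors = FALSE)
  entries <- rbind(pdx, autopsy)

  sites <- list(
    "05-165" = c("bone", "adrenal", "liver", "lymph node"),
    "03-130" = "lymph node",
    "06-134" = c("kidney", "lymph node"),
    "00-010" = c("prostate", "liver"),
    "05-123" = c("prostate", "lymph node"),
    "01-095" = c("liver", "lymph node"),
    "05-144" = c("bone", "adrenal", "liver", "lymph node"),
    "05-214" = c("bone", "liver", "lymph node", "lymph node 2"),
    "05-116" = c("bone", "adrenal", "liver", "lung"),
    "00-029" = "liver",
    "00-090" = "lymph node")
  spec_rows <- lapply(entries$entry_id, function(id) {
    st <- sites[[id]] %||% if (startsWith(id, "LuCaP")) "xenograft" else "lymph node"
    data.frame(specimen_id = paste0(id, " [", st, "]"), entry_id = id,
               site = st, stringsAsFactors = FALSE)
  })
  specimens <- do.call(rbind, spec_rows)
  cohort_manifest(entries, specimens, .reference_lesions())
}
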