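#' Mononucleotide microsatellite capture panel
#'
#' Builds the panel of mononucleotide repeat loci evaluated by the MSI-by-NGS
#' scorer. The default size of 146 loci matches the mononucleotide
#' microsatellite content of the targeted capture design the pipeline models.
#' Coordinates are synthetic (deterministic, hg19-like) since only the locus
#' identity, repeat unit and reference repeat count matter to the scorer;
#' intervals are 0-based half-open and, as mononucleotide runs, the interval
#' width equals the reference repeat count.
#'
#' @param n_loci Number of loci on the panel (default 146).
#' @return A `data.frame` with columns `locus_id`, `chrom`, `start`, `end`,
#'   `repeat_unit`, `ref_repeat_count`.
#' @examples
#' panel <- msi_panel()
#' nrow(panel) # 146
#' @export
msi_panel <- function(n_loci = 146L) {
  .assert(is.numeric(n_loci) && length(n_loci) == 1L && n_loci >= 1,
          "n_loci must be a single number >= 1")
  n_loci <- as.integer(n_loci)
  i <- seq_len(n_loci)
  chrom <- paste0("chr", ((i - 1L) %% 22L) + 1L)
  # deterministic spread of run lengths typical of mononucleotide panels
  ref_repeat_count <- 10L + ((i * 7L) %% 18L)   # 10..27 units
  start <- 1000000L + i * 50000L
  data.frame(
    locus_id = sprintf("MSI_%03d", i),
    chrom = chrom,
    start = start,
    end = start + ref_repeat_count,
    repeat_unit = ifelse(i %% 2L == 0L, "A", "T"),
    ref_repeat_count = ref_repeat_count,
    stringsAsFactors = FALSE
  )
}

#' Synthetic exon model for the mismatch-repair genes
#'
#' Exon-level gene model for MSH2 (16 exons, chr2), MSH6 (10 exons, chr2) and
#' MLH1 (19 exons, chr3) used by the copy-number caller, the breakpoint
#' annotator and the synthetic-data generator. Gene spans follow the hg19
#' neighbourhood of the real genes but exon boundaries are synthetic
#' (evenly spaced); the pipeline only requires consistent exon indexing and
#' gene intervals, not transcript-accurate coordinates. Coordinates are
#' 0-based half-open.
#'
#' @return A `data.frame` with columns `gene`, `exon`, `chrom`, `start`,
#'   `end`, plus per-gene span rows accessible via [gene_spans()].
#' @export
mmr_gene_model <- function() {
  mk <- function(gene, chrom, gstart, gend, n_exon, width = 170L) {
    gap <- (gend - gstart - n_exon * width) %/% max(1L, (n_exon - 1L))
    start <- gstart + (seq_len(n_exon) - 1L) * (width + gap)
    data.frame(gene = gene, exon = seq_len(n_exon), chrom = chrom,
               start = as.integer(start), end = as.integer(start + width),
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("MSH2", "chr2", 47630206L, 47710367L, 16L),
    mk("MSH6", "chr2", 48010221L, 48034092L, 10L),
    mk("MLH1", "chr3", 37034841L, 37092337L, 19L)
  )
}

#' Per-gene genomic spans of the exon model
#'
#' @param model Exon table from [mmr_gene_model()].
#' @return `data.frame` with one row per gene: `gene`, `chrom`, `start`, `end`.
#' @export
gene_spans <- function(model = mmr_gene_model()) {
  sp <- do.call(rbind, lapply(split(model, model$gene), function(g) {
    data.frame(gene = g$gene[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Catalog of MSI-artifact homopolymer tracts
#'
#' Mosaic MSH6 frameshifts recurrently arise in two homopolymer tracts — a
#' poly-G run in exon 5 (c.3261 region) and a poly-A run in exon 7 (c.3573
#' region) — as a downstream consequence of MSI itself rather than as driver
#' lesions, and must be excluded before assessing gene zygosity. The catalog
#' maps those tracts onto the synthetic exon model; exclusion is
#' catalog-based and independent of the specimen's MSI status.
#'
#' @return `data.frame` with columns `gene`, `chrom`, `start`, `end`, `label`.
#' @seealso [exclude_msi_artifacts()]
#' @export
msi_artifact_catalog <- function() {
  model <- mmr_gene_model()
  ex5 <- model[model$gene == "MSH6" & model$exon == 5L, ]
  ex7 <- model[model$gene == "MSH6" & model$exon == 7L, ]
  data.frame(
    gene = "MSH6",
    chrom = ex5$chrom,
    start = c(ex5$start + 60L, ex7$start + 40L),
    end = c(ex5$start + 68L, ex7$start + 48L),
    label = c("MSH6 exon5 polyG (c.3261dup/del)", "MSH6 exon7 polyA (c.3573del)"),
    stringsAsFactors = FALSE
  )
}
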