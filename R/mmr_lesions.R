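#' Cluster clipped reads into structural rearrangement calls
#'
#' Desk-scale split-read SV calling: clip points on the same chromosome and
#' clip side lying within `window` bp of each other form a cluster whose
#' breakpoint is the modal clip position; clusters are then paired through
#' their modal partner coordinates (a cluster pairs with the cluster whose
#' breakpoint lies within `window` bp of its partner position). Both
#' clusters of a pair must reach `min_support` reads. The rearrangement type
#' follows from the pair geometry: different chromosomes give a
#' translocation, opposite strands an inversion, and colinear same-strand
#' pairs a deletion (or tandem duplication when the partner lies upstream).
#'
#' @param reads `data.frame` of clipped-read records: `chrom`, `pos`
#'   (0-based clip point), `clip_side`, `strand`, `partner_chrom`,
#'   `partner_pos`, `partner_strand`.
#' @param min_support Minimum reads per breakpoint cluster (default 4).
#' @param window Clustering/pairing distance in bp (default 10).
#' @param model Gene model used to annotate `genes_hit`
#'   (default [mmr_gene_model()]).
#' @return `data.frame` with one row per rearrangement: `bp1_chrom`,
#'   `bp1_pos`, `bp2_chrom`, `bp2_pos`, `type`, `n_support`, `genes_hit`
#'   (comma-joined gene symbols; a gene is hit if either breakpoint falls in
#'   its span).
#' @export
cluster_breakpoints <- function(reads, min_support = 4L, window = 10L,
                                model = mmr_gene_model()) {
  empty <- data.frame(bp1_chrom = character(), bp1_pos = integer(),
                      bp2_chrom = character(), bp2_pos = integer(),
                      type = character(), n_support = integer(),
                      genes_hit = character(), stringsAsFactors = FALSE)
  if (is.null(reads) || nrow(reads) == 0L) return(empty)
  .assert(all(reads$pos >= 0) && all(reads$partner_pos >= 0),
          "positions must be >= 0")
  # form clusters per (chrom, clip side)
  clusters <- list()
  for (key in split(reads, paste(reads$chrom, reads$clip_side))) {
    key <- key[order(key$pos), ]
    brk <- c(0L, cumsum(diff(key$pos) > window))
    for (g in split(key, brk)) {
      modal <- function(x) {
        t <- table(x)
        names(t)[which.max(t)]      # ties: first (smallest) value
      }
      clusters[[length(clusters) + 1L]] <- list(
        chrom = g$chrom[1], pos = as.integer(modal(g$pos)),
        side = g$clip_side[1], strand = modal(g$strand),
        partner_chrom = modal(g$partner_chrom),
        partner_pos = as.integer(modal(g$partner_pos)),
        partner_strand = modal(g$partner_strand), size = nrow(g))
    }
  }
  keep <- vapply(clusters, function(cl) cl$size >= min_support, logical(1))
  clusters <- clusters[keep]
  if (!length(clusters)) return(empty)
  # pair clusters via partner coordinates
  used <- rep(FALSE, length(clusters))
  out <- list()
  spans <- gene_spans(model)
  for (i in seq_along(clusters)) {
    if (used[i]) next
    a <- clusters[[i]]
    for (j in seq_along(clusters)) {
      if (j == i || used[j]) next
      b <- clusters[[j]]
      if (b$chrom == a$partner_chrom &&
          abs(b$pos - a$partner_pos) <= window &&
          a$chrom == b$partner_chrom &&
          abs(a$pos - b$partner_pos) <= window) {
        used[i] <- used[j] <- TRUE
        # canonical order: lower (chrom, pos) first
        swap <- (a$chrom > b$chrom) || (a$chrom == b$chrom && a$pos > b$pos)
        bp1 <- if (swap) b else a
        bp2 <- if (swap) a else b
        type <- if (bp1$chrom != bp2$chrom) "translocation"
                else if (bp1$strand != bp2$strand) "inversion"
                else if (bp2$pos >= bp1$pos && identical(bp1$side, "right"))
                  "deletion" else "tandem-dup"
        hit <- spans$gene[(spans$chrom == bp1$chrom & bp1$pos >= spans$start &
                             bp1$pos < spans$end) |
                          (spans$chrom == bp2$chrom & bp2$pos >= spans$start &
                             bp2$pos < spans$end)]
        out[[length(out) + 1L]] <- data.frame(
          bp1_chrom = bp1$chrom, bp1_pos = bp1$pos,
          bp2_chrom = bp2$chrom, bp2_pos = bp2$pos, type = type,
          n_support = min(a$size, b$size),
          genes_hit = paste(unique(hit), collapse = ","),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$bp1_chrom, res$bp1_pos), , drop = FALSE]
}

#' Exon-level copy-number calling from depth ratios
#'
#' Each exon is called `homozygous-loss` when its depth ratio is at most
#' `homozygous_max`, `loss` when at most `loss_max`, and `neutral`
#' otherwise. Runs of at least `min_consecutive` exons in the same non-neutral
#' state merge into segments labelled `"<gene> exon i-j del"`.
#'
#' @param exon_depth `data.frame` with `gene`, `exon`, `depth_ratio`
#'   (all ratios must be >= 0).
#' @param loss_max Single-copy-loss bound (default 0.70).
#' @param homozygous_max Homozygous-loss bound (default 0.15).
#' @param min_consecutive Minimum run length for a reported segment
#'   (default 2).
#' @return List with `calls` (input plus `state`) and `segments`
#'   (`gene`, `exon_start`, `exon_end`, `state`, `label`).
#' @export
call_exon_cnv <- function(exon_depth, loss_max = 0.70, homozygous_max = 0.15,
                          min_consecutive = 2L) {
  .assert(all(exon_depth$depth_ratio >= 0), "depth ratios must be >= 0")
  calls <- exon_depth[order(exon_depth$gene, exon_depth$exon), , drop = FALSE]
  calls$state <- ifelse(calls$depth_ratio <= homozygous_max, "homozygous-loss",
                 ifelse(calls$depth_ratio <= loss_max, "loss", "neutral"))
  segs <- list()
  for (g in split(calls, calls$gene)) {
    runs <- rle(g$state)
    stop_idx <- cumsum(runs$lengths)
    start_idx <- stop_idx - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (runs$values[k] == "neutral" || runs$lengths[k] < min_consecutive) next
      e1 <- g$exon[start_idx[k]]
      e2 <- g$exon[stop_idx[k]]
      segs[[length(segs) + 1L]] <- data.frame(
        gene = g$gene[1], exon_start = e1, exon_end = e2,
        state = runs$values[k],
        label = sprintf("%s exon %d-%d %s", g$gene[1], e1, e2,
                        if (runs$values[k] == "homozygous-loss")
                          "homozygous del" else "del"),
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(gene = character(), exon_start = integer(),
               exon_end = integer(), state = character(),
               label = character(), stringsAsFactors = FALSE)
  rownames(calls) <- rownames(segments) <- NULL
  list(calls = calls, segments = segments)
}

#' Partition out MSI-artifact homopolymer-tract frameshifts
#'
#' Frameshifts inside cataloged homopolymer tracts (see
#' [msi_artifact_catalog()]) are secondary consequences of MSI rather than
#' driver lesions and are excluded before zygosity assessment. Exclusion is
#' purely coordinate-based and independent of the specimen's MSI status.
#'
#' @param variants Variant `data.frame` with 1-based `pos` and `chrom`.
#' @param catalog Tract catalog (`chrom`, `start`, `end` 0-based half-open).
#' @return List with `retained` and `excluded` variant tables.
#' @export
exclude_msi_artifacts <- function(variants, catalog = msi_artifact_catalog()) {
  if (nrow(variants) == 0L)
    return(list(retained = variants, excluded = variants))
  inside <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(catalog))) {
    tr <- catalog[i, ]
    inside <- inside | (variants$chrom == tr$chrom &
                          variants$pos > tr$start & variants$pos <= tr$end)
  }
  list(retained = variants[!inside, , drop = FALSE],
       excluded = variants[inside, , drop = FALSE])
}

#' Bi-allelic inactivation verdict for one gene
#'
#' A homozygous copy loss alone inactivates both alleles; otherwise two or
#' more distinct inactivating events are required for a `biallelic` verdict,
#' exactly one event gives `monoallelic`, and none gives `none`. Adding an
#' event can never downgrade the verdict.
#'
#' @param events Character vector of event types for one gene (any of
#'   `"frameshift"`, `"nonsense"`, `"rearrangement"`, `"copy-loss"`,
#'   `"homozygous-loss"`), already de-duplicated (a rearrangement counts
#'   once even if both breakpoints hit the gene).
#' @return `"biallelic"`, `"monoallelic"` or `"none"`.
#' @export
assess_biallelic <- function(events) {
  n <- length(events)
  if (any(events == "homozygous-loss")) return("biallelic")
  if (n >= 2L) return("biallelic")
  if (n == 1L) return("monoallelic")
  "none"
}

#' Integrate all evidence into per-gene lesion sets
#'
#' Collects, for each MMR gene: truncating small variants (frameshift or
#' nonsense, after MSI-artifact exclusion), gene-splitting rearrangements
#' (a rearrangement with at least one breakpoint inside the gene counts
#' once), and copy-loss segments from the exon CNV caller; then issues the
#' bi-allelic inactivation verdict per gene.
#'
#' @param variants Variant table (may be `NULL`); needs `gene`,
#'   `consequence`, `chrom`, `pos`.
#' @param rearrangements Output of [cluster_breakpoints()] (may be `NULL`).
#' @param cnv_segments `segments` table from [call_exon_cnv()] (may be
#'   `NULL`).
#' @param genes Genes to assess (default MSH2, MSH6, MLH1).
#' @param catalog Artifact-tract catalog for [exclude_msi_artifacts()].
#' @return Object of class `gene_lesion_set`: list with `events` (one row
#'   per event: `gene`, `type`, `label`) and `verdicts` (`gene`, `n_events`,
#'   `zygosity_verdict`).
#' @export
gene_lesions <- function(variants = NULL, rearrangements = NULL,
                         cnv_segments = NULL,
                         genes = c("MSH2", "MSH6", "MLH1"),
                         catalog = msi_artifact_catalog()) {
  ev <- list()
  if (!is.null(variants) && nrow(variants)) {
    v <- exclude_msi_artifacts(variants, catalog)$retained
    v <- v[!is.na(v$gene) & v$gene %in% genes &
             v$consequence %in% c("frameshift", "nonsense"), , drop = FALSE]
    if (nrow(v))
      ev[[length(ev) + 1L]] <- data.frame(
        gene = v$gene, type = v$consequence,
        label = ifelse(is.na(v$hgvs),
                       sprintf("%s %s %s:%d", v$gene, v$consequence,
                               v$chrom, v$pos),
                       paste(v$gene, v$consequence, v$hgvs)),
        stringsAsFactors = FALSE)
  }
  if (!is.null(rearrangements) && nrow(rearrangements)) {
    for (i in seq_len(nrow(rearrangements))) {
      r <- rearrangements[i, ]
      hit <- intersect(strsplit(r$genes_hit, ",")[[1]], genes)
      for (g in hit)
        ev[[length(ev) + 1L]] <- data.frame(
          gene = g, type = "rearrangement",
          label = sprintf("%s %s %s:%d-%s:%d", g, r$type, r$bp1_chrom,
                          r$bp1_pos, r$bp2_chrom, r$bp2_pos),
          stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    s <- cnv_segments[cnv_segments$gene %in% genes, , drop = FALSE]
    if (nrow(s))
      ev[[length(ev) + 1L]] <- data.frame(
        gene = s$gene,
        type = ifelse(s$state == "homozygous-loss", "homozygous-loss",
                      "copy-loss"),
        label = s$label, stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(gene = character(), type = character(), label = character(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  verdicts <- data.frame(
    gene = genes,
    n_events = vapply(genes, function(g) sum(events$gene == g), integer(1)),
    zygosity_verdict = vapply(genes, function(g)
      assess_biallelic(events$type[events$gene == g]), character(1)),
    stringsAsFactors = FALSE)
  rownames(verdicts) <- NULL
  structure(list(events = events, verdicts = verdicts),
            class = "gene_lesion_set")
}

#' @export
print.gene_lesion_set <- function(x, ...) {
  cat("<gene_lesion_set>\n")
  print(x$verdicts)
  invisible(x)
}
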