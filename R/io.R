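#' Read and write the pipeline's file formats
#'
#' Plain-text interchange for every pipeline input and output. Panels travel
#' as BED (0-based half-open, written and parsed with `rtracklayer`; the BED
#' name field carries `locus_id|repeat_unit`, and the interval width of a
#' mononucleotide run equals its reference repeat count). Tables (histograms,
#' variants, exon depths, clipped reads, PCR profiles) travel as TSV,
#' variants additionally as VCF (1-based positions on write, with INFO keys
#' `VAF`, `NAB`, `COMMON`, `PALT`, `GENE`, `CSQ`; parsed with `vcfR`),
#' rearrangements as BEDPE, and truth sidecars / baselines as JSON.
#'
#' @param panel,tab,variants,baseline,truth,rearrangements Objects to write.
#' @param path File path.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name msimmr-io
NULL

#' @rdname msimmr-io
#' @export
write_panel_bed <- function(panel, path) {
  gr <- GenomicRanges::GRanges(
    panel$chrom,
    IRanges::IRanges(start = panel$start + 1L, end = panel$end),
    name = paste(panel$locus_id, panel$repeat_unit, sep = "|"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname msimmr-io
#' @export
read_panel_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  data.frame(
    locus_id = vapply(parts, `[`, character(1), 1L),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0,
    repeat_unit = vapply(parts, `[`, character(1), 2L),
    ref_repeat_count = end0 - start0,
    stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname msimmr-io
#' @export
write_histograms_tsv <- function(tab, path) .write_tsv(tab, path)

#' @rdname msimmr-io
#' @export
read_histograms_tsv <- function(path) .read_tsv(path)

#' @rdname msimmr-io
#' @export
write_exon_depth_tsv <- function(tab, path) .write_tsv(tab, path)

#' @rdname msimmr-io
#' @export
read_exon_depth_tsv <- function(path) .read_tsv(path)

#' @rdname msimmr-io
#' @export
write_split_reads_tsv <- function(tab, path) .write_tsv(tab, path)

#' @rdname msimmr-io
#' @export
read_split_reads_tsv <- function(path) .read_tsv(path)

#' @rdname msimmr-io
#' @export
write_variants_tsv <- function(variants, path) .write_tsv(variants, path)

#' @rdname msimmr-io
#' @export
read_variants_tsv <- function(path) .read_tsv(path)

#' @rdname msimmr-io
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=NAB,Number=1,Type=Float,Description=\"Max germline allele balance\">",
    "##INFO=<ID=COMMON,Number=0,Type=Flag,Description=\"Common (dbSNP-style) variant\">",
    "##INFO=<ID=PALT,Number=0,Type=Flag,Description=\"Protein altering\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  info <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    parts <- c(sprintf("VAF=%.4f", v$tumor_vaf),
               sprintf("NAB=%.4f", v$normal_allele_balance),
               if (isTRUE(v$common_variant)) "COMMON",
               if (isTRUE(v$protein_altering)) "PALT",
               if (!is.na(v$gene)) sprintf("GENE=%s", v$gene),
               sprintf("CSQ=%s", v$consequence))
    paste(parts, collapse = ";")
  }, character(1))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname msimmr-io
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_flag <- function(key) {
    vapply(fix$INFO, function(s)
      key %in% strsplit(s, ";", fixed = TRUE)[[1]], logical(1),
      USE.NAMES = FALSE)
  }
  gene <- vcfR::extract.info(v, "GENE")
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT,
    gene = ifelse(is.na(gene), NA_character_, gene),
    consequence = vcfR::extract.info(v, "CSQ"),
    protein_altering = info_flag("PALT"),
    tumor_vaf = as.numeric(vcfR::extract.info(v, "VAF")),
    normal_allele_balance = as.numeric(vcfR::extract.info(v, "NAB")),
    common_variant = info_flag("COMMON"),
    stringsAsFactors = FALSE)
}

#' @rdname msimmr-io
#' @export
write_bedpe <- function(rearrangements, path) {
  r <- rearrangements
  lines <- paste(r$bp1_chrom, r$bp1_pos, r$bp1_pos + 1L,
                 r$bp2_chrom, r$bp2_pos, r$bp2_pos + 1L,
                 r$type, r$n_support, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname msimmr-io
#' @export
write_pcr_profiles_tsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    rbind(
      data.frame(marker = p$marker, trace = "tumor",
                 length = as.integer(names(p$tumor)),
                 intensity = as.numeric(p$tumor), stringsAsFactors = FALSE),
      data.frame(marker = p$marker, trace = "normal",
                 length = as.integer(names(p$normal)),
                 intensity = as.numeric(p$normal), stringsAsFactors = FALSE))
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' @rdname msimmr-io
#' @export
read_pcr_profiles_tsv <- function(path) {
  tab <- .read_tsv(path)
  lapply(split(tab, tab$marker), function(m) {
    tr <- function(which) {
      x <- m[m$trace == which, ]
      setNames(x$intensity, x$length)
    }
    structure(list(marker = m$marker[1], tumor = tr("tumor"),
                   normal = tr("normal")), class = "marker_profile")
  })
}

#' @rdname msimmr-io
#' @export
write_baseline_json <- function(baseline, path) {
  jsonlite::write_json(list(
    support_fraction = attr(baseline, "support_fraction"),
    min_depth = attr(baseline, "min_depth"),
    untrainable = attr(baseline, "untrainable"),
    loci = as.data.frame(baseline)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname msimmr-io
#' @export
read_baseline_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(x$loci), class = c("msi_baseline", "data.frame"),
            untrainable = as.character(x$untrainable %||% character()),
            support_fraction = x$support_fraction, min_depth = x$min_depth)
}

#' @rdname msimmr-io
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$lesions <- lapply(x$lesions, function(l) Filter(Negate(is.null),
                                                    unclass(l)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname msimmr-io
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$lesions <- lapply(x$lesions, function(l) structure(l, class = "lesion"))
  structure(x, class = "specimen_truth")
}
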