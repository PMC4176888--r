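#' Simulation configuration
#'
#' Parameters governing every stochastic feature of the synthetic-data
#' generator. Defaults describe the study conditions the pipeline models:
#' a 146-locus mononucleotide panel, deep targeted coverage, a small PCR
#' deletion-stutter rate, and MMR-deficient specimens in which half of the
#' panel loci are destabilized.
#'
#' @param seed Integer seed; identical seed + config reproduce byte-identical
#'   outputs.
#' @param n_loci Number of panel loci (default 146).
#' @param depth_mean Mean reads per locus (Poisson; default 200).
#' @param stutter_prob Per-replication probability that an observed repeat
#'   length slips by one unit; slip counts follow a geometric tail
#'   (default 0.02).
#' @param msi_locus_fraction Fraction of panel loci destabilized in an
#'   MMR-deficient (MSI-high) specimen (default 0.5).
#' @param msi_shift_mean Mean of the Poisson component of the signed
#'   repeat-unit change at destabilized loci; a destabilized locus gains
#'   novel allele modes at `reference - k` with `k ~ 1 + Poisson(msi_shift_mean)`
#'   (default 1.5).
#' @param contamination_germline_rate Fraction of injected variant records
#'   that are germline-derived contaminants (default 0.3).
#' @param sv_support Clipped reads emitted per rearrangement breakpoint
#'   (default 12).
#' @param sv_jitter Maximum absolute positional jitter (bp) applied to
#'   emitted clip points (default 0, i.e. noiseless breakpoints).
#' @param sv_noise_reads Number of scattered singleton clipped reads added as
#'   background noise (default 5).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 146L, depth_mean = 200,
                       stutter_prob = 0.02, msi_locus_fraction = 0.5,
                       msi_shift_mean = 1.5, contamination_germline_rate = 0.3,
                       sv_support = 12L, sv_jitter = 0L, sv_noise_reads = 5L) {
  .assert(is.numeric(seed) && length(seed) == 1L, "seed must be a single integer")
  .assert(is.numeric(n_loci) && n_loci >= 1, "n_loci must be >= 1")
  .assert(is.numeric(depth_mean) && depth_mean > 0, "depth_mean must be > 0")
  .assert(.is_prob(stutter_prob), "stutter_prob must be a probability in [0,1]")
  .assert(.is_prob(msi_locus_fraction), "msi_locus_fraction must be in [0,1]")
  .assert(is.numeric(msi_shift_mean) && msi_shift_mean >= 0,
          "msi_shift_mean must be >= 0")
  .assert(.is_prob(contamination_germline_rate),
          "contamination_germline_rate must be in [0,1]")
  .assert(contamination_germline_rate < 1,
          "contamination_germline_rate must be < 1")
  structure(list(
    seed = as.integer(seed), n_loci = as.integer(n_loci),
    depth_mean = depth_mean, stutter_prob = stutter_prob,
    msi_locus_fraction = msi_locus_fraction, msi_shift_mean = msi_shift_mean,
    contamination_germline_rate = contamination_germline_rate,
    sv_support = as.integer(sv_support), sv_jitter = as.integer(sv_jitter),
    sv_noise_reads = as.integer(sv_noise_reads)
  ), class = "sim_config")
}

# deterministic sub-seed from a master seed and a string key (< 2^31)
.derive_seed <- function(seed, key) {
  h <- 0
  for (b in utf8ToInt(as.character(key))) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

#' Closed-form stutter slip distribution
#'
#' Probability that a read's observed repeat length lies `k` units below its
#' true allele length under the generator's geometric single-direction
#' slippage model: `P(k) = (1 - p) p^k`, truncated at `max_slip` and
#' renormalized. This is the analytic distribution the simulated histograms
#' converge to, and the oracle used in goodness-of-fit testing.
#'
#' @param k Non-negative integer slip count(s).
#' @param stutter_prob Slip probability `p`.
#' @param max_slip Truncation bound (default 12).
#' @return Numeric vector of probabilities.
#' @export
stutter_pmf <- function(k, stutter_prob, max_slip = 12L) {
  .assert(.is_prob(stutter_prob), "stutter_prob must be in [0,1]")
  .assert(all(k >= 0), "k must be non-negative")
  if (stutter_prob == 0) return(as.numeric(k == 0))
  full <- (1 - stutter_prob) * stutter_prob^(0:max_slip)
  p <- ifelse(k <= max_slip, (1 - stutter_prob) * stutter_prob^k, 0)
  p / sum(full)
}

# draw slip counts for n reads of an allele with true length `len`
.draw_slips <- function(n, len, stutter_prob) {
  if (n == 0L) return(integer())
  max_slip <- min(len - 1L, 12L)
  if (max_slip <= 0L || stutter_prob == 0) return(rep(0L, n))
  pr <- stutter_pmf(0:max_slip, stutter_prob, max_slip)
  sample(0:max_slip, n, replace = TRUE, prob = pr)
}

#' Simulate a repeat-length read histogram for one locus
#'
#' Stable loci concentrate read mass at the reference repeat length with a
#' geometric one-direction stutter tail ([stutter_pmf()]). Unstable loci
#' additionally carry one or two novel allele modes at `reference - k`,
#' `k ~ 1 + Poisson(msi_shift_mean)`, each holding roughly 20-40% of reads,
#' with their own stutter tails.
#'
#' @param locus One row of [msi_panel()] (or any list with `locus_id` and
#'   `ref_repeat_count`).
#' @param unstable Logical; destabilize this locus.
#' @param depth Total reads to draw (>= 0).
#' @param config A [sim_config()].
#' @param shifts Optional integer vector of novel-mode shifts (units below
#'   reference) overriding the random draw; only used when `unstable`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used (so a
#'   specimen-level seed governs).
#' @return A `length_histogram`: list with `locus_id`, `counts` (named
#'   integer vector, names = repeat length) and `depth`.
#' @export
simulate_locus_histogram <- function(locus, unstable = FALSE, depth,
                                     config = sim_config(), shifts = NULL,
                                     seed = NULL) {
  .assert(is.numeric(depth) && length(depth) == 1L && depth >= 0,
          "depth must be a single non-negative number")
  depth <- as.integer(depth)
  run <- function() {
    L <- as.integer(locus$ref_repeat_count)
    if (depth == 0L) {
      return(structure(list(locus_id = locus$locus_id,
                            counts = setNames(integer(), character()),
                            depth = 0L),
                       class = "length_histogram"))
    }
    modes <- L
    weights <- 1
    if (isTRUE(unstable)) {
      if (is.null(shifts)) {
        n_modes <- 1L + stats::rbinom(1L, 1L, 0.5)
        k <- unique(pmin(1L + stats::rpois(n_modes, config$msi_shift_mean), L - 1L))
      } else {
        k <- unique(pmin(as.integer(shifts), L - 1L))
      }
      k <- k[k >= 1L]
      if (length(k)) {
        w <- stats::runif(length(k), 0.2, 0.4)
        w <- w / max(1, sum(w) / 0.6)        # novel modes carry <= 60% of mass
        modes <- c(L, L - k)
        weights <- c(1 - sum(w), w)
      }
    }
    n_mode <- as.vector(stats::rmultinom(1L, depth, weights))
    obs <- unlist(lapply(seq_along(modes), function(i) {
      modes[i] - .draw_slips(n_mode[i], modes[i], config$stutter_prob)
    }), use.names = FALSE)
    tab <- table(obs)
    counts <- setNames(as.integer(tab), names(tab))
    counts <- counts[order(as.integer(names(counts)))]
    structure(list(locus_id = locus$locus_id, counts = counts, depth = depth),
              class = "length_histogram")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> %s: depth %d over %d length(s)\n",
              x$locus_id, x$depth, length(x$counts)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Simulate repeat-length histograms for a whole specimen
#'
#' Draws a per-locus depth (Poisson with mean `depth_mean`) and a repeat
#' length histogram for every panel locus; loci named in `unstable_loci`
#' receive MSI allele shifts. Used both for tumour specimens and for the
#' normal controls that train the MSI baseline.
#'
#' @param specimen_id Specimen label (also seeds the per-specimen RNG stream
#'   together with `config$seed`).
#' @param panel Panel table from [msi_panel()].
#' @param unstable_loci Character vector of destabilized `locus_id`s.
#' @param config A [sim_config()].
#' @return A long-format `data.frame`: `specimen_id`, `locus_id`,
#'   `repeat_length`, `read_count`.
#' @export
simulate_histograms <- function(specimen_id, panel, unstable_loci = character(),
                                config = sim_config()) {
  .assert(nrow(panel) >= 1, "panel must be non-empty")
  withr::with_seed(.derive_seed(config$seed, paste0("hist:", specimen_id)), {
    rows <- lapply(seq_len(nrow(panel)), function(i) {
      locus <- panel[i, ]
      depth <- stats::rpois(1L, config$depth_mean)
      h <- simulate_locus_histogram(locus, locus$locus_id %in% unstable_loci,
                                    depth, config)
      if (!length(h$counts)) return(NULL)
      data.frame(specimen_id = specimen_id, locus_id = locus$locus_id,
                 repeat_length = as.integer(names(h$counts)),
                 read_count = as.integer(h$counts), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Specimen-level ground truth for the generator
#'
#' @param specimen_id Specimen label.
#' @param msi_status `"MSI-high"` or `"MSS"`.
#' @param hypermutated Logical.
#' @param true_burden Number of protein-altering somatic variants to inject
#'   (planted lesion frameshifts and MSI-artifact frameshifts count toward
#'   this total).
#' @param lesions List of planted MMR-gene events built with
#'   [lesion_frameshift()], [lesion_rearrangement()] or [lesion_copy_loss()].
#' @return An object of class `specimen_truth`.
#' @export
specimen_truth <- function(specimen_id, msi_status = c("MSS", "MSI-high"),
                           hypermutated = FALSE, true_burden = 0L,
                           lesions = list()) {
  msi_status <- match.arg(msi_status)
  .assert(is.numeric(true_burden) && true_burden >= 0, "true_burden must be >= 0")
  structure(list(specimen_id = specimen_id, msi_status = msi_status,
                 hypermutated = isTRUE(hypermutated),
                 true_burden = as.integer(true_burden), lesions = lesions),
            class = "specimen_truth")
}

#' Planted lesion constructors
#'
#' Describe MMR-gene events for the generator to plant: a frameshift small
#' variant, a structural rearrangement with one breakpoint inside the gene,
#' or an exon-level copy loss (heterozygous, depth ratio about 0.5, or
#' homozygous, ratio near 0).
#'
#' @param gene Gene symbol present in [mmr_gene_model()].
#' @param exon Exon index for a frameshift (default: exon 3).
#' @param hgvs Optional HGVS-style label carried through to the variant table.
#' @param site_private Optional site label; the lesion is planted only in
#'   specimens from that site.
#' @return A `lesion` list.
#' @export
lesion_frameshift <- function(gene, exon = 3L, hgvs = NULL, site_private = NULL) {
  structure(list(kind = "frameshift", gene = gene, exon = as.integer(exon),
                 hgvs = hgvs, site_private = site_private), class = "lesion")
}

#' @rdname lesion_frameshift
#' @param type Rearrangement type.
#' @param partner_chrom Chromosome of the second breakpoint (required for a
#'   translocation; defaults to the gene's chromosome otherwise).
#' @param partner_label Free-text label of the partner locus (e.g. a fusion
#'   partner gene); also salts the deterministic default breakpoint placement
#'   so that multiple rearrangements in one gene get distinct breakpoints.
#' @param bp1_pos,bp2_pos Optional explicit breakpoint positions (0-based).
#' @export
lesion_rearrangement <- function(gene,
                                 type = c("inversion", "deletion",
                                          "translocation", "tandem-dup"),
                                 partner_chrom = NULL, partner_label = "partner",
                                 bp1_pos = NULL, bp2_pos = NULL,
                                 site_private = NULL) {
  type <- match.arg(type)
  structure(list(kind = "rearrangement", gene = gene, type = type,
                 partner_chrom = partner_chrom, partner_label = partner_label,
                 bp1_pos = bp1_pos, bp2_pos = bp2_pos,
                 site_private = site_private), class = "lesion")
}

#' @rdname lesion_frameshift
#' @param exons Integer vector of affected exon indices (default: whole gene).
#' @param zygosity `"het"` (single-copy loss) or `"hom"` (homozygous loss).
#' @export
lesion_copy_loss <- function(gene, exons = NULL, zygosity = c("het", "hom"),
                             site_private = NULL) {
  zygosity <- match.arg(zygosity)
  structure(list(kind = "copy_loss", gene = gene, exons = exons,
                 zygosity = zygosity, site_private = site_private),
            class = "lesion")
}

# resolve concrete breakpoints for a planted rearrangement
.resolve_breakpoints <- function(lesion, model) {
  span <- gene_spans(model)
  g <- span[span$gene == lesion$gene, ]
  .assert(nrow(g) == 1L, sprintf("gene '%s' absent from the gene model", lesion$gene))
  salt <- .derive_seed(7L, paste0(lesion$gene, "|", lesion$partner_label, "|", lesion$type))
  bp1 <- if (!is.null(lesion$bp1_pos)) as.integer(lesion$bp1_pos) else
    as.integer(g$start + 500L + (salt %% (g$end - g$start - 1000L)))
  if (lesion$type == "translocation") {
    chrom2 <- if (!is.null(lesion$partner_chrom)) lesion$partner_chrom else "chr18"
    bp2 <- if (!is.null(lesion$bp2_pos)) as.integer(lesion$bp2_pos) else
      as.integer(20000000L + (salt %% 5000000L))
  } else {
    chrom2 <- g$chrom
    bp2 <- if (!is.null(lesion$bp2_pos)) as.integer(lesion$bp2_pos) else
      as.integer(g$end + 50000L + (salt %% 300000L))
  }
  list(chrom1 = g$chrom, pos1 = bp1, chrom2 = chrom2, pos2 = bp2)
}

# strand of the partner cluster encodes orientation: inversions join opposite
# strands, deletions/tandem-dups are colinear, translocations cross chromosomes
.sv_strands <- function(type) {
  if (type == "inversion") c("+", "-") else c("+", "+")
}

.sim_split_reads <- function(truth, config, model) {
  les <- Filter(function(l) l$kind == "rearrangement", truth$lesions)
  rows <- list()
  for (l in les) {
    bp <- .resolve_breakpoints(l, model)
    st <- .sv_strands(l$type)
    jit <- function(n) if (config$sv_jitter > 0L)
      sample(seq(-config$sv_jitter, config$sv_jitter), n, replace = TRUE)
    else rep(0L, n)
    n <- config$sv_support
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = bp$chrom1, pos = bp$pos1 + jit(n), clip_side = "right",
      strand = st[1], partner_chrom = bp$chrom2, partner_pos = bp$pos2,
      partner_strand = st[2], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = bp$chrom2, pos = bp$pos2 + jit(n), clip_side = "left",
      strand = st[2], partner_chrom = bp$chrom1, partner_pos = bp$pos1,
      partner_strand = st[1], stringsAsFactors = FALSE)
  }
  if (config$sv_noise_reads > 0L) {
    n <- config$sv_noise_reads
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(100000000L, n),
      clip_side = sample(c("left", "right"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      partner_chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      partner_pos = sample.int(100000000L, n),
      partner_strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), clip_side = character(),
               strand = character(), partner_chrom = character(),
               partner_pos = integer(), partner_strand = character(),
               stringsAsFactors = FALSE)
  if (nrow(out)) out$specimen_id <- truth$specimen_id
  out
}

.sim_exon_depth <- function(truth, config, model) {
  dep <- model[, c("gene", "exon")]
  dep$specimen_id <- truth$specimen_id
  dep$depth_ratio <- pmax(0, stats::rnorm(nrow(dep), 1.0, 0.05))
  for (l in Filter(function(l) l$kind == "copy_loss", truth$lesions)) {
    .assert(l$gene %in% model$gene,
            sprintf("gene '%s' absent from the gene model", l$gene))
    exons <- if (is.null(l$exons)) model$exon[model$gene == l$gene] else l$exons
    idx <- dep$gene == l$gene & dep$exon %in% exons
    dep$depth_ratio[idx] <- if (l$zygosity == "hom")
      pmax(0, stats::rnorm(sum(idx), 0.03, 0.01))
    else pmax(0, stats::rnorm(sum(idx), 0.5, 0.05))
  }
  dep[, c("specimen_id", "gene", "exon", "depth_ratio")]
}

.random_base <- function(n, not = NULL) {
  bases <- c("A", "C", "G", "T")
  out <- sample(bases, n, replace = TRUE)
  if (!is.null(not)) {
    clash <- out == not
    while (any(clash)) {
      out[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- out == not
    }
  }
  out
}

.variant_row <- function(specimen_id, chrom, pos, gene, consequence,
                         protein_altering, vaf, nab, common, truth_class,
                         hgvs = NA_character_) {
  ref <- .random_base(1L)
  data.frame(specimen_id = specimen_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = .random_base(1L, not = ref), gene = gene,
             consequence = consequence, protein_altering = protein_altering,
             tumor_vaf = round(vaf, 4), normal_allele_balance = round(nab, 4),
             common_variant = common, truth_class = truth_class, hgvs = hgvs,
             stringsAsFactors = FALSE)
}

.sim_variants <- function(truth, config, model, site = NULL) {
  sid <- truth$specimen_id
  rows <- list()
  planted <- 0L
  # lesion frameshifts at deterministic in-exon positions
  for (l in Filter(function(l) l$kind == "frameshift", truth$lesions)) {
    ex <- model[model$gene == l$gene & model$exon == l$exon, ]
    .assert(nrow(ex) == 1L,
            sprintf("gene '%s' exon %s absent from the gene model", l$gene, l$exon))
    rows[[length(rows) + 1L]] <- .variant_row(
      sid, ex$chrom, ex$start + 25L + planted, l$gene, "frameshift", TRUE,
      stats::runif(1, 0.2, 0.5), stats::runif(1, 0, 0.03), FALSE, "somatic",
      hgvs = if (is.null(l$hgvs)) NA_character_ else l$hgvs)
    planted <- planted + 1L
  }
  # mosaic homopolymer-tract frameshifts accompany MSI (within burden budget)
  if (truth$msi_status == "MSI-high") {
    cat_tracts <- msi_artifact_catalog()
    for (i in seq_len(nrow(cat_tracts))) {
      if (planted >= truth$true_burden) break
      tr <- cat_tracts[i, ]
      rows[[length(rows) + 1L]] <- .variant_row(
        sid, tr$chrom, tr$start + 3L, tr$gene, "frameshift", TRUE,
        stats::runif(1, 0.1, 0.3), stats::runif(1, 0, 0.03), FALSE, "artifact",
        hgvs = tr$label)
      planted <- planted + 1L
    }
  }
  # remaining protein-altering passenger load
  n_rest <- max(0L, truth$true_burden - planted)
  if (n_rest > 0L) {
    cons <- sample(c("missense", "nonsense"), n_rest, replace = TRUE,
                   prob = c(0.9, 0.1))
    for (i in seq_len(n_rest)) {
      rows[[length(rows) + 1L]] <- .variant_row(
        sid, paste0("chr", sample(1:22, 1L)), sample.int(100000000L, 1L),
        NA_character_, cons[i], TRUE, stats::runif(1, 0.15, 0.6),
        stats::runif(1, 0, 0.05), FALSE, "somatic")
    }
  }
  n_real <- truth$true_burden
  # synonymous passengers that pass all filters but are not protein-altering
  n_syn <- round(0.2 * n_real)
  for (i in seq_len(n_syn)) {
    rows[[length(rows) + 1L]] <- .variant_row(
      sid, paste0("chr", sample(1:22, 1L)), sample.int(100000000L, 1L),
      NA_character_, "synonymous", FALSE, stats::runif(1, 0.15, 0.6),
      stats::runif(1, 0, 0.05), FALSE, "somatic")
  }
  # contaminants the filters must strip
  n_common <- max(5L, round(0.05 * n_real))
  n_lowvaf <- max(5L, round(0.05 * n_real))
  r <- config$contamination_germline_rate
  n_germ <- round(r / (1 - r) * max(n_real + n_syn + n_common + n_lowvaf, 20L))
  for (i in seq_len(n_germ)) {
    rows[[length(rows) + 1L]] <- .variant_row(
      sid, paste0("chr", sample(1:22, 1L)), sample.int(100000000L, 1L),
      NA_character_, sample(c("missense", "synonymous"), 1L),
      stats::runif(1) < 0.5, stats::runif(1, 0.3, 0.7),
      stats::runif(1, 0.40, 0.65),            # allele balance >= 40% in normal
      stats::runif(1) < 0.3, "germline")
  }
  for (i in seq_len(n_common)) {
    rows[[length(rows) + 1L]] <- .variant_row(
      sid, paste0("chr", sample(1:22, 1L)), sample.int(100000000L, 1L),
      NA_character_, "missense", TRUE, stats::runif(1, 0.15, 0.6),
      stats::runif(1, 0, 0.05), TRUE, "common")
  }
  for (i in seq_len(n_lowvaf)) {
    rows[[length(rows) + 1L]] <- .variant_row(
      sid, paste0("chr", sample(1:22, 1L)), sample.int(100000000L, 1L),
      NA_character_, "missense", TRUE, stats::runif(1, 0.01, 0.095),
      stats::runif(1, 0, 0.05), FALSE, "low_vaf")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- .variant_row(sid, "chr1", 1L, NA_character_, "missense", TRUE,
                        0.5, 0, FALSE, "somatic")[0, ]
  rownames(out) <- NULL
  out
}

# lesions active for a given site (site-private events filtered)
.lesions_for_site <- function(lesions, site) {
  Filter(function(l) is.null(l$site_private) ||
           (!is.null(site) && identical(l$site_private, site)), lesions)
}

#' Simulate every pipeline input for one specimen
#'
#' Emits, consistently with the supplied truth: per-locus repeat-length
#' histograms (MSI-high specimens destabilize exactly
#' `round(msi_locus_fraction * n_loci)` loci), a somatic variant table
#' containing `true_burden` protein-altering variants plus germline, common
#' and low-VAF contaminants, per-exon depth ratios with planted copy losses,
#' clipped-read records for planted rearrangements, and five-marker PCR
#' fragment profiles. The returned truth sidecar is augmented with the
#' destabilized locus set and the unstable PCR markers so that downstream
#' recovery can be checked exactly.
#'
#' @param truth A [specimen_truth()].
#' @param panel Panel from [msi_panel()]; must be non-empty.
#' @param config A [sim_config()].
#' @param site Optional site label (activates site-private lesions).
#' @return A list of class `sim_specimen` with elements `truth`,
#'   `histograms`, `variants`, `exon_depth`, `split_reads`, `pcr`.
#' @export
simulate_specimen <- function(truth, panel = msi_panel(), config = sim_config(),
                              site = NULL) {
  .assert(inherits(truth, "specimen_truth"), "truth must be a specimen_truth")
  .assert(nrow(panel) >= 1, "panel must be non-empty")
  model <- mmr_gene_model()
  lesions <- .lesions_for_site(truth$lesions, site)
  for (l in lesions)
    .assert(l$gene %in% model$gene,
            sprintf("gene '%s' absent from the gene model", l$gene))
  truth <- specimen_truth(truth$specimen_id, truth$msi_status,
                          truth$hypermutated, truth$true_burden, lesions)
  sid <- truth$specimen_id
  unstable_loci <- character()
  if (truth$msi_status == "MSI-high") {
    n_unstable <- round(config$msi_locus_fraction * nrow(panel))
    unstable_loci <- withr::with_seed(
      .derive_seed(config$seed, paste0("loci:", sid)),
      sample(panel$locus_id, n_unstable))
  }
  hist <- simulate_histograms(sid, panel, unstable_loci, config)
  variants <- withr::with_seed(.derive_seed(config$seed, paste0("var:", sid)),
                               .sim_variants(truth, config, model, site))
  exon_depth <- withr::with_seed(.derive_seed(config$seed, paste0("cnv:", sid)),
                                 .sim_exon_depth(truth, config, model))
  split_reads <- withr::with_seed(.derive_seed(config$seed, paste0("sv:", sid)),
                                  .sim_split_reads(truth, config, model))
  unstable_markers <- character()
  if (truth$msi_status == "MSI-high") {
    unstable_markers <- withr::with_seed(
      .derive_seed(config$seed, paste0("pcrsel:", sid)),
      sample(names(pcr_markers()), sample(2:5, 1L)))
  }
  pcr <- simulate_pcr_specimen(unstable_markers,
                               seed = .derive_seed(config$seed, paste0("pcr:", sid)))
  truth$unstable_loci <- sort(unstable_loci)
  truth$unstable_markers <- sort(unstable_markers)
  structure(list(truth = truth, histograms = hist, variants = variants,
                 exon_depth = exon_depth, split_reads = split_reads, pcr = pcr),
            class = "sim_specimen")
}

#' The five mononucleotide PCR markers
#'
#' Modal repeat lengths used by the PCR-profile generator for the five
#' mononucleotide markers of the pentaplex MSI panel (NR-21, BAT-26, BAT-25,
#' NR-24, MONO-27); the marker names encode the nominal run lengths.
#'
#' @return Named integer vector of modal repeat lengths.
#' @export
pcr_markers <- function() {
  c("NR-21" = 21L, "BAT-26" = 26L, "BAT-25" = 25L, "NR-24" = 24L,
    "MONO-27" = 27L)
}

#' Simulate a tumor/normal PCR fragment profile for one marker
#'
#' The normal profile is a main peak at the marker's modal repeat length with
#' a short geometric stutter shoulder. A stable tumor reproduces the normal
#' shape; an unstable tumor additionally carries a novel allele cluster
#' shifted 3-6 repeat units below the normal mode — beyond stutter range.
#'
#' @param marker One of `names(pcr_markers())`.
#' @param unstable Logical; plant a shifted tumor allele.
#' @param seed Integer seed.
#' @return A `marker_profile`: list with `marker`, `tumor` and `normal`
#'   (named intensity vectors, names = fragment length in repeat units),
#'   `truth_unstable` and `shift` (NA when stable).
#' @export
simulate_pcr_profile <- function(marker, unstable = FALSE, seed = 1L) {
  .assert(marker %in% names(pcr_markers()),
          sprintf("unknown marker '%s'", marker))
  withr::with_seed(.derive_seed(seed, paste0("pcr:", marker)), {
    M <- pcr_markers()[[marker]]
    # stutter shoulder spans 2 units below the allele, inside the
    # shift_min = 3 window the PCR scorer treats as stutter
    shoulder <- function(main) {
      lens <- M - (0:2)
      ints <- main * 0.45^(0:2) * stats::runif(3L, 0.9, 1.1)
      setNames(round(ints, 1), lens)
    }
    normal <- shoulder(1000 * stats::runif(1, 0.9, 1.1))
    tumor <- shoulder(1000 * stats::runif(1, 0.9, 1.1))
    shift <- NA_integer_
    if (isTRUE(unstable)) {
      shift <- sample(3:6, 1L)
      novel_main <- max(tumor) * stats::runif(1, 0.5, 0.9)
      lens <- (M - shift) - (0:2)
      novel <- setNames(round(novel_main * 0.45^(0:2), 1), lens)
      for (nm in names(novel))
        tumor[nm] <- sum(tumor[nm], novel[nm], na.rm = TRUE)
      tumor <- tumor[order(as.integer(names(tumor)))]
    }
    structure(list(marker = marker, tumor = tumor, normal = normal,
                   truth_unstable = isTRUE(unstable), shift = shift),
              class = "marker_profile")
  })
}

#' Simulate all five marker profiles for one specimen
#'
#' @param unstable_markers Character vector of marker names to destabilize.
#' @param seed Integer seed.
#' @return Named list of five [simulate_pcr_profile()] results.
#' @export
simulate_pcr_specimen <- function(unstable_markers = character(), seed = 1L) {
  bad <- setdiff(unstable_markers, names(pcr_markers()))
  .assert(length(bad) == 0L,
          sprintf("unknown marker(s): %s", paste(bad, collapse = ", ")))
  out <- lapply(names(pcr_markers()), function(m)
    simulate_pcr_profile(m, m %in% unstable_markers, seed))
  setNames(out, names(pcr_markers()))
}

#' Simulate a full cohort from a manifest
#'
#' Every specimen of a manifest entry shares that entry's truth (MSI status,
#' hypermutation, burden, lesions) except for lesions declared site-private,
#' which are planted only at their site.
#'
#' @param manifest A [cohort_manifest()].
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `specimens` (named list of
#'   [simulate_specimen()] outputs), `truth` (one row per specimen) and the
#'   `manifest`.
#' @export
simulate_cohort <- function(manifest, config = sim_config()) {
  .assert(inherits(manifest, "cohort_manifest"), "manifest must be a cohort_manifest")
  specs <- manifest$specimens
  out <- vector("list", nrow(specs))
  names(out) <- specs$specimen_id
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    e <- manifest$entries[manifest$entries$entry_id == sp$entry_id, ]
    truth <- specimen_truth(sp$specimen_id, e$msi_status, e$hypermutated,
                            e$true_burden,
                            manifest$lesions[[sp$entry_id]] %||% list())
    out[[i]] <- simulate_specimen(truth, msi_panel(config$n_loci), config,
                                  site = sp$site)
  }
  truth_df <- do.call(rbind, lapply(out, function(s) data.frame(
    specimen_id = s$truth$specimen_id, msi_status = s$truth$msi_status,
    hypermutated = s$truth$hypermutated, true_burden = s$truth$true_burden,
    n_lesions = length(s$truth$lesions),
    n_unstable_loci = length(s$truth$unstable_loci), stringsAsFactors = FALSE)))
  rownames(truth_df) <- NULL
  structure(list(specimens = out, truth = truth_df, manifest = manifest),
            class = "sim_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
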