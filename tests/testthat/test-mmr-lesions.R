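test_that("breakpoint clustering recovers planted events exactly when noiseless", {
  expect_equal(nrow(cluster_breakpoints(NULL)), 0L)

  cfg <- sim_config(seed = 8, sv_noise_reads = 0L)
  tr <- specimen_truth("SV1", "MSS", lesions = list(
    lesion_rearrangement("MSH2", "inversion", partner_label = "A"),
    lesion_rearrangement("MLH1", "translocation", partner_chrom = "chr18")))
  sim <- simulate_specimen(tr, msi_panel(5), cfg)
  calls <- cluster_breakpoints(sim$split_reads)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$type, c("inversion", "translocation"))
  # recovered positions equal the planted modal clip points exactly
  inv_reads <- sim$split_reads[sim$split_reads$clip_side == "right" &
                                 sim$split_reads$chrom == "chr2", ]
  expect_true(unique(inv_reads$pos) %in%
                c(calls$bp1_pos, calls$bp2_pos))
  expect_true(all(calls$n_support >= 4))
  expect_true(any(grepl("MSH2", calls$genes_hit)))
  expect_true(any(grepl("MLH1", calls$genes_hit)))

  # support below min_support yields no call
  few <- sim$split_reads[c(1:2, 13:14), ]
  expect_equal(nrow(cluster_breakpoints(few, min_support = 4)), 0L)
})

test_that("jittered clip points still cluster within the pairing window", {
  cfg <- sim_config(seed = 8, sv_noise_reads = 0L, sv_jitter = 5L)
  tr <- specimen_truth("SV2", "MSS", lesions = list(
    lesion_rearrangement("MSH6", "deletion", partner_label = "B")))
  sim <- simulate_specimen(tr, msi_panel(5), cfg)
  calls <- cluster_breakpoints(sim$split_reads, window = 10)
  expect_equal(nrow(calls), 1L)
  planted_pos <- unique(sim$split_reads$partner_pos[
    sim$split_reads$clip_side == "left"])
  expect_lte(abs(calls$bp1_pos - planted_pos), 10L)
})

test_that("exon CNV calling thresholds and merges segments", {
  model <- mmr_gene_model()
  dep <- data.frame(gene = model$gene, exon = model$exon,
                    depth_ratio = 1.0)
  r <- call_exon_cnv(dep)
  expect_true(all(r$calls$state == "neutral"))
  expect_equal(nrow(r$segments), 0L)

  dep2 <- dep
  dep2$depth_ratio[dep2$gene == "MSH2" & dep2$exon >= 8] <- 0.5
  r2 <- call_exon_cnv(dep2)
  expect_equal(nrow(r2$segments), 1L)
  expect_equal(r2$segments$label, "MSH2 exon 8-16 del")

  dep3 <- dep
  dep3$depth_ratio[dep3$gene == "MLH1"] <- 0.03
  r3 <- call_exon_cnv(dep3)
  seg <- r3$segments[r3$segments$gene == "MLH1", ]
  expect_equal(seg$state, "homozygous-loss")
  expect_equal(c(seg$exon_start, seg$exon_end), c(1L, 19L))

  # a single-exon dip below min_consecutive is called but not segmented
  dep4 <- dep
  dep4$depth_ratio[dep4$gene == "MSH6" & dep4$exon == 5] <- 0.5
  r4 <- call_exon_cnv(dep4)
  expect_equal(sum(r4$calls$state == "loss"), 1L)
  expect_equal(nrow(r4$segments), 0L)

  expect_error(call_exon_cnv(transform(dep, depth_ratio = -0.1)), ">= 0")
})

test_that("CNV segmentation is idempotent and input-order invariant", {
  model <- mmr_gene_model()
  dep <- data.frame(gene = model$gene, exon = model$exon, depth_ratio = 1.0)
  dep$depth_ratio[dep$gene == "MSH2" & dep$exon %in% 3:6] <- 0.45
  a <- call_exon_cnv(dep)
  set.seed(4)
  shuffled <- dep[sample(nrow(dep)), ]
  b <- call_exon_cnv(shuffled)
  expect_equal(a$segments, b$segments)
  expect_equal(call_exon_cnv(a$calls[, c("gene", "exon", "depth_ratio")])$segments,
               a$segments)
})

test_that("artifact-tract frameshifts are excluded regardless of MSI status", {
  tract <- msi_artifact_catalog()[1, ]
  v_in <- data.frame(specimen_id = "S", chrom = tract$chrom,
                     pos = tract$start + 2L, ref = "G", alt = "GG",
                     gene = "MSH6", consequence = "frameshift",
                     protein_altering = TRUE, tumor_vaf = 0.3,
                     normal_allele_balance = 0, common_variant = FALSE,
                     truth_class = "artifact", hgvs = tract$label,
                     stringsAsFactors = FALSE)
  v_out <- v_in
  v_out$pos <- tract$end + 500L
  v_out$truth_class <- "somatic"
  part <- exclude_msi_artifacts(rbind(v_in, v_out))
  expect_equal(nrow(part$excluded), 1L)
  expect_equal(part$excluded$pos, v_in$pos)
  expect_equal(nrow(part$retained), 1L)
  # exclusion is catalog-based: same result whatever the specimen status
  expect_equal(exclude_msi_artifacts(v_in)$retained,
               v_in[0, ])
})

test_that("zygosity verdicts follow the event-count rule and are monotone", {
  expect_equal(assess_biallelic(character()), "none")
  expect_equal(assess_biallelic("frameshift"), "monoallelic")
  expect_equal(assess_biallelic(c("frameshift", "copy-loss")), "biallelic")
  expect_equal(assess_biallelic("homozygous-loss"), "biallelic")
  expect_equal(assess_biallelic(c("rearrangement", "rearrangement")),
               "biallelic")
  # adding events never downgrades the verdict
  rank <- c(none = 0, monoallelic = 1, biallelic = 2)
  types <- c("frameshift", "nonsense", "rearrangement", "copy-loss",
             "homozygous-loss")
  set.seed(1)
  for (i in 1:25) {
    ev <- sample(types, sample(0:3, 1), replace = TRUE)
    more <- c(ev, sample(types, 1))
    expect_gte(rank[assess_biallelic(more)], rank[assess_biallelic(ev)])
  }
})

test_that("gene lesion integration matches the published zygosity patterns", {
  cfg <- sim_config(seed = 30, sv_noise_reads = 2L)
  panel <- msi_panel(5)

  # homozygous MLH1 deletion alone is biallelic
  s1 <- simulate_specimen(specimen_truth("06-134x", "MSI-high", TRUE, 314,
    lesions = list(lesion_copy_loss("MLH1", zygosity = "hom"))), panel, cfg)
  g1 <- gene_lesions(filter_somatic(s1$variants),
                     cluster_breakpoints(s1$split_reads),
                     call_exon_cnv(s1$exon_depth)$segments)
  expect_equal(g1$verdicts$zygosity_verdict[g1$verdicts$gene == "MLH1"],
               "biallelic")

  # a single frameshift is monoallelic
  s2 <- simulate_specimen(specimen_truth("00-010x", "MSI-high", TRUE, 350,
    lesions = list(lesion_frameshift("MSH2", exon = 14))), panel, cfg)
  g2 <- gene_lesions(filter_somatic(s2$variants),
                     cluster_breakpoints(s2$split_reads),
                     call_exon_cnv(s2$exon_depth)$segments)
  expect_equal(g2$verdicts$zygosity_verdict[g2$verdicts$gene == "MSH2"],
               "monoallelic")

  # two gene-splitting inversions are biallelic
  s3 <- simulate_specimen(specimen_truth("147x", "MSI-high", TRUE, 400,
    lesions = list(
      lesion_rearrangement("MSH2", "inversion", partner_label = "C2orf61"),
      lesion_rearrangement("MSH2", "inversion", partner_label = "KCNK12"))),
    panel, cfg)
  g3 <- gene_lesions(filter_somatic(s3$variants),
                     cluster_breakpoints(s3$split_reads),
                     call_exon_cnv(s3$exon_depth)$segments)
  expect_equal(g3$verdicts$zygosity_verdict[g3$verdicts$gene == "MSH2"],
               "biallelic")
  # mosaic artifact frameshifts in MSH6 tracts do not create MSH6 events
  expect_equal(g3$verdicts$zygosity_verdict[g3$verdicts$gene == "MSH6"],
               "none")
})
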