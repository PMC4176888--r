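test_that("zero-noise and zero-depth histograms are degenerate as expected", {
  cfg <- sim_config(stutter_prob = 0)
  locus <- msi_panel()[1, ]
  h <- simulate_locus_histogram(locus, unstable = FALSE, depth = 100,
                                config = cfg, seed = 7)
  expect_equal(sum(h$counts), 100L)
  expect_equal(names(h$counts), as.character(locus$ref_repeat_count))

  h0 <- simulate_locus_histogram(locus, depth = 0, config = cfg, seed = 7)
  expect_equal(h0$depth, 0L)
  expect_length(h0$counts, 0L)

  expect_error(simulate_locus_histogram(locus, depth = -1, config = cfg),
               "non-negative")
})

test_that("stable-locus stutter matches the closed-form geometric tail", {
  p <- 0.1
  cfg <- sim_config(stutter_prob = p)
  locus <- list(locus_id = "L", ref_repeat_count = 25L)
  depth <- 10000L
  h <- simulate_locus_histogram(locus, unstable = FALSE, depth = depth,
                                config = cfg, seed = 11)
  # expected fraction one unit below reference, from the analytic pmf
  p1 <- stutter_pmf(1L, p)
  obs <- unname(h$counts["24"]) / depth
  se <- sqrt(p1 * (1 - p1) / depth)
  expect_lt(abs(obs - p1), 3 * se)
})

test_that("empirical slip distribution passes chi-square GOF across seeds", {
  p <- 0.08
  cfg <- sim_config(stutter_prob = p)
  locus <- list(locus_id = "L", ref_repeat_count = 20L)
  depth <- 5000L
  max_slip <- min(locus$ref_repeat_count - 1L, 12L)
  expected <- stutter_pmf(0:max_slip, p, max_slip)
  n_pass <- 0L
  seeds <- 1:50
  for (s in seeds) {
    h <- simulate_locus_histogram(locus, depth = depth, config = cfg, seed = s)
    slips <- locus$ref_repeat_count - as.integer(names(h$counts))
    obs <- setNames(rep(0L, max_slip + 1L), 0:max_slip)
    obs[as.character(slips)] <- h$counts
    # pool slip classes with tiny expected counts to keep the test valid
    keep <- expected * depth >= 1
    o <- c(obs[keep], sum(obs[!keep]))
    e <- c(expected[keep], sum(expected[!keep]))
    pval <- suppressWarnings(stats::chisq.test(o, p = e / sum(e)))$p.value
    if (pval > 0.01) n_pass <- n_pass + 1L
  }
  expect_gte(n_pass, 48L)
})

test_that("unstable loci carry novel allele modes and MSS specimens do not", {
  cfg <- small_config(seed = 5)
  panel <- small_panel()
  locus <- panel[3, ]
  h <- simulate_locus_histogram(locus, unstable = TRUE, depth = 500,
                                config = cfg, shifts = c(3L, 5L), seed = 5)
  lens <- as.integer(names(h$counts))
  L <- locus$ref_repeat_count
  frac <- h$counts / h$depth
  expect_true(frac[as.character(L - 3L)] >= 0.1)
  expect_true(frac[as.character(L - 5L)] >= 0.1)
  expect_equal(sum(h$counts), 500L)
})

test_that("specimen simulation respects truth and conserves counts", {
  cfg <- sim_config(seed = 3)
  panel <- msi_panel()
  # MSI-high: exactly round(fraction * n_loci) destabilized loci
  tr <- specimen_truth("T1", "MSI-high", TRUE, 400)
  s <- simulate_specimen(tr, panel, cfg)
  expect_equal(length(s$truth$unstable_loci),
               round(cfg$msi_locus_fraction * nrow(panel)))
  expect_equal(length(s$truth$unstable_loci), 73L)
  # injected protein-altering count matches truth exactly
  expect_equal(sum(s$variants$protein_altering &
                     s$variants$truth_class %in% c("somatic", "artifact")),
               400L)
  # histogram mass equals per-locus totals (conservation over the table)
  expect_true(all(s$histograms$read_count >= 0))

  # MSS specimen with zero burden: contaminants only, all loci stable
  s0 <- simulate_specimen(specimen_truth("T0", "MSS"), panel, cfg)
  expect_length(s0$truth$unstable_loci, 0L)
  expect_true(all(s0$variants$truth_class != "somatic"))

  # unknown gene in a planted lesion is rejected
  bad <- specimen_truth("TX", "MSS", lesions = list(lesion_frameshift("PMS2")))
  expect_error(simulate_specimen(bad, panel, cfg), "absent from the gene model")
})

test_that("planted copy losses shape the exon depth ratios", {
  cfg <- sim_config(seed = 9)
  tr <- specimen_truth("T2", "MSS", lesions = list(
    lesion_copy_loss("MSH2", exons = 8:16)))
  s <- simulate_specimen(tr, msi_panel(), cfg)
  dep <- s$exon_depth
  lost <- dep$gene == "MSH2" & dep$exon >= 8
  intact <- dep$gene == "MSH2" & dep$exon <= 7
  expect_true(all(abs(dep$depth_ratio[lost] - 0.5) < 0.25))
  expect_true(all(abs(dep$depth_ratio[intact] - 1.0) < 0.25))
})

test_that("simulation is byte-identical under a fixed seed and config", {
  cfg <- small_config(seed = 21)
  tr <- specimen_truth("R1", "MSI-high", TRUE, 50,
                       lesions = list(lesion_rearrangement("MSH2", "inversion")))
  a <- simulate_specimen(tr, small_panel(), cfg)
  b <- simulate_specimen(tr, small_panel(), cfg)
  expect_identical(a, b)
  # and sensitive to the seed
  c2 <- simulate_specimen(tr, small_panel(), small_config(seed = 22))
  expect_false(identical(a$histograms, c2$histograms))
})

test_that("PCR profile generator plants detectable shifts with truth sidecar", {
  # stable marker: tumor and normal modal lengths equal
  st <- simulate_pcr_profile("BAT-26", unstable = FALSE, seed = 4)
  expect_equal(names(st$tumor)[which.max(st$tumor)],
               names(st$normal)[which.max(st$normal)])
  expect_false(st$truth_unstable)

  # unstable marker: novel modal length >= 3 units from the normal mode
  un <- simulate_pcr_profile("BAT-26", unstable = TRUE, seed = 4)
  expect_true(un$truth_unstable)
  expect_gte(un$shift, 3L)
  normal_mode <- as.integer(names(un$normal)[which.max(un$normal)])
  novel <- as.integer(names(un$tumor)[un$tumor >= 0.1 * max(un$tumor)])
  expect_true(any(abs(novel - normal_mode) >= 3L))

  expect_error(simulate_pcr_profile("BAT-40"), "unknown marker")
})

test_that("cohort simulation shares truth across sites except private lesions", {
  entries <- data.frame(
    entry_id = "P1", cohort = "autopsy", link = NA_character_,
    msi_status = "MSS", hypermutated = FALSE, true_burden = 20L,
    stringsAsFactors = FALSE)
  specimens <- data.frame(
    specimen_id = c("P1-a", "P1-b"), entry_id = "P1",
    site = c("prostate", "lymph node"), stringsAsFactors = FALSE)
  lesions <- list("P1" = list(
    lesion_frameshift("MSH2", exon = 7),
    lesion_frameshift("MLH1", exon = 12, site_private = "lymph node")))
  m <- cohort_manifest(entries, specimens, lesions)
  sim <- simulate_cohort(m, small_config(seed = 2))
  les_a <- sim$specimens[["P1-a"]]$truth$lesions
  les_b <- sim$specimens[["P1-b"]]$truth$lesions
  expect_length(les_a, 1L)
  expect_length(les_b, 2L)
  genes_b <- vapply(les_b, function(l) l$gene, character(1))
  expect_setequal(setdiff(genes_b, vapply(les_a, function(l) l$gene,
                                          character(1))), "MLH1")

  # duplicate specimen ids are rejected at manifest construction
  expect_error(cohort_manifest(entries, rbind(specimens, specimens[1, ])),
               "duplicate specimen ids")
  # empty manifest gives empty outputs
  m0 <- cohort_manifest(entries[0, ], specimens[0, ])
  sim0 <- simulate_cohort(m0, small_config())
  expect_length(sim0$specimens, 0L)
})
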