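test_that("allele counting applies the support-fraction rule", {
  expect_equal(count_alleles(mk_hist(c(`25` = 100))), 1L)
  expect_equal(count_alleles(mk_hist(c(`25` = 60, `24` = 30, `22` = 10))), 3L)
  # 3 reads sit below the 5-read support threshold at depth 100
  expect_equal(count_alleles(mk_hist(c(`25` = 97, `24` = 3))), 1L)
  expect_error(count_alleles(mk_hist(c(`25` = 0))), "zero depth")
})

test_that("baseline training uses population SD and drops low-depth controls", {
  tab <- do.call(rbind, lapply(1:10, function(i)
    data.frame(specimen_id = paste0("C", i), locus_id = "L1",
               repeat_length = 20L, read_count = 100L)))
  b <- train_baseline(tab)
  expect_equal(b$mean_allele_count, 1.0)
  expect_equal(b$sd_allele_count, 0.0)
  expect_equal(b$n_controls, 10L)

  # allele counts {1, 1, 2}: mean 4/3, population SD
  tab2 <- rbind(
    data.frame(specimen_id = "C1", locus_id = "L1",
               repeat_length = 20L, read_count = 100L),
    data.frame(specimen_id = "C2", locus_id = "L1",
               repeat_length = 20L, read_count = 100L),
    data.frame(specimen_id = "C3", locus_id = "L1",
               repeat_length = c(20L, 18L), read_count = c(60L, 40L)))
  b2 <- train_baseline(tab2)
  expect_equal(b2$mean_allele_count, 4 / 3)
  expect_equal(b2$sd_allele_count, sqrt(mean((c(1, 1, 2) - 4 / 3)^2)))

  # a control at depth 29 is excluded from that locus's baseline
  tab3 <- rbind(tab2,
    data.frame(specimen_id = "C4", locus_id = "L1",
               repeat_length = 20L, read_count = 29L))
  b3 <- train_baseline(tab3, min_depth = 30)
  expect_equal(b3$n_controls, 3L)

  # < 2 passing controls leaves the locus untrainable
  tab4 <- data.frame(specimen_id = c("C1", "C2"), locus_id = "L2",
                     repeat_length = 20L, read_count = c(29L, 100L))
  b4 <- train_baseline(rbind(tab2, tab4))
  expect_true("L2" %in% attr(b4, "untrainable"))
  expect_false("L2" %in% b4$locus_id)
})

test_that("locus evaluation applies depth filter and the mean + 3 SD rule", {
  base <- data.frame(locus_id = "L1", mean_allele_count = 1.2,
                     sd_allele_count = 0.4, n_controls = 10L)
  expect_equal(evaluate_locus(mk_hist(c(`20` = 29)), base), "filtered-low-depth")
  # identity with baseline is stable
  base0 <- data.frame(locus_id = "L1", mean_allele_count = 1.0,
                      sd_allele_count = 0.0, n_controls = 10L)
  expect_equal(evaluate_locus(mk_hist(c(`20` = 100)), base0), "stable")
  # 4 alleles > 1.2 + 3 * 0.4 = 2.4 -> unstable
  h4 <- mk_hist(c(`20` = 40, `18` = 25, `16` = 20, `14` = 15))
  expect_equal(evaluate_locus(h4, base), "unstable")
  # tie at exactly mean + 3 SD stays stable (strict inequality)
  base_tie <- data.frame(locus_id = "L1", mean_allele_count = 1.0,
                         sd_allele_count = 1.0, n_controls = 10L)
  expect_equal(evaluate_locus(h4, base_tie), "stable")
  expect_error(evaluate_locus(mk_hist(c(`20` = 100), "L9"), base), "mismatch")
})

test_that("specimen call uses strict > 0.20 on evaluated loci only", {
  st <- rep("stable", 146)
  expect_equal(call_specimen(st)$call, "MSI-negative")
  expect_equal(call_specimen(st)$fraction_unstable, 0)

  st2 <- c(rep("unstable", 25), rep("stable", 95), rep("filtered-low-depth", 26))
  r2 <- call_specimen(st2)
  expect_equal(r2$n_evaluated, 120L)
  expect_equal(r2$fraction_unstable, 25 / 120)
  expect_equal(r2$call, "MSI-high")

  st3 <- c(rep("unstable", 24), rep("stable", 96))
  r3 <- call_specimen(st3)
  expect_equal(r3$fraction_unstable, 0.20)
  expect_equal(r3$call, "MSI-negative")

  expect_equal(call_specimen(rep("stable", 10))$call, "indeterminate")
})

test_that("flipping a locus to unstable is monotone and order is irrelevant", {
  set.seed(42)
  for (i in 1:20) {
    st <- sample(c("stable", "unstable", "filtered-low-depth"), 60,
                 replace = TRUE, prob = c(0.6, 0.25, 0.15))
    r <- call_specimen(st)
    expect_equal(call_specimen(sample(st))$fraction_unstable,
                 r$fraction_unstable)
    flip <- which(st == "stable")[1]
    if (!is.na(flip)) {
      st2 <- st; st2[flip] <- "unstable"
      r2 <- call_specimen(st2)
      expect_gte(r2$fraction_unstable, r$fraction_unstable)
      if (r$call == "MSI-high") expect_equal(r2$call, "MSI-high")
    }
  }
})

test_that("caller agrees with the brute-force recount oracle", {
  cfg <- sim_config(seed = 13, n_loci = 40)
  panel <- msi_panel(40)
  base <- train_baseline(simulate_controls(6, panel, cfg))
  for (s in 1:5) {
    cfg_s <- sim_config(seed = 100 + s, n_loci = 40)
    unstable <- if (s %% 2 == 0)
      sample(panel$locus_id, 20) else character()
    tab <- simulate_histograms(paste0("S", s), panel, unstable, cfg_s)
    got <- msi_call_specimen(tab, base)
    want <- oracle_fraction(tab, base)
    expect_equal(got$n_evaluated, want$n_evaluated)
    expect_equal(got$n_unstable, want$n_unstable)
    expect_equal(got$fraction_unstable, want$fraction)
  }
})
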