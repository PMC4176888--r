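test_that("unique prevalence collapses the PDX/autopsy overlap", {
  m <- reference_cohort_manifest()
  calls <- data.frame(entry_id = m$entries$entry_id,
                      hypermutated = m$entries$hypermutated)
  p <- unique_prevalence(m, calls)
  expect_equal(p$numerator, 7L)
  expect_equal(p$denominator, 60L)
  expect_equal(p$percent, 11.7)
  expect_equal(p$percent_exact, 700 / 60)
  expect_length(p$discordant_links, 0L)
})

test_that("prevalence is invariant to entry order and link direction", {
  m <- reference_cohort_manifest()
  calls <- data.frame(entry_id = m$entries$entry_id,
                      hypermutated = m$entries$hypermutated)
  p <- unique_prevalence(m, calls)
  # shuffle entries
  set.seed(12)
  m2 <- m
  perm <- sample(nrow(m2$entries))
  m2$entries <- m2$entries[perm, ]
  p2 <- unique_prevalence(m2, calls[sample(nrow(calls)), ])
  expect_equal(p2$numerator, p$numerator)
  expect_equal(p2$denominator, p$denominator)
  # reverse the link direction (store it on the autopsy side)
  m3 <- m
  e <- m3$entries
  for (i in which(!is.na(e$link))) {
    j <- match(e$link[i], e$entry_id)
    e$link[j] <- e$entry_id[i]
    e$link[i] <- NA_character_
  }
  m3$entries <- e
  p3 <- unique_prevalence(m3, calls)
  expect_equal(p3$numerator, p$numerator)
  expect_equal(p3$denominator, p$denominator)
})

test_that("disjoint cohorts sum plainly and discordant links are flagged", {
  entries <- data.frame(
    entry_id = c("X1", "X2", "A1", "A2"),
    cohort = c("PDX", "PDX", "autopsy", "autopsy"),
    link = c(NA, NA, NA, NA),
    msi_status = "MSS", hypermutated = c(TRUE, FALSE, FALSE, FALSE),
    true_burden = 10L, stringsAsFactors = FALSE)
  specimens <- data.frame(specimen_id = entries$entry_id,
                          entry_id = entries$entry_id, site = "s",
                          stringsAsFactors = FALSE)
  m <- cohort_manifest(entries, specimens)
  calls <- data.frame(entry_id = entries$entry_id,
                      hypermutated = entries$hypermutated)
  p <- unique_prevalence(m, calls)
  expect_equal(p$numerator, 1L)
  expect_equal(p$denominator, 4L)

  # linked pair with discordant calls counts once, as hypermutated, flagged
  entries$link[1] <- "A1"
  m2 <- cohort_manifest(entries, specimens)
  p2 <- unique_prevalence(m2, calls)
  expect_equal(p2$denominator, 3L)
  expect_equal(p2$numerator, 1L)
  expect_length(p2$discordant_links, 1L)

  expect_error(unique_prevalence(m, calls[-1, ]), "without a call")
})

test_that("concordance rates cover agreeing, vacuous and discordant cohorts", {
  agree <- data.frame(patient_id = c("A", "A", "B"),
                      specimen_id = c("a1", "a2", "b1"),
                      call = c(TRUE, TRUE, FALSE))
  c1 <- concordance(agree)
  expect_equal(c1$rate, 1.0)
  expect_equal(c1$n_multisite, 1L)

  single <- data.frame(patient_id = c("A", "B"),
                       specimen_id = c("a1", "b1"), call = c(TRUE, FALSE))
  c2 <- concordance(single)
  expect_equal(c2$rate, 1.0)
  expect_equal(c2$n_multisite, 0L)

  disc <- rbind(agree, data.frame(patient_id = "C",
                                  specimen_id = c("c1", "c2"),
                                  call = c(TRUE, FALSE)))
  c3 <- concordance(disc)
  expect_lt(c3$rate, 1.0)
  expect_false(c3$per_patient$concordant[c3$per_patient$patient_id == "C"])
})

test_that("mechanism table audits hypermutated rows and tolerates gaps", {
  calls <- data.frame(
    patient_id = c("H1", "H2", "L1", "N1"),
    hypermutated = c(TRUE, TRUE, FALSE, FALSE),
    msi_ngs = c("MSI-high", "MSI-negative", "MSI-negative", "MSI-negative"),
    msi_pcr = c("MSI-positive", "MSI-negative", "MSI-negative", "MSI-negative"),
    n_mmr_events = c(2L, 0L, 2L, 0L),
    verdict = c("biallelic", "none", "monoallelic", "none"),
    stringsAsFactors = FALSE)
  mt <- mechanism_table(calls)
  expect_false(mt$violation[mt$patient_id == "H1"])
  expect_true(mt$violation[mt$patient_id == "H2"])  # hyper without MSI/lesion
  # lesion-positive, MSI-negative, non-hypermutated is not a violation
  expect_false(mt$violation[mt$patient_id == "L1"])
  expect_equal(attr(mt, "n_violations"), 1L)

  # missing inputs mark the row incomplete, excluded from the audit
  calls$msi_pcr[1] <- NA
  mt2 <- mechanism_table(calls)
  expect_true(mt2$incomplete[1])
  expect_true(is.na(mt2$violation[1]))

  # empty cohort gives an empty table
  mt0 <- mechanism_table(calls[0, ])
  expect_equal(nrow(mt0), 0L)
  expect_equal(attr(mt0, "n_violations"), 0L)
})
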