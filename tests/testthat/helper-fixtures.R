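# shared fixtures built in code at test time

# a histogram object without running the generator
mk_hist <- function(counts, locus_id = "L1") {
  counts <- counts[order(as.integer(names(counts)))]
  structure(list(locus_id = locus_id,
                 counts = setNames(as.integer(counts), names(counts)),
                 depth = sum(counts)),
            class = "length_histogram")
}

# minimal variant table row(s) for filter tests
mk_variants <- function(vaf, nab = 0, common = FALSE, palt = TRUE) {
  n <- max(length(vaf), length(nab), length(common), length(palt))
  data.frame(specimen_id = "S", chrom = "chr1", pos = seq_len(n),
             ref = "A", alt = "C", gene = NA_character_,
             consequence = ifelse(rep_len(palt, n), "missense", "synonymous"),
             protein_altering = rep_len(palt, n),
             tumor_vaf = rep_len(vaf, n),
             normal_allele_balance = rep_len(nab, n),
             common_variant = rep_len(common, n),
             truth_class = "somatic", hgvs = NA_character_,
             stringsAsFactors = FALSE)
}

# small panel + config to keep unit tests fast
small_config <- function(seed = 1L, ...) sim_config(seed = seed, n_loci = 8L, ...)
small_panel <- function() msi_panel(8L)

# brute-force unstable-fraction oracle: recount alleles straight from the
# long-format table, independent of the caller's code path
oracle_fraction <- function(tab, baseline, min_depth = 30, k_sd = 3,
                            support_fraction = 0.05) {
  n_unst <- 0L; n_eval <- 0L
  for (i in seq_len(nrow(baseline))) {
    loc <- baseline$locus_id[i]
    rows <- tab[tab$locus_id == loc, ]
    depth <- sum(rows$read_count)
    if (depth < min_depth) next
    n_eval <- n_eval + 1L
    alleles <- sum(rows$read_count >= support_fraction * depth)
    cutoff <- baseline$mean_allele_count[i] + k_sd * baseline$sd_allele_count[i]
    if (alleles > cutoff) n_unst <- n_unst + 1L
  }
  list(n_evaluated = n_eval, n_unstable = n_unst,
       fraction = if (n_eval) n_unst / n_eval else NA_real_)
}
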