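test_that("config and truth validation reject inconsistent inputs", {
  expect_error(simulation_config(het_site_rate = -1), "non-negative")
  expect_error(simulation_config(sharing_profile = c(NOPE = 0.5)), "unknown strain")
  expect_error(introgression_truth(devoid_gaps = data.frame(start = 1, end = 2)),
               "inside a heterozygous block")
  expect_error(
    generate_congenic_callset(
      simulation_config(chromosome_lengths = c(chr13 = 5e7)),
      introgression_truth()),
    "outside chromosome")
  expect_error(
    generate_congenic_callset(simulation_config(chromosome_lengths = c(chr1 = 1e8)),
                              introgression_truth()),
    "not in config")
})

test_that("with no artifact source every emitted call is het and inside the planted blocks", {
  cfg <- simulation_config(chromosome_lengths = c(chr13 = 1.2e8),
                           artifact_cluster_rate = 0, seed = 7)
  tr <- introgression_truth(
    blocks = data.frame(start = 4e7, end = 5e7, state = "heterozygous"),
    devoid_gaps = NULL, private_site_region = c(4.2e7, 4.4e7))
  sim <- generate_congenic_callset(cfg, tr)
  expect_true(all(sim$calls$genotype == "het"))
  expect_true(all(sim$calls$pos >= 4e7 & sim$calls$pos <= 5e7))
  expect_true(all(sim$truth$origin == "introgression"))
})

test_that("same config and seed give identical call sets; different seeds differ", {
  cfg <- simulation_config(seed = 42)
  tr <- introgression_truth()
  a <- generate_congenic_callset(cfg, tr)
  b <- generate_congenic_callset(cfg, tr)
  expect_identical(a, b)
  c <- generate_congenic_callset(simulation_config(seed = 43), tr)
  expect_false(identical(a$calls, c$calls))
})

test_that("every call carries exactly one origin and devoid gaps carry no calls", {
  for (s in c(1, 2, 3)) {
    cfg <- simulation_config(seed = s)
    tr <- introgression_truth()
    sim <- generate_congenic_callset(cfg, tr)
    expect_identical(sim$truth[, c("chrom", "pos")], sim$calls[, c("chrom", "pos")])
    expect_true(all(sim$truth$origin %in% c("introgression", "artifact")))
    g <- tr$devoid_gaps
    for (i in seq_len(nrow(g)))
      expect_false(any(sim$calls$chrom == tr$chromosome &
                         sim$calls$pos >= g$start[i] & sim$calls$pos <= g$end[i]))
    expect_false(anyDuplicated(paste(sim$calls$chrom, sim$calls$pos)) > 0)
  }
})

test_that("in-block site counts follow the Poisson intensity (4*sqrt(rL) band)", {
  r <- 50; L <- 10  # sites/Mb, Mb
  tr <- introgression_truth(
    blocks = data.frame(start = 1e7 + 1, end = 2e7, state = "heterozygous"),
    devoid_gaps = NULL, private_site_region = c(1.2e7, 1.3e7))
  counts <- vapply(1:100, function(s) {
    cfg <- simulation_config(chromosome_lengths = c(chr13 = 1.2e8),
                             het_site_rate = r, artifact_cluster_rate = 0, seed = s)
    nrow(generate_congenic_callset(cfg, tr)$calls)
  }, 0)
  expect_true(all(abs(counts - r * L) <= 4 * sqrt(r * L)))
  expect_lt(abs(mean(counts) - r * L), 2 * sqrt(r * L / 100) * 3)
})

test_that("panel sharing honours the profile and the private region", {
  cfg0 <- simulation_config(
    panel_strains = c("S1", "S2"), sharing_profile = c(S1 = 0, S2 = 0), seed = 5)
  tr <- introgression_truth()
  sim <- generate_congenic_callset(cfg0, tr)
  pan <- generate_strain_panel(cfg0, sim, tr)
  expect_true(all(pan$site_truth$label == "private"))

  cfg1 <- simulation_config(
    panel_strains = c("S1", "S2"), sharing_profile = c(S1 = 1, S2 = 0.5), seed = 5)
  pan1 <- generate_strain_panel(cfg1, sim, tr)
  non_priv <- !pan1$site_truth$in_private_region
  expect_true(all(pan1$panel$alleles[non_priv, "S1"] == 1L))
  expect_true(all(pan1$panel$alleles[pan1$site_truth$in_private_region, ] == 0L))
  # with a strain at probability 1, realized private = planted private region
  expect_identical(pan1$site_truth$label == "private",
                   pan1$site_truth$in_private_region)
})

test_that("cohort draws match the configured probabilities (binomial oracle)", {
  cc <- cohort_config(n_per_genotype = c("+/+" = 10000L),
                      p_female = c("+/+" = 0.7),
                      gonad_category_probs = list(
                        "+/+" = c(O = 0.5, Ot = 0.2, ot = 0.2, oT = 0.1, T = 0)),
                      seed = 11)
  coh <- generate_cohort(cc)
  expect_equal(nrow(coh), 10000L)
  expect_lt(abs(mean(coh$sex == "F") - 0.7), 0.02)
  expect_lt(abs(mean(coh$gonad == "O") - 0.5), 0.02)
  expect_identical(coh, generate_cohort(cc))
  expect_error(cohort_config(p_female = c("+/+" = 1.5, "int/+" = 0.4)), "0, 1")
})

test_that("p_female 1 gives all females", {
  cc <- cohort_config(n_per_genotype = c("+/+" = 50L, "int/+" = 50L),
                      p_female = c("+/+" = 1, "int/+" = 1), seed = 2)
  expect_true(all(generate_cohort(cc)$sex == "F"))
})

test_that("qPCR generator: zero noise plants the exact fold change", {
  qc <- qpcr_config(true_fold_change = 1, ct_noise_sd = 0, seed = 3)
  ct <- generate_qpcr(qc)
  dd <- ddct_fold_change(ct, calibrator_group = "control")
  expect_equal(dd$groups$fold_change, c(1, 1))

  qc2 <- qpcr_config(true_fold_change = 2, ct_noise_sd = 0, seed = 3)
  dd2 <- ddct_fold_change(generate_qpcr(qc2), calibrator_group = "control")
  expect_equal(dd2$groups$ddct[dd2$groups$group == "carrier"], -1)
  expect_equal(dd2$groups$fold_change[dd2$groups$group == "carrier"], 2)
})

test_that("noisy qPCR recovers the planted fold change on average (Monte-Carlo oracle)", {
  est <- vapply(1:100, function(s) {
    qc <- qpcr_config(true_fold_change = 0.5, ct_noise_sd = 0.2,
                      n_replicates = 5L, seed = s)
    dd <- ddct_fold_change(generate_qpcr(qc), calibrator_group = "control")
    dd$groups$fold_change[dd$groups$group == "carrier"]
  }, 0)
  expect_lt(abs(mean(est) - 0.5) / 0.5, 0.25)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  expected <- runif(1)
  set.seed(99)
  invisible(generate_cohort(cohort_config(seed = 1)))
  expect_identical(runif(1), expected)
})
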