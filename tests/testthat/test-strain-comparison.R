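test_that("private/shared classification follows panel carriage", {
  al <- matrix(0L, 3, 3, dimnames = list(NULL, c("BALB/cJ", "S2", "S3")))
  al[1, 1] <- 1L  # site 1 carried by BALB/cJ only
  pan <- make_panel(strains = c("BALB/cJ", "S2", "S3"), alleles = al)
  sites <- data.frame(chrom = "chr13", pos = c(100, 200, 300))
  prov <- classify_private(sites, pan)
  expect_equal(prov$label, c("shared", "private", "private"))
  expect_equal(prov$sharing_strains[1], "BALB/cJ")
  expect_equal(prov$n_sharing, c(1L, 0L, 0L))
  # partition invariant
  expect_equal(sum(prov$label == "private") + sum(prov$label == "shared"),
               nrow(sites))
})

test_that("sites absent from the panel are logged and counted private", {
  pan <- make_panel(alleles = matrix(1L, 3, 3))
  sites <- data.frame(chrom = "chr13", pos = c(100, 999))
  expect_message(prov <- classify_private(sites, pan), "1 site\\(s\\) absent")
  expect_equal(prov$label, c("shared", "private"))
  expect_equal(prov$in_panel, c(TRUE, FALSE))
})

test_that("empty panel classifies everything private with a warning", {
  pan <- strain_panel(character(0),
                      data.frame(chrom = character(0), pos = numeric(0),
                                 ref = character(0), alt = character(0)),
                      matrix(0L, 0, 0))
  expect_warning(prov <- classify_private(data.frame(chrom = "chr13", pos = 1:3),
                                          pan),
                 "empty panel")
  expect_true(all(prov$label == "private"))
})

test_that("classification recovers the planted truth labels", {
  cfg <- simulation_config(seed = 31)
  tr <- introgression_truth()
  sim <- generate_congenic_callset(cfg, tr)
  pan <- generate_strain_panel(cfg, sim, tr)
  prov <- classify_private(pan$site_truth[, c("chrom", "pos")], pan$panel)
  expect_identical(prov$label, pan$site_truth$label)
  # adding a strain never increases privacy (monotonicity)
  sub <- strain_panel(pan$panel$strains[-1], pan$panel$sites,
                      pan$panel$alleles[, -1, drop = FALSE])
  prov_sub <- classify_private(pan$site_truth[, c("chrom", "pos")], sub)
  expect_true(all(!(prov_sub$label == "shared" & prov$label == "private")))
})

test_that("strain similarity equals per-strain counting, ranks deterministically", {
  al <- matrix(c(1L, 1L, 1L,   # S_all carries everything
                 1L, 0L, 0L,
                 1L, 0L, 0L), 3, 3)
  pan <- make_panel(strains = c("S_all", "B", "A"), alleles = al)
  sites <- data.frame(chrom = "chr13", pos = c(100, 200, 300))
  sim <- strain_similarity(sites, pan)
  expect_equal(sim$fraction[sim$strain == "S_all"], 1)
  expect_equal(sim$rank[sim$strain == "S_all"], 1L)
  # tie between A and B broken by label order
  expect_equal(sim$strain, c("S_all", "A", "B"))

  # brute-force fractions on a generated panel
  cfg <- simulation_config(seed = 17)
  tr <- introgression_truth()
  simc <- generate_congenic_callset(cfg, tr)
  pan2 <- generate_strain_panel(cfg, simc, tr)
  q <- pan2$site_truth[, c("chrom", "pos")]
  got <- strain_similarity(q, pan2$panel)
  brute <- vapply(pan2$panel$strains, function(s) {
    carried <- 0
    for (i in seq_len(nrow(q))) {
      j <- which(pan2$panel$sites$chrom == q$chrom[i] &
                   pan2$panel$sites$pos == q$pos[i])
      if (length(j) && pan2$panel$alleles[j, s] == 1L) carried <- carried + 1
    }
    carried / nrow(q)
  }, 0)
  expect_equal(got$fraction, unname(brute[got$strain]))
  # permutation invariance of the ranking
  set.seed(1)
  perm <- q[sample(nrow(q)), ]
  expect_equal(strain_similarity(perm, pan2$panel), got)
  # planted sharing profile puts BALB/cJ first
  expect_equal(got$strain[1], "BALB/cJ")
  expect_equal(got$strain[36], "C57BL/6NJ")
})

test_that("label-split density conserves per-label counts and locates the private cluster", {
  cfg <- simulation_config(seed = 23)
  tr <- introgression_truth()
  sim <- generate_congenic_callset(cfg, tr)
  pan <- generate_strain_panel(cfg, sim, tr)
  st <- pan$site_truth
  track <- windowed_private_density(st[, c("chrom", "pos")], st$label, "chr13",
                                    cfg$chromosome_lengths[["chr13"]])
  expect_equal(sum(track$private), sum(st$label == "private"))
  expect_equal(sum(track$shared), sum(st$label == "shared"))
  expect_equal(track$counts, track$private + track$shared)
  span <- max_private_span(track)
  expect_equal(span$start, 60e6 + 1)  # planted private region 60-70 Mb

  # all shared -> private track all zeros
  all_shared <- windowed_private_density(st[, c("chrom", "pos")],
                                         rep("shared", nrow(st)), "chr13",
                                         cfg$chromosome_lengths[["chr13"]])
  expect_true(all(all_shared$private == 0L))
})

test_that("marker-based region genotyping withholds majority resolution", {
  mk <- function(genos) data.frame(animal = "a1", marker = sprintf("M%02d", seq_along(genos)),
                                   genotype = genos)
  expect_equal(genotype_region(mk(rep("het", 9)))$region_genotype, "int/+")
  expect_equal(genotype_region(mk(rep("hom_ref", 9)))$region_genotype, "+/+")
  expect_equal(genotype_region(mk(rep("hom_alt", 9)))$region_genotype, "int/int")
  expect_equal(genotype_region(mk(c(rep("het", 5), rep("hom_ref", 4))))$region_genotype,
               "discordant")
  # missing calls are ignored, not discordant
  expect_equal(genotype_region(mk(c("het", "missing", "het")))$region_genotype,
               "int/+")
  expect_error(genotype_region(mk("het"), markers = c("M99")), "unknown marker")
})

test_that("select_markers spans the segment", {
  calls <- make_calls(seq(4e7, 7e7, by = 1e5))
  seg <- data.frame(chrom = "chr13", start = 4e7, end = 7e7)
  mk <- select_markers(calls, seg, n = 9)
  expect_equal(nrow(mk), 9L)
  expect_equal(mk$pos[1], 4e7)
  expect_equal(mk$pos[9], 7e7)
  expect_true(all(diff(mk$pos) > 0))
})
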