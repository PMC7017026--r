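test_that("quality filter removes MQ below threshold and failed-status calls", {
  calls <- make_calls(c(100, 200, 300, 400),
                      mq = c(199, 200, 600, 600),
                      pass = c(TRUE, TRUE, FALSE, TRUE))
  out <- apply_quality_filters(calls, scan_params())
  expect_equal(out$calls$pos, c(200, 400))   # 199 removed, 200 retained
  expect_equal(unname(out$removed), c(1, 1))

  empty <- apply_quality_filters(make_calls(numeric(0)), scan_params())
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(unname(empty$removed), c(0, 0))

  # missing MQ fails the quality criterion
  nacall <- make_calls(10, mq = NA)
  expect_equal(nrow(apply_quality_filters(nacall)$calls), 0L)
})

test_that("raising the MQ threshold never increases the retained count", {
  set.seed(1)
  calls <- make_calls(sort(sample(1e6, 200)), mq = runif(200, 0, 1000),
                      pass = runif(200) < 0.9)
  kept <- vapply(seq(0, 1000, by = 50), function(th)
    nrow(apply_quality_filters(calls, scan_params(mq_threshold = th))$calls), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("het selection is a projection", {
  calls <- make_calls(1:6, genotype = c("het", "hom_ref", "het", "hom_alt",
                                        "missing", "het"))
  het <- select_het_nonref(calls)
  expect_equal(nrow(het), 3L)
  expect_identical(select_het_nonref(het), het)
  expect_equal(nrow(select_het_nonref(make_calls(1:3, genotype = "hom_ref"))), 0L)
})

test_that("window counts match direct counting and conserve totals", {
  calls <- make_calls(c(38200001, 38500000, 39100000))
  tr <- window_density(calls, "chr13", 1.2e8, scan_params())
  expect_equal(tr$counts[39], 2L)  # window 39 covers 38,000,001-39,000,000
  expect_equal(tr$counts[40], 1L)
  expect_equal(sum(tr$counts), 3L)

  expect_true(all(window_density(make_calls(numeric(0)), "chr13", 1e7)$counts == 0L))
  expect_error(window_density(make_calls(2e7), "chr13", 1e7), "beyond chromosome")

  set.seed(4)
  pos <- sort(sample(9.7e7, 500))
  tr2 <- window_density(make_calls(pos), "chr13", 9.7e7, scan_params())
  expect_equal(tr2$counts, oracle_window_counts(pos, 9.7e7, 1e6))
  expect_equal(sum(tr2$counts), 500L)
})

make_track <- function(counts, w = 1e6) {
  n <- length(counts)
  structure(list(chromosome = "chr13", window_size = w,
                 chromosome_length = n * w, counts = counts,
                 start = (seq_len(n) - 1) * w + 1, end = seq_len(n) * w),
            class = "window_track")
}

test_that("segment calling follows run semantics, gap bridging and size triage", {
  p <- scan_params(min_snps_per_window = 3, max_gap_windows = 0,
                   min_segment_windows = 3)
  seg <- call_segments(make_track(c(0, 0, 5, 7, 6, 0, 0)), p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 2e6 + 1)   # windows 3-5
  expect_equal(seg$end, 5e6)
  expect_equal(seg$n_supporting_snps, 18)
  expect_equal(seg$classification, "introgressed")

  # max_gap 1 merges [5, 0, 5]
  p1 <- scan_params(min_snps_per_window = 3, max_gap_windows = 1,
                    min_segment_windows = 3)
  merged <- call_segments(make_track(c(5, 0, 5)), p1)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_windows, 3L)
  # max_gap 0 splits it into two sub-minimum runs -> artifact candidates
  split2 <- call_segments(make_track(c(5, 0, 5)),
                          scan_params(min_snps_per_window = 3, max_gap_windows = 0,
                                      min_segment_windows = 3))
  expect_equal(nrow(split2), 2L)
  expect_true(all(split2$classification == "artifact_candidate"))

  expect_equal(nrow(call_segments(make_track(c(0, 0, 0)), p)), 0L)
})

test_that("boundaries trim to supporting SNPs when calls are supplied", {
  calls <- make_calls(c(2100000, 2200000, 2400000, 3100000, 3300000, 3500000,
                        4200000, 4600000, 4900000))
  tr <- window_density(calls, "chr13", 7e6, scan_params(min_snps_per_window = 3))
  seg <- call_segments(tr, scan_params(min_snps_per_window = 3), calls)
  expect_equal(seg$start, 2100000)
  expect_equal(seg$end, 4900000)
  expect_equal(seg$n_supporting_snps, 9)
})

test_that("segment calls are invariant to input call ordering", {
  set.seed(9)
  pos <- sample(c(sample(3.8e7:7.5e7, 800), sample(1:1e7, 5)))
  calls <- make_calls(pos)
  shuffled <- calls[sample(nrow(calls)), ]
  p <- scan_params()
  t1 <- window_density(calls, "chr13", 1.2e8, p)
  t2 <- window_density(shuffled, "chr13", 1.2e8, p)
  expect_identical(call_segments(t1, p, calls), call_segments(t2, p, shuffled))
})

test_that("artifact triage annotates candidate clusters", {
  calls <- make_calls(c(5e6 + 1, 5e6 + 100,
                        2e7 + seq(1, 37e6, by = 2e4)),
                      mq = c(120, 130, rep(650, 1851)))
  p <- scan_params(min_snps_per_window = 2)
  tr <- window_density(calls, "chr13", 1.2e8, p)
  segs <- flag_artifact_clusters(call_segments(tr, p, calls), calls)
  art <- segs[segs$classification == "artifact_candidate", ]
  big <- segs[segs$classification == "introgressed", ]
  expect_equal(nrow(art), 1L)
  expect_equal(art$n_calls, 2L)
  expect_equal(art$mean_mq, 125)
  expect_equal(nrow(big), 1L)
  expect_gte(big$n_windows, 37L)
})

test_that("devoid gaps match a brute-force scan and recover a planted gap", {
  seg <- data.frame(chrom = "chr13", start = 1e6, end = 2e7)
  set.seed(12)
  pos <- sort(c(sample(1e6:8e6, 300), sample(1.3e7:2e7, 300)))  # gap 8-13 Mb
  gaps <- find_devoid_gaps(seg, make_calls(pos), min_gap_bp = 1e6)
  oracle <- oracle_gaps(1e6, 2e7, pos, 1e6)
  expect_equal(gaps$start, oracle$start)
  expect_equal(gaps$end, oracle$end)
  expect_equal(gaps$width_bp, oracle$width)
  expect_gt(gaps$width_bp[1], 4.9e6)
  expect_true(gaps$start[1] <= 1e7 && gaps$end[1] >= 1e7)

  # uniformly dense calls -> no gap at 1 Mb
  dense <- make_calls(seq(1e6, 2e7, by = 1e4))
  expect_equal(nrow(find_devoid_gaps(seg, dense, 1e6)), 0L)
})

test_that("the planted 4.5 Mb devoid gap around the 51.8 Mb locus is the widest", {
  cfg <- simulation_config(seed = 21)
  tr <- introgression_truth()
  sim <- generate_congenic_callset(cfg, tr)
  het <- select_het_nonref(apply_quality_filters(sim$calls)$calls)
  track <- window_density(het, "chr13", cfg$chromosome_lengths[["chr13"]])
  segs <- call_segments(track, scan_params(), het)
  seg <- segs[which.max(segs$end - segs$start), ]
  gaps <- find_devoid_gaps(seg, het, 1e6)
  expect_true(gaps$start[1] <= 51.8e6 && gaps$end[1] >= 51.8e6)
  expect_lt(abs(gaps$width_bp[1] - 4.5e6), 1e6)
})

test_that("interval annotation equals the quadratic all-pairs oracle", {
  segs <- data.frame(chrom = c("chr13", "chr13", "chr4"),
                     start = c(3.8e7, 9e7, 1e6), end = c(7.57e7, 9.1e7, 2e6))
  gaps <- data.frame(chrom = "chr13", start = 4.95e7, end = 5.4e7)
  set.seed(5)
  feats <- data.frame(
    chrom = sample(c("chr13", "chr4", "chr7"), 60, replace = TRUE),
    start = sample(1.2e8, 60))
  feats$end <- feats$start + sample(5e5, 60)
  ann <- annotate_intervals(segs, feats, gaps)
  expect_equal(ann$overlaps_segment, oracle_overlaps(feats, segs))
  expect_equal(ann$in_gap, oracle_overlaps(feats, gaps, within = TRUE))

  inside <- data.frame(chrom = "chr13", start = 5.17e7, end = 5.19e7)
  one <- annotate_intervals(segs, inside, gaps)
  expect_true(one$overlaps_segment)  # feature wholly inside segment
  expect_true(one$in_gap)            # and inside the devoid gap
})
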