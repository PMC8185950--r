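test_that("genome-tiling features give ratio exactly 1", {
  truth <- shared_truth
  tiling <- do.call(rbind, lapply(seq_len(nrow(truth$genome)), function(i) {
    data.frame(chrom = truth$genome$chrom[i], start = 0,
               end = truth$genome$length[i])
  }))
  res <- matched_null_enrichment(shared_pchic, tiling, truth$fragmap,
                                 n_iter = 20, seed = 2)
  expect_equal(res$ratio, 1)
  expect_true(all(res$expected == res$observed))
  expect_true(res$degenerate)  # zero-variance null, t-test undefined
})

test_that("uniform random features are not called enriched", {
  truth <- shared_truth
  set.seed(77)
  ratios <- vapply(1:4, function(i) {
    start <- floor(runif(1000, 0, 19e6))
    feats <- data.frame(chrom = sample(truth$genome$chrom, 1000, replace = TRUE),
                        start = start, end = start + 5000)
    matched_null_enrichment(shared_pchic, feats, truth$fragmap,
                            n_iter = 50, seed = 90 + i)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("the (length, distance) joint distribution is preserved per iteration", {
  truth <- shared_truth
  feats <- as.data.frame(truth$planted_features)
  res <- matched_null_enrichment(shared_pchic, feats, truth$fragmap,
                                 n_iter = 5, seed = 4, keep_placements = TRUE)
  df <- as.data.frame(shared_pchic)
  cis <- df[!is.na(df$distance_bp), ]
  oe <- cis[!duplicated(cis$other_frag), ]
  expected_pairs <- sort(paste((oe$other_end - oe$other_start), oe$distance_bp))
  got_pairs <- sort(paste(res$placements$length, res$placements$distance_bp))
  # every placed pair must come from the observed multiset (skips allowed)
  expect_true(all(got_pairs %in% expected_pairs))
  expect_gte(length(got_pairs), length(expected_pairs) - res$n_skipped)
})

test_that("features planted at half the other-ends are strongly enriched", {
  truth <- shared_truth
  res <- matched_null_enrichment(shared_pchic, truth$planted_features,
                                 truth$fragmap, n_iter = 100, seed = 6)
  expect_gt(res$ratio, 1.5)
  expect_lt(res$t_p, 1e-6)
})

test_that("empty feature sets degenerate instead of crashing", {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  res <- matched_null_enrichment(shared_pchic, empty, shared_truth$fragmap,
                                 n_iter = 5)
  expect_equal(res$observed, 0)
  expect_true(res$degenerate)
  expect_error(matched_null_enrichment(shared_pchic, empty,
                                       shared_truth$fragmap, n_iter = 1),
               "n_iter")
})

test_that("oscillatory enhancers are preferentially contacted by circadian baits", {
  truth <- shared_truth
  osc <- truth$enhancers[truth$enhancers$oscillatory, ]
  nonosc <- truth$enhancers[!truth$enhancers$oscillatory, ]
  circ_baits <- truth$genes$frag_id[truth$genes$circadian]
  res <- erna_contact_enrichment(shared_pchic, osc, nonosc, circ_baits,
                                 n_iter = 100, seed = 8)
  expect_gt(res$ratio, 1)
  expect_lt(res$t_p, 0.01)

  # zero circadian baits -> degenerate
  res0 <- erna_contact_enrichment(shared_pchic, osc, nonosc, integer(0),
                                  n_iter = 10)
  expect_true(res0$degenerate)
  expect_equal(res0$observed, 0)

  expect_error(erna_contact_enrichment(shared_pchic, truth$enhancers,
                                       osc[1:3, ], circ_baits), "nonosc")
})

test_that("label-shuffled enhancer sets are not called enriched", {
  truth <- shared_truth
  enh <- truth$enhancers
  set.seed(91)
  ratios <- replicate(20, {
    flip <- sample(nrow(enh), nrow(enh) / 2)
    osc_s <- enh[flip, ]
    nonosc_s <- enh[-flip, ]
    erna_contact_enrichment(shared_pchic, osc_s, nonosc_s,
                            truth$genes$frag_id[truth$genes$circadian],
                            n_iter = 50, seed = sample.int(1e6, 1))$ratio
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("phase binning maps hours to the eight 3-hour groups", {
  truth <- shared_truth
  calls <- classify_circadian(shared_expr)
  targets <- data.frame(frag_id = truth$enhancers$frag_id,
                        phase_hr = truth$enhancers$phase_hr)
  pc <- phase_coherence(shared_pchic, calls, targets, "hr8x3")
  expect_equal(names(pc$diurnal), as.character(0:7))
  # binning rule: hour 0 -> bin 0, hour 23.5 -> bin 7
  expect_equal(floor(0 / 3), 0)
  expect_equal(floor(23.5 / 3), 7)
  # planted assortative wiring separates the groups
  expect_lt(pc$wilcoxon_p, 0.01)
})

test_that("promoter-target phase coherence detects planted assortativity", {
  truth <- shared_truth
  calls <- classify_circadian(shared_expr)
  targets <- data.frame(frag_id = truth$genes$frag_id,
                        phase_hr = truth$genes$phase)
  pc <- phase_coherence(shared_pchic, calls, targets, "zt4")
  expect_false(pc$degenerate)
  expect_lt(pc$wilcoxon_p, 0.01)
})

test_that("core-clock style comparisons detect planted contact differences", {
  truth <- shared_truth
  calls <- classify_circadian(shared_expr)
  dyn <- classify_dynamic(shared_pchic)
  circ_in <- intersect(calls$gene_id[calls$circadian],
                       unique(shared_pchic$bait_name))
  core <- circ_in[1:10]
  res <- coreclock_comparison(shared_pchic, calls, dyn, core_list = core,
                              n_iter = 100, seed = 12)
  expect_equal(nrow(res$core), 10)
  expect_equal(res$resample_size, 10)
  expect_true(is.finite(res$p_contacts))

  # single dynamic contact -> dynamic fraction 1
  one <- res$core$dynamic_fraction
  expect_true(all(one[!is.na(one)] >= 0 & one[!is.na(one)] <= 1))

  expect_error(coreclock_comparison(shared_pchic, calls, dyn,
                                    core_list = "absent_gene"), "core-clock")
})
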