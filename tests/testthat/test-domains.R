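test_that("insulation equals brute-force window means and is linear", {
  # constant field: interior scores all equal the constant
  cm <- contact_matrix(matrix(4, 12, 12), "chrT", 1)
  ins <- insulation_score(cm, 2)
  expect_true(all(is.na(ins$score[c(1, 2, 11, 12)])))
  expect_true(all(ins$score[3:10] == 4))

  # 12x12 toy vs brute force
  M <- random_symmetric(12, seed = 31)
  cm2 <- contact_matrix(M, "chrT", 1)
  ins2 <- insulation_score(cm2, 2)
  for (i in 3:10) {
    expect_equal(ins2$score[i], mean(M[(i - 2):(i - 1), (i + 1):(i + 2)]))
  }

  # linearity: score(cM) = c * score(M)
  ins3 <- insulation_score(contact_matrix(M * 5, "chrT", 1), 2)
  expect_equal(ins3$score, ins2$score * 5)

  expect_error(insulation_score(cm2, 12), "larger than chromosome")
})

test_that("block junctions are global insulation minima", {
  n <- 20
  M <- matrix(1, n, n)
  M[1:10, 1:10] <- 10
  M[11:20, 11:20] <- 10
  ins <- insulation_score(contact_matrix(M, "chrT", 1), 3)
  # bins 10 and 11 flank the junction symmetrically; the minimum is there
  expect_true(which.min(ins$score) %in% c(10, 11))
})

test_that("call_tads respects threshold, minima and the size filter", {
  # nothing below threshold -> no TADs
  M <- random_symmetric(30, seed = 4)
  ins <- insulation_score(contact_matrix(M, "chrT", 1e4), 2e4)
  expect_equal(nrow(call_tads(ins, threshold = min(ins$score, na.rm = TRUE))), 0)

  # two planted boundaries 1 Mb apart -> exactly one TAD of 1 Mb
  n <- 60
  bs <- 5e4
  B <- matrix(1, n, n)
  blocks <- list(1:15, 16:35, 36:60)  # boundaries at bins 16 and 36
  for (b in blocks) B[b, b] <- 8
  ins2 <- insulation_score(contact_matrix(B * 50, "chrT", bs), 2e5)
  tt <- call_tads(ins2, threshold = mean(ins2$score, na.rm = TRUE),
                  min_size_bp = 3e5, max_size_bp = 1.5e6)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$end - tt$start, 20 * bs)  # 1 Mb between the two boundaries
  # junction ties resolve to the leftmost flanking bin
  expect_true(abs(tt$start_bin - 16) <= 1)
  expect_true(abs(tt$end_bin - 36) <= 1)
})

test_that("planted boundaries are recovered within one bin", {
  truth <- shared_truth
  reps <- lapply(1:3, function(r) simulate_hic(truth, "chr1", 0, r, bin_size = 5e4))
  ins <- insulation_score(merge_replicates(reps), 2e5)
  tt <- call_tads(ins, threshold = mean(ins$score, na.rm = TRUE))
  called <- attr(tt, "boundaries")
  true_b <- truth$tads$start[truth$tads$chrom == "chr1"]
  true_bins <- true_b[true_b > 0] / 5e4 + 1
  w <- ins$window_bins
  eligible <- true_bins > w & true_bins <= length(ins$score) - w
  hits <- vapply(true_bins[eligible], function(b) any(abs(called - b) <= 1),
                 logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("TAD sharing uses a strict >80% overlap rule", {
  a <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  # identical sets: shared
  expect_equal(shared_tads(a, a)$n_shared, 1)
  # exactly 0.80 overlap: not shared
  b80 <- data.frame(chrom = "chr1", start = 2e5, end = 1e6)
  expect_equal(shared_tads(a, b80)$n_shared, 0)
  # 0.85 overlap: shared
  b85 <- data.frame(chrom = "chr1", start = 1.5e5, end = 1e6)
  res <- shared_tads(a, b85)
  expect_equal(res$n_shared, 1)
  expect_equal(res$pairs$overlap_frac, 0.85)
})

test_that("rescaled TAD metaplot matches the area-weighted rebinning oracle", {
  # O/E identically 1 -> all-ones grid
  ones <- matrix(1, 40, 40)
  tads <- data.frame(start_bin = 11, end_bin = 21)
  mp <- tad_metaplot(ones, tads, flank_bins = 5, n_core = 5)
  expect_true(all(abs(mp$grid - 1) < 1e-12))

  # single toy TAD equals the brute-force rebinning of its window
  set.seed(7)
  oe <- random_symmetric(40, seed = 7)
  b1 <- 11; b2 <- 21
  mp2 <- tad_metaplot(oe, data.frame(start_bin = b1, end_bin = b2),
                      flank_bins = 5, n_core = 5)
  len <- b2 - b1; flank <- len / 2
  lo <- round(b1 - flank); hi <- round(b2 - 1 + flank)
  sub <- oe[lo:hi, lo:hi]
  # piecewise oracle: flanks and core rescaled separately
  idx_f1 <- 1:(b1 - lo); idx_core <- (b1 - lo + 1):(b1 - lo + len)
  idx_f2 <- (b1 - lo + len + 1):nrow(sub)
  expect_equal(mp2$grid[6:10, 6:10], oracle_rebin_2d(sub[idx_core, idx_core], 5),
               ignore_attr = TRUE)
  expect_equal(mp2$grid[1:5, 1:5], oracle_rebin_2d(sub[idx_f1, idx_f1], 5),
               ignore_attr = TRUE)
  expect_equal(mp2$grid[11:15, 11:15], oracle_rebin_2d(sub[idx_f2, idx_f2], 5),
               ignore_attr = TRUE)
})

test_that("planted TADs enrich the metaplot core over the corners", {
  # isolated domains (keep 1 in 5) in a decay-only background, raw O/E:
  # flank corners then sit in un-enriched chromatin
  cfg <- sim_config(seed = 42, compartment_contrast = 0)
  truth <- simulate_truth(cfg)
  truth$tads <- truth$tads[seq(1, nrow(truth$tads), by = 5), ]
  grids <- lapply(truth$genome$chrom, function(ch) {
    reps <- lapply(1:3, function(r) simulate_hic(truth, ch, 0, r, bin_size = 5e4))
    oe <- oe_transform(merge_replicates(reps))
    td <- truth$tads[truth$tads$chrom == ch, ]
    tads <- data.frame(start_bin = td$start / 5e4 + 1, end_bin = td$end / 5e4 + 1)
    tad_metaplot(oe, tads)$grid
  })
  g <- Reduce(`+`, grids) / length(grids)
  core <- mean(g[6:10, 6:10])
  corners <- mean(c(g[1:3, 13:15], g[13:15, 1:3]))
  expect_gte(core / corners, 2)
})

test_that("random intervals on a null simulation give a flat metaplot", {
  null_truth <- simulate_truth(sim_config(seed = 19, compartment_contrast = 0,
                                          tad_enrichment = 1))
  set.seed(3)
  grids <- lapply(null_truth$genome$chrom, function(ch) {
    reps <- lapply(1:3, function(r) simulate_hic(null_truth, ch, 0, r,
                                                 bin_size = 5e4))
    oe <- oe_transform(balance_matrix(merge_replicates(reps)))
    starts <- sample(50:300, 150)
    tads <- data.frame(start_bin = starts,
                       end_bin = starts + sample(8:16, 150, replace = TRUE))
    tad_metaplot(oe, tads)$grid
  })
  g <- Reduce(`+`, grids) / length(grids)
  expect_true(all(abs(g - 1) < 0.1))
})

test_that("point metaplots aggregate fixed neighborhoods", {
  oe <- matrix(1, 15, 15)
  expect_true(all(abs(point_metaplot(oe, c(5, 9), 2)$grid - 1) < 1e-12))

  oe2 <- random_symmetric(15, seed = 12)
  mp <- point_metaplot(oe2, 8, window_bins = 1)
  expect_equal(mp$grid, oe2[7:9, 7:9], ignore_attr = TRUE)

  # points too close to the edge are skipped with a count
  mp2 <- point_metaplot(oe2, c(1, 8), window_bins = 3)
  expect_equal(mp2$n_skipped, 1)
  expect_equal(mp2$n_used, 1)
})

test_that("boundary-anchored metaplots show the insulation quadrant geometry", {
  truth <- shared_truth
  reps <- lapply(1:3, function(r) simulate_hic(truth, "chr1", 0, r, bin_size = 5e4))
  oe <- oe_transform(balance_matrix(merge_replicates(reps)))
  bpts <- truth$tads$start[truth$tads$chrom == "chr1"]
  bpts <- bpts[bpts > 0] / 5e4 + 1
  mp <- point_metaplot(oe, bpts, window_bins = 5)
  k <- 5
  ul <- mean(mp$grid[1:k, 1:k])          # upstream-upstream (inside TAD)
  lr <- mean(mp$grid[(k + 2):(2 * k + 1), (k + 2):(2 * k + 1)])
  off <- mean(mp$grid[1:k, (k + 2):(2 * k + 1)])  # across the boundary
  expect_gt(mean(c(ul, lr)), off)
})
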