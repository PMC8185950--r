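plaid_matrix <- function(n = 40, block = 20, within = 2, cross = 0.5) {
  lab <- rep(c(1, 2), each = block)[1:n]
  decay <- (1 + abs(outer(1:n, 1:n, "-")))^(-1)
  same <- outer(lab, lab, "==")
  M <- decay * ifelse(same, within, cross) * 1000
  contact_matrix((M + t(M)) / 2, "chrT", 1e5)
}

test_that("PC1 signs partition an ideal two-block plaid exactly", {
  cm <- plaid_matrix()
  act <- c(rep(1, 20), rep(0, 20))  # block 1 is the active one
  ev <- compute_pc1(balance_matrix(cm), act)
  expect_true(all(ev$pc1[1:20] > 0))
  expect_true(all(ev$pc1[21:40] < 0))
})

test_that("PC1 matches a power-iteration oracle on a 50-bin toy", {
  set.seed(99)
  n <- 50
  M <- random_symmetric(n, seed = 99) * 100
  b <- balance_matrix(M)
  act <- stats::rnorm(n)
  ev <- compute_pc1(b, act)
  # rebuild the correlation matrix exactly as the pipeline defines it
  oe <- oe_transform(b)
  oe[is.na(oe)] <- 0
  C <- stats::cor(oe)
  v <- oracle_power_iteration(C)
  cosine <- abs(sum(v * ev$pc1) / sqrt(sum(v^2) * sum(ev$pc1^2)))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("negating the activity track negates PC1 and scaling leaves it unchanged", {
  cm <- plaid_matrix()
  act <- c(rep(1, 20), rep(0, 20))
  ev <- compute_pc1(balance_matrix(cm), act)
  ev_neg <- compute_pc1(balance_matrix(cm), -act)
  expect_equal(ev_neg$pc1, -ev$pc1)

  scaled <- contact_matrix(cm$counts * 7.5, cm$chrom, cm$bin_size)
  ev_scaled <- compute_pc1(balance_matrix(scaled), act)
  expect_equal(ev_scaled$pc1, ev$pc1, tolerance = 1e-6)
})

test_that("compartment segmentation produces maximal same-sign runs", {
  mk_track <- function(v) {
    arr <- array(rep(v, 8), c(length(v), 4, 2))
    eigen_track(arr, matrix(rep(v, 4), ncol = 4), c(0, 6, 12, 18), bin_size = 10)
  }
  all_pos <- segment_compartments(mk_track(rep(0.5, 6)), 0)
  expect_equal(nrow(all_pos), 1)
  expect_equal(all_pos$label, "A")
  expect_equal(all_pos$n_bins, 6)

  runs <- segment_compartments(mk_track(c(1, 1, -1, -1, 1)), 0)
  expect_equal(runs$label, c("A", "B", "A"))
  expect_equal(runs$n_bins, c(2, 2, 1))

  masked <- segment_compartments(mk_track(c(1, 1, NA, 1, 1)), 0)
  expect_equal(masked$label, c("A", "A"))
  expect_equal(nrow(masked), 2)
})

test_that("detect_occ requires both significance and a sign switch", {
  # constant PC1 -> no OCC
  v <- rep(0.8, 10)
  arr <- array(rep(v, 12), c(10, 4, 3))
  tr <- eigen_track(arr, matrix(rep(v, 4), ncol = 4), c(0, 6, 12, 18))
  occ <- detect_occ(tr)
  expect_equal(sum(occ$bins$oscillatory), 0)

  # the worked 12-number example: significant, category AABA
  reps <- rbind(ZT0 = c(0.9, 1.0, 1.1), ZT6 = c(1.0, 1.1, 0.9),
                ZT12 = c(-1.0, -0.9, -1.1), ZT18 = c(1.1, 0.9, 1.0))
  arr2 <- array(NA_real_, c(1, 4, 3))
  arr2[1, , ] <- reps
  merged <- matrix(rowMeans(reps), nrow = 1)
  tr2 <- eigen_track(arr2, merged, c(0, 6, 12, 18))
  occ2 <- detect_occ(tr2, alpha = 0.05)
  oracle <- oracle_anova_f(as.vector(t(reps)), rep(1:4, each = 3))
  expect_equal(occ2$bins$anova_p, oracle$p, tolerance = 1e-12)
  expect_true(occ2$bins$oscillatory)
  expect_equal(occ2$bins$category, "AABA")
  expect_equal(occ2$regions$category, "AABA")

  # a large same-sign change is never an OCC
  reps_pos <- rbind(c(0.2, 0.25, 0.22), c(1.9, 2.0, 2.1),
                    c(0.2, 0.21, 0.19), c(2.0, 1.95, 2.05))
  arr3 <- array(NA_real_, c(1, 4, 3)); arr3[1, , ] <- reps_pos
  tr3 <- eigen_track(arr3, matrix(rowMeans(reps_pos), 1), c(0, 6, 12, 18))
  occ3 <- detect_occ(tr3)
  expect_lt(occ3$bins$q, 0.05)
  expect_false(occ3$bins$oscillatory)
})

test_that("category strings reproduce the merged sign sequence", {
  truth <- shared_truth
  mats <- lapply(c(0, 6, 12, 18), function(t) {
    lapply(1:3, function(r) simulate_hic(truth, "chr2", t, r))
  })
  act <- truth$activity[truth$activity$chrom == "chr2", ]
  tr <- eigen_track_from_matrices(mats, act)
  occ <- detect_occ(tr)
  osc <- which(occ$bins$oscillatory)
  expect_gt(length(osc), 0)
  for (b in osc[seq_len(min(10, length(osc)))]) {
    expected <- paste(ifelse(tr$merged[b, ] >= 0, "A", "B"), collapse = "")
    expect_equal(occ$bins$category[b], expected)
  }
  # both letters always present
  expect_true(all(grepl("A", occ$bins$category[osc]) &
                    grepl("B", occ$bins$category[osc])))
})

test_that("quantify_in_regions computes log2 RPM and group tests", {
  q <- quantify_in_regions(c(0, 1000), 1e6, pseudocount = 1)
  expect_equal(q$log2rpm[1], 0)
  expect_equal(q$rpm[2], 1000)
  expect_equal(q$log2rpm[2], log2(1001))
  expect_error(quantify_in_regions(1, 0), "> 0")

  # identical group signals -> maximal Mann-Whitney p
  x <- rep(c(5, 6, 7, 8), 2)
  g <- rep(c("A", "B"), each = 4)
  q2 <- quantify_in_regions(x, 1e6, g, test = "mannwhitney")
  expect_gt(q2$p, 0.99)

  q3 <- quantify_in_regions(c(1, 2, 3, 100, 110, 120), 1e6,
                            rep(c("A", "B"), each = 3), test = "anova+tukey")
  expect_lt(q3$p, 0.01)
  expect_s3_class(q3$tukey, "TukeyHSD")
})
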