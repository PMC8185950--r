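test_that("config validation rejects out-of-range fractions", {
  expect_error(sim_config(occ_fraction = 1.2), "occ_fraction")
  expect_error(sim_config(circadian_fraction = -0.1), "circadian_fraction")
  expect_error(sim_config(phase_probs = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("truth generation is deterministic and respects occ_fraction", {
  cfg <- sim_config(seed = 5)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$bins, t2$bins)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$interactions, t2$interactions)

  # no switching when occ_fraction = 0
  t0 <- simulate_truth(sim_config(seed = 5, occ_fraction = 0))
  lab <- as.matrix(t0$bins[, paste0("ZT", c(0, 6, 12, 18))])
  expect_true(all(apply(lab, 1, function(s) length(unique(s)) == 1)))

  # OCC bins switch; non-OCC bins are constant
  lab1 <- as.matrix(t1$bins[, paste0("ZT", c(0, 6, 12, 18))])
  n_states <- apply(lab1, 1, function(s) length(unique(s)))
  expect_true(all(n_states[t1$bins$occ] > 1))
  expect_true(all(n_states[!t1$bins$occ] == 1))
})

test_that("OCC bin count falls in the binomial 99% interval", {
  cfg <- sim_config(seed = 8, n_chrom = 1, chrom_length = 100e6,
                    occ_fraction = 0.2)
  truth <- simulate_truth(cfg)
  n <- nrow(truth$bins)
  expect_equal(n, 1000)
  k <- sum(truth$bins$occ)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.2)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("hi-c depth and null limits behave as the contact model says", {
  truth <- shared_truth
  m0 <- simulate_hic(truth, "chr2", 0, 1, depth = 0)
  expect_true(all(m0$counts == 0))
  expect_error(simulate_hic(truth, "chr2", 3, 1), "timepoint")

  # same seed -> identical matrix
  a <- simulate_hic(truth, "chr2", 6, 2)
  b <- simulate_hic(truth, "chr2", 6, 2)
  expect_identical(a$counts, b$counts)
})

test_that("null simulation has flat O/E and delta=1 doubles same-compartment contacts", {
  null_truth <- simulate_truth(sim_config(seed = 21, n_chrom = 1,
                                          compartment_contrast = 0,
                                          tad_enrichment = 1))
  m <- simulate_hic(null_truth, "chr1", 0, 1, depth = 200)
  oe <- oe_transform(balance_matrix(m))
  # mean O/E per diagonal is 1 by construction; check raw-count O/E against
  # the generative model on short-range diagonals with decent counts
  for (d in 1:5) {
    i <- seq_len(nrow(oe) - d)
    v <- oe[cbind(i, i + d)]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - 1), 3 * se + 1e-9)
  }

  truth <- simulate_truth(sim_config(seed = 22, n_chrom = 1,
                                     compartment_contrast = 1,
                                     tad_enrichment = 1))
  m1 <- simulate_hic(truth, "chr1", 0, 1, depth = 2000)
  lab <- truth$bins$ZT0[truth$bins$chrom == "chr1"]
  # same- vs cross-compartment mean raw counts at matched distance
  ratios <- sapply(5:15, function(d) {
    i <- seq_len(nrow(m1$counts) - d)
    same <- lab[i] == lab[i + d]
    mean(m1$counts[cbind(i, i + d)][same]) / mean(m1$counts[cbind(i, i + d)][!same])
  })
  expect_lt(abs(mean(ratios) - 2), 0.2)  # generative ratio 1 + delta
})

test_that("expression means follow the cosine model", {
  truth <- shared_truth
  expr <- simulate_expression(truth)
  expect_identical(expr, simulate_expression(truth))

  # zero amplitude -> flat expectations
  t_flat <- simulate_truth(sim_config(seed = 3, amplitude = 0))
  e_flat <- simulate_expression(t_flat, rna_replicates = 200, sigma = 0.2)
  cols0 <- grep("fpkm_ZT0_", names(e_flat))
  cols12 <- grep("fpkm_ZT12_", names(e_flat))
  m0 <- rowMeans(as.data.frame(e_flat)[, cols0])
  m12 <- rowMeans(as.data.frame(e_flat)[, cols12])
  se <- apply(as.data.frame(e_flat)[, cols0], 1, stats::sd) / sqrt(200)
  expect_gt(mean(abs(m0 - m12) < 4 * sqrt(2) * se), 0.95)

  # cosine extremes: phase 12, A=1 -> mean 2*baseline at ZT12, 0 at ZT0
  g12 <- which(truth$genes$circadian & truth$genes$phase == 12)[1]
  e <- simulate_expression(truth, rna_replicates = 500, sigma = 0.1)
  v12 <- as.numeric(as.data.frame(e)[g12, grep("fpkm_ZT12_", names(e))])
  v0 <- as.numeric(as.data.frame(e)[g12, grep("fpkm_ZT0_", names(e))])
  base <- truth$genes$baseline[g12]
  expect_lt(abs(mean(v12) - 2 * base) / (2 * base), 0.03)
  expect_true(all(v0 == 0))
})

test_that("capture counts honor the planted dynamics", {
  tab <- shared_pchic
  expect_identical(as.data.frame(tab), as.data.frame(simulate_pchic(shared_truth)))

  # no dynamic contacts when the fraction is zero
  t0 <- simulate_truth(sim_config(seed = 13, fraction_dynamic_contacts = 0))
  p0 <- simulate_pchic(t0)
  expect_false(any(p0$class == "dynamic"))

  # empirical peak/trough ratio approx dynamic_fold
  dyn <- which(tab$class == "dynamic")
  expect_gt(length(dyn), 50)
  peak_mean <- mean(vapply(dyn, function(i) {
    mean(counts_at(tab, tab$peak_zt[i])[i, ])
  }, numeric(1)))
  other_tps <- function(p) setdiff(c(0, 6, 12, 18), p)
  trough_mean <- mean(vapply(dyn, function(i) {
    mean(vapply(other_tps(tab$peak_zt[i]),
                function(t) mean(counts_at(tab, t)[i, ]), numeric(1)))
  }, numeric(1)))
  expect_lt(abs(peak_mean / trough_mean - 4) / 4, 0.25)
})

test_that("planted-truth accessors expose every scored label", {
  truth <- shared_truth
  expect_true(all(c("occ") %in% names(truth$bins)))
  expect_true(all(c("circadian", "phase") %in% names(truth$genes)))
  expect_true(all(c("class", "peak_zt") %in% names(truth$interactions)))
  expect_true(all(truth$interactions$class[!is.na(truth$interactions$peak_zt)] == "dynamic"))
  expect_true(nrow(truth$tads) > 0)
})
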