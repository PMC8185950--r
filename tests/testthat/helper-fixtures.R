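# Shared fixtures, built once per test run.

tiny_genome <- genome_def(c("chr1", "chr2"), c(1e6, 5e5))

# 4-kb uniform fragments on the tiny genome
tiny_fragmap <- restriction_map(tiny_genome, list(
  chr1 = seq(4000, 1e6 - 1, by = 4000),
  chr2 = seq(4000, 5e5 - 1, by = 4000)
))

# One default-scale synthetic world reused across test files.
shared_cfg <- sim_config(seed = 42)
shared_truth <- simulate_truth(shared_cfg)
shared_expr <- simulate_expression(shared_truth)
shared_pchic <- simulate_pchic(shared_truth)

# Small symmetric random positive matrix.
random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0.5, 2), n, n)
  (A + t(A)) / 2
}

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
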