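test_that("genome_def enforces unique names and positive lengths", {
  g <- genome_def(c("chr1", "chr2"), c(100, 200))
  expect_s3_class(g, "genome_def")
  expect_error(genome_def(c("chr1", "chr1"), c(100, 200)), "unique")
  expect_error(genome_def("chr1", 0), "> 0")
})

test_that("read_bed parses minimal BED3 and validates coordinates", {
  f <- write_tmp("chr1\t0\t100")
  fs <- read_bed(f, tiny_genome)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$start, 0)
  expect_equal(fs$end, 100)

  bad <- write_tmp("chr1\t500\t100")
  expect_error(read_bed(bad, tiny_genome), "end must be > start")

  beyond <- write_tmp("chr1\t0\t2000000")
  expect_error(read_bed(beyond, tiny_genome), "beyond chromosome")

  malformed <- write_tmp(c("chr1\t0\t100", "chr1\t50"))
  expect_error(read_bed(malformed, tiny_genome), "line 2")
})

test_that("BED round-trips through write_bed, including the phase column", {
  df <- feature_set <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 5000, 100), end = c(100, 9000, 400),
    name = c("a", "b", "c"), strand = c("+", "-", "."),
    phase_hr = c(0, 13, 22))
  f <- tempfile()
  write_bed(df, f)
  back <- read_bed(f, tiny_genome)
  expect_equal(back$chrom, df$chrom)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$name, df$name)
  expect_equal(back$phase_hr, df$phase_hr)
})

test_that("bedGraph reader validates and round-trips signal", {
  tr <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                   value = c(1.5, -2.25))
  f <- tempfile()
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, tiny_genome)
  expect_equal(back$value, tr$value)
  expect_equal(attr(back, "units"), "raw")
})

test_that("restriction map tiles chromosomes with increasing IDs", {
  expect_equal(tiny_fragmap$start[1], 0)
  for (ch in tiny_genome$chrom) {
    sub <- tiny_fragmap[tiny_fragmap$chrom == ch, ]
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])  # contiguous
    expect_equal(sub$end[nrow(sub)], chrom_length(tiny_genome, ch))
    expect_true(all(diff(sub$frag_id) == 1))
  }
  expect_equal(locate_fragment(tiny_fragmap, "chr1", 0), 1L)
  expect_equal(locate_fragment(tiny_fragmap, "chr1", 4000), 2L)
  expect_error(locate_fragment(tiny_fragmap, "chr1", 2e6), "outside")
})

test_that("ibed distances are fragment-midpoint differences", {
  f <- write_tmp(c(
    paste("bait_chr", "bait_start", "bait_end", "bait_name", "otherEnd_chr",
          "otherEnd_start", "otherEnd_end", "otherEnd_name", "N_reads", "score",
          sep = "\t"),
    "chr1\t0\t4000\tgeneA\tchr1\t100000\t104000\t.\t12\t6.2"))
  tab <- read_interactions(f, "ibed", fragmap = tiny_fragmap)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$distance_bp, 100000)  # midpoints 2000 and 102000
  expect_equal(tab$score, 6.2)
})

test_that("trans records keep a null distance and empty files parse", {
  f <- write_tmp(c(
    paste("bait_chr", "bait_start", "bait_end", "bait_name", "otherEnd_chr",
          "otherEnd_start", "otherEnd_end", "otherEnd_name", "N_reads", "score",
          sep = "\t"),
    "chr1\t0\t4000\tgeneA\tchr2\t8000\t12000\t.\t3\t1.0"))
  tab <- read_interactions(f, "ibed", fragmap = tiny_fragmap)
  expect_true(is.na(tab$distance_bp))
  expect_equal(nrow(tab), 1)

  empty <- write_tmp(paste("bait_chr", "bait_start", "bait_end", "bait_name",
                           "otherEnd_chr", "otherEnd_start", "otherEnd_end",
                           "otherEnd_name", "N_reads", "score", sep = "\t"))
  tab0 <- read_interactions(empty, "ibed", fragmap = tiny_fragmap)
  expect_equal(nrow(tab0), 0)
})

test_that("negative replicate counts are rejected", {
  df <- data.frame(bait_frag = 1L, other_frag = 30L,
                   bait_chrom = "chr1", bait_start = 0, bait_end = 4000,
                   other_chrom = "chr1", other_start = 116000, other_end = 120000,
                   count_ZT0_R1 = -1)
  expect_error(interaction_table(df), "negative")
})

test_that("canonical TSV and longrange dialects round-trip", {
  tab <- shared_pchic
  f <- tempfile()
  write_interactions(tab, f, "tsv_counts")
  back <- read_interactions(f, "tsv_counts")
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$distance_bp, tab$distance_bp)
  expect_equal(counts_at(back, 12), counts_at(tab, 12), ignore_attr = TRUE)

  # longrange keeps (bait, other, score) triples
  sub <- interaction_table(as.data.frame(tab)[1:20, ], baits = attr(tab, "baits"))
  f2 <- tempfile()
  write_interactions(sub, f2, "longrange")
  back2 <- read_interactions(f2, "longrange", fragmap = shared_truth$fragmap)
  expect_equal(back2$bait_frag, sub$bait_frag)
  expect_equal(back2$other_frag, sub$other_frag)
  expect_equal(back2$score, sub$score, tolerance = 1e-6)
})

test_that("COO matrix writer and reader invert each other", {
  m <- simulate_hic(shared_truth, "chr2", 6, 1)
  f <- tempfile(); fb <- tempfile()
  write_coo_matrix(m, f, fb)
  back <- read_coo_matrix(f, fb, timepoint = 6, replicate = 1)
  expect_equal(back$counts, m$counts)
  expect_equal(back$bin_size, m$bin_size)
  expect_equal(back$chrom, "chr2")
})
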