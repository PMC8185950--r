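# rhythmhic

Temporally resolved 3D-genome analysis across the circadian cycle.

Peripheral clocks such as the liver's rewire transcription over the day.
`rhythmhic` is for genomicists asking how chromosome conformation tracks that
rhythm when Hi-C, promoter capture Hi-C (CHi-C) and RNA-seq are sampled at
several Zeitgeber times (ZT0/6/12/18, hours after lights-on). It implements,
as a tested R pipeline:

* **Oscillatory chromatin compartments (OCCs).** Per sample, the balanced
  contact matrix is O/E-transformed, correlated, and its leading eigenvector
  (PC1) oriented against an activity track; positive PC1 = A compartment. A
  bin is oscillatory iff a per-bin one-way ANOVA of replicate PC1 across
  timepoints is significant after BH adjustment *and* the merged PC1 sign
  switches between timepoints. OCC regions carry 4-letter categories such as
  `AABA` (A at ZT0/6/18, B at ZT12).
* **TAD calling and invariance.** Insulation score
  `s(i) = mean C[i-w..i-1, i+1..i+w]`, boundaries at strict local minima
  below a threshold, TADs between boundaries, cross-timepoint sharing at the
  strict >80% overlap rule, and rescaled-TAD / point metaplots.
* **Circadian expression.** Per-gene one-way ANOVA on log2(FPKM+1) across
  timepoints, BH-adjusted, circadian iff q < 0.01; phase = timepoint of
  maximal mean FPKM; diurnal = phase in {ZT0, ZT6}.
* **cTAD statistics.** Genes map to TADs by TSS; TADs with circadian genes
  are cTADs; the chance that all k circadian genes in a TAD share a phase
  under independence is `sum_i p_i^k`, tested by chi-square; cTAD-OCC
  overlap by resampling non-cTAD sets.
* **Dynamic vs stable promoter contacts.** Per interaction, a
  negative-binomial likelihood-ratio test (timepoint factor vs intercept,
  library-size offsets, moment dispersion shrunk toward the common value),
  BH within near (<=150 kb) and far distance regimes; dynamic iff q < FDR
  and |log2FC| >= 1.
* **Matched-permutation enrichment.** Other-end feature overlaps against
  nulls that re-place every observed (fragment length, bait distance) pair
  at random baits — preserving that joint distribution exactly — with a
  t-test against the observed count; plus oscillatory-eRNA contact
  enrichment, promoter/eRNA phase coherence, and core-clock contrasts.
* **Promoter-promoter networks.** igraph graphs of significant bait-bait
  contacts, circadian-edge z-scores against resampled non-circadian node
  sets, and edge-support comparisons.
* **A seeded synthetic generator** (`sim_config()`, `simulate_truth()`,
  `simulate_hic()`, `simulate_expression()`, `simulate_pchic()`) that plants
  every structure above — switching plaid compartments, invariant TAD
  blocks, cosine expression, phase-locked contacts, assortative promoter
  wiring — so the whole pipeline is testable offline against known truth.

Standard formats are read and written directly: BED3/6 (+phase column),
bedGraph, ibed, washU longrange, COO matrix TSV with a bins sidecar.

## Worked example

```r
library(rhythmhic)

cfg   <- sim_config(seed = 1)      # 2 x 20 Mb genome, 4 ZTs, 3 Hi-C reps
truth <- simulate_truth(cfg)
truth
#> architecture_truth: 2 chrom, 400 bins ( 74 OCC ), 63 TADs, 300 genes
#> ( 90 circadian ), 829 planted contacts

report <- run_all(list(seed = 1))  # simulate -> compartments -> ... -> networks
report
#> run_report with sections: compartments, tads, expression, ctads, interactome, networks
#>   compartments: 18.2% of bins oscillatory (sens 0.99, FDR 0.00)
#>   tads: 288 called, boundary recovery 1.00
#>   expression: 90 circadian genes (sens 1.00)
#>   interactome: 121 dynamic / 589 stable
#>   networks: 290 nodes, 474 edges, circadian z 47.63
```

Reading the numbers: 74 of 400 bins were planted as compartment-switching
and the OCC caller recovers them with 0.99 sensitivity at zero false
discoveries, so 18.2% of bins are called oscillatory; all planted TAD
boundaries are recovered within one 50-kb bin; all 90 planted circadian
genes are detected at q < 0.01; the dynamic-contact classifier separates
phase-locked from constant contacts; and circadian promoters form far more
edges among themselves than resampled non-circadian promoter sets
(z = 47.6). `write_run_report(report, "report.json")` serializes the run;
the JSON is byte-identical across runs with the same seed.

Single stages work standalone, e.g.

```r
b   <- balance_matrix(simulate_hic(truth, "chr1", 0, 1))
ev  <- compute_pc1(b, truth$activity[truth$activity$chrom == "chr1", ])
occ <- detect_occ(eigen_track_from_matrices(mats, activity), alpha = 0.05)
v4c <- virtual_4c(simulate_pchic(truth), bait = truth$genes$frag_id[1])
```

A thin CLI over the same functions lives at `inst/scripts/rhythmhic.R`
(`run` and `simulate` subcommands).

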