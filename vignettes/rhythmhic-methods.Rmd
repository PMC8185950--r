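---
title: "Circadian 3D-genome analysis with rhythmhic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian 3D-genome analysis with rhythmhic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmhic)
```

# The scientific problem

Mammalian tissues such as liver rewire transcription around the clock.
`rhythmhic` analyses chromosome-conformation data sampled at several
Zeitgeber times (ZT; hours after lights-on) to ask how the 3D genome tracks
that rhythm at three scales:

* **A/B compartments** — the megabase-scale partition of chromatin into an
  active (A) and inactive (B) interaction compartment, read from the sign of
  the leading eigenvector (PC1) of the Hi-C correlation matrix. Regions whose
  A/B label switches between timepoints are *oscillatory chromatin
  compartments* (OCCs), labelled by a 4-letter category string over
  ZT0/6/12/18 (e.g. `AABA` = A at ZT0, ZT6 and ZT18, B at ZT12).
* **TADs** — topologically associating domains called from insulation-score
  minima; these are expected to be time-invariant, but *circadian TADs*
  (cTADs, those containing at least one circadian gene) concentrate genes
  with shared transcriptional phase and overlap OCCs.
* **Promoter contacts** — capture Hi-C interactions between promoter baits
  and other-end fragments, classified as *stable* or *dynamic* across the
  day, tested for regulatory-feature enrichment against matched permutation
  nulls, and assembled into promoter-promoter networks.

Every stage can run on a seeded synthetic data set in which all of these
structures are planted, so the complete pipeline is testable without any
external download.

# Models and procedures

## Compartments and OCC detection

Per chromosome and sample, the contact matrix is balanced to equal row sums
by a diagonal scaling (iterative correction). The balanced matrix goes
through an observed/expected transform — `expected(d)` is the mean of
unmasked entries at diagonal offset `d` — then a Pearson correlation matrix
over unmasked bins, whose leading eigenvector is PC1. The sign is oriented
so PC1 correlates positively with an activity covariate (any
active-chromatin coverage track on the same bins; the synthetic runs use the
generator's gene-openness track). Positive PC1 = A.

OCC calling uses two conditions per bin, both required:

1. a one-way ANOVA of replicate PC1 values grouped by timepoint, adjusted
   across bins (Benjamini-Hochberg, `alpha = 0.05` by default), flags a
   consistent temporal change, and
2. the merged-replicate PC1 sign differs between at least one timepoint
   pair — a large same-sign excursion is not a compartment switch.

The omnibus threshold and the adjustment are defaults of this package, made
explicit because a per-bin rule is needed to call regions. Bins with PC1
exactly zero count as A and carry a tie flag. Adjacent oscillatory bins with
the same category merge into OCC regions.

## TAD calling

The insulation score of bin $i$ with window $w$ bins is the mean contact
count in the off-diagonal square $[i-w, i) \times (i, i+w]$; it is undefined
within $w$ bins of a chromosome end. Boundaries are strict local minima of
the raw score within $\pm w$ bins that also lie below a score threshold;
tied plateaus resolve to their leftmost bin so calls are reproducible. TADs
are the intervals between consecutive boundaries, filtered to 150 kb - 1.5
Mb by default, never across masked gaps. Two TAD sets are compared with the
conventional sharing rule: a TAD is shared if a partner covers strictly more
than 80% of its length.

On real data the threshold is in raw-score units tied to sequencing depth
(published analyses used 140 at 50-kb resolution and 76 at 25-kb with their
depth); the synthetic pipeline uses the chromosome-mean score as the
threshold, and recovery is scored against planted boundaries rather than
against any fixed constant. Calling at 25-kb bins yields sub-TAD-scale
domains through the same algorithm — a parameter choice, not a separate
caller.

Rescaled-TAD metaplots map each TAD (plus flanks of half its length per
side) by area-weighted rebinning onto a fixed grid of five central bins plus
five per flank, taking the cell-wise median across TADs; point metaplots
aggregate fixed $(2k+1)^2$ neighborhoods. Note that on *balanced* matrices
the bins outside domains acquire biases below one, which lifts the
off-domain flank baseline of a metaplot; the planted-truth contrast checks
therefore use raw observed/expected input.

## Circadian expression

Genes are classified from a replicated FPKM table by a per-gene one-way
ANOVA on `log2(FPKM + 1)` across the four timepoints, BH-adjusted across
genes, circadian iff `q < 0.01`. This preserves the published classification
rule — differential between at least one pair of timepoints at q < 0.01 —
while replacing the original transcript-assembly-based differential engine
with a direct test on the expression table, which is this package's input
boundary. Phase is the timepoint of highest mean FPKM (ties to the smallest
ZT, flagged); diurnal means phase in {ZT0, ZT6}, nocturnal otherwise.
Harmonic-regression rhythm detection is deliberately out of scope: the rule
implemented is the pairwise-difference rule.

## cTAD statistics

Genes map to TADs by TSS (half-open `[start, end)`), matching the
promoter-centric framing; whole-gene-body assignment is not used. For TADs
with exactly $k$ circadian genes, the probability that all $k$ share a phase
under independent assignment with phase frequencies $p$ is $\sum_i p_i^k$,
compared to the observed same-phase proportion with a 1-df chi-square.
"Same phase" for $k > 2$ means all $k$ identical. Phase frequencies default
to the full circadian-gene universe (TAD-resident-only frequencies are a
caller choice, passed through the `phase_freqs` argument). cTAD-OCC overlap
is tested by resampling equal-sized non-cTAD sets (z-score and one-sided
empirical p `(1 + #{null >= obs})/(n_iter + 1)`); a per-chromosome Wilcoxon
is emitted alongside for fidelity with rank-based reporting, since the
original pairing structure of that test is not specified.

## Dynamic vs stable contacts

Replicate capture counts per interaction are modelled as negative binomial
with library-size offsets. The per-interaction dispersion is a
method-of-moments estimate shrunk 50/50 toward the trimmed-mean common
dispersion (trim 0.2, floor 1e-4) — a deliberately simple, fully
reproducible stand-in for heavier empirical-Bayes machinery. The test is a
likelihood-ratio test of a timepoint-factor model against an intercept-only
null (3 df). To absorb the distance bias of capture counts, records split
into near (cis $\le$ 150 kb; the boundary itself is near) and far (greater,
plus trans) regimes, each BH-adjusted separately, then recombined. Dynamic
iff `q < 0.05` and |log2 fold change| $\ge$ 1; the fold change is computed
on the counts-per-million scale so that uniform depth rescaling cannot
change it. The FDR and fold-change cutoffs are package defaults (the
published analysis filtered on both without printing values) and are
configurable.

## Permutation enrichment at interacting regions

The observed statistic is the number of unique other-end fragments
overlapping a feature set. Each null iteration re-places every observed
(other-end length $L$, bait distance $D$) pair as an interval of length $L$
at signed distance $\pm D$ (fair coin) from a bait drawn uniformly from the
bait universe, redrawing up to 100 times when the placement leaves the
chromosome (then skipping with a count). The placement preserves the
empirical joint $(L, D)$ distribution exactly, which is the point of the
design: enrichment is measured against fragments that look like the
observed ones and sit at the observed distances from promoters. Significance
is a two-sided one-sample t-test of the per-iteration expected counts
against the observed value; the enrichment ratio is observed over expected
mean. Unique other-ends are counted once even when they serve several baits
(record-level counting is available through the eRNA variant, which counts
interactions).

## Phase coherence and core-clock contrasts

Contacts are counted as significant at a timepoint when their score at that
timepoint reaches 5, the conventional capture-interaction cutoff
(configurable). Peak-contact timepoints compare to transcriptional
acrophases as circular offsets on the 4-ZT grid (0, 6 or 12 h); the cohort
chi-square tests the observed offset distribution against the one implied by
independence of the two marginals. Contacted-element phases are compared
between diurnal- and nocturnal-anchored groups with a Wilcoxon rank-sum test
on hours from lights-on; hourly eRNA phases bin into eight 3-hour groups
(`floor(h/3)`). Fully circular statistics are out of scope — the
diurnal/nocturnal split makes the within-day ordering well defined.

Core-clock promoters (Npas2, Clock, Arntl, Cry1, Cry2, Per1, Per2, Rorc,
Nr1d1, Nr1d2) are contrasted with resamples of equally many circadian
non-core genes on two metrics: unique significant interactions (union over
ZTs) and dynamic-contact fraction, each with a Mann-Whitney test against the
pooled null. The resample size defaults to the number of core genes present
in the data; a fixed size (e.g. 11) can be forced with `resample_size`.

## Networks

Promoter-promoter graphs take baits with at least one significant bait-bait
interaction as nodes and deduplicated unordered bait pairs as edges, with
summed supporting read counts as the edge attribute; unnamed baits get locus
labels `uce_<chrom>_<start>`. Inter- and intra-chromosomal edges are both
retained, and components under 4 nodes can be dropped for display. The
circadian-edge z-score resamples *nodes* (equal-sized sets of non-circadian
promoters), matching the published null of random non-circadian promoter
sets; degree-preserving nulls are deliberately not the default. Candidate
pools are sorted before sampling so results are invariant to vertex order.

# The synthetic generator

`sim_config()` fixes the study design: 4 timepoints (ZT0/6/12/18), 3 Hi-C
replicates, 4 RNA replicates, 100-kb compartment bins, 50-kb TAD bins,
HindIII-scale fragments (mean 4 kb, gamma-distributed). Contact means follow

$$\mu_{ij} \propto (1+|i-j|)^{-\alpha}\,(1 + \delta\,[\text{same
compartment at } t])\,(\tau\,[\text{same TAD}])$$

with Poisson counts for Hi-C (eigen and insulation statistics need no
overdispersion) and negative-binomial counts (dispersion $\varphi$) for
capture interactions, which feed a dispersion-aware test. Defaults:
$\delta = 1$, $\tau = 3$, $\alpha = 1$, $\varphi = 0.1$, depth 20, 20% of
bins oscillatory, 30% of genes circadian with uniform phases and relative
amplitude 1, lognormal expression noise $\sigma = 0.2$, capture mean 30 per
replicate, 30% dynamic contacts with fold 4 at their peak. The study gives
no effect-size estimates for these contrasts, so they are free parameters
chosen once at values a liver Hi-C experiment of this depth could plausibly
resolve; acceptance measures recovery at these settings, not agreement with
any published effect size.

Planted structure: OCC bins switch as independent Bernoulli draws with a
random mixed category; TAD blocks are time-invariant (300 kb - 1 Mb);
circadian genes sit preferentially in bins that are A at their phase;
oscillatory enhancers carry hourly phases and are wired assortatively
(within 3 h) to circadian promoters; circadian promoters are also wired
preferentially to same-diel circadian promoters with boosted read support
(x1.5). Dynamic contacts peak at their gene's phase and carry significant
scores only there; stable contacts are significant at every timepoint.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: no trans-contact structure beyond uniform
background, no ligation-junction or fragment-level read noise, no
copy-number or mappability artifacts, hard-switching compartments rather
than graded PC1 drift, independent per-bin OCC draws rather than spatially
correlated switching blocks, and noise-free significance scores (real
interaction callers misclassify near the threshold). Recovery rates on this
generator are upper bounds on real-data performance.

The default toy genome is 2 chromosomes x 20 Mb (400 compartment bins, 800
TAD bins, ~300 genes, ~1100 interaction records); the OCC acceptance run
uses one 100-Mb chromosome (1000 bins). These sizes make every property
measurable with comfortable statistical margins while the full suite and
the acceptance script run in a few minutes on one CPU.

# Numerical choices and degenerate inputs

* Balancing masks all-zero bins and reports a residual; non-convergence is
  an error naming the achieved residual, never a silent pass-through.
  Re-balancing a balanced matrix moves biases by less than the tolerance.
* O/E diagonals with zero expected value stay masked; an all-masked matrix
  is an error.
* PC1 requires at least 10 usable bins and errors on zero-variance input;
  each replicate is oriented against the activity covariate independently
  (whether the published replicates were oriented jointly is unstated).
* All-zero count rows classify as stable with p = 1; all-tied Wilcoxon
  comparisons return p = 1 rather than NaN.
* Resampling tests flag degeneracy (zero-variance nulls, empty feature
  sets, saturated node sets) instead of fabricating a p-value.
* Every stochastic step takes a seed; the pipeline derives per-stage seeds
  from one root seed, so stage-level reruns and the end-to-end JSON report
  are byte-reproducible.

# Known limitations

The insulation threshold on real data must be chosen per depth and
resolution; no automatic selection is provided. The ANOVA on PC1 assumes
roughly equal replicate variance per timepoint. The NB dispersion shrinkage
is cruder than empirical-Bayes tag-wise shrinkage and will be conservative
for very low-count interactions. Circular statistics are reduced to the
4-ZT grid and a diurnal/nocturnal split. The OCC caller labels bins, not
change-points, so an OCC region boundary is only bin-resolution accurate.
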