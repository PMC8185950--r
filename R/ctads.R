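#' Assign genes to TADs by TSS
#'
#' A gene belongs to a TAD iff its TSS lies in `[start, end)`; genes outside
#' all TADs stay unassigned.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param tads data.frame with `chrom`, `start`, `end`.
#' @return List with `genes` (input plus `tad` index into `tads`, `NA` when
#'   unassigned), `per_tad` (list of gene-id vectors per TAD) and
#'   `mean_genes_per_tad`.
#' @export
assign_genes_to_tads <- function(genes, tads) {
  tad <- rep(NA_integer_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ti <- which(tads$chrom == ch)
    if (!length(ti)) next
    sub <- tads[ti, , drop = FALSE]
    ord <- order(sub$start)
    sub <- sub[ord, ]; ti <- ti[ord]
    hit <- findInterval(genes$tss[gi], sub$start)
    ok <- hit >= 1 & genes$tss[gi] < sub$end[pmax(hit, 1L)]
    tad[gi[ok]] <- ti[hit[ok]]
  }
  per_tad <- lapply(seq_len(nrow(tads)), function(i) genes$gene_id[which(tad == i)])
  counts <- lengths(per_tad)
  genes$tad <- tad
  list(genes = genes, per_tad = per_tad,
       n_genes_per_tad = counts,
       mean_genes_per_tad = mean(counts))
}

#' Classify circadian TADs (cTADs)
#'
#' A TAD containing at least one circadian gene is a cTAD; each is
#' annotated with its circadian genes, their phases and whether all phases
#' agree.
#'
#' @param tads data.frame of TADs.
#' @param calls a `circadian_calls` data.frame with `chrom` and `tss`.
#' @return List with `tads` (input plus `n_genes`, `n_circadian`,
#'   `all_same_phase`, `is_ctad`), `phases` (list of circadian phase vectors
#'   per TAD), `ctad_idx`.
#' @export
classify_ctads <- function(tads, calls) {
  asg <- assign_genes_to_tads(calls, tads)
  tad_of <- asg$genes$tad
  n_genes <- tabulate(tad_of[!is.na(tad_of)], nbins = nrow(tads))
  circ <- asg$genes$circadian
  phases <- lapply(seq_len(nrow(tads)), function(i) {
    asg$genes$phase[which(tad_of == i & circ)]
  })
  n_circ <- lengths(phases)
  tads$n_genes <- n_genes
  tads$n_circadian <- n_circ
  tads$all_same_phase <- vapply(phases, function(p) {
    if (length(p) == 0) NA else length(unique(p)) == 1
  }, logical(1))
  tads$is_ctad <- n_circ >= 1
  list(tads = tads, phases = phases, ctad_idx = which(n_circ >= 1))
}

#' Expected same-phase probability and phase-sharing test
#'
#' For TADs holding exactly `k` circadian genes, the chance that all `k`
#' share a phase under independent assignment with phase frequencies `p` is
#' `sum_i p_i^k`. The observed same-phase proportion among those TADs is
#' compared to that expectation with a 1-df chi-square on (same, not-same)
#' counts.
#'
#' @param ctads result of [classify_ctads()].
#' @param phase_freqs phase frequencies over the circadian-gene universe
#'   (named by ZT, summing to 1).
#' @param ks values of `k` to evaluate (defaults to every k >= 2 present).
#' @return data.frame per `k`: `k`, `n_tads`, `observed_same`,
#'   `observed_prop`, `expected_prop`, `chi2`, `p`, `low_count` flag (set
#'   when an expected cell count is below 5).
#' @export
phase_sharing <- function(ctads, phase_freqs, ks = NULL) {
  if (abs(sum(phase_freqs) - 1) > 1e-8) stop("phase_freqs must sum to 1")
  n_circ <- ctads$tads$n_circadian
  if (is.null(ks)) ks <- sort(unique(n_circ[n_circ >= 2]))
  out <- lapply(ks, function(k) {
    idx <- which(n_circ == k)
    expected <- sum(phase_freqs^k)
    n <- length(idx)
    same <- sum(vapply(ctads$phases[idx], function(p) length(unique(p)) == 1, logical(1)))
    chi2 <- NA_real_; p <- NA_real_
    if (n > 0) {
      exp_counts <- n * c(expected, 1 - expected)
      chi2 <- sum((c(same, n - same) - exp_counts)^2 / exp_counts)
      p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    }
    data.frame(k = k, n_tads = n, observed_same = same,
               observed_prop = if (n > 0) same / n else NA_real_,
               expected_prop = expected, chi2 = chi2, p = p,
               low_count = n > 0 && any(n * c(expected, 1 - expected) < 5))
  })
  do.call(rbind, out)
}

#' Phase frequencies of the circadian gene universe
#' @param calls a `circadian_calls` data.frame.
#' @return Named numeric vector of phase frequencies summing to 1.
#' @export
phase_frequencies <- function(calls) {
  ph <- calls$phase[calls$circadian]
  tab <- table(ph)
  freq <- as.numeric(tab) / sum(tab)
  names(freq) <- names(tab)
  freq
}

#' Resampling test for cTAD - OCC overlap enrichment
#'
#' Counts cTADs overlapping at least one oscillatory-compartment bin and
#' compares against draws of equally many non-cTADs: a z-score against the
#' null distribution, a one-sided empirical p-value
#' `(1 + #{null >= obs}) / (n_iter + 1)`, and (for fidelity with
#' rank-based reporting) a Wilcoxon test between the observed
#' per-chromosome overlap counts and the null per-chromosome means.
#'
#' @param ctads data.frame of cTADs (`chrom`, `start`, `end`).
#' @param non_ctads data.frame of non-cTADs; must have at least as many
#'   rows as `ctads`.
#' @param occs data.frame of OCC regions (`chrom`, `start`, `end`).
#' @param n_iter resampling iterations (>= 100 recommended).
#' @param seed RNG seed.
#' @return List with `observed`, `null_draws`, `z`, `empirical_p`,
#'   `wilcoxon_p`, `degenerate` flag.
#' @export
occ_overlap_test <- function(ctads, non_ctads, occs, n_iter = 1000, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (nrow(non_ctads) < nrow(ctads)) stop("need |non_ctads| >= |ctads|")
  overlaps_occ <- function(tads) count_feature_overlaps(tads, occs) > 0
  obs_flags <- overlaps_occ(ctads)
  observed <- sum(obs_flags)
  non_flags <- overlaps_occ(non_ctads)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      sum(non_flags[sample(length(non_flags), nrow(ctads))])
    }, numeric(1))
  })
  degenerate <- nrow(occs) == 0 || stats::sd(nulls) == 0
  z <- if (!degenerate) (observed - mean(nulls)) / stats::sd(nulls) else NA_real_
  emp_p <- (1 + sum(nulls >= observed)) / (n_iter + 1)
  ## per-chromosome fidelity Wilcoxon
  wilcox_p <- NA_real_
  chroms <- unique(c(ctads$chrom, non_ctads$chrom))
  if (!degenerate && length(chroms) > 1) {
    obs_per_chrom <- vapply(chroms, function(ch) sum(obs_flags[ctads$chrom == ch]), numeric(1))
    null_per_chrom <- vapply(chroms, function(ch) {
      mean(non_flags[non_ctads$chrom == ch]) * sum(ctads$chrom == ch)
    }, numeric(1))
    wilcox_p <- tryCatch(
      stats::wilcox.test(obs_per_chrom, null_per_chrom, paired = TRUE,
                         exact = FALSE)$p.value,
      error = function(e) NA_real_)
  }
  list(observed = observed, null_draws = nulls, z = z, empirical_p = emp_p,
       wilcoxon_p = wilcox_p, degenerate = degenerate, n_iter = n_iter)
}
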