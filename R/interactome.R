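#' Classify interactions as dynamic or stable across timepoints
#'
#' Negative-binomial likelihood-ratio test per interaction: replicate
#' counts, normalized by library size through an offset, are fit with a
#' timepoint-factor model against an intercept-only null (3 df for 4
#' timepoints). The per-interaction dispersion is a method-of-moments
#' estimate shrunk 50/50 toward the trimmed-mean common dispersion across
#' interactions. To absorb the distance bias in capture counts, records are
#' split into near (cis distance <= `distance_cut`; the boundary itself is
#' near) and far (greater distances and trans) regimes, each BH-adjusted
#' separately, then recombined. Dynamic iff q < `fdr` and
#' |log2 fold change (max vs min normalized timepoint mean)| >= `min_lfc`.
#'
#' @param table an [interaction_table()] with >= 2 replicates per timepoint.
#' @param distance_cut near/far regime boundary in bp.
#' @param fdr q-value cutoff.
#' @param min_lfc minimum |log2 fold change|.
#' @param bait_filter optional vector of bait fragment IDs to test (e.g.
#'   baits overlapping circadian genes).
#' @param dispersion optional fixed dispersion (phi); overrides estimation.
#' @return A `dynamic_calls` data.frame aligned to the tested records:
#'   `row` (row index into `table`), `regime`, `dispersion`, `lrt_stat`,
#'   `p`, `q`, `log2fc`, `class` (`"dynamic"`/`"stable"`).
#' @export
classify_dynamic <- function(table, distance_cut = 150000, fdr = 0.05,
                             min_lfc = 1.0, bait_filter = NULL,
                             dispersion = NULL) {
  df <- as.data.frame(table)
  rows <- seq_len(nrow(df))
  if (!is.null(bait_filter)) rows <- rows[df$bait_frag[rows] %in% bait_filter]
  if (!length(rows)) stop("no interactions to test")
  tps <- table_timepoints(table)
  reps <- table_replicates(table)
  if (length(reps) < 2) stop("need >= 2 replicates per timepoint")
  cols <- as.vector(outer(reps, tps, function(r, t) sprintf("count_ZT%d_R%d", t, r)))
  Y <- as.matrix(df[rows, cols, drop = FALSE])
  grp <- factor(rep(tps, each = length(reps)))
  lib <- colSums(as.matrix(df[, cols, drop = FALSE]))
  lib <- lib / mean(lib)
  norm <- sweep(Y, 2, lib, "/")

  ## dispersion: per-interaction method of moments, shrunk to common
  mom <- apply(norm, 1, function(y) {
    m <- tapply(y, grp, mean); v <- tapply(y, grp, stats::var)
    ok <- m > 0
    if (!any(ok)) return(NA_real_)
    max(mean((v[ok] - m[ok]) / m[ok]^2, na.rm = TRUE), 1e-4)
  })
  if (is.null(dispersion)) {
    common <- mean(mom, trim = 0.2, na.rm = TRUE)
    if (!is.finite(common)) common <- 0.1
    phi <- ifelse(is.na(mom), common, 0.5 * mom + 0.5 * common)
  } else {
    phi <- rep(dispersion, length(rows))
  }

  off <- log(lib)
  fit_one <- function(y, phi_i) {
    if (all(y == 0)) return(c(lrt = 0, p = 1))
    fam <- MASS::negative.binomial(theta = 1 / phi_i)
    full <- tryCatch(
      suppressWarnings(stats::glm(y ~ grp + offset(off), family = fam,
                                  control = stats::glm.control(epsilon = 1e-12,
                                                               maxit = 200))),
      error = function(e) NULL)
    null <- tryCatch(
      suppressWarnings(stats::glm(y ~ 1 + offset(off), family = fam,
                                  control = stats::glm.control(epsilon = 1e-12,
                                                               maxit = 200))),
      error = function(e) NULL)
    if (is.null(full) || is.null(null)) return(c(lrt = NA_real_, p = 1))
    lrt <- max(0, null$deviance - full$deviance)
    c(lrt = lrt, p = stats::pchisq(lrt, df = nlevels(grp) - 1, lower.tail = FALSE))
  }
  res <- t(vapply(seq_along(rows), function(i) fit_one(Y[i, ], phi[i]), numeric(2)))

  ## fold change on the counts-per-million scale: invariant to uniform
  ## depth rescaling, with a small pseudocount for zero groups
  cpm <- sweep(Y, 2, colSums(as.matrix(df[, cols, drop = FALSE])), "/") * 1e6
  gm <- t(apply(cpm, 1, function(y) tapply(y, grp, mean)))
  log2fc <- log2((apply(gm, 1, max) + 0.5) / (apply(gm, 1, min) + 0.5))

  dist <- df$distance_bp[rows]
  regime <- ifelse(!is.na(dist) & dist <= distance_cut, "near", "far")
  q <- rep(NA_real_, length(rows))
  for (rg in unique(regime)) {
    i <- regime == rg
    q[i] <- stats::p.adjust(res[i, "p"], method = "BH")
  }
  calls <- data.frame(row = rows, regime = regime, dispersion = phi,
                      lrt_stat = res[, "lrt"], p = res[, "p"], q = q,
                      log2fc = log2fc, stringsAsFactors = FALSE)
  calls$class <- ifelse(calls$q < fdr & abs(calls$log2fc) >= min_lfc,
                        "dynamic", "stable")
  structure(calls, class = c("dynamic_calls", "data.frame"),
            fdr = fdr, min_lfc = min_lfc, distance_cut = distance_cut)
}

#' @export
print.dynamic_calls <- function(x, ...) {
  cat("dynamic_calls:", nrow(x), "tested;",
      sum(x$class == "dynamic"), "dynamic /", sum(x$class == "stable"),
      "stable (fdr", attr(x, "fdr"), ", |lfc| >=", attr(x, "min_lfc"), ")\n")
  invisible(x)
}

circ_offset <- function(a, b) pmin((a - b) %% 24, (b - a) %% 24)

#' Contacts per timepoint and peak-phase coupling
#'
#' For each circadian promoter, counts the interactions significant at each
#' timepoint (score >= `score_threshold`), finds the peak-contact timepoint
#' (ties flagged and excluded), and measures the circular offset between
#' peak-contact time and transcriptional acrophase (0, 6 or 12 h on the
#' 4-ZT grid). The cohort chi-square compares the observed offset
#' distribution to the one implied by independence of the two marginals.
#'
#' @param table an [interaction_table()] whose `bait_name` carries gene IDs.
#' @param calls a `circadian_calls` data.frame.
#' @param score_threshold per-timepoint significance cutoff.
#' @return List with `per_promoter` (gene, contacts per ZT, `peak_zt`,
#'   `acrophase`, `offset`, `tie_flag`), `offset_table`, `expected_probs`,
#'   `chi2`, `p`, `n_excluded`.
#' @export
contacts_per_timepoint <- function(table, calls, score_threshold = 5) {
  tps <- table_timepoints(table)
  circ <- calls[calls$circadian & !calls$tie_flag, , drop = FALSE]
  df <- as.data.frame(table)
  rowsig <- do.call(cbind, lapply(tps, function(t) {
    score_at(table, t) >= score_threshold
  }))
  per <- lapply(seq_len(nrow(circ)), function(i) {
    g <- circ$gene_id[i]
    rec <- which(df$bait_name == g)
    if (!length(rec)) return(NULL)
    counts <- colSums(rowsig[rec, , drop = FALSE])
    if (all(counts == 0)) return(NULL)
    mx <- max(counts)
    peaks <- tps[counts == mx]
    tie <- length(peaks) > 1
    data.frame(gene_id = g, t(stats::setNames(counts, paste0("contacts_ZT", tps))),
               peak_zt = peaks[1], acrophase = circ$phase[i],
               offset = if (tie) NA_real_ else circ_offset(peaks[1], circ$phase[i]),
               tie_flag = tie, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no circadian promoter has significant contacts")
  n_excluded <- sum(per$tie_flag)
  ok <- per[!per$tie_flag, , drop = FALSE]
  offs <- c(0, 6, 12)
  obs <- vapply(offs, function(d) sum(ok$offset == d), numeric(1))
  ## independence expectation from the two marginals
  p_peak <- table(factor(ok$peak_zt, levels = tps)) / nrow(ok)
  p_acro <- table(factor(ok$acrophase, levels = tps)) / nrow(ok)
  expected <- vapply(offs, function(d) {
    sum(outer(as.numeric(p_peak), as.numeric(p_acro)) *
          (outer(tps, tps, circ_offset) == d))
  }, numeric(1))
  keep <- expected > 0
  chi <- if (sum(keep) >= 2 && nrow(ok) >= 2) {
    suppressWarnings(stats::chisq.test(obs[keep], p = expected[keep],
                                       rescale.p = TRUE))
  } else list(statistic = NA_real_, p.value = NA_real_)
  list(per_promoter = per,
       offset_table = stats::setNames(obs, paste0("offset_", offs)),
       expected_probs = stats::setNames(expected, paste0("offset_", offs)),
       chi2 = unname(chi$statistic), p = unname(chi$p.value),
       n_excluded = n_excluded)
}

#' Matched-permutation feature enrichment at promoter-interacting regions
#'
#' Observed: the number of unique other-end fragments overlapping at least
#' one feature. Null: in each iteration every observed (other-end length L,
#' bait distance D) pair is re-placed as an interval of length L at signed
#' distance +/- D (fair coin) from a bait drawn uniformly from the bait
#' universe, redrawn up to 100 times if it falls off the chromosome; the
#' placement therefore preserves the empirical joint (L, D) distribution
#' exactly. Significance: two-sided one-sample t-test of the per-iteration
#' expected overlap counts against the observed value.
#'
#' @param table an [interaction_table()].
#' @param features a `feature_set` (or data.frame `chrom,start,end`).
#' @param fragmap a [restriction_map()] (for bait midpoints and chromosome
#'   bounds).
#' @param baits bait fragment universe; defaults to the table's.
#' @param n_iter iterations (>= 2; >= 100 recommended).
#' @param seed RNG seed.
#' @param keep_placements return the first iteration's placements (for
#'   auditing the preserved (L, D) joint distribution).
#' @return An `enrichment_result` list: `observed`, `expected` (vector),
#'   `expected_mean`, `expected_sd`, `ratio`, `t_p`, `n_iter`, `n_skipped`,
#'   `degenerate`, and optionally `placements`.
#' @export
matched_null_enrichment <- function(table, features, fragmap, baits = NULL,
                                    n_iter = 100, seed = 1,
                                    keep_placements = FALSE) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  if (is.null(baits)) baits <- attr(table, "baits")
  df <- as.data.frame(table)
  cis <- df[!is.na(df$distance_bp), , drop = FALSE]
  oe <- cis[!duplicated(cis$other_frag), , drop = FALSE]
  feats <- as.data.frame(features)
  observed <- sum(count_feature_overlaps(
    data.frame(chrom = oe$other_chrom, start = oe$other_start, end = oe$other_end),
    feats) > 0)
  if (nrow(feats) == 0) {
    return(structure(list(observed = 0, expected = rep(0, n_iter),
                          expected_mean = 0, expected_sd = 0, ratio = NA_real_,
                          t_p = NA_real_, n_iter = n_iter, n_skipped = 0,
                          degenerate = TRUE), class = "enrichment_result"))
  }
  L <- oe$other_end - oe$other_start
  D <- oe$distance_bp
  genome <- attr(fragmap, "genome")
  bait_mid <- frag_mid(fragmap, baits)
  bait_chrom <- fragmap$chrom[match(baits, fragmap$frag_id)]
  chrom_len <- chrom_length(genome, bait_chrom)
  n_pairs <- length(L)
  placements <- NULL
  res <- with_seed(seed, {
    expected <- numeric(n_iter)
    skipped_total <- 0L
    for (it in seq_len(n_iter)) {
      pchrom <- character(n_pairs); pstart <- numeric(n_pairs)
      pend <- numeric(n_pairs); placed <- logical(n_pairs)
      todo <- seq_len(n_pairs)
      for (attempt in 1:100) {
        if (!length(todo)) break
        bi <- sample.int(length(baits), length(todo), replace = TRUE)
        side <- ifelse(stats::runif(length(todo)) < 0.5, -1, 1)
        mid <- bait_mid[bi] + side * D[todo]
        s <- mid - L[todo] / 2; e <- mid + L[todo] / 2
        ok <- s >= 0 & e <= chrom_len[bi]
        hit <- todo[ok]
        pchrom[hit] <- bait_chrom[bi[ok]]; pstart[hit] <- s[ok]; pend[hit] <- e[ok]
        placed[hit] <- TRUE
        todo <- todo[!ok]
      }
      skipped_total <- skipped_total + sum(!placed)
      ok <- which(placed)
      hits <- count_feature_overlaps(
        data.frame(chrom = pchrom[ok], start = pstart[ok], end = pend[ok]),
        feats) > 0
      expected[it] <- sum(hits)
      if (keep_placements && it == 1) {
        placements <- data.frame(chrom = pchrom[ok], start = pstart[ok],
                                 end = pend[ok], length = L[ok],
                                 distance_bp = D[ok])
      }
    }
    list(expected = expected, n_skipped = skipped_total)
  })
  expected <- res$expected
  degenerate <- stats::sd(expected) == 0
  t_p <- if (!degenerate) stats::t.test(expected, mu = observed)$p.value else
    if (all(expected == observed)) 1 else NA_real_
  ratio <- if (mean(expected) > 0) observed / mean(expected) else NA_real_
  structure(list(observed = observed, expected = expected,
                 expected_mean = mean(expected), expected_sd = stats::sd(expected),
                 ratio = ratio, t_p = t_p, n_iter = n_iter,
                 n_skipped = res$n_skipped, degenerate = degenerate,
                 placements = placements),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result: observed", x$observed, "vs expected",
      format(x$expected_mean, digits = 4), "+/-",
      format(x$expected_sd, digits = 3), "| ratio",
      format(x$ratio, digits = 4), "t_p", format(x$t_p, digits = 3), "\n")
  invisible(x)
}

#' Oscillatory-eRNA contact enrichment at circadian promoters
#'
#' Observed: interactions between circadian baits and other-end fragments
#' overlapping oscillatory-enhancer features. Null: each iteration samples
#' as many enhancers from the non-oscillatory set (without replacement) and
#' recounts; t-test and ratio as in [matched_null_enrichment()].
#'
#' @param table an [interaction_table()].
#' @param osc,nonosc `feature_set`s of oscillatory and non-oscillatory
#'   enhancers (`|nonosc| >= |osc|`).
#' @param circadian_baits bait fragment IDs of circadian promoters.
#' @param n_iter iterations.
#' @param seed RNG seed.
#' @return An `enrichment_result`.
#' @export
erna_contact_enrichment <- function(table, osc, nonosc, circadian_baits,
                                    n_iter = 100, seed = 1) {
  osc <- as.data.frame(osc); nonosc <- as.data.frame(nonosc)
  if (nrow(nonosc) < nrow(osc)) stop("need |nonosc| >= |osc|")
  df <- as.data.frame(table)
  sub <- df[df$bait_frag %in% circadian_baits, , drop = FALSE]
  oeq <- data.frame(chrom = sub$other_chrom, start = sub$other_start,
                    end = sub$other_end)
  count_with <- function(feats) sum(count_feature_overlaps(oeq, feats) > 0)
  observed <- count_with(osc)
  if (length(circadian_baits) == 0 || nrow(sub) == 0) {
    return(structure(list(observed = 0, expected = rep(NA_real_, n_iter),
                          expected_mean = NA_real_, expected_sd = NA_real_,
                          ratio = NA_real_, t_p = NA_real_, n_iter = n_iter,
                          n_skipped = 0, degenerate = TRUE),
                     class = "enrichment_result"))
  }
  expected <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      count_with(nonosc[sample(nrow(nonosc), nrow(osc)), , drop = FALSE])
    }, numeric(1))
  })
  degenerate <- stats::sd(expected) == 0
  t_p <- if (!degenerate) stats::t.test(expected, mu = observed)$p.value else NA_real_
  ratio <- if (mean(expected) > 0) observed / mean(expected) else NA_real_
  structure(list(observed = observed, expected = expected,
                 expected_mean = mean(expected), expected_sd = stats::sd(expected),
                 ratio = ratio, t_p = t_p, n_iter = n_iter, n_skipped = 0,
                 degenerate = degenerate),
            class = "enrichment_result")
}

#' Phase coherence between anchor promoters and contacted phased elements
#'
#' Splits circadian anchor promoters into diurnal (acrophase ZT0/ZT6) and
#' nocturnal groups, collects the phases of the phased elements each group
#' contacts, bins them (4 ZT bins for promoter targets, eight 3-hour bins
#' for hourly eRNA phases: hour h falls in bin floor(h/3)), and compares the
#' two groups' contacted-phase hour distributions with a Wilcoxon rank-sum
#' test. Phases enter the test as hours from lights-on (ZT0), which the
#' diurnal/nocturnal split makes well ordered.
#'
#' @param table an [interaction_table()] whose `bait_name` carries gene IDs.
#' @param anchors a `circadian_calls` data.frame.
#' @param targets data.frame with `frag_id` and `phase_hr` of phased
#'   elements (other-end fragments).
#' @param target_binning `"zt4"` or `"hr8x3"`.
#' @return A `phase_coherence_result`: per-group binned distributions,
#'   raw contacted phases, and `wilcoxon_p` (degenerate-flagged when a group
#'   has no contacted phased targets).
#' @export
phase_coherence <- function(table, anchors, targets,
                            target_binning = c("zt4", "hr8x3")) {
  target_binning <- match.arg(target_binning)
  df <- as.data.frame(table)
  circ <- anchors[anchors$circadian, , drop = FALSE]
  phases_for <- function(group) {
    genes <- circ$gene_id[circ$diel == group]
    rec <- df[df$bait_name %in% genes, , drop = FALSE]
    ph <- targets$phase_hr[match(rec$other_frag, targets$frag_id)]
    ph[!is.na(ph)]
  }
  diurnal <- phases_for("diurnal")
  nocturnal <- phases_for("nocturnal")
  bin_phases <- function(ph) {
    if (target_binning == "zt4") {
      table(factor(ph, levels = ZT_DEFAULT))
    } else {
      table(factor(floor(ph / 3), levels = 0:7))
    }
  }
  degenerate <- length(diurnal) == 0 || length(nocturnal) == 0
  p <- if (!degenerate) {
    stats::wilcox.test(diurnal, nocturnal, exact = FALSE)$p.value
  } else NA_real_
  structure(list(diurnal = bin_phases(diurnal), nocturnal = bin_phases(nocturnal),
                 diurnal_phases = diurnal, nocturnal_phases = nocturnal,
                 wilcoxon_p = p, degenerate = degenerate,
                 binning = target_binning),
            class = "phase_coherence_result")
}

CORE_CLOCK_GENES <- c("Npas2", "Clock", "Arntl", "Cry1", "Cry2",
                      "Per1", "Per2", "Rorc", "Nr1d1", "Nr1d2")

#' Core-clock vs other circadian promoter contact comparison
#'
#' Per gene: the number of unique significant interactions (union over
#' timepoints at the score cutoff) and the fraction of its tested contacts
#' classified dynamic. Core-clock genes are compared against `n_iter`
#' resamples of equally many circadian non-core genes (pooled), with a
#' Mann-Whitney test per metric.
#'
#' @param table an [interaction_table()] whose `bait_name` carries gene IDs.
#' @param calls a `circadian_calls` data.frame.
#' @param dynamic a `dynamic_calls` result from [classify_dynamic()] on the
#'   same table.
#' @param core_list core-clock gene IDs; the canonical mammalian
#'   transcription-translation-feedback-loop set by default.
#' @param n_iter resampling iterations.
#' @param seed RNG seed.
#' @param resample_size genes drawn per iteration; defaults to the number
#'   of core genes found in the data.
#' @param score_threshold significance cutoff.
#' @return List with `core` (per-gene metrics), `null_contacts`,
#'   `null_dynfrac` (pooled null values), `p_contacts`, `p_dynfrac`.
#' @export
coreclock_comparison <- function(table, calls, dynamic,
                                 core_list = CORE_CLOCK_GENES,
                                 n_iter = 100, seed = 1, resample_size = NULL,
                                 score_threshold = 5) {
  df <- as.data.frame(table)
  tps <- table_timepoints(table)
  sig_any <- Reduce(`|`, lapply(tps, function(t) score_at(table, t) >= score_threshold))
  dyn_class <- rep(NA_character_, nrow(df))
  dyn_class[dynamic$row] <- dynamic$class
  metrics_for <- function(gene) {
    rec <- which(df$bait_name == gene)
    n_sig <- length(unique(df$other_frag[rec[sig_any[rec]]]))
    tested <- dyn_class[rec]
    tested <- tested[!is.na(tested)]
    dynfrac <- if (length(tested)) mean(tested == "dynamic") else NA_real_
    c(n_sig, dynfrac)
  }
  circ_genes <- calls$gene_id[calls$circadian]
  core_in <- intersect(core_list, intersect(circ_genes, unique(df$bait_name)))
  if (!length(core_in)) stop("no core-clock gene found in the data")
  pool <- setdiff(intersect(circ_genes, unique(df$bait_name)), core_list)
  if (!length(pool)) stop("no circadian non-core genes to resample from")
  if (is.null(resample_size)) resample_size <- length(core_in)
  core_m <- t(vapply(core_in, metrics_for, numeric(2)))
  pool_m <- t(vapply(pool, metrics_for, numeric(2)))
  draws <- with_seed(seed, {
    replicate(n_iter, sample(length(pool), min(resample_size, length(pool))))
  })
  null_contacts <- as.vector(pool_m[draws, 1])
  null_dynfrac <- as.vector(pool_m[draws, 2])
  p_contacts <- stats::wilcox.test(core_m[, 1], null_contacts, exact = FALSE)$p.value
  p_dynfrac <- suppressWarnings(
    stats::wilcox.test(core_m[, 2], null_dynfrac, exact = FALSE)$p.value)
  list(core = data.frame(gene_id = core_in, n_contacts = core_m[, 1],
                         dynamic_fraction = core_m[, 2]),
       null_contacts = null_contacts, null_dynfrac = null_dynfrac,
       mean_core_contacts = mean(core_m[, 1]),
       mean_null_contacts = mean(null_contacts, na.rm = TRUE),
       mean_core_dynfrac = mean(core_m[, 2], na.rm = TRUE),
       mean_null_dynfrac = mean(null_dynfrac, na.rm = TRUE),
       p_contacts = p_contacts, p_dynfrac = p_dynfrac,
       n_iter = n_iter, resample_size = resample_size)
}
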