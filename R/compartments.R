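#' Compute the compartment eigenvector (PC1) of a balanced matrix
#'
#' Pipeline: observed/expected transform, Pearson correlation matrix over
#' unmasked bins, leading eigenvector of that correlation matrix, then sign
#' orientation: the vector is flipped if its Pearson correlation with the
#' supplied activity covariate (an active-chromatin coverage track on the
#' same bins) is negative, so positive PC1 = A compartment by convention.
#'
#' @param matrix a `balanced_matrix` (cis, typically 100-kb bins).
#' @param activity numeric vector of activity values per bin, or a
#'   `coverage_track` on the same bin grid.
#' @return An `eigen_vector` list: `pc1` (per-bin value, `NA` on masked
#'   bins), `mask`, `eigenvalue`, `chrom`, `bin_size`, `oriented`.
#' @export
compute_pc1 <- function(matrix, activity) {
  OE <- oe_transform(matrix)
  n <- nrow(OE)
  if (inherits(activity, "coverage_track") || is.data.frame(activity)) {
    activity <- activity$value
  }
  if (length(activity) != n) stop("activity covariate length != number of bins")
  unmasked <- which(rowSums(!is.na(OE)) > 1)
  if (length(unmasked) < 10) stop("fewer than 10 unmasked bins")
  sub <- OE[unmasked, unmasked, drop = FALSE]
  sub[is.na(sub)] <- 0
  sds <- apply(sub, 2, stats::sd)
  if (all(sds == 0)) stop("zero-variance observed/expected input")
  keep <- unmasked[sds > 0]
  sub <- sub[sds > 0, sds > 0, drop = FALSE]
  if (length(keep) < 10) stop("fewer than 10 usable bins")
  C <- stats::cor(sub)
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1]
  pc1 <- rep(NA_real_, n)
  pc1[keep] <- v
  act <- activity[keep]
  oriented <- FALSE
  if (stats::sd(act) > 0 && stats::sd(v) > 0) {
    if (stats::cor(v, act) < 0) pc1 <- -pc1
    oriented <- TRUE
  }
  chrom <- if (inherits(matrix, "balanced_matrix")) matrix$source$chrom else NA
  bin_size <- if (inherits(matrix, "balanced_matrix")) matrix$source$bin_size else NA
  structure(list(pc1 = pc1, mask = is.na(pc1), eigenvalue = ev$values[1],
                 chrom = chrom, bin_size = bin_size, oriented = oriented),
            class = "eigen_vector")
}

#' Assemble per-replicate and merged PC1 values into an eigen track
#'
#' @param pc1_array numeric array `bins x timepoints x replicates` of
#'   replicate PC1 values (each replicate oriented independently against the
#'   activity covariate).
#' @param merged numeric matrix `bins x timepoints` of PC1 from
#'   merged-replicate matrices.
#' @param timepoints ZT hours, in array order.
#' @param chrom,bin_size coordinate metadata.
#' @return An `eigen_track` list.
#' @export
eigen_track <- function(pc1_array, merged, timepoints, chrom = NA, bin_size = NA) {
  stopifnot(length(dim(pc1_array)) == 3, ncol(merged) == length(timepoints),
            dim(pc1_array)[1] == nrow(merged),
            dim(pc1_array)[2] == length(timepoints))
  structure(list(pc1 = pc1_array, merged = merged, timepoints = timepoints,
                 chrom = chrom, bin_size = bin_size),
            class = "eigen_track")
}

#' Build an eigen track from per-(timepoint, replicate) matrices
#'
#' Balances each matrix, computes replicate PC1s (each oriented against the
#' activity covariate independently), merges replicates per timepoint by
#' summing counts, and computes the merged PC1 used for A/B assignment.
#'
#' @param matrices nested list: `matrices[[tp]][[rep]]` of
#'   [contact_matrix()] objects for one chromosome.
#' @param activity activity covariate on the same bins.
#' @param timepoints ZT hours in list order.
#' @return An `eigen_track`.
#' @export
eigen_track_from_matrices <- function(matrices, activity, timepoints = ZT_DEFAULT) {
  n_tp <- length(matrices)
  n_rep <- length(matrices[[1]])
  n <- nrow(matrices[[1]][[1]]$counts)
  arr <- array(NA_real_, c(n, n_tp, n_rep))
  merged <- matrix(NA_real_, n, n_tp)
  for (t in seq_len(n_tp)) {
    for (r in seq_len(n_rep)) {
      arr[, t, r] <- compute_pc1(balance_matrix(matrices[[t]][[r]]), activity)$pc1
    }
    mm <- merge_replicates(matrices[[t]])
    merged[, t] <- compute_pc1(balance_matrix(mm), activity)$pc1
  }
  eigen_track(arr, merged, timepoints,
              chrom = matrices[[1]][[1]]$chrom,
              bin_size = matrices[[1]][[1]]$bin_size)
}

#' Segment merged PC1 into A/B compartment runs
#'
#' Compartments are maximal same-sign runs of the merged PC1: positive = A,
#' negative = B, exact zero counts as A (flagged upstream as a tie). Masked
#' bins break runs.
#'
#' @param track an `eigen_track`.
#' @param timepoint ZT hours.
#' @return data.frame of segments: `start_bin`, `end_bin` (1-based bin
#'   indices, inclusive), `start`, `end` (bp, when `bin_size` known),
#'   `label`, `n_bins`, `timepoint`.
#' @export
segment_compartments <- function(track, timepoint) {
  ti <- match(timepoint, track$timepoints)
  if (is.na(ti)) stop("timepoint not in track: ", timepoint)
  v <- track$merged[, ti]
  lab <- ifelse(is.na(v), NA_character_, ifelse(v >= 0, "A", "B"))
  n <- length(lab)
  segs <- list()
  i <- 1
  while (i <= n) {
    if (is.na(lab[i])) { i <- i + 1; next }
    j <- i
    while (j < n && !is.na(lab[j + 1]) && lab[j + 1] == lab[i]) j <- j + 1
    segs[[length(segs) + 1]] <- data.frame(start_bin = i, end_bin = j,
                                           label = lab[i], n_bins = j - i + 1)
    i <- j + 1
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start_bin = integer(), end_bin = integer(),
               label = character(), n_bins = integer())
  out$timepoint <- timepoint
  if (!is.na(track$bin_size)) {
    out$start <- (out$start_bin - 1) * track$bin_size
    out$end <- out$end_bin * track$bin_size
  }
  out
}

#' Detect oscillatory chromatin compartments (OCCs)
#'
#' Per bin, a one-way ANOVA of replicate PC1 values grouped by timepoint
#' tests for a consistent change across the day; p-values are adjusted
#' across bins (Benjamini-Hochberg by default). A bin is oscillatory iff its
#' adjusted p-value is below `alpha` *and* the merged PC1 sign differs
#' between at least one pair of timepoints — large same-sign PC1 changes are
#' not compartment switches. Each oscillatory bin gets a 4-letter category
#' string over the sampled ZTs (e.g. "AABA" = A at ZT0/ZT6/ZT18, B at ZT12);
#' adjacent oscillatory bins with identical category merge into regions.
#'
#' @param track an `eigen_track` with >= 2 replicates per timepoint.
#' @param alpha significance level on the adjusted p-value.
#' @param adjust p-value adjustment method (see [stats::p.adjust()]).
#' @return List with `bins` (per-bin data.frame: `anova_p`, `q`, `switches`,
#'   `oscillatory`, `category`, `tie`) and `regions` (merged OCC regions
#'   with `start_bin`, `end_bin`, `category`, `anova_p` = min adjusted p in
#'   the region, `n_bins`) plus `n_skipped`.
#' @export
detect_occ <- function(track, alpha = 0.05, adjust = "BH") {
  n <- dim(track$pc1)[1]
  n_tp <- dim(track$pc1)[2]
  n_rep <- dim(track$pc1)[3]
  if (n_rep < 2) stop("need >= 2 replicates per timepoint")
  grp <- factor(rep(seq_len(n_tp), times = n_rep))
  pvals <- rep(NA_real_, n)
  skipped <- 0L
  for (b in seq_len(n)) {
    y <- as.vector(track$pc1[b, , ])
    if (anyNA(y)) { skipped <- skipped + 1L; next }
    if (stats::sd(y) == 0) { pvals[b] <- 1; next }
    fit <- stats::aov(y ~ grp)
    pvals[b] <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(pvals[b])) pvals[b] <- 1
  }
  q <- rep(NA_real_, n)
  ok <- !is.na(pvals)
  q[ok] <- stats::p.adjust(pvals[ok], method = adjust)
  merged_sign <- track$merged >= 0  # exact zero treated as A
  tie <- apply(track$merged == 0, 1, any, na.rm = TRUE)
  switches <- apply(merged_sign, 1, function(s) {
    s <- s[!is.na(s)]
    length(unique(s)) > 1
  })
  category <- apply(merged_sign, 1, function(s) {
    if (anyNA(s)) NA_character_ else paste(ifelse(s, "A", "B"), collapse = "")
  })
  oscillatory <- ok & !is.na(q) & q < alpha & switches & !is.na(category)
  bins <- data.frame(bin = seq_len(n), anova_p = pvals, q = q,
                     switches = switches, oscillatory = oscillatory,
                     category = category, tie = tie)
  ## merge adjacent oscillatory bins with identical category
  regions <- list()
  i <- 1
  while (i <= n) {
    if (!oscillatory[i]) { i <- i + 1; next }
    j <- i
    while (j < n && oscillatory[j + 1] && category[j + 1] == category[i]) j <- j + 1
    regions[[length(regions) + 1]] <- data.frame(
      start_bin = i, end_bin = j, category = category[i],
      anova_p = min(q[i:j]), n_bins = j - i + 1)
    i <- j + 1
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(start_bin = integer(), end_bin = integer(),
               category = character(), anova_p = numeric(), n_bins = integer())
  if (!is.na(track$bin_size) && nrow(regions)) {
    regions$start <- (regions$start_bin - 1) * track$bin_size
    regions$end <- regions$end_bin * track$bin_size
  }
  list(bins = bins, regions = regions, n_skipped = skipped,
       alpha = alpha, adjust = adjust)
}

#' Quantify a signal track within regions and compare groups
#'
#' Converts raw per-region read counts to reads-per-million and
#' log2(RPM + pseudocount), then runs the requested group comparison:
#' Kruskal-Wallis across all groups, Mann-Whitney or paired Wilcoxon between
#' two groups, or one-way ANOVA with Tukey's post hoc.
#'
#' @param counts numeric vector of raw read counts per region.
#' @param library_total total mapped reads of the library.
#' @param group factor of region group labels (e.g. compartment A/B).
#' @param test one of `"kruskal"`, `"mannwhitney"`, `"wilcoxon-paired"`,
#'   `"anova+tukey"`, or `"none"`.
#' @param pseudocount added to RPM before the log.
#' @return List with `rpm`, `log2rpm`, `test`, `p`, and `tukey` (for
#'   `"anova+tukey"`).
#' @export
quantify_in_regions <- function(counts, library_total, group = NULL,
                                test = c("none", "kruskal", "mannwhitney",
                                         "wilcoxon-paired", "anova+tukey"),
                                pseudocount = 1) {
  test <- match.arg(test)
  if (library_total <= 0) stop("library total must be > 0")
  rpm <- counts / library_total * 1e6
  log2rpm <- log2(rpm + pseudocount)
  p <- NA_real_
  tukey <- NULL
  if (test != "none") {
    if (is.null(group)) stop("group required for test ", test)
    group <- factor(group)
    if (test == "kruskal") {
      p <- stats::kruskal.test(log2rpm, group)$p.value
    } else if (test == "mannwhitney") {
      if (nlevels(group) != 2) stop("mannwhitney needs exactly 2 groups")
      sp <- split(log2rpm, group)
      p <- stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE)$p.value
    } else if (test == "wilcoxon-paired") {
      if (nlevels(group) != 2) stop("paired Wilcoxon needs exactly 2 groups")
      sp <- split(log2rpm, group)
      if (length(sp[[1]]) != length(sp[[2]])) stop("paired test needs equal group sizes")
      p <- stats::wilcox.test(sp[[1]], sp[[2]], paired = TRUE, exact = FALSE)$p.value
    } else {
      fit <- stats::aov(log2rpm ~ group)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tukey <- stats::TukeyHSD(fit)
    }
  }
  list(rpm = rpm, log2rpm = log2rpm, test = test, p = p, tukey = tukey)
}
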