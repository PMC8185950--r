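#' Insulation score of a contact matrix
#'
#' For each bin `i`, the mean contact count in the off-diagonal square
#' upstream x downstream of the bin: rows `[i-w, i)`, columns `(i, i+w]`
#' with `w = window_bp / bin_size`. Bins within `w` of a chromosome end are
#' masked. Domain boundaries show up as local minima. The normalized score
#' is `log2(score / mean score)`.
#'
#' @param matrix a [contact_matrix()] or `balanced_matrix`.
#' @param window_bp window size in bp; must be a multiple of the bin size
#'   and at least two bins.
#' @return An `insulation_track` list: `score`, `normalized_score`, `chrom`,
#'   `bin_size`, `window_bp`, `window_bins`.
#' @export
insulation_score <- function(matrix, window_bp) {
  M <- working_counts(matrix)
  bin_size <- if (inherits(matrix, "balanced_matrix")) matrix$source$bin_size
  else if (inherits(matrix, "contact_matrix")) matrix$bin_size else NA
  chrom <- if (inherits(matrix, "balanced_matrix")) matrix$source$chrom
  else if (inherits(matrix, "contact_matrix")) matrix$chrom else NA
  n <- nrow(M)
  if (!is.na(bin_size)) {
    if (window_bp %% bin_size != 0) stop("window_bp must be a multiple of bin_size")
    w <- as.integer(window_bp / bin_size)
  } else {
    w <- as.integer(window_bp)
  }
  if (w < 2) stop("window must span at least 2 bins")
  if (2 * w >= n) stop("window larger than chromosome")
  score <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    block <- M[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    score[i] <- mean(block)
  }
  m <- mean(score, na.rm = TRUE)
  normalized <- if (is.finite(m) && m > 0) log2(score / m) else rep(NA_real_, n)
  structure(list(score = score, normalized_score = normalized, chrom = chrom,
                 bin_size = bin_size, window_bp = window_bp, window_bins = w),
            class = "insulation_track")
}

#' Call TADs from an insulation track
#'
#' Boundaries are bins that are strict local minima of the raw insulation
#' score within +/- `w` bins (ties resolved to the leftmost bin of a
#' minimal plateau) *and* whose score lies below `threshold`. TADs are the
#' intervals between consecutive boundaries, filtered to
#' `[min_size_bp, max_size_bp]`; no TAD is emitted across a masked gap.
#'
#' @param track an [insulation_score()] result.
#' @param threshold score cutoff on the raw-score scale (a boundary's score
#'   must be strictly below it).
#' @param min_size_bp,max_size_bp TAD size filter.
#' @return data.frame of TADs: `chrom`, `start`, `end`, `start_bin`,
#'   `end_bin` (bin index range, half-open on bins), with attribute
#'   `boundaries` (boundary bin indices).
#' @export
call_tads <- function(track, threshold, min_size_bp = 150e3, max_size_bp = 1.5e6) {
  s <- track$score
  n <- length(s)
  w <- track$window_bins
  boundaries <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(s[i]) || s[i] >= threshold) next
    lo <- max(1, i - w); hi <- min(n, i + w)
    nb <- s[setdiff(lo:hi, i)]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    if (all(s[i] < nb)) {
      boundaries <- c(boundaries, i)
    } else if (all(s[i] <= nb)) {
      # plateau tie: keep only the leftmost bin of the tied run
      if (i == 1 || is.na(s[i - 1]) || s[i - 1] > s[i]) boundaries <- c(boundaries, i)
    }
  }
  bin_size <- if (is.na(track$bin_size)) 1 else track$bin_size
  tads <- list()
  if (length(boundaries) >= 2) {
    for (k in seq_len(length(boundaries) - 1)) {
      b1 <- boundaries[k]; b2 <- boundaries[k + 1]
      if (anyNA(s[b1:b2])) next  # masked gap
      size <- (b2 - b1) * bin_size
      if (size < min_size_bp || size > max_size_bp) next
      tads[[length(tads) + 1]] <- data.frame(
        chrom = track$chrom, start = (b1 - 1) * bin_size, end = (b2 - 1) * bin_size,
        start_bin = b1, end_bin = b2, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(tads)) do.call(rbind, tads) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               start_bin = integer(), end_bin = integer())
  attr(out, "boundaries") <- boundaries
  out
}

#' Shared TADs between two timepoints
#'
#' A TAD from set `a` is shared if some TAD in `b` covers strictly more than
#' `min_frac` of its length (the conventional >80% reciprocal-style overlap
#' rule, applied from `a`'s side); the best-overlap partner is reported.
#'
#' @param a,b data.frames of TADs (`chrom`, `start`, `end`).
#' @param min_frac overlap fraction that must be exceeded.
#' @return List with `pairs` (rows of `a` with partner index in `b` and
#'   `overlap_frac`), `shared_a` (logical per row of `a`), and `unshared`
#'   (rows of `a` not shared).
#' @export
shared_tads <- function(a, b, min_frac = 0.8) {
  n <- nrow(a)
  partner <- rep(NA_integer_, n)
  frac <- rep(0, n)
  for (i in seq_len(n)) {
    cand <- which(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
    if (!length(cand)) next
    ov <- pmin(b$end[cand], a$end[i]) - pmax(b$start[cand], a$start[i])
    k <- which.max(ov)
    partner[i] <- cand[k]
    frac[i] <- ov[k] / (a$end[i] - a$start[i])
  }
  shared <- frac > min_frac
  pairs <- cbind(a, partner = partner, overlap_frac = frac)[shared, , drop = FALSE]
  list(pairs = pairs, shared_a = shared, unshared = a[!shared, , drop = FALSE],
       n_shared = sum(shared), n_total = n)
}

# Area-weighted 1-D rebinning weights: rows = target bins, cols = source bins.
# Source domain [0, n_src] is mapped onto n_tgt equal target bins.
rebin_weights <- function(n_src, n_tgt) {
  W <- matrix(0, n_tgt, n_src)
  width <- n_src / n_tgt
  for (t in seq_len(n_tgt)) {
    lo <- (t - 1) * width; hi <- t * width
    for (s in seq_len(n_src)) {
      ov <- min(hi, s) - max(lo, s - 1)
      if (ov > 0) W[t, s] <- ov
    }
    W[t, ] <- W[t, ] / sum(W[t, ])
  }
  W
}

#' Rescaled-TAD metaplot
#'
#' Each TAD's observed/expected submatrix, extended by flanks of half the
#' TAD length on each side, is rescaled by area-weighted averaging onto a
#' fixed grid of `n_core` central bins plus `flank_bins` per side; the
#' metaplot is the cell-wise median across TADs.
#'
#' @param oe observed/expected matrix (from [oe_transform()]).
#' @param tads data.frame with `start_bin`, `end_bin` on the same bin grid.
#' @param flank_bins target flank bins per side.
#' @param n_core target core bins the TAD body is scaled to.
#' @param sample_n optional random subsample size.
#' @param seed seed for the subsample.
#' @return A `metaplot_result`: list with `grid` (median matrix), `n_used`,
#'   `n_skipped`.
#' @export
tad_metaplot <- function(oe, tads, flank_bins = 5, n_core = 5,
                         sample_n = NULL, seed = 1) {
  if (nrow(tads) == 0) stop("no TADs supplied")
  if (!is.null(sample_n) && sample_n < nrow(tads)) {
    tads <- with_seed(seed, tads[sample(nrow(tads), sample_n), , drop = FALSE])
  }
  n <- nrow(oe)
  g <- n_core + 2 * flank_bins
  stack <- array(NA_real_, c(g, g, nrow(tads)))
  used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(tads))) {
    b1 <- tads$start_bin[k]; b2 <- tads$end_bin[k]
    len <- b2 - b1
    if (len < n_core) { skipped <- skipped + 1L; next }
    flank <- len / 2
    lo <- round(b1 - flank); hi <- round(b2 - 1 + flank)
    if (lo < 1 || hi > n) { skipped <- skipped + 1L; next }
    sub <- oe[lo:hi, lo:hi, drop = FALSE]
    n_src <- nrow(sub)
    src_flank <- b1 - lo
    src_tail <- hi - (b2 - 1)
    if (src_flank < 1 || src_tail < 1) { skipped <- skipped + 1L; next }
    # map: flank | core | flank, each rescaled to its own target width
    W <- matrix(0, g, n_src)
    W[1:flank_bins, 1:src_flank] <- rebin_weights(src_flank, flank_bins)
    W[(flank_bins + 1):(flank_bins + n_core), (src_flank + 1):(src_flank + len)] <-
      rebin_weights(len, n_core)
    W[(flank_bins + n_core + 1):g, (src_flank + len + 1):n_src] <-
      rebin_weights(src_tail, flank_bins)
    sub0 <- sub; sub0[is.na(sub0)] <- 0
    wt <- (!is.na(sub)) * 1
    num <- W %*% sub0 %*% t(W)
    den <- W %*% wt %*% t(W)
    cell <- ifelse(den > 0, num / den, NA_real_)
    used <- used + 1L
    stack[, , k] <- cell
  }
  if (used == 0) stop("no usable TADs for the metaplot")
  grid <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  structure(list(grid = grid, n_used = used, n_skipped = skipped,
                 mode = "tad", n_core = n_core, flank_bins = flank_bins),
            class = "metaplot_result")
}

#' Point-anchored metaplot
#'
#' Median observed/expected in the `(2k+1) x (2k+1)` bin neighborhood of
#' each anchor point (the anchor occupies the central bin).
#'
#' @param oe observed/expected matrix.
#' @param point_bins integer vector of anchor bin indices (1-based).
#' @param window_bins half-window `k` in bins.
#' @param sample_n optional random subsample size.
#' @param seed seed for the subsample.
#' @return A `metaplot_result` with a `(2k+1)^2` grid.
#' @export
point_metaplot <- function(oe, point_bins, window_bins = 10,
                           sample_n = NULL, seed = 1) {
  k <- window_bins
  n <- nrow(oe)
  if (!is.null(sample_n) && sample_n < length(point_bins)) {
    point_bins <- with_seed(seed, sample(point_bins, sample_n))
  }
  g <- 2 * k + 1
  keep <- point_bins > k & point_bins <= n - k
  skipped <- sum(!keep)
  point_bins <- point_bins[keep]
  if (!length(point_bins)) stop("no usable anchor points")
  stack <- array(NA_real_, c(g, g, length(point_bins)))
  for (j in seq_along(point_bins)) {
    p <- point_bins[j]
    stack[, , j] <- oe[(p - k):(p + k), (p - k):(p + k)]
  }
  grid <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  structure(list(grid = grid, n_used = length(point_bins), n_skipped = skipped,
                 mode = "point", window_bins = k),
            class = "metaplot_result")
}

#' @export
print.metaplot_result <- function(x, ...) {
  cat("metaplot_result (", x$mode, "):", nrow(x$grid), "x", ncol(x$grid),
      "grid from", x$n_used, "features (", x$n_skipped, "skipped )\n")
  invisible(x)
}
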