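# Independent oracles used to check package computations.

# Alternating-scaling (iterative proportional fitting) oracle for matrix
# balancing, run far past the package tolerance.
oracle_ipf <- function(M, tol = 1e-10, max_iter = 5000) {
  B <- M
  for (i in seq_len(max_iter)) {
    rs <- rowSums(B)
    if (max(abs(rs / mean(rs) - 1)) < tol) break
    b <- sqrt(rs / mean(rs))
    B <- B / outer(b, b)
  }
  B
}

# Power-iteration oracle for the leading eigenvector of a symmetric matrix.
oracle_power_iteration <- function(C, n_iter = 5000) {
  v <- rep(1, nrow(C)) + seq_len(nrow(C)) / nrow(C)
  for (i in seq_len(n_iter)) {
    v2 <- C %*% v
    v <- v2 / sqrt(sum(v2^2))
  }
  as.numeric(v)
}

# Closed-form one-way ANOVA F test.
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  ss_between <- sum(tapply(values, groups, function(g) length(g) * (mean(g) - gm)^2))
  ss_within <- sum(tapply(values, groups, function(g) sum((g - mean(g))^2)))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Brute-force NB likelihood-ratio statistic at fixed dispersion phi, with
# library-size offsets, maximizing each group's log-mean numerically.
oracle_nb_lrt <- function(y, group, lib, phi) {
  size <- 1 / phi
  ll <- function(beta, yy, off) {
    mu <- exp(beta + off)
    sum(stats::dnbinom(yy, size = size, mu = mu, log = TRUE))
  }
  maximize <- function(yy, off) {
    stats::optimize(ll, c(-20, 20), yy = yy, off = off, maximum = TRUE,
                    tol = 1e-10)$objective
  }
  off <- log(lib)
  ll_full <- sum(vapply(levels(factor(group)), function(g) {
    i <- group == g
    maximize(y[i], off[i])
  }, numeric(1)))
  ll_null <- maximize(y, off)
  2 * (ll_full - ll_null)
}

# Area-weighted rebinning oracle: averages source cells into target cells by
# exact overlap areas on the continuous [0, n_src]^2 square.
oracle_rebin_2d <- function(sub, n_tgt) {
  n_src <- nrow(sub)
  w1 <- matrix(0, n_tgt, n_src)
  width <- n_src / n_tgt
  for (t in seq_len(n_tgt)) {
    for (s in seq_len(n_src)) {
      ov <- min(t * width, s) - max((t - 1) * width, s - 1)
      if (ov > 0) w1[t, s] <- ov
    }
  }
  w1 <- w1 / rowSums(w1)
  w1 %*% sub %*% t(w1)
}
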