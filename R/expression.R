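fpkm_cols <- function(df) grep("^fpkm_ZT[0-9]+_R[0-9]+$", names(df), value = TRUE)

expr_timepoints <- function(expr) {
  sort(unique(as.numeric(sub("^fpkm_ZT([0-9]+)_R[0-9]+$", "\\1", fpkm_cols(expr)))))
}

#' Read a replicated expression table
#'
#' Expected TSV columns: `gene_id, chrom, tss, strand` followed by
#' `fpkm_ZT<t>_R<r>` value columns.
#'
#' @param path TSV path.
#' @return An `expression_matrix` data.frame.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!length(fpkm_cols(df))) stop("no fpkm_ZT<t>_R<r> columns found")
  if (any(df[fpkm_cols(df)] < 0)) stop("negative FPKM value")
  structure(df, class = c("expression_matrix", "data.frame"))
}

#' Write an expression table
#' @param expr an `expression_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(as.data.frame(expr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Classify circadian genes from replicated expression
#'
#' Per gene, a one-way ANOVA on log2(FPKM + 1) across the sampled
#' timepoints tests for differential expression between at least one pair
#' of timepoints; p-values are Benjamini-Hochberg adjusted across genes and
#' a gene is circadian iff its q-value is below `q_threshold`. Circadian
#' genes get a phase (the timepoint of highest mean FPKM; ties go to the
#' smallest ZT with a flag) and a diel class: diurnal for phases in the
#' light half (ZT0, ZT6), nocturnal otherwise.
#'
#' @param expr an `expression_matrix` with >= 2 replicates per timepoint.
#' @param q_threshold q-value cutoff for the circadian call.
#' @return A `circadian_calls` data.frame: `gene_id`, `p`, `q`, `circadian`,
#'   `phase`, `diel`, `tie_flag` (plus gene metadata columns present in the
#'   input).
#' @export
classify_circadian <- function(expr, q_threshold = 0.01) {
  tps <- expr_timepoints(expr)
  cols <- fpkm_cols(expr)
  col_tp <- as.numeric(sub("^fpkm_ZT([0-9]+)_R[0-9]+$", "\\1", cols))
  if (min(table(col_tp)) < 2) stop("need >= 2 replicates per timepoint")
  vals <- log2(as.matrix(as.data.frame(expr)[, cols]) + 1)
  grp <- factor(col_tp)
  p <- apply(vals, 1, function(y) {
    if (stats::sd(y) == 0) return(1)
    fit <- stats::aov(y ~ grp)
    pv <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(pv)) 1 else pv
  })
  q <- stats::p.adjust(p, method = "BH")
  ph <- t(apply(as.matrix(as.data.frame(expr)[, cols]), 1, function(y) {
    means <- tapply(y, col_tp, mean)
    mx <- max(means)
    peak <- as.numeric(names(means))[means == mx]
    c(phase = min(peak), tie = as.numeric(length(peak) > 1))
  }))
  out <- data.frame(gene_id = expr$gene_id, p = p, q = q,
                    circadian = q < q_threshold,
                    phase = ph[, "phase"],
                    tie_flag = ph[, "tie"] > 0,
                    stringsAsFactors = FALSE)
  out$diel <- ifelse(out$phase %in% c(0, 6), "diurnal", "nocturnal")
  for (col in c("chrom", "tss", "strand")) {
    if (!is.null(expr[[col]])) out[[col]] <- expr[[col]]
  }
  rownames(out) <- NULL
  structure(out, class = c("circadian_calls", "data.frame"),
            q_threshold = q_threshold, timepoints = tps)
}

#' @export
print.circadian_calls <- function(x, ...) {
  cat("circadian_calls:", nrow(x), "genes,", sum(x$circadian), "circadian (q <",
      attr(x, "q_threshold"), ")\n")
  if (any(x$circadian)) {
    print(table(phase = x$phase[x$circadian]))
  }
  invisible(x)
}

#' Acrophase of a single gene
#'
#' The timepoint with the highest average FPKM; ties resolve to the
#' smallest ZT and are flagged.
#'
#' @param expr an `expression_matrix`.
#' @param gene gene ID.
#' @return List with `phase` (ZT hours) and `tie_flag`.
#' @export
assign_phase <- function(expr, gene) {
  i <- match(gene, expr$gene_id)
  if (is.na(i)) stop("gene not found: ", gene)
  cols <- fpkm_cols(expr)
  col_tp <- as.numeric(sub("^fpkm_ZT([0-9]+)_R[0-9]+$", "\\1", cols))
  y <- as.numeric(as.data.frame(expr)[i, cols])
  means <- tapply(y, col_tp, mean)
  mx <- max(means)
  peak <- as.numeric(names(means))[means == mx]
  list(phase = min(peak), tie_flag = length(peak) > 1)
}

#' Filter calls against an external gene list
#'
#' Supports intersecting the circadian set with an externally supplied list
#' (e.g. an intronic-oscillator resource); genes outside the list lose
#' their circadian flag.
#'
#' @param calls a `circadian_calls` data.frame.
#' @param gene_list character vector of gene IDs to keep circadian.
#' @return The filtered `circadian_calls`.
#' @export
filter_circadian_calls <- function(calls, gene_list) {
  calls$circadian <- calls$circadian & calls$gene_id %in% gene_list
  calls
}
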