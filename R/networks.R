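#' Build a promoter-promoter interaction graph
#'
#' Nodes are bait fragments participating in at least one significant
#' bait-bait interaction at the requested timepoint (or at any timepoint
#' for the union graph); edges are deduplicated unordered bait pairs with
#' their summed supporting read counts as the `support` edge attribute.
#' Unnamed baits get locus labels `uce_<chrom>_<start>` (the convention for
#' ultraconserved-element baits).
#'
#' @param table an [interaction_table()].
#' @param timepoint ZT hours, or `NULL` for the union over timepoints.
#' @param score_threshold significance cutoff on the per-timepoint score.
#' @return An [igraph::graph] with vertex attributes `name` (fragment ID as
#'   character) and `label`, and edge attribute `support`.
#' @export
build_graph <- function(table, timepoint = NULL, score_threshold = 5) {
  df <- as.data.frame(table)
  if (is.null(timepoint)) {
    tps <- table_timepoints(table)
    sig <- Reduce(`|`, lapply(tps, function(t) score_at(table, t) >= score_threshold))
    cc <- count_cols(df)
  } else {
    sig <- score_at(table, timepoint) >= score_threshold
    cc <- grep(sprintf("^count_ZT%d_R[0-9]+$", timepoint), names(df), value = TRUE)
  }
  bb <- df[df$is_bait_bait & sig & df$bait_frag != df$other_frag, , drop = FALSE]
  if (nrow(bb) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  support <- if (length(cc)) rowSums(bb[, cc, drop = FALSE]) else bb$N_reads
  a <- pmin(bb$bait_frag, bb$other_frag)
  b <- pmax(bb$bait_frag, bb$other_frag)
  agg <- stats::aggregate(support, by = list(a = a, b = b), FUN = sum)
  label_of <- function(frag) {
    nm <- df$bait_name[match(frag, df$bait_frag)]
    alt <- df$other_name[match(frag, df$other_frag)]
    nm[is.na(nm)] <- alt[is.na(nm)]
    miss <- is.na(nm)
    if (any(miss)) {
      i <- match(frag[miss], df$bait_frag)
      j <- match(frag[miss], df$other_frag)
      ch <- ifelse(is.na(i), df$other_chrom[j], df$bait_chrom[i])
      st <- ifelse(is.na(i), df$other_start[j], df$bait_start[i])
      nm[miss] <- sprintf("uce_%s_%d", sub("^chr", "", ch), as.integer(st))
    }
    nm
  }
  nodes <- sort(unique(c(agg$a, agg$b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(agg$a), to = as.character(agg$b),
               support = agg$x),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes), label = label_of(nodes)))
  igraph::simplify(g, edge.attr.comb = list(support = "sum"))
}

#' Drop small connected components
#' @param graph an igraph graph.
#' @param min_nodes components with fewer nodes are removed (the
#'   conventional display filter keeps components of 4+ nodes).
#' @return The filtered graph.
#' @export
filter_small_components <- function(graph, min_nodes = 4) {
  comp <- igraph::components(graph)
  keep <- which(comp$csize[comp$membership] >= min_nodes)
  igraph::induced_subgraph(graph, keep)
}

#' Z-score of circadian-circadian edges against node resampling
#'
#' Observed: edges with both endpoints circadian. Null: `n_iter` draws of
#' equally many nodes from the non-circadian node set, counting the edges
#' of each induced subgraph.
#'
#' @param graph an igraph graph (vertex names = fragment IDs).
#' @param circadian_nodes vertex names of circadian promoters.
#' @param n_iter resampling iterations.
#' @param seed RNG seed.
#' @return List with `observed`, `null_draws`, `null_mean`, `null_sd`, `z`,
#'   `empirical_p`, `degenerate`.
#' @export
circadian_edge_zscore <- function(graph, circadian_nodes, n_iter = 1000, seed = 1) {
  vn <- igraph::V(graph)$name
  circ <- intersect(as.character(circadian_nodes), vn)
  if (!length(circ)) stop("circadian node set empty on this graph")
  noncirc <- sort(setdiff(vn, circ))  # sorted: invariant to vertex order
  observed <- igraph::ecount(igraph::induced_subgraph(graph, circ))
  if (length(noncirc) < length(circ)) {
    return(list(observed = observed, null_draws = numeric(0),
                null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
                empirical_p = NA_real_, degenerate = TRUE))
  }
  nulls <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      igraph::ecount(igraph::induced_subgraph(graph, sample(noncirc, length(circ))))
    }, numeric(1))
  })
  degenerate <- stats::sd(nulls) == 0
  z <- if (!degenerate) (observed - mean(nulls)) / stats::sd(nulls) else NA_real_
  list(observed = observed, null_draws = nulls, null_mean = mean(nulls),
       null_sd = stats::sd(nulls), z = z,
       empirical_p = (1 + sum(nulls >= observed)) / (n_iter + 1),
       degenerate = degenerate)
}

#' Edge-support comparison: circadian vs resampled promoter pairs
#'
#' Read support of circadian-circadian edges versus the pooled support of
#' edges induced by equal-size resamples of non-circadian nodes, compared
#' with a Mann-Whitney rank-sum test.
#'
#' @inheritParams circadian_edge_zscore
#' @return List with `circadian_support`, `null_support`, `mannwhitney_p`,
#'   `degenerate`.
#' @export
edge_support_comparison <- function(graph, circadian_nodes, n_iter = 100, seed = 1) {
  vn <- igraph::V(graph)$name
  circ <- intersect(as.character(circadian_nodes), vn)
  noncirc <- sort(setdiff(vn, circ))
  sub <- igraph::induced_subgraph(graph, circ)
  circ_support <- igraph::E(sub)$support
  if (length(circ_support) == 0) {
    return(list(circadian_support = numeric(0), null_support = numeric(0),
                mannwhitney_p = NA_real_, degenerate = TRUE))
  }
  null_support <- with_seed(seed, {
    unlist(lapply(seq_len(n_iter), function(i) {
      s <- igraph::induced_subgraph(graph, sample(noncirc, min(length(circ), length(noncirc))))
      igraph::E(s)$support
    }))
  })
  degenerate <- length(null_support) == 0
  p <- if (degenerate) {
    NA_real_
  } else if (stats::sd(c(circ_support, null_support)) == 0) {
    1  # every edge has identical support: no difference to detect
  } else {
    suppressWarnings(stats::wilcox.test(circ_support, null_support,
                                        exact = FALSE)$p.value)
  }
  list(circadian_support = circ_support, null_support = null_support,
       mannwhitney_p = p, degenerate = degenerate)
}

#' Export a graph as an edge-list TSV
#' @param graph an igraph graph with `support` edge attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
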