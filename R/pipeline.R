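#' Validate a pipeline configuration
#'
#' A pipeline config is a list (or YAML file) with an optional `sim` block
#' of [sim_config()] overrides, an optional `paths` block (pre-computed
#' inputs: `expression` TSV, `interactions` canonical TSV, `matrices`
#' directory), stage parameter overrides (`alpha`, `q_threshold`, `fdr`,
#' `min_lfc`, `score_threshold`, `tad_window_bp`, `n_iter`), and a `seed`.
#' Every referenced path must exist before any stage runs.
#'
#' @param config list or path to a YAML file.
#' @return The normalized config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) config$seed <- 1L
  defaults <- list(alpha = 0.05, q_threshold = 0.01, fdr = 0.05, min_lfc = 1,
                   score_threshold = 5, tad_window_bp = 2e5, n_iter = 200)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  }
  config
}

#' Run the full circadian 3D-genome pipeline
#'
#' Executes the stages in dependency order — simulate (or ingest) ->
#' balance -> compartments -> TADs -> expression -> cTADs -> interactome ->
#' networks — and returns a run report whose JSON serialization is
#' byte-reproducible under a fixed seed. In synthetic mode (no `paths`
#' block) every stage is additionally scored against the planted truth.
#'
#' @param config pipeline config (list or YAML path); see
#'   [validate_pipeline_config()].
#' @param stages character vector of stages to run (default all).
#' @param out_dir optional directory for JSON/TSV outputs.
#' @return A `run_report` list with one section per executed stage.
#' @export
run_all <- function(config = list(), stages = c("compartments", "tads",
                                                "expression", "ctads",
                                                "interactome", "networks"),
                    out_dir = NULL) {
  config <- validate_pipeline_config(config)
  report <- list(parameters = config[c("seed", "alpha", "q_threshold", "fdr",
                                       "min_lfc", "score_threshold",
                                       "tad_window_bp", "n_iter")])
  warnings_log <- character()

  sim_args <- config$sim
  if (is.null(sim_args)) sim_args <- list()
  sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)
  truth <- simulate_truth(scfg)
  synthetic <- is.null(config$paths)

  expr <- if (!synthetic && !is.null(config$paths$expression)) {
    read_expression(config$paths$expression)
  } else simulate_expression(truth)
  ptable <- if (!synthetic && !is.null(config$paths$interactions)) {
    read_interactions(config$paths$interactions, "tsv_counts")
  } else simulate_pchic(truth)

  tps <- scfg$timepoints
  chroms <- truth$genome$chrom

  occ_result <- NULL
  tads_called <- NULL
  calls <- NULL
  dynamic <- NULL

  if ("compartments" %in% stages) {
    occ_bins_all <- list(); occ_regions <- list(); recovered <- c(tp = 0, fp = 0, fn = 0)
    for (ch in chroms) {
      mats <- lapply(tps, function(t) {
        lapply(seq_len(scfg$hic_replicates), function(r) {
          simulate_hic(truth, ch, t, r, bin_size = scfg$bin_size_compartment)
        })
      })
      act <- truth$activity[truth$activity$chrom == ch, ]
      track <- eigen_track_from_matrices(mats, act, tps)
      occ <- detect_occ(track, alpha = config$alpha)
      occ$bins$chrom <- ch
      occ_bins_all[[ch]] <- occ$bins
      if (nrow(occ$regions)) {
        occ$regions$chrom <- ch
        occ_regions[[ch]] <- occ$regions
      }
      truth_occ <- truth$bins$occ[truth$bins$chrom == ch]
      recovered <- recovered + c(
        tp = sum(occ$bins$oscillatory & truth_occ),
        fp = sum(occ$bins$oscillatory & !truth_occ),
        fn = sum(!occ$bins$oscillatory & truth_occ))
    }
    occ_bins <- do.call(rbind, occ_bins_all)
    occ_result <- list(
      bins = occ_bins,
      regions = if (length(occ_regions)) do.call(rbind, occ_regions) else NULL)
    bin_bp <- scfg$bin_size_compartment
    sens <- unname(recovered["tp"] / max(1, recovered["tp"] + recovered["fn"]))
    fdr_occ <- unname(recovered["fp"] / max(1, recovered["tp"] + recovered["fp"]))
    report$compartments <- list(
      n_bins = nrow(occ_bins),
      n_oscillatory_bins = sum(occ_bins$oscillatory),
      occ_span_bp = sum(occ_bins$oscillatory) * bin_bp,
      occ_genome_fraction = mean(occ_bins$oscillatory),
      category_counts = as.list(table(occ_bins$category[occ_bins$oscillatory])),
      recovery = list(sensitivity = sens, fdr = fdr_occ))
  }

  if ("tads" %in% stages) {
    tad_list <- list(); recov <- c(found = 0, total = 0)
    for (ch in chroms) {
      for (t in tps) {
        reps <- lapply(seq_len(scfg$hic_replicates), function(r) {
          simulate_hic(truth, ch, t, r, bin_size = scfg$bin_size_tad)
        })
        mm <- merge_replicates(reps)
        ins <- insulation_score(mm, config$tad_window_bp)
        thr <- mean(ins$score, na.rm = TRUE)
        tt <- call_tads(ins, threshold = thr)
        if (nrow(tt)) {
          tt$timepoint <- t
          tad_list[[paste(ch, t)]] <- tt
        }
        if (t == tps[1]) {
          true_b <- truth$tads$start[truth$tads$chrom == ch]
          true_b <- true_b[true_b > 0]
          true_bins <- true_b / scfg$bin_size_tad + 1
          called_b <- attr(tt, "boundaries")
          hit <- vapply(true_bins, function(b) any(abs(called_b - b) <= 1), logical(1))
          # boundaries inside the insulation mask cannot be called
          w <- ins$window_bins
          n_bins_ch <- length(ins$score)
          eligible <- true_bins > w & true_bins <= n_bins_ch - w
          recov <- recov + c(found = sum(hit[eligible]), total = sum(eligible))
        }
      }
    }
    tads_called <- do.call(rbind, tad_list)
    rownames(tads_called) <- NULL
    t0 <- tads_called[tads_called$timepoint == tps[1], , drop = FALSE]
    t2 <- tads_called[tads_called$timepoint == tps[3], , drop = FALSE]
    sh <- if (nrow(t0) && nrow(t2)) shared_tads(t0, t2) else NULL
    report$tads <- list(
      n_tads = nrow(tads_called),
      n_per_timepoint = as.list(table(tads_called$timepoint)),
      median_size_bp = stats::median(tads_called$end - tads_called$start),
      boundary_recovery = unname(recov["found"] / max(1, recov["total"])),
      shared_ZT0_ZT12 = if (!is.null(sh)) sh$n_shared / max(1, sh$n_total) else NA)
  }

  if ("expression" %in% stages) {
    calls <- classify_circadian(expr, q_threshold = config$q_threshold)
    truth_flag <- truth$genes$circadian[match(calls$gene_id, truth$genes$gene_id)]
    sens <- sum(calls$circadian & truth_flag) / max(1, sum(truth_flag))
    fdr_e <- sum(calls$circadian & !truth_flag) / max(1, sum(calls$circadian))
    phase_ok <- calls$circadian & truth_flag &
      calls$phase == truth$genes$phase[match(calls$gene_id, truth$genes$gene_id)]
    report$expression <- list(
      n_genes = nrow(calls),
      n_circadian = sum(calls$circadian),
      phase_histogram = as.list(table(calls$phase[calls$circadian])),
      recovery = list(sensitivity = sens, fdr = fdr_e,
                      phase_accuracy = sum(phase_ok) / max(1, sum(calls$circadian & truth_flag))))
  }

  if ("ctads" %in% stages) {
    if (is.null(calls)) calls <- classify_circadian(expr, q_threshold = config$q_threshold)
    ct <- classify_ctads(truth$tads, calls)
    freqs <- phase_frequencies(calls)
    ps <- phase_sharing(ct, freqs)
    occ_df <- if (!is.null(occ_result) && !is.null(occ_result$regions)) {
      occ_result$regions[, c("chrom", "start", "end")]
    } else {
      truth$bins[truth$bins$occ, c("chrom", "start", "end")]
    }
    ctads_df <- ct$tads[ct$tads$is_ctad, , drop = FALSE]
    non_df <- ct$tads[!ct$tads$is_ctad, , drop = FALSE]
    ov <- if (nrow(ctads_df) > 0 && nrow(non_df) >= nrow(ctads_df)) {
      occ_overlap_test(ctads_df, non_df, occ_df,
                       n_iter = config$n_iter, seed = derive_seed(config$seed, "ctadocc"))
    } else NULL
    report$ctads <- list(
      n_ctads = sum(ct$tads$is_ctad),
      mean_genes_per_tad = mean(ct$tads$n_genes),
      phase_sharing = lapply(seq_len(nrow(ps)), function(i) as.list(ps[i, ])),
      occ_overlap = if (!is.null(ov)) list(observed = ov$observed, z = ov$z,
                                           empirical_p = ov$empirical_p) else NULL)
  }

  if ("interactome" %in% stages) {
    if (is.null(calls)) calls <- classify_circadian(expr, q_threshold = config$q_threshold)
    circ_baits <- truth$genes$frag_id[truth$genes$gene_id %in%
                                        calls$gene_id[calls$circadian]]
    dynamic <- classify_dynamic(ptable, fdr = config$fdr, min_lfc = config$min_lfc,
                                bait_filter = circ_baits)
    truth_class <- ptable$class[dynamic$row]
    power <- if (any(truth_class == "dynamic")) {
      mean(dynamic$class[truth_class == "dynamic"] == "dynamic")
    } else NA
    cpt <- tryCatch(contacts_per_timepoint(ptable, calls,
                                           score_threshold = config$score_threshold),
                    error = function(e) NULL)
    enr <- matched_null_enrichment(ptable, truth$planted_features, truth$fragmap,
                                   n_iter = max(100, config$n_iter %/% 2),
                                   seed = derive_seed(config$seed, "enrich"))
    osc <- truth$enhancers[truth$enhancers$oscillatory, ]
    nonosc <- truth$enhancers[!truth$enhancers$oscillatory, ]
    ern <- if (nrow(nonosc) >= nrow(osc)) {
      erna_contact_enrichment(ptable, osc, nonosc, circ_baits,
                              n_iter = 100, seed = derive_seed(config$seed, "erna"))
    } else NULL
    targets <- data.frame(frag_id = truth$enhancers$frag_id,
                          phase_hr = truth$enhancers$phase_hr)
    pc <- phase_coherence(ptable, calls, targets, "hr8x3")
    ccc <- tryCatch(
      coreclock_comparison(ptable, calls, dynamic,
                           core_list = utils::head(calls$gene_id[calls$circadian], 10),
                           n_iter = config$n_iter,
                           seed = derive_seed(config$seed, "coreclock")),
      error = function(e) NULL)
    report$interactome <- list(
      n_tested = nrow(dynamic),
      n_dynamic = sum(dynamic$class == "dynamic"),
      n_stable = sum(dynamic$class == "stable"),
      dynamic_power = power,
      peak_phase_chi2_p = if (!is.null(cpt)) cpt$p else NA,
      enrichment_ratio = enr$ratio,
      enrichment_t_p = enr$t_p,
      erna_ratio = if (!is.null(ern)) ern$ratio else NA,
      phase_coherence_p = pc$wilcoxon_p)
  }

  if ("networks" %in% stages) {
    if (is.null(calls)) calls <- classify_circadian(expr, q_threshold = config$q_threshold)
    g <- build_graph(ptable, timepoint = NULL,
                     score_threshold = config$score_threshold)
    gf <- filter_small_components(g)
    circ_nodes <- as.character(truth$genes$frag_id[truth$genes$gene_id %in%
                                                     calls$gene_id[calls$circadian]])
    z <- tryCatch(circadian_edge_zscore(g, circ_nodes, n_iter = config$n_iter,
                                        seed = derive_seed(config$seed, "netz")),
                  error = function(e) NULL)
    es <- edge_support_comparison(g, circ_nodes, n_iter = 100,
                                  seed = derive_seed(config$seed, "netsupport"))
    report$networks <- list(
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
      n_nodes_filtered = igraph::vcount(gf),
      circadian_edge_z = if (!is.null(z)) z$z else NA,
      circadian_edge_p = if (!is.null(z)) z$empirical_p else NA,
      edge_support_p = es$mannwhitney_p)
  }

  report$warnings <- warnings_log
  report <- structure(report, class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_report(report, file.path(out_dir, "run_report.json"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' The serialization contains no timestamps, so identical seeded runs give
#' byte-identical files.
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  clean <- report
  if (!is.null(clean$compartments)) {
    clean$compartments$bins <- NULL
  }
  json <- jsonlite::toJSON(unclass(clean), auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null", force = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report with sections:",
      paste(setdiff(names(x), c("parameters", "warnings")), collapse = ", "), "\n")
  if (!is.null(x$compartments)) {
    cat(sprintf("  compartments: %.1f%% of bins oscillatory (sens %.2f, FDR %.2f)\n",
                100 * x$compartments$occ_genome_fraction,
                x$compartments$recovery$sensitivity, x$compartments$recovery$fdr))
  }
  if (!is.null(x$tads)) {
    cat(sprintf("  tads: %d called, boundary recovery %.2f\n",
                x$tads$n_tads, x$tads$boundary_recovery))
  }
  if (!is.null(x$expression)) {
    cat(sprintf("  expression: %d circadian genes (sens %.2f)\n",
                x$expression$n_circadian, x$expression$recovery$sensitivity))
  }
  if (!is.null(x$interactome)) {
    cat(sprintf("  interactome: %d dynamic / %d stable\n",
                x$interactome$n_dynamic, x$interactome$n_stable))
  }
  if (!is.null(x$networks)) {
    cat(sprintf("  networks: %d nodes, %d edges, circadian z %.2f\n",
                x$networks$n_nodes, x$networks$n_edges,
                x$networks$circadian_edge_z))
  }
  invisible(x)
}
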