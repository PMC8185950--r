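#' Configuration for the synthetic multi-timepoint generator
#'
#' Defaults describe the emulated study design: 4 Zeitgeber timepoints
#' (ZT0/6/12/18), 3 Hi-C replicates, 4 RNA replicates, plaid compartment
#' structure with a fraction of bins switching A/B label over the day,
#' time-invariant TAD blocks, cosine circadian expression with phases at the
#' sampled ZTs, capture interaction counts with negative-binomial noise and
#' planted stable vs dynamic (phase-locked) contacts, and enhancers carrying
#' hourly eRNA phases. The toy genome (2 chromosomes x 20 Mb) keeps every
#' downstream stage fast while leaving hundreds of bins per chromosome.
#'
#' @param seed root seed; all stage seeds are derived from it.
#' @param n_chrom,chrom_length genome shape.
#' @param bin_size_compartment,bin_size_tad Hi-C bin sizes (bp) used for
#'   compartment and TAD matrices.
#' @param fragment_mean mean restriction-fragment length (bp).
#' @param timepoints sampled ZT hours.
#' @param hic_replicates,rna_replicates replicates per timepoint.
#' @param depth Hi-C sequencing-depth scaler (expected counts multiplier).
#' @param occ_fraction fraction of compartment bins that switch label.
#' @param compartment_contrast plaid contrast delta >= 0: same-compartment
#'   contacts are enriched by (1 + delta).
#' @param tad_enrichment within-TAD contact enrichment tau >= 1.
#' @param decay_exponent distance-decay exponent alpha.
#' @param dispersion negative-binomial dispersion phi of capture counts.
#' @param n_genes,circadian_fraction,phase_probs gene model; `phase_probs`
#'   are probabilities over the sampled ZTs.
#' @param amplitude relative cosine amplitude A of circadian expression.
#' @param expr_sigma lognormal noise sd on expression.
#' @param baseline_fpkm median baseline expression.
#' @param n_enhancers,osc_enhancer_fraction enhancer (eRNA) resource;
#'   oscillatory enhancers carry hourly phases 0..23.
#' @param fraction_dynamic_contacts,dynamic_fold planted contact dynamics:
#'   dynamic contacts are phase-locked, with mean multiplied by
#'   `dynamic_fold` at their peak timepoint.
#' @param pchic_mean baseline capture-count mean per replicate.
#' @param n_background background (non-significant) interaction records.
#' @param n_enh_contacts enhancer contacts planted per circadian gene.
#' @param n_pp_circadian same-diel promoter-promoter contacts planted per
#'   circadian gene.
#' @param n_pp_background random promoter-promoter contacts per gene.
#' @param pp_support_fold read-support multiplier on circadian
#'   promoter-promoter edges.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2, chrom_length = 20e6,
                       bin_size_compartment = 1e5, bin_size_tad = 5e4,
                       fragment_mean = 4000,
                       timepoints = c(0, 6, 12, 18),
                       hic_replicates = 3, rna_replicates = 4,
                       depth = 20,
                       occ_fraction = 0.2,
                       compartment_contrast = 1,
                       tad_enrichment = 3,
                       decay_exponent = 1,
                       dispersion = 0.1,
                       n_genes = 300, circadian_fraction = 0.3,
                       phase_probs = c(0.25, 0.25, 0.25, 0.25),
                       amplitude = 1, expr_sigma = 0.2, baseline_fpkm = 10,
                       n_enhancers = 200, osc_enhancer_fraction = 0.5,
                       fraction_dynamic_contacts = 0.3, dynamic_fold = 4,
                       pchic_mean = 30, n_background = 300,
                       n_enh_contacts = 4, n_pp_circadian = 2,
                       n_pp_background = 1, pp_support_fold = 1.5) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$phase_probs) - 1) > 1e-8) stop("phase_probs must sum to 1")
  for (f in c("occ_fraction", "circadian_fraction", "osc_enhancer_fraction",
              "fraction_dynamic_contacts")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  }
  if (cfg$compartment_contrast < 0) stop("compartment_contrast must be >= 0")
  if (cfg$amplitude < 0) stop("amplitude must be >= 0")
  if (cfg$tad_enrichment < 1) stop("tad_enrichment must be >= 1")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

# Derive a stable 31-bit stage seed from the root seed and a label chain.
derive_seed <- function(root, ...) {
  parts <- paste(c(root, ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(parts)) h <- (h * 131 + code) %% 2147483647
  as.integer((h + as.integer(root)) %% 2147483647) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

ALL_CATEGORIES <- apply(expand.grid(rep(list(c("A", "B")), 4))[, 4:1], 1, paste, collapse = "")
MIXED_CATEGORIES <- setdiff(ALL_CATEGORIES, c("AAAA", "BBBB"))

#' Simulate the planted architecture ground truth
#'
#' Draws, deterministically under the config seed: per-bin A/B labels per
#' timepoint (with an `occ_fraction` of bins switching), time-invariant TAD
#' boundaries, a restriction-fragment map, genes with TSS at fragment starts
#' inside TADs (circadian genes preferentially in bins that are A at their
#' phase), phased enhancers, and planted capture interactions
#' (promoter-enhancer and promoter-promoter; stable or dynamic with a peak
#' timepoint equal to the gene's phase).
#'
#' @param config a [sim_config()].
#' @return An `architecture_truth` list: `config`, `genome`, `bins`
#'   (chrom/start/end plus one label column per ZT and `occ` flag), `tads`,
#'   `fragmap`, `genes`, `enhancers`, `interactions` (planted contacts with
#'   `class` and `peak_zt`), `activity` (gene-openness covariate track) and
#'   `planted_features` (marks covering half the true other-ends).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "truth"), {
    tp <- config$timepoints
    genome <- genome_def(paste0("chr", seq_len(config$n_chrom)),
                         rep(config$chrom_length, config$n_chrom))

    ## compartment bins: plaid base blocks, then per-bin OCC switching
    bins <- do.call(rbind, lapply(genome$chrom, function(ch) {
      n <- ceiling(config$chrom_length / config$bin_size_compartment)
      data.frame(chrom = ch,
                 start = (seq_len(n) - 1) * config$bin_size_compartment,
                 end = pmin(seq_len(n) * config$bin_size_compartment, config$chrom_length),
                 stringsAsFactors = FALSE)
    }))
    n_bins <- nrow(bins)
    base <- character(n_bins)
    for (ch in genome$chrom) {
      i <- which(bins$chrom == ch)
      lab <- "A"
      j <- 1
      while (j <= length(i)) {
        run <- min(3 + stats::rgeom(1, 1 / 5), length(i) - j + 1)
        base[i[j:(j + run - 1)]] <- lab
        lab <- if (lab == "A") "B" else "A"
        j <- j + run
      }
    }
    occ <- stats::runif(n_bins) < config$occ_fraction
    labels <- matrix(rep(base, length(tp)), ncol = length(tp))
    colnames(labels) <- paste0("ZT", tp)
    if (any(occ)) {
      cats <- sample(MIXED_CATEGORIES, sum(occ), replace = TRUE)
      labels[occ, ] <- t(vapply(strsplit(cats, ""), identity, character(length(tp))))
    }
    bins <- cbind(bins, as.data.frame(labels, stringsAsFactors = FALSE))
    bins$occ <- occ

    ## time-invariant TADs on the TAD-bin grid
    tads <- do.call(rbind, lapply(genome$chrom, function(ch) {
      len <- config$chrom_length
      bounds <- 0
      while (bounds[length(bounds)] < len) {
        size <- sample(6:20, 1) * config$bin_size_tad  # 300 kb - 1 Mb
        bounds <- c(bounds, min(bounds[length(bounds)] + size, len))
      }
      data.frame(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1],
                 stringsAsFactors = FALSE)
    }))
    tads$tad_id <- seq_len(nrow(tads))

    ## restriction fragments tiling each chromosome
    cut_sites <- lapply(genome$chrom, function(ch) {
      n_draw <- ceiling(config$chrom_length / config$fragment_mean * 1.5) + 10
      gaps <- pmax(500, round(stats::rgamma(n_draw, shape = 4,
                                            scale = config$fragment_mean / 4)))
      cuts <- cumsum(gaps)
      while (cuts[length(cuts)] < config$chrom_length) {
        more <- pmax(500, round(stats::rgamma(n_draw, shape = 4,
                                              scale = config$fragment_mean / 4)))
        cuts <- c(cuts, cuts[length(cuts)] + cumsum(more))
      }
      cuts[cuts < config$chrom_length]
    })
    names(cut_sites) <- genome$chrom
    fragmap <- restriction_map(genome, cut_sites)

    ## genes: TSS at fragment starts; circadian ones prefer A-at-phase bins
    n_circ <- round(config$n_genes * config$circadian_fraction)
    circadian <- c(rep(TRUE, n_circ), rep(FALSE, config$n_genes - n_circ))
    phase <- rep(NA_real_, config$n_genes)
    phase[circadian] <- sample(tp, n_circ, replace = TRUE, prob = config$phase_probs)
    pick_tss <- function(want_A_at) {
      for (try in 1:50) {
        fr <- fragmap[sample(nrow(fragmap), 1), ]
        tss <- fr$start
        bi <- which(bins$chrom == fr$chrom &
                      bins$start <= tss & tss < bins$end)
        in_tad <- any(tads$chrom == fr$chrom & tads$start <= tss & tss < tads$end)
        if (!in_tad || !length(bi)) next
        if (is.na(want_A_at)) {
          if (stats::runif(1) < 0.7 ||
              mean(labels[bi, ] == "A") > 0.5) return(c(fr$frag_id, tss, bi))
        } else if (labels[bi, paste0("ZT", want_A_at)] == "A") {
          return(c(fr$frag_id, tss, bi))
        }
      }
      fr <- fragmap[sample(nrow(fragmap), 1), ]
      bi <- which(bins$chrom == fr$chrom & bins$start <= fr$start & fr$start < bins$end)
      c(fr$frag_id, fr$start, bi[1])
    }
    placement <- t(vapply(seq_len(config$n_genes),
                          function(g) pick_tss(phase[g]), numeric(3)))
    genes <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
      frag_id = as.integer(placement[, 1]),
      tss = placement[, 2],
      bin = as.integer(placement[, 3]),
      chrom = fragmap$chrom[match(placement[, 1], fragmap$frag_id)],
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      circadian = circadian,
      phase = phase,
      baseline = config$baseline_fpkm * exp(stats::rnorm(config$n_genes, 0, 0.5)),
      stringsAsFactors = FALSE
    )

    ## enhancers with hourly eRNA phases
    e_chrom <- sample(genome$chrom, config$n_enhancers, replace = TRUE)
    e_start <- floor(stats::runif(config$n_enhancers, 0, config$chrom_length - 2000))
    oscillatory <- stats::runif(config$n_enhancers) < config$osc_enhancer_fraction
    enhancers <- data.frame(
      chrom = e_chrom, start = e_start, end = e_start + 1500,
      name = sprintf("enh%03d", seq_len(config$n_enhancers)),
      strand = ".",
      phase_hr = ifelse(oscillatory,
                        sample(0:23, config$n_enhancers, replace = TRUE), NA_real_),
      oscillatory = oscillatory,
      stringsAsFactors = FALSE
    )
    enhancers$frag_id <- resolve_fragment_row(fragmap, enhancers$chrom,
                                              enhancers$start, enhancers$end)

    ## planted interactions
    baits <- sort(unique(genes$frag_id))
    circ_hours <- function(a, b) pmin((a - b) %% 24, (b - a) %% 24)
    planted <- list()
    add <- function(bait, other, class, peak, kind) {
      planted[[length(planted) + 1]] <<- data.frame(
        bait_frag = bait, other_frag = other, class = class,
        peak_zt = peak, kind = kind, stringsAsFactors = FALSE)
    }
    osc_enh <- enhancers[enhancers$oscillatory, ]
    for (g in seq_len(nrow(genes))) {
      gene <- genes[g, ]
      if (gene$circadian) {
        # enhancer contacts, phase-assortative
        pool <- osc_enh[osc_enh$chrom == gene$chrom &
                          circ_hours(osc_enh$phase_hr, gene$phase) <= 3, ]
        if (nrow(pool) == 0) pool <- osc_enh[osc_enh$chrom == gene$chrom, ]
        if (nrow(pool) > 0) {
          pick <- pool[sample(nrow(pool), min(config$n_enh_contacts, nrow(pool))), ]
          for (k in seq_len(nrow(pick))) {
            dyn <- stats::runif(1) < config$fraction_dynamic_contacts
            add(gene$frag_id, pick$frag_id[k],
                if (dyn) "dynamic" else "stable",
                if (dyn) gene$phase else NA_real_, "enhancer")
          }
        }
        # same-diel promoter-promoter contacts
        diel <- gene$phase %in% c(0, 6)
        mates <- genes[genes$circadian & genes$gene_id != gene$gene_id &
                         (genes$phase %in% c(0, 6)) == diel, ]
        if (nrow(mates) > 0) {
          pick <- mates[sample(nrow(mates), min(config$n_pp_circadian, nrow(mates))), ]
          for (k in seq_len(nrow(pick))) {
            add(gene$frag_id, pick$frag_id[k], "stable", NA_real_, "promoter")
          }
        }
      }
      # background promoter-promoter wiring for every gene
      others <- genes$frag_id[genes$gene_id != gene$gene_id]
      if (config$n_pp_background > 0 && length(others) > 0) {
        for (of in sample(others, config$n_pp_background)) {
          add(gene$frag_id, of, "stable", NA_real_, "promoter_bg")
        }
      }
    }
    interactions <- do.call(rbind, planted)
    # deduplicate unordered pairs, keeping the first (most specific) record
    key <- paste(pmin(interactions$bait_frag, interactions$other_frag),
                 pmax(interactions$bait_frag, interactions$other_frag))
    interactions <- interactions[!duplicated(key), ]
    rownames(interactions) <- NULL

    ## activity covariate: gene-openness per compartment bin (emulates an
    ## active-chromatin coverage track: high where bins are mostly A)
    openness <- rowMeans(labels == "A")
    activity <- coverage_track(data.frame(
      chrom = bins$chrom, start = bins$start, end = bins$end,
      value = openness + 2 * tabulate(genes$bin, nbins = n_bins) +
        stats::rnorm(n_bins, 0, 0.05)))

    ## planted feature map: marks covering half the unique other-ends
    oe <- unique(interactions$other_frag)
    half <- sample(oe, floor(length(oe) / 2))
    fi <- match(half, fragmap$frag_id)
    planted_features <- feature_set(data.frame(
      chrom = fragmap$chrom[fi], start = fragmap$start[fi], end = fragmap$end[fi],
      name = sprintf("mark%03d", seq_along(fi)), strand = ".",
      phase_hr = NA_real_, stringsAsFactors = FALSE), "planted_marks")

    structure(list(config = config, genome = genome, bins = bins, tads = tads,
                   fragmap = fragmap, genes = genes, enhancers = enhancers,
                   interactions = interactions, baits = baits,
                   activity = activity, planted_features = planted_features),
              class = "architecture_truth")
  })
}

#' @export
print.architecture_truth <- function(x, ...) {
  cat("architecture_truth:", nrow(x$genome), "chrom,", nrow(x$bins), "bins (",
      sum(x$bins$occ), "OCC ),", nrow(x$tads), "TADs,", nrow(x$genes), "genes (",
      sum(x$genes$circadian), "circadian ),", nrow(x$interactions),
      "planted contacts\n")
  invisible(x)
}

bin_index_of <- function(pos, bin_size) floor(pos / bin_size) + 1L

# per-bin compartment label and TAD id on an arbitrary bin grid
grid_annotation <- function(truth, chrom, bin_size) {
  len <- chrom_length(truth$genome, chrom)
  n <- ceiling(len / bin_size)
  mid <- (seq_len(n) - 0.5) * bin_size
  cb <- truth$bins[truth$bins$chrom == chrom, , drop = FALSE]
  ci <- pmin(bin_index_of(mid, truth$config$bin_size_compartment), nrow(cb))
  labels <- as.matrix(cb[ci, paste0("ZT", truth$config$timepoints)])
  td <- truth$tads[truth$tads$chrom == chrom, , drop = FALSE]
  tad_id <- rep(NA_integer_, n)
  hit <- findInterval(mid, td$start)
  ok <- hit >= 1 & mid < td$end[pmax(hit, 1L)]
  tad_id[ok] <- td$tad_id[hit[ok]]
  list(n = n, labels = labels, tad_id = tad_id)
}

#' Simulate one Hi-C contact matrix
#'
#' Expected contacts follow a power-law distance decay modulated by the
#' planted plaid and domain structure:
#' `mu_ij = (1+|i-j|)^(-alpha) * (1 + delta * same_compartment_t) *
#' (tau if same TAD else 1)`, with counts drawn Poisson(depth * mu) and
#' symmetrized.
#'
#' @param truth an [simulate_truth()] result.
#' @param chrom chromosome to simulate.
#' @param timepoint ZT hours (must be one of the config timepoints).
#' @param replicate replicate index.
#' @param bin_size bin size (bp); defaults to the compartment bin size.
#' @param depth depth scaler; defaults to the config depth.
#' @param seed RNG seed; defaults to a seed derived from the config seed and
#'   the (chrom, timepoint, replicate, bin_size) coordinates.
#' @return A [contact_matrix()].
#' @export
simulate_hic <- function(truth, chrom, timepoint, replicate,
                         bin_size = truth$config$bin_size_compartment,
                         depth = truth$config$depth, seed = NULL) {
  cfg <- truth$config
  if (!timepoint %in% cfg$timepoints) stop("timepoint not simulated: ", timepoint)
  if (depth < 0) stop("depth must be >= 0")
  if (is.null(seed)) {
    seed <- derive_seed(cfg$seed, "hic", chrom, timepoint, replicate, bin_size)
  }
  ann <- grid_annotation(truth, chrom, bin_size)
  n <- ann$n
  lab <- ann$labels[, paste0("ZT", timepoint)]
  with_seed(seed, {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    mu <- (1 + d)^(-cfg$decay_exponent)
    same_comp <- outer(lab, lab, "==")
    mu <- mu * (1 + cfg$compartment_contrast * same_comp)
    same_tad <- outer(ann$tad_id, ann$tad_id, "==")
    same_tad[is.na(same_tad)] <- FALSE
    mu <- mu * ifelse(same_tad, cfg$tad_enrichment, 1)
    up <- upper.tri(mu, diag = TRUE)
    counts <- matrix(0, n, n)
    counts[up] <- stats::rpois(sum(up), depth * mu[up])
    counts <- counts + t(counts) - diag(diag(counts))
    contact_matrix(counts, chrom = chrom, bin_size = bin_size,
                   timepoint = timepoint, replicate = replicate)
  })
}

#' Simulate the replicated expression table
#'
#' Circadian genes follow `baseline * (1 + A*cos(2*pi*(t - phase)/24))`;
#' flat genes stay at baseline. Noise is multiplicative lognormal with the
#' mean-one correction, so sample means converge to the model means.
#'
#' @param truth an [simulate_truth()] result.
#' @param rna_replicates number of replicates; defaults to config.
#' @param sigma lognormal noise sd; defaults to config.
#' @param seed RNG seed (derived from the config seed by default).
#' @return An `expression_matrix`: data.frame with gene metadata columns
#'   (`gene_id,chrom,tss,strand`) and `fpkm_ZT<t>_R<r>` value columns.
#' @export
simulate_expression <- function(truth, rna_replicates = truth$config$rna_replicates,
                                sigma = truth$config$expr_sigma, seed = NULL) {
  cfg <- truth$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "expression")
  genes <- truth$genes
  with_seed(seed, {
    out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                      tss = genes$tss, strand = genes$strand,
                      stringsAsFactors = FALSE)
    for (t in cfg$timepoints) {
      mean_t <- ifelse(genes$circadian,
                       genes$baseline *
                         pmax(0, 1 + cfg$amplitude * cos(2 * pi * (t - genes$phase) / 24)),
                       genes$baseline)
      for (r in seq_len(rna_replicates)) {
        noise <- exp(stats::rnorm(nrow(genes), -sigma^2 / 2, sigma))
        out[[sprintf("fpkm_ZT%d_R%d", t, r)]] <- mean_t * noise
      }
    }
    structure(out, class = c("expression_matrix", "data.frame"))
  })
}

#' Simulate the capture Hi-C interaction table
#'
#' Planted interactions get negative-binomial replicate counts: stable
#' contacts keep a constant mean across timepoints, dynamic contacts have
#' their mean multiplied by `dynamic_fold` at their peak timepoint.
#' Significance scores are set so planted contacts pass the conventional
#' score-5 cutoff at their active timepoints (all ZTs for stable, the peak
#' for dynamic); background records stay below it.
#'
#' @param truth an [simulate_truth()] result.
#' @param seed RNG seed (derived from the config seed by default).
#' @return An [interaction_table()] with per-(timepoint, replicate) counts,
#'   per-timepoint scores and a `class` column carrying the planted truth.
#' @export
simulate_pchic <- function(truth, seed = NULL) {
  cfg <- truth$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "pchic")
  fragmap <- truth$fragmap
  with_seed(seed, {
    pl <- truth$interactions
    ## background pairs by distance decay
    if (cfg$n_background > 0) {
      b <- sample(truth$baits, cfg$n_background, replace = TRUE)
      bi <- match(b, fragmap$frag_id)
      offs <- sample(c(-1, 1), cfg$n_background, replace = TRUE) *
        round(stats::rexp(cfg$n_background, 1 / 2e5) + 2e4)
      target_mid <- frag_mid(fragmap, b) + offs
      target_mid <- pmin(pmax(target_mid, 1), chrom_length(truth$genome, fragmap$chrom[bi]) - 1)
      of <- vapply(seq_len(cfg$n_background), function(i) {
        locate_fragment(fragmap, fragmap$chrom[bi[i]], target_mid[i])
      }, integer(1))
      bg <- data.frame(bait_frag = b, other_frag = of, class = "background",
                       peak_zt = NA_real_, kind = "background",
                       stringsAsFactors = FALSE)
      bg <- bg[bg$bait_frag != bg$other_frag, ]
      pl <- rbind(pl, bg)
    }
    key <- paste(pmin(pl$bait_frag, pl$other_frag),
                 pmax(pl$bait_frag, pl$other_frag))
    pl <- pl[!duplicated(key), ]

    bi <- match(pl$bait_frag, fragmap$frag_id)
    oi <- match(pl$other_frag, fragmap$frag_id)
    df <- data.frame(
      bait_frag = pl$bait_frag, other_frag = pl$other_frag,
      bait_chrom = fragmap$chrom[bi], bait_start = fragmap$start[bi],
      bait_end = fragmap$end[bi],
      bait_name = truth$genes$gene_id[match(pl$bait_frag, truth$genes$frag_id)],
      other_chrom = fragmap$chrom[oi], other_start = fragmap$start[oi],
      other_end = fragmap$end[oi],
      other_name = NA_character_,
      stringsAsFactors = FALSE
    )
    base_mean <- ifelse(pl$class == "background", cfg$pchic_mean / 6, cfg$pchic_mean)
    # circadian promoter-promoter edges carry boosted read support
    circ_frags <- truth$genes$frag_id[truth$genes$circadian]
    pp_circ <- pl$kind == "promoter" & pl$bait_frag %in% circ_frags &
      pl$other_frag %in% circ_frags
    base_mean[pp_circ] <- base_mean[pp_circ] * cfg$pp_support_fold
    size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
    for (t in cfg$timepoints) {
      mu_t <- base_mean * ifelse(pl$class == "dynamic" & !is.na(pl$peak_zt) &
                                   pl$peak_zt == t, cfg$dynamic_fold, 1)
      for (r in seq_len(cfg$hic_replicates)) {
        df[[sprintf("count_ZT%d_R%d", t, r)]] <-
          if (is.finite(size)) stats::rnbinom(nrow(pl), mu = mu_t, size = size)
          else stats::rpois(nrow(pl), mu_t)
      }
      active <- (pl$class == "stable") |
        (pl$class == "dynamic" & !is.na(pl$peak_zt) & pl$peak_zt == t)
      df[[sprintf("score_ZT%d", t)]] <- ifelse(active,
                                               stats::runif(nrow(pl), 6, 12),
                                               stats::runif(nrow(pl), 0, 4.5))
    }
    df$score <- do.call(pmax, df[score_cols(df)])
    df$N_reads <- rowSums(df[, count_cols(df), drop = FALSE])
    tab <- interaction_table(df, baits = truth$baits)
    tab$class <- pl$class
    tab$peak_zt <- pl$peak_zt
    tab
  })
}
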