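ZT_DEFAULT <- c(0, 6, 12, 18)

count_cols <- function(df) grep("^count_ZT[0-9]+_R[0-9]+$", names(df), value = TRUE)
score_cols <- function(df) grep("^score_ZT[0-9]+$", names(df), value = TRUE)

interaction_core_cols <- c(
  "bait_frag", "other_frag", "bait_chrom", "bait_start", "bait_end", "bait_name",
  "other_chrom", "other_start", "other_end", "other_name",
  "is_bait_bait", "distance_bp", "N_reads", "score"
)

#' Construct a capture Hi-C interaction table
#'
#' Canonical container for bait/other-end records. Per-sample replicate
#' counts live in columns `count_ZT<t>_R<r>`; per-timepoint interaction
#' scores (the capture pipeline's significance score, conventionally
#' significant at >= 5) in `score_ZT<t>`. `distance_bp` is the
#' midpoint-to-midpoint separation for cis records and `NA` for trans.
#'
#' @param df data.frame carrying at least `bait_frag`, `other_frag`,
#'   `bait_chrom`, `bait_start`, `bait_end`, `other_chrom`, `other_start`,
#'   `other_end`; missing optional columns are filled.
#' @param baits bait fragment universe (integer IDs); defaults to the baits
#'   present in `df`.
#' @return An `interaction_table` (data.frame subclass) with attribute
#'   `baits`.
#' @export
interaction_table <- function(df, baits = NULL) {
  n <- nrow(df)
  if (is.null(df$bait_name)) df$bait_name <- rep(NA_character_, n)
  if (is.null(df$other_name)) df$other_name <- rep(NA_character_, n)
  if (is.null(df$N_reads)) df$N_reads <- rep(0, n)
  if (is.null(df$score)) df$score <- rep(0, n)
  if (is.null(df$distance_bp)) {
    cis <- df$bait_chrom == df$other_chrom
    mid_b <- (df$bait_start + df$bait_end) / 2
    mid_o <- (df$other_start + df$other_end) / 2
    df$distance_bp <- ifelse(cis, abs(mid_b - mid_o), NA_real_)
  }
  if (is.null(baits)) baits <- sort(unique(df$bait_frag))
  if (nrow(df) > 0 && !all(df$bait_frag %in% baits)) {
    stop("bait fragment outside declared bait universe")
  }
  if (is.null(df$is_bait_bait)) df$is_bait_bait <- df$other_frag %in% baits
  cc <- count_cols(df)
  if (length(cc) && any(df[cc] < 0)) stop("negative replicate count")
  if (any(!is.na(df$distance_bp) & df$distance_bp < 0)) stop("negative distance")
  keep <- c(interaction_core_cols, score_cols(df), cc)
  df <- df[, intersect(keep, names(df)), drop = FALSE]
  structure(df, class = c("interaction_table", "data.frame"), baits = baits)
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("interaction_table:", nrow(x), "records,",
      length(attr(x, "baits")), "baits,",
      sum(x$is_bait_bait), "bait-bait,",
      sum(is.na(x$distance_bp)), "trans\n")
  invisible(x)
}

table_timepoints <- function(table) {
  cc <- count_cols(table)
  if (!length(cc)) return(ZT_DEFAULT)
  sort(unique(as.numeric(sub("^count_ZT([0-9]+)_R[0-9]+$", "\\1", cc))))
}

table_replicates <- function(table) {
  cc <- count_cols(table)
  if (!length(cc)) return(integer())
  sort(unique(as.integer(sub("^count_ZT[0-9]+_R([0-9]+)$", "\\1", cc))))
}

#' Extract the replicate-count matrix for one timepoint
#' @param table an [interaction_table()].
#' @param timepoint ZT hours.
#' @return Numeric matrix, records x replicates.
#' @export
counts_at <- function(table, timepoint) {
  cc <- grep(sprintf("^count_ZT%d_R[0-9]+$", timepoint), names(table), value = TRUE)
  if (!length(cc)) stop("no count columns for ZT", timepoint)
  as.matrix(as.data.frame(table)[, cc, drop = FALSE])
}

#' Per-timepoint significance score for every record
#' @param table an [interaction_table()].
#' @param timepoint ZT hours; falls back to the overall `score` column when
#'   no `score_ZT<t>` column exists.
#' @return Numeric vector of scores.
#' @export
score_at <- function(table, timepoint) {
  col <- sprintf("score_ZT%d", timepoint)
  if (col %in% names(table)) table[[col]] else table$score
}

resolve_fragment_row <- function(fragmap, chrom, start, end) {
  mid <- (start + end) / 2
  ids <- integer(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    if (!ch %in% fragmap$chrom) stop("cannot resolve fragment on unknown chromosome ", ch)
    ids[i] <- locate_fragment(fragmap, ch, mid[i])
  }
  ids
}

#' Read an interaction table from standard capture Hi-C formats
#'
#' Dialects: `ibed` (tab-separated with header `bait_chr bait_start bait_end
#' bait_name otherEnd_chr otherEnd_start otherEnd_end otherEnd_name N_reads
#' score`, optionally extended with `score_ZT<t>` and `count_ZT<t>_R<r>`
#' columns), `longrange` (washU `chr start end chr2:start2-end2,score`), and
#' `tsv_counts` (this package's canonical columns written by
#' [write_interactions()]).
#'
#' @param path input path.
#' @param dialect one of `"ibed"`, `"longrange"`, `"tsv_counts"`.
#' @param fragmap a [restriction_map()], required for `ibed`/`longrange` to
#'   resolve fragment IDs from coordinates.
#' @param baits optional bait fragment universe.
#' @return An [interaction_table()].
#' @export
read_interactions <- function(path, dialect = c("ibed", "longrange", "tsv_counts"),
                              fragmap = NULL, baits = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv_counts") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    return(interaction_table(df, baits = baits))
  }
  if (is.null(fragmap)) stop("fragmap required for dialect ", dialect)
  if (dialect == "ibed") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0) {
      return(interaction_table(
        data.frame(bait_frag = integer(), other_frag = integer(),
                   bait_chrom = character(), bait_start = numeric(),
                   bait_end = numeric(), other_chrom = character(),
                   other_start = numeric(), other_end = numeric()),
        baits = baits))
    }
    out <- data.frame(
      bait_chrom = as.character(df$bait_chr), bait_start = df$bait_start,
      bait_end = df$bait_end, bait_name = as.character(df$bait_name),
      other_chrom = as.character(df$otherEnd_chr), other_start = df$otherEnd_start,
      other_end = df$otherEnd_end, other_name = as.character(df$otherEnd_name),
      N_reads = df$N_reads, score = df$score, stringsAsFactors = FALSE
    )
    extra <- grep("^(score_ZT[0-9]+|count_ZT[0-9]+_R[0-9]+)$", names(df), value = TRUE)
    for (col in extra) out[[col]] <- df[[col]]
    out$bait_frag <- resolve_fragment_row(fragmap, out$bait_chrom, out$bait_start, out$bait_end)
    out$other_frag <- resolve_fragment_row(fragmap, out$other_chrom, out$other_start, out$other_end)
    return(interaction_table(out, baits = baits))
  }
  # longrange: chr\tstart\tend\tchr2:start2-end2,score
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(interaction_table(data.frame(
      bait_frag = integer(), other_frag = integer(),
      bait_chrom = character(), bait_start = numeric(), bait_end = numeric(),
      other_chrom = character(), other_start = numeric(), other_end = numeric()),
      baits = baits))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 4)
  if (length(bad)) stop("malformed longrange line ", bad[1])
  m <- regmatches(
    vapply(parts, `[`, "", 4),
    regexec("^([^:]+):([0-9]+)-([0-9]+),([-0-9.eE+]+)$", vapply(parts, `[`, "", 4))
  )
  if (any(vapply(m, length, 0L) != 5)) {
    stop("malformed longrange target field at line ",
         which(vapply(m, length, 0L) != 5)[1])
  }
  out <- data.frame(
    bait_chrom = vapply(parts, `[`, "", 1),
    bait_start = as.numeric(vapply(parts, `[`, "", 2)),
    bait_end = as.numeric(vapply(parts, `[`, "", 3)),
    other_chrom = vapply(m, `[`, "", 2),
    other_start = as.numeric(vapply(m, `[`, "", 3)),
    other_end = as.numeric(vapply(m, `[`, "", 4)),
    score = as.numeric(vapply(m, `[`, "", 5)),
    stringsAsFactors = FALSE
  )
  out$bait_frag <- resolve_fragment_row(fragmap, out$bait_chrom, out$bait_start, out$bait_end)
  out$other_frag <- resolve_fragment_row(fragmap, out$other_chrom, out$other_start, out$other_end)
  interaction_table(out, baits = baits)
}

#' Write an interaction table
#'
#' `tsv_counts` writes the canonical columns (lossless round-trip with
#' [read_interactions()]); `ibed` writes the standard header plus any
#' per-timepoint score/count columns; `longrange` writes washU arcs with the
#' overall score.
#'
#' @param table an [interaction_table()].
#' @param path output path.
#' @param dialect output dialect.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(table, path,
                               dialect = c("tsv_counts", "ibed", "longrange")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(table)
  if (dialect == "tsv_counts") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (dialect == "ibed") {
    out <- data.frame(
      bait_chr = df$bait_chrom, bait_start = df$bait_start, bait_end = df$bait_end,
      bait_name = ifelse(is.na(df$bait_name), ".", df$bait_name),
      otherEnd_chr = df$other_chrom, otherEnd_start = df$other_start,
      otherEnd_end = df$other_end,
      otherEnd_name = ifelse(is.na(df$other_name), ".", df$other_name),
      N_reads = df$N_reads, score = df$score, stringsAsFactors = FALSE,
      check.names = FALSE
    )
    for (col in c(score_cols(df), count_cols(df))) out[[col]] <- df[[col]]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    target <- sprintf("%s:%d-%d,%.10g", df$other_chrom, as.integer(df$other_start),
                      as.integer(df$other_end), df$score)
    out <- data.frame(df$bait_chrom, as.integer(df$bait_start),
                      as.integer(df$bait_end), target)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Virtual 4C: one-viewpoint contact profile around a bait
#'
#' Sums replicate counts per contacted fragment within a window of the bait,
#' emulating a 4C profile from capture data, and collects significant records
#' as arcs for browser display (writable with
#' `write_interactions(..., "longrange")`).
#'
#' @param table an [interaction_table()].
#' @param bait bait fragment ID, or `"chrom:pos"` string resolved through
#'   `fragmap`.
#' @param window_bp half-window in bp around the bait fragment midpoint;
#'   `Inf` keeps every cis record.
#' @param fragmap a [restriction_map()] (needed for `"chrom:pos"` baits).
#' @param timepoint restrict the profile to one ZT's counts; `NULL` sums all.
#' @param score_threshold records with per-timepoint (or overall) score at or
#'   above this are emitted as arcs.
#' @return List with `track` (a `coverage_track` of per-fragment summed raw
#'   counts) and `arcs` (an [interaction_table()] of significant records).
#' @export
virtual_4c <- function(table, bait, window_bp = Inf, fragmap = NULL,
                       timepoint = NULL, score_threshold = 5) {
  if (is.character(bait)) {
    if (is.null(fragmap)) stop("fragmap required to resolve bait ", bait)
    m <- regmatches(bait, regexec("^([^:]+):([0-9]+)$", bait))[[1]]
    if (length(m) != 3) stop("bait must be a fragment ID or 'chrom:pos'")
    bait <- locate_fragment(fragmap, m[2], as.numeric(m[3]))
  }
  if (!bait %in% attr(table, "baits")) stop("bait fragment ", bait, " not in bait universe")
  rec <- as.data.frame(table)[table$bait_frag == bait, , drop = FALSE]
  keep <- is.na(rec$distance_bp) | rec$distance_bp <= window_bp
  keep[is.na(rec$distance_bp)] <- FALSE  # trans records excluded from the cis window profile
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    track <- coverage_track(data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), value = numeric()))
    return(list(track = track, arcs = interaction_table(rec, baits = attr(table, "baits"))))
  }
  cc <- if (is.null(timepoint)) count_cols(rec) else
    grep(sprintf("^count_ZT%d_R[0-9]+$", timepoint), names(rec), value = TRUE)
  total <- if (length(cc)) rowSums(rec[, cc, drop = FALSE]) else rec$N_reads
  agg <- stats::aggregate(total,
                          by = list(chrom = rec$other_chrom, start = rec$other_start,
                                    end = rec$other_end),
                          FUN = sum)
  names(agg)[4] <- "value"
  agg <- agg[order(agg$chrom, agg$start), ]
  sc <- if (is.null(timepoint)) rec$score else score_at(interaction_table(rec), timepoint)
  arcs <- interaction_table(rec[sc >= score_threshold, , drop = FALSE],
                            baits = attr(table, "baits"))
  list(track = coverage_track(agg, units = "raw"), arcs = arcs)
}
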