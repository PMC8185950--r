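#' Define a genome as an ordered set of chromosomes
#'
#' The coordinate frame every other object in the package is validated
#' against. Coordinates are 0-based half-open (`[start, end)`) throughout;
#' 1-based coordinates appear only in display strings.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in base pairs.
#' @return An object of class `genome_def`: a data.frame with columns
#'   `chrom` and `length`, one row per chromosome in the given order.
#' @examples
#' genome_def(c("chr1", "chr2"), c(20e6, 20e6))
#' @export
genome_def <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) stop("chromosome lengths must be > 0")
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_def", "data.frame"))
}

#' @export
print.genome_def <- function(x, ...) {
  cat("genome_def:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

#' Validate genomic intervals against a genome
#'
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @param genome a [genome_def()].
#' @param what label used in error messages.
#' @return `df`, invisibly, after validation.
#' @keywords internal
validate_intervals <- function(df, genome, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop(what, ": negative start coordinate")
  if (any(df$end <= df$start)) stop(what, ": end must be > start")
  len <- chrom_length(genome, df$chrom)
  bad <- which(df$end > len)
  if (length(bad)) {
    stop(what, " beyond chromosome end at row ", bad[1], " (",
         df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]], ")")
  }
  invisible(df)
}

#' Read a BED file into a feature set
#'
#' Accepts BED3 and BED6; an optional 7th numeric column is interpreted as
#' the feature's circadian phase in hours (`phase_hr`, in `[0, 24)`), the
#' convention used for phased enhancer (eRNA) sets.
#'
#' @param path path to a tab-separated BED file.
#' @param genome a [genome_def()] used to validate coordinates.
#' @param set_name name attached to the returned feature set.
#' @return A `feature_set`: data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `strand`, `phase_hr` and attribute `set_name`.
#' @export
read_bed <- function(path, genome, set_name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) return(feature_set(empty_features(), set_name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, 0L)
  if (any(n < 3)) {
    stop("malformed BED line ", which(n < 3)[1], ": fewer than 3 fields")
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  }
  df <- data.frame(
    chrom = get(1), start = start, end = end,
    name = get(4), strand = get(6),
    phase_hr = suppressWarnings(as.numeric(get(7))),
    stringsAsFactors = FALSE
  )
  df$strand[!df$strand %in% c("+", "-")] <- "."
  validate_intervals(df, genome, "BED record")
  feature_set(df, set_name)
}

empty_features <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), strand = character(), phase_hr = numeric(),
             stringsAsFactors = FALSE)
}

feature_set <- function(df, set_name = "features") {
  for (col in c("name", "strand", "phase_hr")) {
    if (is.null(df[[col]])) df[[col]] <- if (col == "phase_hr") NA_real_ else NA_character_
  }
  df <- df[, c("chrom", "start", "end", "name", "strand", "phase_hr")]
  structure(df, class = c("feature_set", "data.frame"), set_name = set_name)
}

#' Write a feature set as BED
#'
#' Emits BED6 when any name/strand is set, BED3 otherwise; a 7th column is
#' appended when any feature carries `phase_hr`.
#'
#' @param features a `feature_set` or data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  df <- as.data.frame(features)
  cols <- c("chrom", "start", "end")
  has_phase <- !is.null(df$phase_hr) && any(!is.na(df$phase_hr))
  has_name <- !is.null(df$name) && any(!is.na(df$name))
  if (has_name || has_phase) {
    df$name <- ifelse(is.na(df$name), ".", df$name)
    df$score <- 0
    df$strand <- if (is.null(df$strand)) "." else ifelse(is.na(df$strand), ".", df$strand)
    cols <- c(cols, "name", "score", "strand")
  }
  if (has_phase) {
    df$phase_hr <- ifelse(is.na(df$phase_hr), ".", format(df$phase_hr, trim = TRUE))
    cols <- c(cols, "phase_hr")
  }
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (`chrom start end value`).
#' @param genome a [genome_def()].
#' @param units declared units of the signal column.
#' @return A `coverage_track`: data.frame `chrom,start,end,value` with a
#'   `units` attribute.
#' @export
read_bedgraph <- function(path, genome, units = c("raw", "RPM", "log2RPM")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  validate_intervals(df, genome, "bedGraph record")
  if (any(!is.finite(df$value))) stop("non-finite signal value")
  coverage_track(df, units)
}

coverage_track <- function(df, units = "raw") {
  structure(df, class = c("coverage_track", "data.frame"), units = units)
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track` or data.frame `chrom,start,end,value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- as.data.frame(track)[, c("chrom", "start", "end", "value")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a restriction-fragment map
#'
#' Fragments tile each chromosome contiguously (`[0, length)`) and carry
#' stable integer IDs increasing in genomic order, chromosome by chromosome.
#'
#' @param genome a [genome_def()].
#' @param cut_sites named list (by chromosome) of sorted internal cut
#'   positions in bp; fragment boundaries are `0, cuts..., length`.
#' @return A `restriction_map`: data.frame `frag_id,chrom,start,end` with the
#'   genome attached as attribute `genome`.
#' @export
restriction_map <- function(genome, cut_sites) {
  frags <- list()
  next_id <- 1L
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    len <- genome$length[i]
    cuts <- sort(unique(as.numeric(cut_sites[[chrom]])))
    cuts <- cuts[cuts > 0 & cuts < len]
    bounds <- c(0, cuts, len)
    df <- data.frame(
      frag_id = seq(next_id, length.out = length(bounds) - 1L),
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      stringsAsFactors = FALSE
    )
    next_id <- next_id + nrow(df)
    frags[[chrom]] <- df
  }
  out <- do.call(rbind, frags)
  rownames(out) <- NULL
  structure(out, class = c("restriction_map", "data.frame"), genome = genome)
}

#' Locate the fragment containing a genomic position
#' @param fragmap a [restriction_map()].
#' @param chrom chromosome name.
#' @param pos 0-based position in bp.
#' @return Integer fragment ID.
#' @export
locate_fragment <- function(fragmap, chrom, pos) {
  sub <- fragmap[fragmap$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) stop("no fragments on ", chrom)
  i <- findInterval(pos, sub$start)
  if (any(i == 0) || any(pos >= sub$end[pmax(i, 1L)])) {
    stop("position outside fragment map on ", chrom)
  }
  sub$frag_id[i]
}

frag_mid <- function(fragmap, frag_id) {
  i <- match(frag_id, fragmap$frag_id)
  if (anyNA(i)) stop("unknown fragment ID(s): ", paste(frag_id[is.na(i)], collapse = ","))
  (fragmap$start[i] + fragmap$end[i]) / 2
}

#' Count overlaps of query intervals with a feature set
#'
#' @param query data.frame with `chrom`, `start`, `end`.
#' @param features data.frame with `chrom`, `start`, `end`.
#' @return Integer vector: for each query row, the number of overlapping
#'   features (half-open interval semantics).
#' @export
count_feature_overlaps <- function(query, features) {
  out <- integer(nrow(query))
  if (nrow(query) == 0 || nrow(features) == 0) return(out)
  for (chrom in unique(query$chrom)) {
    qi <- which(query$chrom == chrom)
    fi <- which(features$chrom == chrom)
    if (length(fi) == 0) next
    # half-open [start,end) -> closed integer ranges [start, end-1]
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    f <- IRanges::IRanges(start = features$start[fi] + 1L, end = features$end[fi])
    out[qi] <- IRanges::countOverlaps(q, f)
  }
  out
}
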