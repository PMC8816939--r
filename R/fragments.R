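# Fragment-level I/O, filtering and size features.
#
# Fragments live in a plain data.frame with BED-style 0-based half-open
# coordinates: columns `chrom`, `start`, `end`, `size`, and optional
# annotation columns `d_start`, `d_end`, `pbnb_score`, `is_mutant`,
# `origin` (the last is a simulator truth label, never used by the
# analysis itself).

FRAG_ANNOT_COLS <- c("size", "d_start", "d_end", "pbnb_score", "is_mutant", "origin")

#' Construct a fragment table
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open interval per fragment.
#' @param ... Optional annotation columns (`d_start`, `d_end`, `pbnb_score`,
#'   `is_mutant`, `origin`), recycled by `data.frame()` rules.
#' @return A data frame with `size = end - start` computed.
#' @export
fragment_table <- function(chrom, start, end, ...) {
  if (any(end <= start)) stop("every fragment must satisfy end > start")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$size <- df$end - df$start
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

#' Fragment size under the half-open convention
#'
#' @param frags Fragment data frame.
#' @return Integer vector, `end - start` per fragment.
#' @export
compute_size <- function(frags) {
  as.integer(frags$end - frags$start)
}

#' Drop non-autosomal and out-of-range fragments
#'
#' Keeps fragments on autosomes (`chr1`..`chr22` or `1`..`22`) with size
#' in 1..800 bp. Idempotent. The number of dropped records is reported
#' via [message()].
#'
#' @param frags Fragment data frame.
#' @param max_size Upper size bound in bp (inclusive).
#' @return The filtered data frame.
#' @export
filter_fragments <- function(frags, max_size = 800L) {
  keep <- is_autosome(frags$chrom) & frags$size >= 1L & frags$size <= max_size
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("filter_fragments: dropped %d of %d records", dropped, nrow(frags)))
  }
  frags[keep, , drop = FALSE]
}

#' Read fragments from a BED3+ file
#'
#' Columns beyond the third are interpreted, in order, as `size`,
#' `d_start`, `d_end`, `pbnb_score`, `is_mutant` (0/1) and `origin`;
#' `.` denotes a missing value. A stored `size` column is recomputed
#' from the coordinates (it is redundant by construction).
#'
#' @param path BED file path.
#' @param apply_filters Drop non-autosomal fragments and sizes outside
#'   1..800 bp (the default analysis filter).
#' @return Fragment data frame in file order.
#' @export
load_fragments <- function(path, apply_filters = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    return(fragment_table(character(), integer(), integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", na.strings = ".",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(fragment_table(character(), integer(), integer()))
  }
  if (ncol(dt) < 3L) stop("BED file must have >= 3 columns: ", path)
  ncols <- min(ncol(dt), 3L + length(FRAG_ANNOT_COLS))
  dt <- dt[, seq_len(ncols), with = FALSE]
  names(dt) <- c("chrom", "start", "end", FRAG_ANNOT_COLS)[seq_len(ncols)]
  for (col in c("start", "end")) {
    v <- dt[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v))) {
      bad <- which(!grepl("^-?[0-9]+$", as.character(v)))[1]
      if (is.na(bad)) bad <- which(is.na(v))[1]
      stop(sprintf("malformed BED line %d in %s: non-integer %s", bad, path, col))
    }
  }
  df <- as.data.frame(dt)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) {
    stop(sprintf("malformed BED line %d in %s: end <= start",
                 which(df$end <= df$start)[1], path))
  }
  df$size <- df$end - df$start
  if ("is_mutant" %in% names(df)) df$is_mutant <- as.logical(df$is_mutant)
  df <- df[, c("chrom", "start", "end",
               intersect(FRAG_ANNOT_COLS, names(df))), drop = FALSE]
  if (apply_filters) df <- filter_fragments(df)
  df
}

#' Write fragments as BED3+
#'
#' Annotation columns present in `frags` are written as tab-separated
#' columns 4+ in the canonical order (`size`, `d_start`, `d_end`,
#' `pbnb_score`, `is_mutant`, `origin`); missing values are written as
#' `.`, and skipped columns before a present one are filled with `.` so
#' column positions stay meaningful. Round-trips with [load_fragments()].
#'
#' @param frags Fragment data frame.
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  present <- intersect(FRAG_ANNOT_COLS, names(frags))
  cols <- c("chrom", "start", "end")
  if (length(present) > 0L) {
    upto <- max(match(present, FRAG_ANNOT_COLS))
    cols <- c(cols, FRAG_ANNOT_COLS[seq_len(upto)])
  }
  out <- frags
  for (nm in setdiff(cols, names(out))) out[[nm]] <- NA
  out <- out[, cols, drop = FALSE]
  if ("is_mutant" %in% names(out)) out$is_mutant <- as.integer(out$is_mutant)
  if (nrow(out) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, na = ".",
                     quote = FALSE, scipen = 50)
  invisible(path)
}

#' The 16 default fragment-size bins
#'
#' Size bins anchored on the ~10 bp periodic peaks below 200 bp and on
#' the window where the di-nucleosomal peak shifts between tumor and
#' healthy plasma. Bounds are inclusive; the published 53--64 / 64--73
#' boundary shares 64 bp verbatim, and joint membership tests resolve
#' lowest-bin-first.
#'
#' @return Data frame with columns `lo` and `hi` (bp, inclusive), 16 rows.
#' @export
default_size_bins <- function() {
  data.frame(
    lo = c(0L, 53L, 64L, 74L, 84L, 95L, 105L, 115L, 126L, 136L, 144L,
           154L, 161L, 172L, 240L, 325L),
    hi = c(52L, 64L, 73L, 83L, 94L, 104L, 114L, 125L, 135L, 143L, 153L,
           160L, 171L, 239L, 324L, 400L)
  )
}

#' Select fragments whose size falls in a union of bins
#'
#' @param frags Fragment data frame.
#' @param bins Data frame with inclusive `lo`/`hi` columns (e.g. rows of
#'   [default_size_bins()]).
#' @return The subset of `frags`, order preserved.
#' @export
select_by_size <- function(frags, bins) {
  if (nrow(bins) == 0L) stop("`bins` must be non-empty")
  if (any(bins$lo > bins$hi)) stop("each bin must satisfy lo <= hi")
  keep <- rep(FALSE, nrow(frags))
  for (i in seq_len(nrow(bins))) {
    keep <- keep | (frags$size >= bins$lo[i] & frags$size <= bins$hi[i])
  }
  frags[keep, , drop = FALSE]
}

#' Empirical fragment-size distribution
#'
#' @param frags Non-empty fragment data frame.
#' @return Data frame with one row per observed size: `size`, `count`,
#'   `density` (densities sum to 1).
#' @export
size_distribution <- function(frags) {
  if (nrow(frags) == 0L) stop("size_distribution: empty input")
  tab <- table(frags$size)
  data.frame(size = as.integer(names(tab)),
             count = as.integer(tab),
             density = as.numeric(tab) / nrow(frags))
}
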