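# Nucleosome-dyad annotation: signed distance of fragment start/end sites
# to the nearest dyad, and core/linker classification.
#
# Site convention: the start site is the fragment's `start` coordinate;
# the end site is `end - 1`, the last covered base (the half-open `end`
# itself is not covered). Distances are site - dyad, so positive means
# the site lies downstream (higher coordinate) of its nearest dyad.
# Equidistant ties break to the lower-coordinate dyad.

#' Construct a nucleosome track from dyad coordinates
#'
#' @param dyads Named list of integer vectors, one per chromosome;
#'   coordinates are 0-based dyad positions. Sorted and deduplicated here.
#' @param label Provenance label (e.g. `"synthetic"`).
#' @return A `nucleosome_track` object.
#' @export
nucleosome_track <- function(dyads, label = "unknown") {
  stopifnot(is.list(dyads), !is.null(names(dyads)))
  dyads <- lapply(dyads, function(d) sort(unique(as.integer(d))))
  structure(list(dyads = dyads, label = label), class = "nucleosome_track")
}

#' @export
print.nucleosome_track <- function(x, ...) {
  cat(sprintf("Nucleosome track '%s': %d dyads on %d chromosome(s)\n",
              x$label, sum(lengths(x$dyads)), length(x$dyads)))
  invisible(x)
}

#' Read a nucleosome track from a BED file
#'
#' The dyad of each interval is its midpoint, `floor((start + end) / 2)`.
#' Dyads are sorted and deduplicated per chromosome.
#'
#' @param path BED3 file of nucleosome calls.
#' @param label Provenance label stored on the track.
#' @return A `nucleosome_track` object.
#' @export
load_nucleosome_track <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) return(nucleosome_track(setNames(list(), character()), label))
  if (ncol(dt) < 3L) stop("BED file must have >= 3 columns: ", path)
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (!is.numeric(dt$start) || !is.numeric(dt$end) || anyNA(dt$start) || anyNA(dt$end)) {
    stop("malformed nucleosome BED (non-integer coordinates): ", path)
  }
  mid <- (as.integer(dt$start) + as.integer(dt$end)) %/% 2L
  nucleosome_track(split(mid, dt$chrom), label)
}

# Nearest dyad distances for 0-based sites on one chromosome.
# Returns signed site - dyad; ties go to the lower-coordinate dyad.
nearest_dyad_distance <- function(sites, dyads) {
  if (length(dyads) == 0L) return(rep(NA_integer_, length(sites)))
  idx <- findInterval(sites, dyads)              # last dyad <= site (0 if none)
  lo <- ifelse(idx >= 1L, dyads[pmax(idx, 1L)], NA_integer_)
  hi <- ifelse(idx < length(dyads), dyads[pmin(idx + 1L, length(dyads))], NA_integer_)
  d_lo <- sites - lo                              # >= 0 where defined
  d_hi <- sites - hi                              # <= 0 where defined
  take_lo <- !is.na(d_lo) & (is.na(d_hi) | abs(d_lo) <= abs(d_hi))
  as.integer(ifelse(take_lo, d_lo, d_hi))
}

#' Annotate fragments with signed distances to the nearest dyad
#'
#' Start and end sites are matched to their nearest dyads independently
#' (the two sites may pick different dyads). Fragments on chromosomes
#' absent from the track get `NA` distances and are counted in a message.
#'
#' @param frags Fragment data frame.
#' @param track A [nucleosome_track()].
#' @return `frags` with integer columns `d_start` and `d_end` added.
#' @export
annotate_dyad_distance <- function(frags, track) {
  stopifnot(inherits(track, "nucleosome_track"))
  d_start <- rep(NA_integer_, nrow(frags))
  d_end <- rep(NA_integer_, nrow(frags))
  for (chr in unique(frags$chrom)) {
    i <- which(frags$chrom == chr)
    dy <- track$dyads[[chr]]
    if (is.null(dy) || length(dy) == 0L) next
    d_start[i] <- nearest_dyad_distance(frags$start[i], dy)
    d_end[i] <- nearest_dyad_distance(frags$end[i] - 1L, dy)
  }
  n_missing <- sum(is.na(d_start))
  if (n_missing > 0L) {
    message(sprintf(
      "annotate_dyad_distance: %d fragment(s) on chromosomes with no dyads left unannotated",
      n_missing))
  }
  frags$d_start <- d_start
  frags$d_end <- d_end
  frags
}

#' Classify fragments as nucleosome core, linker or mixed
#'
#' A fragment is `core` when both its start and end sites lie within
#' `w` bp of a dyad, `linker` when both lie outside, `mixed` otherwise.
#'
#' @param frags Fragment data frame with `d_start`/`d_end` columns (see
#'   [annotate_dyad_distance()]).
#' @param w Half-window in bp around the dyad (default 75, the
#'   nucleosome core region).
#' @return Factor with levels `core`, `linker`, `mixed` (`NA` for
#'   unannotated fragments).
#' @export
classify_core_linker <- function(frags, w = 75L) {
  in_s <- abs(frags$d_start) <= w
  in_e <- abs(frags$d_end) <= w
  out <- ifelse(in_s & in_e, "core", ifelse(!in_s & !in_e, "linker", "mixed"))
  factor(out, levels = c("core", "linker", "mixed"))
}

#' Density of fragment end sites relative to nucleosome dyads
#'
#' Pools `d_start` and `d_end` offsets of all annotated fragments and
#' histograms them over integer offsets in `[-max_offset, max_offset]`.
#'
#' @param frags Annotated fragment data frame.
#' @param max_offset Half-range of offsets to tabulate (bp).
#' @return Data frame with columns `offset` and `density`; densities sum
#'   to 1 over the tabulated range.
#' @export
dyad_distance_density <- function(frags, max_offset = 200L) {
  offs <- c(frags$d_start, frags$d_end)
  offs <- offs[!is.na(offs) & abs(offs) <= max_offset]
  if (length(offs) == 0L) stop("dyad_distance_density: no annotated sites in range")
  tab <- tabulate(offs + max_offset + 1L, nbins = 2L * max_offset + 1L)
  data.frame(offset = seq(-max_offset, max_offset),
             density = tab / sum(tab))
}
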