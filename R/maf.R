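# Aggregated mutant allele fraction (MAF) at a designated point-mutation
# locus, under fragment feature selections.
#
# Mutant/wild-type flags are input data (the `is_mutant` column), carried
# on each fragment by the upstream targeted assay or the simulator; this
# module never inspects base calls.

#' Define a point-mutation locus
#'
#' @param chrom Chromosome name (autosome).
#' @param pos 0-based position of the mutated base.
#' @param ref,alt Reference and alternate bases (informational).
#' @return A `mutation_locus` list.
#' @export
mutation_locus <- function(chrom, pos, ref = NA_character_, alt = NA_character_) {
  if (!is_autosome(chrom)) stop("mutation_locus: locus must be on an autosome")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt),
            class = "mutation_locus")
}

#' Collect the fragments covering a locus
#'
#' Half-open convention: a fragment covers the locus when
#' `start <= pos < end`.
#'
#' @param frags Fragment data frame with an `is_mutant` column.
#' @param locus A [mutation_locus()].
#' @return A `locus_pileup`: the covering fragments, the locus, and the
#'   aggregated `depth`. An empty pileup is allowed.
#' @export
collect_locus_fragments <- function(frags, locus) {
  stopifnot(inherits(locus, "mutation_locus"))
  hit <- frags$chrom == locus$chrom & frags$start <= locus$pos & frags$end > locus$pos
  sub <- frags[hit, , drop = FALSE]
  structure(list(frags = sub, locus = locus, depth = nrow(sub)),
            class = "locus_pileup")
}

#' @export
print.locus_pileup <- function(x, ...) {
  cat(sprintf("Locus pileup %s:%d depth %d (%d mutant)\n",
              x$locus$chrom, x$locus$pos, x$depth,
              sum(x$frags$is_mutant, na.rm = TRUE)))
  invisible(x)
}

#' Aggregated MAF under a feature selection
#'
#' Pools one or several pileups (summed counts across patients), applies
#' the selector, and reports mutant / total over the selected fragments.
#' Results below `min_depth` selected fragments are flagged `low_depth`
#' but still returned; zero selected fragments yield an `undefined`
#' flag with `NA` MAF.
#'
#' @param pileups A `locus_pileup` or a list of them.
#' @param selector A [feature_selector()] (default: identity).
#' @param min_depth Depth below which the result is flagged (default 25).
#' @return List with `maf`, `depth`, `mutant`, `low_depth`, `undefined`.
#' @export
aggregated_maf <- function(pileups, selector = feature_selector(), min_depth = 25L) {
  if (inherits(pileups, "locus_pileup")) pileups <- list(pileups)
  frags <- do.call(rbind, lapply(pileups, `[[`, "frags"))
  sel <- apply_selector(frags, selector)
  depth <- nrow(sel)
  if (depth == 0L) {
    return(list(maf = NA_real_, depth = 0L, mutant = 0L,
                low_depth = TRUE, undefined = TRUE))
  }
  mutant <- sum(sel$is_mutant, na.rm = TRUE)
  list(maf = mutant / depth, depth = depth, mutant = as.integer(mutant),
       low_depth = depth < min_depth, undefined = FALSE)
}

#' Relative aggregated MAF
#'
#' Ratio of the aggregated MAF under a feature selection to the
#' aggregated MAF with no selection; above 1 the selection enriches
#' mutant (tumor-derived) fragments.
#'
#' @param selected,unselected Results of [aggregated_maf()].
#' @return List with `ratio` (`NA` + `undefined` flag when the
#'   unselected MAF is 0 or undefined).
#' @export
relative_maf <- function(selected, unselected) {
  if (unselected$undefined || is.na(unselected$maf) || unselected$maf == 0) {
    return(list(ratio = NA_real_, undefined = TRUE))
  }
  list(ratio = selected$maf / unselected$maf,
       undefined = is.na(selected$maf))
}

#' Per-selector MAF table
#'
#' @param pileups A `locus_pileup` or list of them (pooled).
#' @param selectors List of [feature_selector()] objects.
#' @param min_depth Depth flag threshold.
#' @return Data frame: selector, depth, mutant, maf, relative_maf,
#'   low_depth.
#' @export
maf_table <- function(pileups, selectors, min_depth = 25L) {
  base <- aggregated_maf(pileups, feature_selector(), min_depth)
  rows <- lapply(selectors, function(sel) {
    m <- aggregated_maf(pileups, sel, min_depth)
    r <- relative_maf(m, base)
    data.frame(selector = sel$label, depth = m$depth, mutant = m$mutant,
               maf = m$maf, relative_maf = r$ratio, low_depth = m$low_depth)
  })
  do.call(rbind, rows)
}
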