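# Simplified shallow-WGS copy-number tumor-fraction estimator.
#
# Same contract as ichorCNA: fragment counts in fixed genomic bins,
# normalized against a panel of normals built under the identical
# feature selection, segmented with a 3-state Gaussian HMM
# (loss / neutral / gain) and converted to a tumor fraction under
# single-copy events:
#
#   gain (c = 3):  2^r = 1 + f/2  =>  f = 2 (2^r - 1)
#   loss (c = 1):  2^r = 1 - f/2  =>  f = 2 (1 - 2^r)
#
# The overall estimate is the length-weighted mean over aberrant
# segments, clipped to [0, 1], and 0 when nothing is aberrant.

#' Tile a chromosome layout into fixed-width bins
#'
#' @param layout Data frame with `chrom` and `length` columns (see
#'   [genome_layout()]).
#' @param bin_width Bin width in bp (default 1 Mb); the last bin of a
#'   chromosome may be shorter.
#' @return Data frame with `chrom`, `start`, `end` per bin.
#' @export
make_bins <- function(layout, bin_width = 1e6) {
  bin_width <- as.integer(bin_width)
  out <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq.int(0L, len - 1L, by = bin_width)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + bin_width, len))
  })
  do.call(rbind, out)
}

#' Count fragments per genomic bin
#'
#' Each fragment is assigned to the single bin containing its midpoint.
#' Fragments outside the layout are counted in a message, not fatal.
#'
#' @param frags Fragment data frame (autosome-filtered).
#' @param layout Chromosome layout ([genome_layout()]).
#' @param bin_width Bin width in bp.
#' @return A `binned_coverage` object: `bins` data frame with a `count`
#'   column, plus `total` and `bin_width`.
#' @export
bin_fragments <- function(frags, layout, bin_width = 1e6) {
  bin_width <- as.integer(bin_width)
  bins <- make_bins(layout, bin_width)
  nb_per_chrom <- table(factor(bins$chrom, levels = layout$chrom))
  offset <- setNames(cumsum(c(0L, as.integer(nb_per_chrom)))[seq_len(nrow(layout))],
                     layout$chrom)
  chrom_len <- setNames(layout$length, layout$chrom)
  mid <- (frags$start + frags$end) %/% 2L
  known <- frags$chrom %in% layout$chrom
  inside <- known & mid >= 0L & mid < unname(chrom_len[frags$chrom])
  n_out <- sum(!inside)
  if (n_out > 0L) {
    message(sprintf("bin_fragments: %d fragment(s) outside the layout ignored", n_out))
  }
  idx <- unname(offset[frags$chrom[inside]]) + mid[inside] %/% bin_width + 1L
  bins$count <- tabulate(idx, nbins = nrow(bins))
  structure(list(bins = bins, total = sum(bins$count), bin_width = bin_width),
            class = "binned_coverage")
}

log2_depth <- function(bc) log2((bc$bins$count + 0.5) / bc$total)

#' Build a panel of normals from control replicates
#'
#' Per bin: median and MAD of depth-normalized `log2((count + 0.5) /
#' total)` across replicates. Bins are masked when their median raw
#' count across replicates is below `min_median_count`, or their MAD is
#' in the top 1% of bins.
#'
#' @param control_replicates List of >= 2 `binned_coverage` objects with
#'   identical layouts.
#' @param min_median_count Mask threshold on the median raw count.
#' @param selection Label of the feature selection the panel was built
#'   under (panels are selection-specific).
#' @return A `panel_of_normals` object.
#' @export
build_pon <- function(control_replicates, min_median_count = 10, selection = "none") {
  if (length(control_replicates) < 2L) stop("build_pon: need >= 2 control replicates")
  ref <- control_replicates[[1]]$bins[, c("chrom", "start", "end")]
  for (bc in control_replicates[-1]) {
    if (!identical(bc$bins[, c("chrom", "start", "end")], ref)) {
      stop("build_pon: bin layout mismatch across replicates")
    }
  }
  lr <- vapply(control_replicates, log2_depth,
               numeric(nrow(ref)))
  counts <- vapply(control_replicates, function(bc) bc$bins$count,
                   numeric(nrow(ref)))
  med <- apply(lr, 1L, stats::median)
  mad <- apply(lr, 1L, stats::mad)
  med_count <- apply(counts, 1L, stats::median)
  mask <- med_count < min_median_count | mad > stats::quantile(mad, 0.99)
  structure(list(bins = ref, median = med, mad = mad, mask = mask,
                 selection = selection, n_replicates = length(control_replicates)),
            class = "panel_of_normals")
}

#' Per-bin log2 ratio of a sample against a panel of normals
#'
#' `r_b = log2((count_b + 0.5) / total) - median_PoN_b` over unmasked
#' bins.
#'
#' @param sample A `binned_coverage` object.
#' @param pon A `panel_of_normals` with the same bin layout.
#' @return Data frame of unmasked bins with a `ratio` column.
#' @export
log2_ratio <- function(sample, pon) {
  if (!identical(sample$bins[, c("chrom", "start", "end")], pon$bins)) {
    stop("log2_ratio: bin layout mismatch with panel of normals")
  }
  r <- log2_depth(sample) - pon$median
  out <- sample$bins[!pon$mask, c("chrom", "start", "end")]
  out$ratio <- r[!pon$mask]
  rownames(out) <- NULL
  out
}

# Viterbi decode of a 3-state (loss/neutral/gain) Gaussian HMM in log
# space. Returns the most probable state path (integers 1..3) and its
# joint log-probability.
viterbi3 <- function(x, means, sd, self_transition = 0.99) {
  n <- length(x)
  K <- length(means)
  lt <- matrix(log((1 - self_transition) / (K - 1)), K, K)
  diag(lt) <- log(self_transition)
  emis <- vapply(means, function(m) stats::dnorm(x, m, sd, log = TRUE),
                 numeric(n))
  emis <- matrix(emis, nrow = n)
  delta <- matrix(-Inf, n, K)
  back <- matrix(0L, n, K)
  delta[1, ] <- log(1 / K) + emis[1, ]
  if (n > 1L) {
    for (t in 2:n) {
      for (j in 1:K) {
        cand <- delta[t - 1L, ] + lt[, j]
        back[t, j] <- which.max(cand)
        delta[t, j] <- cand[back[t, j]] + emis[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  list(path = path, loglik = max(delta[n, ]))
}

# Shared emission SD from the central 80% of the ratios.
central_sd <- function(x) {
  q <- stats::quantile(x, c(0.1, 0.9))
  core <- x[x >= q[1] & x <= q[2]]
  max(stats::sd(core), 1e-3)
}

#' Segment log2 ratios with a 3-state Gaussian HMM
#'
#' States loss / neutral / gain with fixed means (defaults -0.32, 0,
#' +0.26, single-copy events at tumor fraction ~0.5), shared emission SD
#' estimated from the central 80% of the data, self-transition 0.99 and
#' symmetric switching. Chromosomes are decoded independently; adjacent
#' same-state bins merge into segments.
#'
#' @param ratios Data frame from [log2_ratio()].
#' @param means State means for (loss, neutral, gain).
#' @param self_transition HMM self-transition probability.
#' @param sd Emission SD; estimated from the data when `NULL`.
#' @return Data frame of segments: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_ratio`, `state` (`loss`/`neutral`/`gain`); attribute
#'   `loglik` is the summed Viterbi path log-probability.
#' @export
segment_bins <- function(ratios, means = c(-0.32, 0, 0.26),
                         self_transition = 0.99, sd = NULL) {
  if (nrow(ratios) == 0L) stop("segment_bins: no unmasked bins")
  if (is.null(sd)) sd <- central_sd(ratios$ratio)
  states <- c("loss", "neutral", "gain")
  segs <- list()
  loglik <- 0
  for (chr in unique(ratios$chrom)) {
    d <- ratios[ratios$chrom == chr, ]
    vit <- viterbi3(d$ratio, means, sd, self_transition)
    loglik <- loglik + vit$loglik
    runs <- rle(vit$path)
    hi <- cumsum(runs$lengths)
    lo <- hi - runs$lengths + 1L
    segs[[chr]] <- data.frame(
      chrom = chr,
      start = d$start[lo],
      end = d$end[hi],
      n_bins = runs$lengths,
      mean_ratio = vapply(seq_along(lo),
                          function(i) mean(d$ratio[lo[i]:hi[i]]), 0),
      state = states[runs$values])
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "loglik") <- loglik
  attr(out, "sd") <- sd
  out
}

#' Tumor fraction from segment calls
#'
#' Assumes single-copy events: per gain segment `f = 2 (2^r - 1)`, per
#' loss segment `f = 2 (1 - 2^r)`; the overall estimate is the
#' bin-length-weighted mean over aberrant segments, clipped to `[0, 1]`,
#' and 0 when no segment is aberrant.
#'
#' @param segments Data frame from [segment_bins()].
#' @return A `tumor_fraction_estimate`: `f`, per-segment `f_seg`, and
#'   `aberrant_fraction` of bins in non-neutral states.
#' @export
estimate_tumor_fraction <- function(segments) {
  ab <- segments$state != "neutral"
  f_seg <- rep(NA_real_, nrow(segments))
  f_seg[segments$state == "gain"] <- 2 * (2^segments$mean_ratio[segments$state == "gain"] - 1)
  f_seg[segments$state == "loss"] <- 2 * (1 - 2^segments$mean_ratio[segments$state == "loss"])
  f <- if (!any(ab)) 0 else {
    stats::weighted.mean(pmin(pmax(f_seg[ab], 0), 1), segments$n_bins[ab])
  }
  structure(list(f = min(max(f, 0), 1),
                 segments = cbind(segments, f_seg = f_seg),
                 aberrant_fraction = sum(segments$n_bins[ab]) / sum(segments$n_bins)),
            class = "tumor_fraction_estimate")
}

#' @export
print.tumor_fraction_estimate <- function(x, ...) {
  cat(sprintf("Tumor fraction %.4f (aberrant genome fraction %.3f)\n",
              x$f, x$aberrant_fraction))
  invisible(x)
}

#' Estimate tumor fraction of a sample against a panel of normals
#'
#' Scans a grid of candidate tumor fractions f, sets the HMM state means
#' to `log2(1 - f/2)` / 0 / `log2(1 + f/2)` (single-copy loss / neutral /
#' gain at fraction f), decodes each, and keeps the decode with the
#' highest Viterbi log-probability — the same solution-scan idea the
#' published sWGS estimators use, reduced to single-copy events. The
#' reported fraction is then recomputed from the decoded segments'
#' observed mean ratios ([estimate_tumor_fraction()]), so it is not
#' quantized to the grid. Guards against fabricating aberrations on flat
#' genomes: the estimate is 0 unless the best decode marks at least
#' `min_aberrant` of the genome aberrant and beats the all-neutral decode
#' by `min_loglik_gain` log units.
#'
#' @param sample A `binned_coverage` object.
#' @param pon A matching `panel_of_normals`.
#' @param f_grid Candidate tumor fractions to scan.
#' @param min_aberrant Minimum aberrant bin fraction for a nonzero call
#'   (default 0.10: isolated outlier bins that escape the panel mask must
#'   not fabricate a tumor fraction).
#' @param min_loglik_gain Minimum Viterbi log-likelihood improvement
#'   over the all-neutral model for a nonzero call (default 30: on flat
#'   synthetic genomes the best spurious decode gains well under this,
#'   while a 10% tumor fraction over a fifth of the genome gains several
#'   times more at 0.1x coverage).
#' @param self_transition HMM self-transition probability.
#' @return A `tumor_fraction_estimate`.
#' @export
tumor_fraction <- function(sample, pon, f_grid = seq(0.05, 0.8, by = 0.05),
                           min_aberrant = 0.1, min_loglik_gain = 30,
                           self_transition = 0.99) {
  ratios <- log2_ratio(sample, pon)
  sd <- central_sd(ratios$ratio)
  null_ll <- sum(stats::dnorm(ratios$ratio, 0, sd, log = TRUE)) + log(1/3) +
    (nrow(ratios) - length(unique(ratios$chrom))) * log(self_transition) +
    (length(unique(ratios$chrom)) - 1L) * log(1/3)
  best <- NULL
  best_ll <- -Inf
  for (f in f_grid) {
    means <- c(log2(1 - f / 2), 0, log2(1 + f / 2))
    segs <- segment_bins(ratios, means = means,
                         self_transition = self_transition, sd = sd)
    ll <- attr(segs, "loglik")
    if (ll > best_ll) {
      best_ll <- ll
      best <- segs
    }
  }
  est <- estimate_tumor_fraction(best)
  if (est$aberrant_fraction < min_aberrant ||
      best_ll - null_ll < min_loglik_gain) {
    est$f <- 0
  }
  est$loglik_gain <- best_ll - null_ll
  est
}
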