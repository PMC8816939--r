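# Per-base nucleotide bias score: PC1 loadings separating healthy from
# tumor bootstrap-replicate PWMs, used as weights in a dot product with
# a fragment's binary end-context indicators.
#
#   score = S . L_start + E . L_end
#
# where S and E mark which k-mer is anchored at each context position of
# the start and end sites. Loadings are oriented so healthy replicates
# project positive: larger scores are more healthy-like, more negative
# scores more tumor-like.

#' Assemble the bootstrap-replicate PWM matrix
#'
#' One row per replicate: the vectorized PWM of that replicate's
#' contexts. Healthy rows come first.
#'
#' @param healthy_reps,tumor_reps Lists of context character vectors
#'   (or [extract_context()] data frames), one element per replicate.
#' @param k k-mer order (1, 2 or 3).
#' @param site `"start"` or `"end"`.
#' @return Numeric matrix `(n_healthy + n_tumor) x 4^k*(21-k+1)` with a
#'   `cohort` attribute (`"healthy"`/`"tumor"` per row) and attributes
#'   `k`, `site`.
#' @export
assemble_replicate_matrix <- function(healthy_reps, tumor_reps, k = 3L,
                                      site = c("start", "end")) {
  site <- match.arg(site)
  reps <- c(healthy_reps, tumor_reps)
  if (any(vapply(reps, function(r) NROW(r) == 0L, logical(1)))) {
    stop("assemble_replicate_matrix: empty replicate")
  }
  rows <- lapply(reps, function(r) vectorize_pwm(build_pwm(r, k = k, site = site)))
  m <- do.call(rbind, rows)
  cohort <- rep(c("healthy", "tumor"), c(length(healthy_reps), length(tumor_reps)))
  rownames(m) <- paste0(cohort, "_", c(seq_along(healthy_reps), seq_along(tumor_reps)))
  structure(m, cohort = cohort, k = as.integer(k), site = site)
}

#' Learn oriented PC1 loading weights from replicate PWM matrices
#'
#' Each matrix is column-mean-centred (no variance scaling) and its
#' first right singular vector taken as the PC1 loading vector. The sign
#' is fixed so the mean projection of healthy replicates is positive,
#' making scores healthy-positive regardless of the arbitrary rotation
#' the decomposition returns.
#'
#' @param m_start,m_end Matrices from [assemble_replicate_matrix()] for
#'   the start- and end-site PWMs (same `k`, >= 2 replicates per cohort).
#' @return A `loading_weights` object: unit-norm vectors `start` and
#'   `end`, `k`, orientation note, and per-replicate PC1 `projections`
#'   for diagnostics.
#' @export
learn_weights <- function(m_start, m_end) {
  k <- attr(m_start, "k")
  if (!identical(k, attr(m_end, "k"))) stop("learn_weights: k mismatch")
  pc1 <- function(m) {
    cohort <- attr(m, "cohort")
    if (length(unique(cohort)) < 2L || min(table(cohort)) < 2L) {
      stop("learn_weights: need >= 2 replicates per cohort")
    }
    x <- scale(m, center = TRUE, scale = FALSE)
    if (sum(x^2) < 1e-24) stop("degenerate: cohorts indistinguishable")
    sv <- svd(x, nu = 0L, nv = 1L)
    v <- drop(sv$v)
    proj <- drop(x %*% v)
    if (mean(proj[cohort == "healthy"]) < 0) {
      v <- -v
      proj <- -proj
    }
    names(proj) <- rownames(m)
    list(loadings = setNames(v, colnames(m)), projections = proj)
  }
  s <- pc1(m_start)
  e <- pc1(m_end)
  structure(list(start = s$loadings, end = e$loadings, k = k,
                 orientation = "healthy-positive",
                 projections = list(start = s$projections, end = e$projections),
                 n_replicates = nrow(m_start)),
            class = "loading_weights")
}

#' @export
print.loading_weights <- function(x, ...) {
  cat(sprintf("PC1 loading weights (k = %d, %d entries per site, %s)\n",
              x$k, length(x$start), x$orientation))
  invisible(x)
}

#' Binary end-context indicators
#'
#' Marks which k-mer is anchored at each position of the start and end
#' contexts: exactly `21 - k + 1` ones per site, in the flat index space
#' of [vectorize_pwm()] (lengths 84 / 320 / 1216 for k = 1 / 2 / 3).
#'
#' @param start_context,end_context 21-base ACGT strings.
#' @param k k-mer order.
#' @return List with binary vectors `S` (start) and `E` (end).
#' @export
make_indicator <- function(start_context, end_context, k = 3L) {
  one <- function(ctx) {
    codes <- BASE_CODE[utf8ToInt(ctx)]
    if (length(codes) != CONTEXT_LEN || anyNA(codes)) {
      stop("make_indicator: context must be a 21-base ACGT string")
    }
    ncol_out <- CONTEXT_LEN - k + 1L
    idx <- codes[seq_len(ncol_out)]
    if (k >= 2L) idx <- idx * 4L + codes[seq_len(ncol_out) + 1L]
    if (k >= 3L) idx <- idx * 4L + codes[seq_len(ncol_out) + 2L]
    v <- numeric(4L^k * ncol_out)
    v[idx * ncol_out + seq_len(ncol_out)] <- 1
    v
  }
  list(S = one(start_context), E = one(end_context), k = as.integer(k))
}

#' Score one fragment from its indicators
#'
#' The per-base nucleotide bias score `S . L_start + E . L_end`. With
#' healthy-positive orientation, higher scores are more healthy-like.
#'
#' @param ind Indicator list from [make_indicator()].
#' @param weights A `loading_weights` object of matching `k`.
#' @return Numeric score.
#' @export
score_fragment <- function(ind, weights) {
  if (length(ind$S) != length(weights$start) ||
      length(ind$E) != length(weights$end)) {
    stop("score_fragment: indicator/weights dimension mismatch")
  }
  sum(ind$S * weights$start) + sum(ind$E * weights$end)
}

#' Score a fragment table in bulk
#'
#' Vectorized equivalent of [make_indicator()] + [score_fragment()] per
#' fragment, reading contexts straight off the reference. Fragments
#' whose windows fall off the chromosome or contain non-ACGT bases get
#' `NA`.
#'
#' @param frags Fragment data frame.
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param weights A `loading_weights` object.
#' @return `frags` with a `pbnb_score` column added.
#' @export
score_fragments <- function(frags, genome, weights) {
  genome <- as_genome(genome)
  k <- weights$k
  ncol_out <- CONTEXT_LEN - k + 1L
  Ls <- weights$start
  Le <- weights$end
  score <- rep(NA_real_, nrow(frags))
  for (chr in unique(frags$chrom)) {
    if (!chr %in% names(genome)) next
    i <- which(frags$chrom == chr)
    codes <- BASE_CODE[utf8ToInt(genome[[chr]])]
    len <- length(codes)
    s_site <- frags$start[i]        # 0-based
    e_site <- frags$end[i] - 1L
    ok <- s_site - CONTEXT_FLANK >= 0L & e_site + CONTEXT_FLANK <= len - 1L
    i <- i[ok]; s_site <- s_site[ok]; e_site <- e_site[ok]
    if (length(i) == 0L) next
    acc <- numeric(length(i))
    bad <- logical(length(i))
    for (j in seq_len(ncol_out)) {
      # 0-based anchor of the j-th k-mer, converted to 1-based indexing
      ps <- s_site - CONTEXT_FLANK + (j - 1L) + 1L
      pe <- e_site - CONTEXT_FLANK + (j - 1L) + 1L
      cs <- codes[ps]
      ce <- codes[pe]
      if (k >= 2L) { cs <- cs * 4L + codes[ps + 1L]; ce <- ce * 4L + codes[pe + 1L] }
      if (k >= 3L) { cs <- cs * 4L + codes[ps + 2L]; ce <- ce * 4L + codes[pe + 2L] }
      miss <- is.na(cs) | is.na(ce)
      bad <- bad | miss
      cs[miss] <- 0L; ce[miss] <- 0L
      acc <- acc + Ls[cs * ncol_out + j] + Le[ce * ncol_out + j]
    }
    acc[bad] <- NA_real_
    score[i] <- acc
  }
  frags$pbnb_score <- score
  frags
}

#' Two-sample Kolmogorov--Smirnov statistic
#'
#' `D = sup_x |ECDF_a(x) - ECDF_b(x)|`, ties handled exactly. Used to
#' rank k-mer orders by how well their scores separate cohorts (larger
#' D separates better).
#'
#' @param a,b Non-empty numeric samples.
#' @return D in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("ks_statistic: empty sample")
  z <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(z) - stats::ecdf(b)(z)))
}

#' Select fragments by score threshold
#'
#' Inclusive comparison, matching the published "score <= t / >= t"
#' cutoffs.
#'
#' @param frags Fragment data frame with a `pbnb_score` column; an
#'   unscored (`NA`) fragment is an error.
#' @param threshold Score cutoff.
#' @param direction `"le"` (keep scores <= threshold) or `"ge"`.
#' @return The subset of `frags`, order preserved.
#' @export
select_by_score <- function(frags, threshold, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  if (is.null(frags$pbnb_score) || anyNA(frags$pbnb_score)) {
    stop("select_by_score: all fragments must carry a pbnb_score")
  }
  keep <- if (direction == "le") frags$pbnb_score <= threshold
          else frags$pbnb_score >= threshold
  frags[keep, , drop = FALSE]
}

#' Serialize loading weights as TSV
#'
#' Long format: columns `site`, `kmer`, `position`, `loading`, preceded
#' by `#`-prefixed metadata header lines (k, orientation, replicates).
#'
#' @param weights A `loading_weights` object.
#' @param path Output path.
#' @export
write_weights <- function(weights, path) {
  meta <- c(sprintf("# k\t%d", weights$k),
            sprintf("# orientation\t%s", weights$orientation),
            sprintf("# n_replicates\t%d", weights$n_replicates))
  long <- do.call(rbind, lapply(c("start", "end"), function(site) {
    nm <- strsplit(names(weights[[site]]), "@", fixed = TRUE)
    data.frame(site = site,
               kmer = vapply(nm, `[`, "", 1L),
               position = as.integer(vapply(nm, `[`, "", 2L)),
               loading = unname(weights[[site]]))
  }))
  con <- file(path, "w")
  writeLines(meta, con)
  close(con)
  data.table::fwrite(long, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read loading weights written by [write_weights()]
#'
#' @param path TSV path.
#' @return A `loading_weights` object (without training projections).
#' @export
read_weights <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- strsplit(sub("^# ", "", hdr), "\t")
  meta <- setNames(vapply(meta, `[`, "", 2L), vapply(meta, `[`, "", 1L))
  long <- data.table::fread(path, skip = length(hdr), sep = "\t", header = TRUE)
  k <- as.integer(meta[["k"]])
  get_site <- function(site) {
    d <- long[long$site == site, ]
    setNames(d$loading, paste0(d$kmer, "@", d$position))
  }
  structure(list(start = get_site("start"), end = get_site("end"), k = k,
                 orientation = meta[["orientation"]],
                 projections = NULL,
                 n_replicates = as.integer(meta[["n_replicates"]])),
            class = "loading_weights")
}
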