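# End-motif position weight matrices over the 21-position cleavage
# context (positions -10..+10, cleavage site indexed 0).
#
# Both contexts are read from the reference plus strand, for start and
# end sites alike, so the start- and end-site PWMs share one coordinate
# frame. k-mers are anchored at their first base: the k = 2 matrix spans
# positions -10..+9 (20 columns) and k = 3 spans -10..+8 (19 columns),
# because the final flank positions would require bases beyond the
# extracted window.

CONTEXT_FLANK <- 10L
CONTEXT_LEN <- 2L * CONTEXT_FLANK + 1L

pwm_positions <- function(k) seq(-CONTEXT_FLANK, CONTEXT_FLANK - k + 1L)

#' Extract the 21-base cleavage context around fragment start and end sites
#'
#' The start-site window covers reference bases `[start - flank,
#' start + flank]`; the end-site window is centred on `end - 1`, the
#' last covered base. Fragments whose windows run off the chromosome or
#' contain non-ACGT bases are skipped (counts reported via [message()]).
#'
#' @param frags Fragment data frame.
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param flank Bases either side of the site (default 10).
#' @return Data frame with character columns `start_context` and
#'   `end_context` (uppercase, length `2 * flank + 1`) for accepted
#'   fragments; integer attribute `kept` holds their row indices in
#'   `frags`.
#' @export
extract_context <- function(frags, genome, flank = CONTEXT_FLANK) {
  genome <- as_genome(genome)
  n <- nrow(frags)
  sc <- rep(NA_character_, n)
  ec <- rep(NA_character_, n)
  for (chr in unique(frags$chrom)) {
    if (!chr %in% names(genome)) next
    i <- which(frags$chrom == chr)
    len <- nchar(genome[[chr]])
    s <- frags$start[i]          # 0-based site
    e <- frags$end[i] - 1L
    ok <- s - flank >= 0L & e + flank <= len - 1L
    # 0-based [site-flank, site+flank] -> 1-based substring bounds
    sc[i[ok]] <- substring(genome[[chr]], s[ok] - flank + 1L, s[ok] + flank + 1L)
    ec[i[ok]] <- substring(genome[[chr]], e[ok] - flank + 1L, e[ok] + flank + 1L)
  }
  clean <- !is.na(sc) & !is.na(ec) &
    !grepl("[^ACGT]", sc) & !grepl("[^ACGT]", ec)
  n_skip <- sum(!clean)
  if (n_skip > 0L) {
    message(sprintf("extract_context: skipped %d of %d fragments (edge or ambiguous base)",
                    n_skip, n))
  }
  out <- data.frame(start_context = sc[clean], end_context = ec[clean],
                    stringsAsFactors = FALSE)
  attr(out, "kept") <- which(clean)
  out
}

#' Build a per-position k-mer frequency matrix
#'
#' Entry `W[i, n]` is the fraction of contexts whose k-mer anchored at
#' position `n` equals k-mer `i`. Every column sums to 1.
#'
#' @param contexts Character vector of fixed-length (21) ACGT contexts,
#'   or the data frame returned by [extract_context()] (then `site`
#'   picks the column).
#' @param k k-mer order, 1, 2 or 3.
#' @param site `"start"` or `"end"`; recorded on the result and used to
#'   pick the context column when a data frame is supplied.
#' @return Matrix of dimension `4^k x (21 - k + 1)` with k-mer rownames
#'   and position colnames; attributes `k`, `site`, `n_contexts`.
#' @export
build_pwm <- function(contexts, k = 1L, site = c("start", "end")) {
  site <- match.arg(site)
  if (is.data.frame(contexts)) {
    contexts <- contexts[[paste0(site, "_context")]]
  }
  stopifnot(k %in% 1:3)
  n <- length(contexts)
  if (n == 0L) stop("build_pwm: no contexts")
  if (any(nchar(contexts) != CONTEXT_LEN)) {
    stop("build_pwm: every context must have length ", CONTEXT_LEN)
  }
  codes <- matrix(BASE_CODE[utf8ToInt(paste(contexts, collapse = ""))],
                  nrow = n, ncol = CONTEXT_LEN, byrow = TRUE)
  if (anyNA(codes)) stop("build_pwm: contexts contain non-ACGT bases")
  ncol_out <- CONTEXT_LEN - k + 1L
  W <- matrix(0, nrow = 4L^k, ncol = ncol_out,
              dimnames = list(kmer_names(k), pwm_positions(k)))
  for (j in seq_len(ncol_out)) {
    idx <- codes[, j]
    if (k >= 2L) idx <- idx * 4L + codes[, j + 1L]
    if (k >= 3L) idx <- idx * 4L + codes[, j + 2L]
    W[, j] <- tabulate(idx + 1L, nbins = 4L^k) / n
  }
  structure(W, k = as.integer(k), site = site, n_contexts = n,
            class = c("ctfrag_pwm", "matrix", "array"))
}

#' Flatten a PWM to the score index space
#'
#' Row-major (k-mer-major, position-minor) flattening: entry
#' `(kmer i, position n)` lands at index `(i - 1) * n_positions + n`.
#' Lengths are 84, 320 and 1216 for k = 1, 2, 3 — the index space shared
#' by the binary end indicators and the loading weights.
#'
#' @param p A PWM from [build_pwm()].
#' @return Named numeric vector (`"kmer@position"` names).
#' @export
vectorize_pwm <- function(p) {
  v <- as.vector(t(p))
  names(v) <- paste0(rep(rownames(p), each = ncol(p)), "@", colnames(p))
  attr(v, "k") <- attr(p, "k")
  attr(v, "site") <- attr(p, "site")
  v
}

#' Invert [vectorize_pwm()]
#'
#' @param v Flat vector of length `4^k * (21 - k + 1)`.
#' @param k k-mer order.
#' @return The `4^k x (21 - k + 1)` matrix.
#' @export
unvectorize_pwm <- function(v, k) {
  ncol_out <- CONTEXT_LEN - k + 1L
  stopifnot(length(v) == 4L^k * ncol_out)
  matrix(v, nrow = 4L^k, ncol = ncol_out, byrow = TRUE,
         dimnames = list(kmer_names(k), pwm_positions(k)))
}

#' Serialize a PWM as TSV
#'
#' @param p PWM matrix.
#' @param path Output path; header row holds positions, first column the
#'   k-mer labels.
#' @export
write_pwm <- function(p, path) {
  df <- data.frame(kmer = rownames(p), as.data.frame(unclass(p), check.names = FALSE))
  names(df) <- c("kmer", colnames(p))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
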