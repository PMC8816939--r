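# Internal helpers shared across modules.

AUTOSOME_RE <- "^(chr)?([1-9]|1[0-9]|2[0-2])$"

is_autosome <- function(chrom) grepl(AUTOSOME_RE, chrom)

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library code never
#' perturbs the user's random stream. A `NULL` seed evaluates the code
#' under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive n independent child seeds (< 2^31) from one master seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Map a DNA string to integer codes A=0, C=1, G=2, T=3; anything else NA.
BASE_CODE <- local({
  x <- rep(NA_integer_, 127L)
  x[utf8ToInt("A")] <- 0L; x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L; x[utf8ToInt("T")] <- 3L
  x[utf8ToInt("a")] <- 0L; x[utf8ToInt("c")] <- 1L
  x[utf8ToInt("g")] <- 2L; x[utf8ToInt("t")] <- 3L
  x
})

dna_codes <- function(s) BASE_CODE[utf8ToInt(s)]

codes_to_dna <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes + 1L])
}

#' All k-mers over ACGT in lexicographic order
#' @noRd
kmer_names <- function(k) {
  stopifnot(k >= 1L, k <= 8L)
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  do.call(paste0, grid)
}

#' Normalize a genome argument to a named character vector of sequences
#'
#' Accepts a named character vector, a `Biostrings::DNAStringSet`, or a
#' path to a FASTA file.
#' @noRd
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome))) {
    stop("`genome` must be a named character vector, DNAStringSet or FASTA path")
  }
  # FASTA headers may carry descriptions after whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  toupper(genome)
}

#' Chromosome layout of a genome
#'
#' @param genome Named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA path.
#' @return A data frame with columns `chrom` and `length` (bp).
#' @export
genome_layout <- function(genome) {
  genome <- as_genome(genome)
  data.frame(chrom = names(genome), length = nchar(genome),
             row.names = NULL, stringsAsFactors = FALSE)
}
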