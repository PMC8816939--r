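# Shared synthetic world for the unit tests: a 2 x 1 Mb genome with one
# gain and one loss (20% of a chromosome each), a phased nucleosome
# track, annotated + scored healthy and tumor pools, and tri-nucleotide
# score weights trained on them. Built once per test run.

test_cfg <- function(...) {
  simulation_config(
    chrom_length = 1e6,
    cna = data.frame(chrom = c("chr1", "chr2"),
                     start = c(2e5, 5e5), end = c(4e5, 7e5),
                     copy = c(3L, 1L)),
    locus = list(chrom = "chr1", pos = 8e5),
    ...)
}

fixture_env <- new.env(parent = emptyenv())

test_world <- function() {
  if (!is.null(fixture_env$world)) return(fixture_env$world)
  cfg <- test_cfg()
  ref <- simulate_reference(cfg, seed = 404L)
  healthy <- simulate_fragments("healthy", 400000L, cfg, ref, seed = 405L)
  tumor <- simulate_fragments("tumor", 120000L, cfg, ref, seed = 406L)
  weights <- learn_pbnb_weights(healthy, tumor, ref$genome, k = 3L,
                                n_reps = 4L, rep_size = 30000L, seed = 407L)
  healthy <- score_fragments(annotate_dyad_distance(healthy, ref$track),
                             ref$genome, weights)
  tumor <- score_fragments(annotate_dyad_distance(tumor, ref$track),
                           ref$genome, weights)
  fixture_env$world <- list(cfg = cfg, ref = ref, healthy = healthy,
                            tumor = tumor, weights = weights)
  fixture_env$world
}

# A deterministic toy genome: "ACGT" repeated, two chromosomes.
toy_genome <- function(len = 100L) {
  s <- paste(rep("ACGT", ceiling(len / 4)), collapse = "")
  c(chr1 = substr(s, 1, len), chr2 = substr(s, 1, len))
}

# Random ACGT string of length n under the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force oracle: signed distance to the nearest dyad by linear scan,
# ties to the lower-coordinate dyad.
oracle_distance <- function(site, dyads) {
  d <- site - dyads
  d[order(abs(d), dyads)][1]
}

# Exhaustive maximum-probability path over all 3^n state sequences of a
# 3-state Gaussian HMM (shared sd, symmetric switching).
oracle_path <- function(x, means, sd, self = 0.99) {
  K <- 3L
  n <- length(x)
  lt <- matrix(log((1 - self) / 2), K, K); diag(lt) <- log(self)
  best <- NULL; best_lp <- -Inf
  grid <- expand.grid(rep(list(1:K), n))
  for (i in seq_len(nrow(grid))) {
    p <- as.integer(grid[i, ])
    lp <- log(1 / K) + sum(dnorm(x, means[p], sd, log = TRUE)) +
      sum(lt[cbind(p[-n], p[-1])])
    if (lp > best_lp) { best_lp <- lp; best <- p }
  }
  list(path = best, loglik = best_lp)
}
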