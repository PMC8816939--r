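# Synthetic cfDNA cohorts: a composition-controlled reference genome, a
# phased nucleosome track, and healthy/tumor fragment pools carrying
# every statistical structure the analysis assumes:
#
#   * healthy sizes: mono-nucleosomal mode near 167 bp plus a
#     di-nucleosomal peak near 334 bp;
#   * tumor sizes: left-shifted peaks (145 / 300 bp) plus a short
#     component over 74-144 bp;
#   * nucleosome-phased cleavage, with tumor ends concentrated inside
#     +/- 75 bp of dyads and healthy ends favoring linkers;
#   * origin-specific base composition in the +/- 10 bp cleavage context,
#     induced by rejection sampling against the fixed reference (the
#     motif signal is genuinely encoded in genomic sequence, exactly as
#     the analysis assumes) — a mono-nucleotide component at the cleavage
#     site plus a pure third-order (trinucleotide-parity) component, so
#     discrimination grows with k-mer order;
#   * tumor fragment placement weighted by a copy-number layout;
#   * a point mutation at a copy-neutral locus carried by every
#     tumor-origin fragment covering it.

#' Simulation configuration
#'
#' Returns the default study conditions, with any element overridden via
#' named arguments (nested lists are merged recursively).
#'
#' Defaults: two 20 Mb autosome-labelled chromosomes of i.i.d. uniform
#' composition; dyads every 187 bp (jitter SD 15); healthy sizes
#' 0.8 N(167, 15) + 0.2 N(334, 20); tumor sizes 0.35 U(74, 144) +
#' 0.5 N(145, 15) + 0.15 N(300, 20); healthy cleavage lands in the
#' linker with probability 0.6, tumor in the core with probability 0.7;
#' motif bias strengths `beta_mono = 0.12`, `beta_tri = 0.35`; one
#' single-copy gain (chr1:4-8 Mb) and one loss (chr2:10-14 Mb), each 20%
#' of a chromosome (the layout scales with `chrom_length` unless given
#' explicitly); mutation locus at the copy-neutral chr1:15,000,000,
#' mutant with probability 1 on tumor fragments. Explicit 64-entry trimer
#' weight tables (`motif$w_healthy` / `motif$w_tumor`) override the
#' parametric motif bias.
#'
#' @param ... Named overrides of the defaults.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    chrom_names = c("chr1", "chr2"),
    chrom_length = 20e6,
    base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    dyad_spacing = 187,
    dyad_jitter_sd = 15,
    sizes = list(
      healthy = list(w_short = 0, w_mono = 0.8, w_di = 0.2,
                     mu_mono = 167, sd_mono = 15, mu_di = 334, sd_di = 20,
                     short_lo = 74, short_hi = 144),
      tumor = list(w_short = 0.35, w_mono = 0.5, w_di = 0.15,
                   mu_mono = 145, sd_mono = 15, mu_di = 300, sd_di = 20,
                   short_lo = 74, short_hi = 144)),
    placement = list(p_core_healthy = 0.4, p_core_tumor = 0.7,
                     core_halfwidth = 75),
    motif = list(beta_mono = 0.12, beta_tri = 0.35),
    cna = NULL,
    locus = NULL,
    mutant_prob = 1,
    cohort = list(n_healthy_pool = 6e5, n_tumor_pool = 2e5,
                  n_replicates = 10L, replicate_size = 2e5,
                  patient_fractions = c(0.1, 0.2, 0.3, 0.5),
                  patient_size = 2e5)
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
    cfg <- merge_config(cfg, overrides)
  }
  # The default CNA layout and mutation locus scale with the chromosome
  # length: one single-copy gain and one loss spanning 20% of a
  # chromosome each, and a copy-neutral locus clear of both.
  L <- cfg$chrom_length
  if (is.null(cfg$cna)) {
    cfg$cna <- data.frame(chrom = c("chr1", "chr2"),
                          start = c(0.2, 0.5) * L, end = c(0.4, 0.7) * L,
                          copy = c(3L, 1L))
  }
  if (is.null(cfg$locus)) {
    cfg$locus <- list(chrom = "chr1", pos = round(0.75 * L))
  }
  structure(cfg, class = "simulation_config")
}

# Recursive override merge; data frames (e.g. the CNA layout) are
# replaced wholesale, never merged column-wise.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    b <- base[[nm]]
    o <- override[[nm]]
    if (is.list(b) && !is.data.frame(b) && is.list(o) && !is.data.frame(o)) {
      base[[nm]] <- merge_config(b, o)
    } else {
      base[[nm]] <- o
    }
  }
  base
}

# Trimer acceptance weights at the cleavage site for one origin.
# mono component: AT-preference (healthy) vs CG-preference (tumor) at
# the central base; parity component: a pure third-order interaction
# (product of per-base signs), whose mono and di marginals vanish.
trimer_weights <- function(origin, motif) {
  explicit <- motif[[paste0("w_", origin)]]
  if (!is.null(explicit)) {
    stopifnot(length(explicit) == 64L, all(explicit > 0))
    return(as.numeric(explicit))
  }
  s <- if (origin == "healthy") 1 else -1
  base_sign <- c(A = 1, C = -1, G = -1, T = 1)      # central-base preference
  parity_sign <- c(A = 1, C = 1, G = -1, T = -1)
  tri <- kmer_names(3L)
  center <- substr(tri, 2L, 2L)
  parity <- vapply(strsplit(tri, ""), function(b) prod(parity_sign[b]), 0)
  w <- (1 + s * motif$beta_mono * base_sign[center]) *
       (1 + s * motif$beta_tri * parity)
  stopifnot(all(w > 0))
  unname(w)
}

#' Simulate the reference genome and nucleosome track
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; the output is deterministic given
#'   (`cfg`, `seed`).
#' @return List with `genome` (named character vector), `track`
#'   (a [nucleosome_track()] labelled `"synthetic"`) and `layout`.
#' @export
simulate_reference <- function(cfg = simulation_config(), seed = 1L) {
  with_seed(seed, {
    genome <- setNames(vector("character", length(cfg$chrom_names)),
                       cfg$chrom_names)
    dyads <- setNames(vector("list", length(cfg$chrom_names)), cfg$chrom_names)
    margin <- 300L
    for (chr in cfg$chrom_names) {
      len <- as.integer(cfg$chrom_length)
      codes <- sample.int(4L, len, replace = TRUE, prob = cfg$base_probs) - 1L
      genome[[chr]] <- codes_to_dna(codes)
      n_est <- ceiling(len / cfg$dyad_spacing) + 100L
      gaps <- pmax(round(stats::rnorm(n_est, cfg$dyad_spacing, cfg$dyad_jitter_sd)), 30)
      pos <- margin + cumsum(gaps)
      dyads[[chr]] <- as.integer(pos[pos < len - margin])
    }
    list(genome = genome,
         track = nucleosome_track(dyads, label = "synthetic"),
         layout = data.frame(chrom = cfg$chrom_names,
                             length = as.integer(cfg$chrom_length)))
  })
}

# Copy number at integer positions of one chromosome under the layout.
copy_at <- function(chrom, pos, cna) {
  copy <- rep(2L, length(pos))
  rows <- which(cna$chrom == chrom)
  for (i in rows) {
    hit <- pos >= cna$start[i] & pos < cna$end[i]
    copy[hit] <- cna$copy[i]
  }
  copy
}

# Sample one size per fragment from the origin's mixture.
sample_sizes <- function(m, sz) {
  u <- stats::runif(m)
  out <- numeric(m)
  short <- u < sz$w_short
  mono <- !short & u < sz$w_short + sz$w_mono
  di <- !short & !mono
  out[short] <- sample.int(sz$short_hi - sz$short_lo + 1L, sum(short),
                           replace = TRUE) + sz$short_lo - 1L
  out[mono] <- round(stats::rnorm(sum(mono), sz$mu_mono, sz$sd_mono))
  out[di] <- round(stats::rnorm(sum(di), sz$mu_di, sz$sd_di))
  as.integer(out)
}

# Dyad-relative start-site offsets: core (uniform within +/- hw) with the
# origin's core probability, otherwise linker (uniform over
# +/- (hw+1 .. half the dyad spacing)).
sample_offsets <- function(m, p_core, hw, spacing) {
  max_linker <- max(floor(spacing / 2), hw + 1L)
  core <- stats::runif(m) < p_core
  off <- integer(m)
  off[core] <- sample.int(2L * hw + 1L, sum(core), replace = TRUE) - hw - 1L
  n_link <- sum(!core)
  mag <- sample.int(max_linker - hw, n_link, replace = TRUE) + hw
  off[!core] <- mag * sample(c(-1L, 1L), n_link, replace = TRUE)
  off
}

#' Simulate a fragment pool of one origin
#'
#' Each fragment is built by (1) picking a dyad — copy-number-weighted
#' for tumor fragments, uniform for healthy; (2) placing the start site
#' at a dyad-relative offset from the origin's core/linker mixture;
#' (3) drawing a size from the origin's size mixture; (4) accepting the
#' candidate by rejection sampling against the origin's cleavage-motif
#' weights evaluated on the reference trinucleotides at both the start
#' site and the end site. Tumor fragments covering the mutation locus
#' are flagged mutant.
#'
#' @param origin `"healthy"` or `"tumor"`.
#' @param n Number of fragments to generate.
#' @param cfg A [simulation_config()].
#' @param reference Output of [simulate_reference()].
#' @param seed Integer seed.
#' @return Fragment data frame with `origin` and `is_mutant` columns.
#' @export
simulate_fragments <- function(origin = c("healthy", "tumor"), n, cfg,
                               reference, seed = 1L) {
  origin <- match.arg(origin)
  if (n == 0L) {
    return(fragment_table(character(), integer(), integer(),
                          origin = character(), is_mutant = logical()))
  }
  genome <- reference$genome
  dyads <- reference$track$dyads[cfg$chrom_names]
  codes <- lapply(genome, dna_codes)
  wt <- trimer_weights(origin, cfg$motif)
  wmax2 <- max(wt)^2
  sz <- cfg$sizes[[origin]]
  p_core <- if (origin == "healthy") cfg$placement$p_core_healthy else
    cfg$placement$p_core_tumor
  hw <- cfg$placement$core_halfwidth
  # per-dyad weights: local copy number for tumor, uniform for healthy
  dyad_w <- lapply(cfg$chrom_names, function(chr) {
    if (origin == "tumor") copy_at(chr, dyads[[chr]], cfg$cna) / 2 else
      rep(1, length(dyads[[chr]]))
  })
  names(dyad_w) <- cfg$chrom_names
  chrom_w <- vapply(dyad_w, sum, 0)
  with_seed(seed, {
    out <- vector("list", 0L)
    got <- 0L
    tried <- 0L
    accepted <- 0L
    while (got < n) {
      m <- as.integer(min(max(ceiling((n - got) * 2.2), 5e4), 4e6))
      chr_idx <- sample.int(length(chrom_w), m, replace = TRUE,
                            prob = chrom_w)
      starts <- integer(m); chroms <- character(m)
      for (ci in seq_along(cfg$chrom_names)) {
        j <- which(chr_idx == ci)
        if (length(j) == 0L) next
        chr <- cfg$chrom_names[ci]
        di <- sample.int(length(dyads[[chr]]), length(j), replace = TRUE,
                         prob = dyad_w[[chr]])
        starts[j] <- dyads[[chr]][di] +
          sample_offsets(length(j), p_core, hw, cfg$dyad_spacing)
        chroms[j] <- chr
      }
      sizes <- sample_sizes(m, sz)
      ends <- starts + sizes
      len <- as.integer(cfg$chrom_length)
      ok <- sizes >= 1L & sizes <= 800L &
        starts - 11L >= 0L & ends + 10L <= len - 1L
      # motif rejection on the site trinucleotides (positions -1, 0, +1)
      acc_p <- rep(0, m)
      for (ci in seq_along(cfg$chrom_names)) {
        chr <- cfg$chrom_names[ci]
        j <- which(ok & chroms == chr)
        if (length(j) == 0L) next
        cd <- codes[[chr]]
        ts <- cd[starts[j]] * 16L + cd[starts[j] + 1L] * 4L + cd[starts[j] + 2L]
        te <- cd[ends[j] - 1L] * 16L + cd[ends[j]] * 4L + cd[ends[j] + 1L]
        acc_p[j] <- wt[ts + 1L] * wt[te + 1L] / wmax2
      }
      keep <- ok & stats::runif(m) < acc_p
      tried <- tried + m
      accepted <- accepted + sum(keep)
      if (tried >= 2e5 && accepted / tried < 0.01) {
        stop("simulate_fragments: rejection-sampling acceptance rate below 1%; ",
             "reduce the motif bias strength")
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chroms[keep], start = as.integer(starts[keep]),
        end = as.integer(ends[keep]), stringsAsFactors = FALSE)
      got <- got + sum(keep)
    }
    df <- do.call(rbind, out)[seq_len(n), , drop = FALSE]
    rownames(df) <- NULL
    df$size <- df$end - df$start
    df$origin <- origin
    covers <- df$chrom == cfg$locus$chrom &
      df$start <= cfg$locus$pos & df$end > cfg$locus$pos
    df$is_mutant <- origin == "tumor" & covers &
      stats::runif(nrow(df)) < cfg$mutant_prob
    df
  })
}

#' Mix healthy and tumor pools into a patient-like cohort
#'
#' Each fragment is independently of tumor origin with probability `f`;
#' rows are drawn without replacement from the pools. The `origin`
#' column is retained as hidden truth for evaluation only.
#'
#' @param healthy_pool,tumor_pool Fragment data frames from
#'   [simulate_fragments()].
#' @param f True tumor fraction in `[0, 1]`.
#' @param n_total Cohort size.
#' @param seed Integer seed.
#' @return Fragment data frame of `n_total` rows in random order.
#' @export
mix_cohort <- function(healthy_pool, tumor_pool, f, n_total, seed = 1L) {
  stopifnot(f >= 0, f <= 1)
  with_seed(seed, {
    n_tumor <- stats::rbinom(1L, n_total, f)
    n_healthy <- n_total - n_tumor
    if (n_healthy > nrow(healthy_pool) || n_tumor > nrow(tumor_pool)) {
      stop(sprintf(
        "mix_cohort: pools too small (need %d healthy of %d, %d tumor of %d)",
        n_healthy, nrow(healthy_pool), n_tumor, nrow(tumor_pool)))
    }
    df <- rbind(
      healthy_pool[sample.int(nrow(healthy_pool), n_healthy), , drop = FALSE],
      tumor_pool[sample.int(nrow(tumor_pool), n_tumor), , drop = FALSE])
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Generate a complete on-disk test cohort
#'
#' Writes the reference FASTA, the nucleosome track (BED3), the healthy
#' and tumor pools and the control replicates (BED+ with truth columns),
#' patient mixtures at the configured tumor fractions, and a truth JSON
#' recording the configuration, seeds and per-file true fractions.
#' Byte-identical when regenerated with the same config and master seed.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, a manifest list of written paths plus the in-memory
#'   objects (`reference`, `healthy_pool`, `tumor_pool`, `controls`,
#'   `patients`).
#' @export
make_test_cohort <- function(cfg = simulation_config(), out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "controls"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "patients"), showWarnings = FALSE)
  seeds <- spawn_seeds(seed, 4L + cfg$cohort$n_replicates +
                         length(cfg$cohort$patient_fractions))
  reference <- simulate_reference(cfg, seeds[1])
  fa_path <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference$genome), fa_path)
  track_path <- file.path(out_dir, "nucleosomes.bed")
  track_df <- do.call(rbind, lapply(names(reference$track$dyads), function(chr) {
    d <- reference$track$dyads[[chr]]
    data.frame(chrom = chr, start = d - 73L, end = d + 74L)
  }))
  data.table::fwrite(track_df, track_path, sep = "\t", col.names = FALSE)
  healthy_pool <- simulate_fragments("healthy", cfg$cohort$n_healthy_pool,
                                     cfg, reference, seeds[2])
  tumor_pool <- simulate_fragments("tumor", cfg$cohort$n_tumor_pool,
                                   cfg, reference, seeds[3])
  healthy_path <- file.path(out_dir, "healthy_pool.bed")
  tumor_path <- file.path(out_dir, "tumor_pool.bed")
  write_fragments(healthy_pool, healthy_path)
  write_fragments(tumor_pool, tumor_path)
  control_paths <- character(cfg$cohort$n_replicates)
  controls <- vector("list", cfg$cohort$n_replicates)
  for (r in seq_len(cfg$cohort$n_replicates)) {
    controls[[r]] <- subsample(healthy_pool, cfg$cohort$replicate_size,
                               seed = seeds[4L + r])
    control_paths[r] <- file.path(out_dir, "controls",
                                  sprintf("control_%02d.bed", r))
    write_fragments(controls[[r]], control_paths[r])
  }
  patients <- vector("list", length(cfg$cohort$patient_fractions))
  patient_paths <- character(length(patients))
  for (i in seq_along(cfg$cohort$patient_fractions)) {
    f <- cfg$cohort$patient_fractions[i]
    patients[[i]] <- mix_cohort(healthy_pool, tumor_pool, f,
                                cfg$cohort$patient_size,
                                seed = seeds[4L + cfg$cohort$n_replicates + i])
    patient_paths[i] <- file.path(out_dir, "patients",
                                  sprintf("patient_f%s.bed", format(f)))
    write_fragments(patients[[i]], patient_paths[i])
  }
  truth <- list(
    seed = seed,
    chrom_length = cfg$chrom_length,
    cna = cfg$cna,
    locus = cfg$locus,
    patients = data.frame(path = basename(patient_paths),
                          true_tumor_fraction = cfg$cohort$patient_fractions),
    controls = basename(control_paths))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(list(
    paths = list(reference = fa_path, track = track_path,
                 healthy_pool = healthy_path, tumor_pool = tumor_path,
                 controls = control_paths, patients = patient_paths,
                 truth = truth_path),
    reference = reference, healthy_pool = healthy_pool,
    tumor_pool = tumor_pool, controls = controls, patients = patients))
}

#' Learn score weights from two fragment cohorts
#'
#' Pipeline wrapper: draws `n_reps` bootstrap replicates of `rep_size`
#' fragments from each cohort, extracts start/end contexts, builds the
#' replicate PWM matrices for both sites and returns the oriented PC1
#' loading weights. Mirrors the published training design (10 replicates
#' of 3 million fragments, healthy pool vs the highest-burden tumor
#' sample); reduced sizes are appropriate for synthetic cohorts.
#'
#' @param healthy_frags,tumor_frags Fragment data frames.
#' @param genome Reference (named character vector / DNAStringSet / path).
#' @param k k-mer order (default 3, the published choice).
#' @param n_reps Bootstrap replicates per cohort.
#' @param rep_size Fragments per replicate.
#' @param seed Master seed.
#' @return A `loading_weights` object.
#' @export
learn_pbnb_weights <- function(healthy_frags, tumor_frags, genome, k = 3L,
                               n_reps = 10L, rep_size = 3e6, seed = NULL) {
  seeds <- spawn_seeds(seed, 2L * n_reps)
  draw <- function(frags, s) {
    extract_context(subsample(frags, min(rep_size, nrow(frags)), s), genome)
  }
  h_reps <- lapply(seq_len(n_reps), function(r) draw(healthy_frags, seeds[r]))
  t_reps <- lapply(seq_len(n_reps), function(r) draw(tumor_frags, seeds[n_reps + r]))
  m_start <- assemble_replicate_matrix(h_reps, t_reps, k = k, site = "start")
  m_end <- assemble_replicate_matrix(h_reps, t_reps, k = k, site = "end")
  learn_weights(m_start, m_end)
}
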