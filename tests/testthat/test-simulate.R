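test_that("reference simulation is deterministic with phased dyads", {
  cfg <- test_cfg()
  r1 <- simulate_reference(cfg, seed = 1)
  r2 <- simulate_reference(cfg, seed = 1)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$track$dyads, r2$track$dyads)
  expect_equal(sum(nchar(r1$genome)), 2e6)
  expect_false(identical(r1$genome, simulate_reference(cfg, seed = 2)$genome))
  d <- r1$track$dyads$chr1
  expect_true(all(diff(d) > 0))
  expect_lt(abs(mean(diff(d)) - 187), 2)
})

test_that("fragment pools carry the configured size and placement structure", {
  w <- test_world()
  expect_equal(nrow(simulate_fragments("healthy", 0L, w$cfg, w$ref)), 0L)
  expect_true(all(w$healthy$size >= 1 & w$healthy$size <= 800))
  # tumor mass in the short bin far exceeds healthy mass
  in_short <- function(f) mean(f$size >= 74 & f$size <= 144)
  expect_gt(in_short(w$tumor), 0.45)
  expect_lt(in_short(w$healthy), 0.12)
  # determinism
  a <- simulate_fragments("healthy", 500L, w$cfg, w$ref, seed = 9)
  b <- simulate_fragments("healthy", 500L, w$cfg, w$ref, seed = 9)
  expect_identical(a, b)
})

test_that("tumor placement follows the copy-number layout at ratio ~1.5", {
  w <- test_world()
  tu <- simulate_fragments("tumor", 200000L, w$cfg, w$ref, seed = 11)
  mid <- (tu$start + tu$end) / 2
  gain <- w$cfg$cna[w$cfg$cna$copy == 3L, ]
  in_gain <- tu$chrom == gain$chrom & mid >= gain$start & mid < gain$end
  # density per bp in the copy-3 segment vs a copy-2 segment of equal width
  neutral <- tu$chrom == gain$chrom & mid >= 6e5 & mid < 8e5
  ratio <- sum(in_gain) / sum(neutral)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 1.6)
  # loss segment at ~0.5x
  loss <- w$cfg$cna[w$cfg$cna$copy == 1L, ]
  in_loss <- tu$chrom == loss$chrom & mid >= loss$start & mid < loss$end
  neutral2 <- tu$chrom == loss$chrom & mid >= 1e5 & mid < 3e5
  expect_lt(sum(in_loss) / sum(neutral2), 0.62)
})

test_that("cohort mixing hits the requested tumor fraction within 3 sigma", {
  w <- test_world()
  m0 <- mix_cohort(w$healthy, w$tumor, 0, 5000, seed = 13)
  expect_true(all(m0$origin == "healthy"))
  m1 <- mix_cohort(w$healthy, w$tumor, 1, 5000, seed = 13)
  expect_true(all(m1$origin == "tumor"))
  m <- mix_cohort(w$healthy, w$tumor, 0.3, 10000, seed = 13)
  expect_equal(nrow(m), 10000L)
  expect_lt(abs(sum(m$origin == "tumor") - 3000), 3 * sqrt(10000 * 0.3 * 0.7))
  expect_error(mix_cohort(w$healthy[1:10, ], w$tumor, 0, 100),
               "pools too small")
})

test_that("motif rejection encodes origin-specific context bias in the reference", {
  w <- test_world()
  ctx_h <- suppressMessages(extract_context(w$healthy[1:20000, ], w$ref$genome))
  ctx_t <- suppressMessages(extract_context(w$tumor[1:20000, ], w$ref$genome))
  ph <- build_pwm(ctx_h, k = 1, site = "start")
  pt <- build_pwm(ctx_t, k = 1, site = "start")
  # the cleavage site (position 0) is AT-enriched in healthy, CG in tumor
  at_h <- sum(ph[c("A", "T"), "0"]); at_t <- sum(pt[c("A", "T"), "0"])
  expect_gt(at_h, at_t)
  expect_gt(at_h, 0.5)
  # flanking positions stay near the uniform composition
  expect_lt(max(abs(ph[, "-10"] - 0.25)), 0.03)
  # disabling the bias removes the difference
  cfg0 <- test_cfg(motif = list(beta_mono = 0, beta_tri = 0))
  h0 <- simulate_fragments("healthy", 20000L, cfg0, w$ref, seed = 15)
  t0 <- simulate_fragments("tumor", 20000L, cfg0, w$ref, seed = 16)
  p0h <- build_pwm(suppressMessages(extract_context(h0, w$ref$genome)), 1, "start")
  p0t <- build_pwm(suppressMessages(extract_context(t0, w$ref$genome)), 1, "start")
  expect_lt(max(abs(p0h[, "0"] - p0t[, "0"])), 0.03)
})

test_that("an overstrong motif bias aborts with an actionable error", {
  w <- test_world()
  cfg_bad <- test_cfg(motif = list(w_healthy = c(1000, rep(1, 63))))
  expect_error(simulate_fragments("healthy", 5000L, cfg_bad, w$ref, seed = 17),
               "acceptance rate below 1%")
})

test_that("make_test_cohort writes a complete, reproducible bundle", {
  cfg <- simulation_config(
    chrom_length = 2e5,
    cna = data.frame(chrom = c("chr1", "chr2"), start = c(4e4, 1e5),
                     end = c(8e4, 1.4e5), copy = c(3L, 1L)),
    locus = list(chrom = "chr1", pos = 1.6e5),
    cohort = list(n_healthy_pool = 8000, n_tumor_pool = 3000,
                  n_replicates = 3L, replicate_size = 2000,
                  patient_fractions = c(0.2, 0.5), patient_size = 4000))
  d1 <- withr::local_tempdir()
  b1 <- make_test_cohort(cfg, d1, seed = 19)
  expect_length(b1$paths$controls, 3L)
  expect_length(b1$paths$patients, 2L)
  expect_true(all(file.exists(unlist(b1$paths))))
  truth <- jsonlite::read_json(b1$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$patients$true_tumor_fraction, c(0.2, 0.5))
  # the FASTA and track round-trip through the standard readers
  g <- genome_layout(b1$paths$reference)
  expect_equal(g$length, c(2e5L, 2e5L))
  tr <- load_nucleosome_track(b1$paths$track)
  expect_identical(tr$dyads, b1$reference$track$dyads)
  frags <- suppressMessages(load_fragments(b1$paths$healthy_pool))
  expect_identical(frags[, c("chrom", "start", "end")],
                   b1$healthy_pool[, c("chrom", "start", "end")])
  # byte-identical regeneration under the same master seed
  d2 <- withr::local_tempdir()
  b2 <- make_test_cohort(cfg, d2, seed = 19)
  for (f in c("reference", "track", "healthy_pool", "truth")) {
    expect_identical(readLines(b1$paths[[f]]), readLines(b2$paths[[f]]))
  }
})

test_that("switching each bias off removes the corresponding separation", {
  w <- test_world()
  cfg_flat <- test_cfg(
    sizes = list(tumor = list(w_short = 0, w_mono = 0.8, w_di = 0.2,
                              mu_mono = 167, sd_mono = 15,
                              mu_di = 334, sd_di = 20,
                              short_lo = 74, short_hi = 144)),
    placement = list(p_core_healthy = 0.4, p_core_tumor = 0.4,
                     core_halfwidth = 75))
  t_flat <- simulate_fragments("tumor", 30000L, cfg_flat, w$ref, seed = 21)
  h <- w$healthy
  expect_lt(abs(mean(t_flat$size >= 74 & t_flat$size <= 144) -
                mean(h$size >= 74 & h$size <= 144)), 0.02)
  t_ann <- annotate_dyad_distance(t_flat, w$ref$track)
  core_rate <- function(f) mean(classify_core_linker(f) == "core", na.rm = TRUE)
  expect_lt(abs(core_rate(t_ann) - core_rate(h)), 0.04)
})
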