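test_that("replicate PWM matrices have one vectorized PWM row per replicate", {
  set.seed(23)
  reps <- lapply(1:2, function(i) vapply(1:30, function(j) random_dna(21L), ""))
  m <- assemble_replicate_matrix(reps, reps, k = 1, site = "start")
  expect_equal(dim(m), c(4L, 84L))
  expect_equal(attr(m, "cohort"), rep(c("healthy", "tumor"), each = 2))
  # identical contexts in every replicate -> identical rows
  same <- assemble_replicate_matrix(list(reps[[1]], reps[[1]]),
                                    list(reps[[1]], reps[[1]]), k = 3, site = "end")
  expect_equal(dim(same), c(4L, 1216L))
  expect_true(all(apply(same, 2, function(col) length(unique(col)) == 1L)))
  expect_error(assemble_replicate_matrix(list(character()), reps, k = 1),
               "empty replicate")
})

test_that("learning is degenerate on indistinguishable cohorts and flips with labels", {
  set.seed(29)
  one <- vapply(1:40, function(j) random_dna(21L), "")
  m_same <- assemble_replicate_matrix(list(one, one), list(one, one),
                                      k = 1, site = "start")
  expect_error(learn_weights(m_same, m_same), "degenerate")
  w <- test_world()
  reps_h <- lapply(1:3, function(i) suppressMessages(
    extract_context(subsample(w$healthy, 5000, seed = i), w$ref$genome)))
  reps_t <- lapply(1:3, function(i) suppressMessages(
    extract_context(subsample(w$tumor, 5000, seed = 10 + i), w$ref$genome)))
  ms <- assemble_replicate_matrix(reps_h, reps_t, k = 3, site = "start")
  me <- assemble_replicate_matrix(reps_h, reps_t, k = 3, site = "end")
  ww <- learn_weights(ms, me)
  # healthy replicates project positive, tumor negative, non-overlapping
  for (site in c("start", "end")) {
    proj <- ww$projections[[site]]
    cohort <- attr(ms, "cohort")
    expect_true(all(proj[cohort == "healthy"] > 0))
    expect_true(all(proj[cohort == "tumor"] < 0))
  }
  expect_equal(sum(ww$start^2), 1, tolerance = 1e-9)  # unit-norm loadings
  # swapping the cohort labels flips every loading sign exactly
  ms_swap <- assemble_replicate_matrix(reps_t, reps_h, k = 3, site = "start")
  me_swap <- assemble_replicate_matrix(reps_t, reps_h, k = 3, site = "end")
  ww_swap <- learn_weights(ms_swap, me_swap)
  expect_equal(ww_swap$start, -ww$start, tolerance = 1e-12)
  expect_equal(ww_swap$end, -ww$end, tolerance = 1e-12)
})

test_that("PC1 projections match a direct eigen-decomposition", {
  set.seed(31)
  reps_h <- lapply(1:3, function(i) vapply(1:50, function(j)
    paste0(random_dna(10L), "A", random_dna(10L)), ""))
  reps_t <- lapply(1:3, function(i) vapply(1:50, function(j)
    paste0(random_dna(10L), sample(c("C", "G"), 1), random_dna(10L)), ""))
  m <- assemble_replicate_matrix(reps_h, reps_t, k = 3, site = "start")
  ww <- learn_weights(m, m)
  x <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(x), symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (sum(v * ww$start) < 0) v <- -v
  expect_equal(unname(ww$start), v, tolerance = 1e-8)
  expect_equal(unname(ww$projections$start), unname(drop(x %*% v)),
               tolerance = 1e-8)
})

test_that("indicators are binary with 21-k+1 ones in the shared index space", {
  set.seed(37)
  ctx <- random_dna(21L)
  lens <- c(84L, 320L, 1216L)
  for (k in 1:3) {
    ind <- make_indicator(ctx, ctx, k = k)
    expect_length(ind$S, lens[k])
    expect_length(ind$E, lens[k])
    expect_equal(sum(ind$S), 21 - k + 1)
    expect_true(all(ind$S %in% c(0, 1)))
  }
  indA <- make_indicator(strrep("A", 21), strrep("A", 21), k = 1)
  expect_equal(which(indA$S == 1), 1:21)   # the A-row block spans indices 1..21
})

test_that("scores are the stated dot products: additive, linear, zero on zero", {
  w <- test_world()
  ctx <- suppressMessages(extract_context(w$healthy[1:20, ], w$ref$genome))
  zero <- w$weights
  zero$start[] <- 0; zero$end[] <- 0
  ind <- make_indicator(ctx$start_context[1], ctx$end_context[1], k = 3)
  expect_equal(score_fragment(ind, zero), 0)
  full <- score_fragment(ind, w$weights)
  s_only <- w$weights; s_only$end[] <- 0
  e_only <- w$weights; e_only$start[] <- 0
  expect_equal(score_fragment(ind, s_only) + score_fragment(ind, e_only), full)
  # linear in the loadings
  twice <- w$weights; twice$start <- 2 * twice$start; twice$end <- 2 * twice$end
  expect_equal(score_fragment(ind, twice), 2 * full)
  # a single nonzero loading picks out exactly one context match
  single <- zero
  single$start[paste0(substr(ctx$start_context[1], 1, 3), "@-10")] <- 0.5
  expect_equal(score_fragment(ind, single), 0.5)
  expect_error(score_fragment(make_indicator(ctx$start_context[1],
                                             ctx$end_context[1], k = 1),
                              w$weights), "dimension mismatch")
})

test_that("bulk scoring equals per-fragment indicator scoring", {
  w <- test_world()
  sub <- w$healthy[101:130, ]
  scored <- score_fragments(sub, w$ref$genome, w$weights)
  ctx <- suppressMessages(extract_context(sub, w$ref$genome))
  kept <- attr(ctx, "kept")
  manual <- vapply(seq_along(kept), function(i) {
    score_fragment(make_indicator(ctx$start_context[i], ctx$end_context[i], k = 3),
                   w$weights)
  }, 0)
  expect_equal(scored$pbnb_score[kept], manual, tolerance = 1e-12)
})

test_that("held-out healthy fragments score higher than tumor fragments", {
  w <- test_world()
  expect_gt(mean(w$healthy$pbnb_score, na.rm = TRUE),
            mean(w$tumor$pbnb_score, na.rm = TRUE))
})

test_that("the KS statistic is an exact sup-ECDF gap", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 1), c(2, 3)), 1)
  expect_error(ks_statistic(numeric(), 1), "empty")
  set.seed(41)
  a <- rnorm(200); b <- rnorm(150, 0.4)
  expect_equal(ks_statistic(a, b),
               unname(suppressWarnings(stats::ks.test(a, b))$statistic))
  # ties handled exactly
  expect_equal(ks_statistic(c(1, 1, 2), c(1, 2, 2)), 1/3)
  # invariant under a common monotone transform
  expect_equal(ks_statistic(exp(a), exp(b)), ks_statistic(a, b))
})

test_that("tri-nucleotide scores separate cohorts at least as well as mono", {
  w <- test_world()
  D <- vapply(c(1L, 3L), function(k) {
    wk <- learn_pbnb_weights(w$healthy, w$tumor, w$ref$genome, k = k,
                             n_reps = 3L, rep_size = 20000L, seed = 43L)
    h <- score_fragments(w$healthy[1:30000, ], w$ref$genome, wk)$pbnb_score
    t <- score_fragments(w$tumor[1:30000, ], w$ref$genome, wk)$pbnb_score
    ks_statistic(h[!is.na(h)], t[!is.na(t)])
  }, 0)
  expect_gte(D[2], D[1])
})

test_that("score selection is inclusive, direction-aware and partitions", {
  f <- fragment_table("chr1", c(0L, 10L, 20L), c(100L, 110L, 120L),
                      pbnb_score = c(-0.5, 0, 0.4))
  expect_equal(nrow(select_by_score(f, -0.3, "le")), 1L)
  expect_identical(select_by_score(f, max(f$pbnb_score), "le"), f)
  le <- select_by_score(f, 0, "le"); ge <- select_by_score(f, 0, "ge")
  expect_equal(sort(unique(c(le$start, ge$start))), sort(f$start))  # union is all
  expect_equal(intersect(le$start, ge$start),
               f$start[f$pbnb_score == 0])
  f$pbnb_score[2] <- NA
  expect_error(select_by_score(f, 0, "le"), "pbnb_score")
})

test_that("weights serialize and reload faithfully", {
  w <- test_world()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w$weights, path)
  back <- read_weights(path)
  expect_equal(back$k, 3L)
  expect_equal(back$start, w$weights$start, tolerance = 1e-12)
  expect_equal(back$end, w$weights$end, tolerance = 1e-12)
})
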