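# ctDNA in-silico bootstrap enrichment process (CISBEP).
#
# Apply a fragment selection, repeatedly down-sample to shallow-WGS
# scale, build a selection-matched panel of normals from the control
# pool, estimate tumor fraction per replicate, and report the relative
# tumor fraction: median over selected replicates divided by the median
# over unselected (baseline) replicates.

#' Declarative fragment selector
#'
#' A conjunction of up to three conditions: size in a union of bins,
#' dyad class (core/linker within a window), and a score threshold with
#' direction. All `NULL` means the identity selection.
#'
#' @param size_bins Data frame with `lo`/`hi` columns, or `NULL`.
#' @param dyad_class `"core"`, `"linker"` or `NULL`.
#' @param dyad_window Half-window (bp) for the dyad classification.
#' @param score_threshold Numeric score cutoff, or `NULL`.
#' @param score_direction `"le"` or `"ge"`.
#' @param label Human-readable label; auto-generated when `NULL`.
#' @return A `feature_selector` object.
#' @export
feature_selector <- function(size_bins = NULL, dyad_class = NULL,
                             dyad_window = 75L, score_threshold = NULL,
                             score_direction = c("le", "ge"), label = NULL) {
  score_direction <- match.arg(score_direction)
  if (!is.null(dyad_class)) dyad_class <- match.arg(dyad_class, c("core", "linker"))
  if (is.null(label)) {
    parts <- character()
    if (!is.null(size_bins)) {
      parts <- c(parts, paste(paste0(size_bins$lo, "-", size_bins$hi), collapse = ","))
    }
    if (!is.null(dyad_class)) parts <- c(parts, dyad_class)
    if (!is.null(score_threshold)) {
      parts <- c(parts, sprintf("score%s%g",
                                if (score_direction == "le") "<=" else ">=",
                                score_threshold))
    }
    label <- if (length(parts) == 0L) "all" else paste(parts, collapse = " & ")
  }
  structure(list(size_bins = size_bins, dyad_class = dyad_class,
                 dyad_window = as.integer(dyad_window),
                 score_threshold = score_threshold,
                 score_direction = score_direction, label = label),
            class = "feature_selector")
}

#' @export
print.feature_selector <- function(x, ...) {
  cat("Feature selector:", x$label, "\n")
  invisible(x)
}

#' Apply a feature selector to a fragment table
#'
#' @param frags Fragment data frame carrying whatever annotations the
#'   selector needs (`size`, `d_start`/`d_end`, `pbnb_score`).
#' @param selector A [feature_selector()].
#' @return The selected subset, order preserved.
#' @export
apply_selector <- function(frags, selector) {
  stopifnot(inherits(selector, "feature_selector"))
  if (!is.null(selector$size_bins)) {
    frags <- select_by_size(frags, selector$size_bins)
  }
  if (!is.null(selector$dyad_class)) {
    cls <- classify_core_linker(frags, w = selector$dyad_window)
    frags <- frags[!is.na(cls) & cls == selector$dyad_class, , drop = FALSE]
  }
  if (!is.null(selector$score_threshold)) {
    frags <- select_by_score(frags, selector$score_threshold,
                             selector$score_direction)
  }
  frags
}

#' Uniform down-sampling without replacement
#'
#' @param frags Fragment data frame with at least `n` rows (an error
#'   names both sizes otherwise, mirroring the rule that selections
#'   retaining fewer fragments than one shallow-WGS replicate are not
#'   analysed).
#' @param n Replicate size (default 2.2 million fragments, ~0.1x genome
#'   coverage).
#' @param seed Seed for this draw; the caller's RNG state is untouched.
#' @return `n` rows of `frags` in original relative order.
#' @export
subsample <- function(frags, n = 2.2e6, seed = NULL) {
  n <- as.integer(n)
  if (nrow(frags) < n) {
    stop(sprintf("subsample: population has %d fragments, fewer than n = %d",
                 nrow(frags), n))
  }
  if (nrow(frags) == n) return(frags)
  idx <- with_seed(seed, sort(sample.int(nrow(frags), n)))
  frags[idx, , drop = FALSE]
}

# One CISBEP arm: PoN from control subsamples, tumor fraction per
# patient subsample.
cisbep_arm <- function(patient_frags, control_frags, n_reps, n, seeds,
                       layout, bin_width, selection_label, ...) {
  if (nrow(control_frags) < n) {
    stop(sprintf(
      "cisbep: selected control population has %d fragments, fewer than n = %d (selection '%s')",
      nrow(control_frags), n, selection_label))
  }
  if (nrow(patient_frags) < n) {
    stop(sprintf(
      "cisbep: selected patient population has %d fragments, fewer than n = %d (selection '%s')",
      nrow(patient_frags), n, selection_label))
  }
  ctrl_bc <- lapply(seq_len(n_reps), function(r) {
    bin_fragments(subsample(control_frags, n, seeds[r]), layout, bin_width)
  })
  pon <- build_pon(ctrl_bc, selection = selection_label)
  tf <- vapply(seq_len(n_reps), function(r) {
    bc <- bin_fragments(subsample(patient_frags, n, seeds[n_reps + r]),
                        layout, bin_width)
    tumor_fraction(bc, pon, ...)$f
  }, numeric(1))
  list(tf = tf, pon = pon)
}

#' Run the ctDNA in-silico bootstrap enrichment process
#'
#' Applies `selector` to both cohorts, draws `n_reps` subsamples of `n`
#' fragments per arm, builds a selection-matched panel of normals from
#' the selected controls, estimates a tumor fraction per selected
#' patient replicate, repeats everything with no selection for the
#' baseline arm (its own panel), and reports the relative tumor
#' fraction `median(selected) / median(baseline)`.
#'
#' @param patient_frags,control_frags Annotated fragment data frames.
#' @param selector A [feature_selector()].
#' @param layout Chromosome layout ([genome_layout()]).
#' @param n_reps Bootstrap replicates per arm (default 10).
#' @param n Fragments per replicate (default 2.2 million).
#' @param seed Master seed; per-replicate streams are spawned from it
#'   and recorded in the result.
#' @param bin_width Copy-number bin width in bp.
#' @param baseline Optional precomputed baseline arm (from a previous
#'   result's `$baseline`), shared across selectors for one patient.
#' @param ... Passed to [tumor_fraction()].
#' @return A `cisbep_result`: per-replicate fractions for both arms,
#'   their medians, `relative_tf`, an `undefined` flag (selected median
#'   positive over a zero baseline), seeds and sizes, and the reusable
#'   `baseline` arm.
#' @export
run_cisbep <- function(patient_frags, control_frags, selector = feature_selector(),
                       layout, n_reps = 10L, n = 2.2e6, seed = NULL,
                       bin_width = 1e6, baseline = NULL, ...) {
  # Both arms reuse one seed block (a paired design): with the identity
  # selector the two arms are then computed identically, so the relative
  # tumor fraction is exactly 1 on any cohort.
  seeds <- spawn_seeds(seed, 2L * n_reps)
  sel_patient <- apply_selector(patient_frags, selector)
  sel_control <- apply_selector(control_frags, selector)
  sel_arm <- cisbep_arm(sel_patient, sel_control, n_reps, n,
                        seeds, layout, bin_width, selector$label, ...)
  if (is.null(baseline)) {
    base_arm <- cisbep_arm(patient_frags, control_frags, n_reps, n,
                           seeds, layout, bin_width, "none", ...)
    baseline <- list(tf = base_arm$tf, seeds = seeds)
  }
  med_sel <- stats::median(sel_arm$tf)
  med_base <- stats::median(baseline$tf)
  undefined <- med_base == 0 && med_sel > 0
  relative <- if (med_base == 0 && med_sel == 0) 0
              else if (undefined) NA_real_
              else med_sel / med_base
  structure(list(selector = selector$label,
                 tf_selected = sel_arm$tf,
                 tf_baseline = baseline$tf,
                 median_selected = med_sel,
                 median_baseline = med_base,
                 relative_tf = relative,
                 undefined = undefined,
                 n_reps = n_reps, n = as.integer(n),
                 seeds = seeds, baseline = baseline),
            class = "cisbep_result")
}

#' @export
print.cisbep_result <- function(x, ...) {
  cat(sprintf("CISBEP '%s': relative tumor fraction %s (selected %.4f / baseline %.4f, %d reps of %d)\n",
              x$selector,
              if (x$undefined) "undefined (zero baseline)" else sprintf("%.3f", x$relative_tf),
              x$median_selected, x$median_baseline, x$n_reps, x$n))
  invisible(x)
}

#' Compare several selectors on one patient
#'
#' The baseline (no-selection) arm is computed once and shared by every
#' selector.
#'
#' @param patient_frags,control_frags Annotated fragment data frames.
#' @param selectors List of [feature_selector()] objects.
#' @param ... Passed to [run_cisbep()].
#' @return Data frame (one row per selector, sorted by decreasing
#'   relative tumor fraction) with the full `cisbep_result` objects in
#'   the `results` attribute.
#' @export
compare_selectors <- function(patient_frags, control_frags, selectors, ...) {
  if (length(selectors) == 0L) stop("compare_selectors: need >= 1 selector")
  results <- vector("list", length(selectors))
  baseline <- NULL
  for (i in seq_along(selectors)) {
    results[[i]] <- run_cisbep(patient_frags, control_frags, selectors[[i]],
                               baseline = baseline, ...)
    baseline <- results[[i]]$baseline
  }
  tab <- data.frame(
    selector = vapply(results, `[[`, "", "selector"),
    median_selected = vapply(results, `[[`, 0, "median_selected"),
    median_baseline = vapply(results, `[[`, 0, "median_baseline"),
    relative_tf = vapply(results, `[[`, 0, "relative_tf"),
    undefined = vapply(results, `[[`, NA, "undefined"))
  ord <- order(-tab$relative_tf)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[ord]
  tab
}
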