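#' Assay presets for the feasibility-control scenarios
#'
#' Four control conditions of the assay chemistry: capture probe alone (every
#' site fluoresces), capture probe quenched by probe 2 (residual spots from
#' incomplete pairing only), quenched probe challenged with 10 pM target
#' (signal-on displacement), and a no-streptavidin control where the capture
#' probe cannot anchor (non-specific adsorption only).
#'
#' @param name One of `"probe1_only"`, `"quenched"`, `"target"`,
#'   `"no_streptavidin"`.
#' @param ... Overrides passed on to [assay_config()].
#' @return An `smi_assay`.
#' @export
scenario_assay <- function(name = c("probe1_only", "quenched", "target",
                                    "no_streptavidin"),
                           ...) {
  name <- match.arg(name)
  base <- switch(name,
    probe1_only = list(probe2_conc = 0, target_conc = 0,
                       unquenched_baseline_fraction = 1),
    quenched = list(target_conc = 0),
    target = list(target_conc = 10e-12),
    no_streptavidin = list(probe1_surface_density = 0, probe2_conc = 0,
                           target_conc = 0,
                           unquenched_baseline_fraction = 0))
  do.call(assay_config, utils::modifyList(base, list(...)))
}

#' Imaging presets for counting and photobleaching validation
#'
#' `"counting"` is the standard protocol (30 frames, 100 ms); `"validation"`
#' uses a longer acquisition (150 frames) with stronger excitation-driven
#' bleaching so that essentially every fluorophore is seen to bleach within
#' the movie, which is what the one-level-trace check requires.
#'
#' @param name `"counting"` or `"validation"`.
#' @param ... Overrides passed on to [imaging_config()].
#' @return An `smi_imaging`.
#' @export
scenario_imaging <- function(name = c("counting", "validation"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    counting = list(),
    validation = list(n_frames = 150, bleach_rate = 0.04))
  do.call(imaging_config, utils::modifyList(base, list(...)))
}

# Expected emitter counts whose accepted-spot expectation equals the target
# counts: inverts the geometric crowding model combined with the
# density-dependent acceptance efficiency (both measured with fixed internal
# seeds, so the configuration is deterministic).
configure_emitter_counts <- function(targets, img, det,
                                     trace_params = list(),
                                     mode = "counting") {
  invert <- function(tt) emitters_for_expected_count(
    tt, img, min_sep = det$min_separation, border_margin = det$border_margin)
  n0 <- vapply(targets, invert, numeric(1))
  if (all(n0 <= 0)) return(n0)
  eff_fun <- acceptance_model(img, det, n_ref = max(n0), trace_params, mode)
  n <- n0
  for (k in 1:2)
    n <- vapply(seq_along(targets), function(j)
      if (targets[j] <= 0) 0 else invert(targets[j] / eff_fun(n[j])),
      numeric(1))
  n
}

#' Recover a printed log-linear count response through the full pipeline
#'
#' Configures the simulator so that the expected accepted spot count per
#' field follows the line `N = slope * log10(x) + intercept` at the given
#' concentrations (pM) or cell numbers, runs the complete
#' simulate-detect-filter-count chain (default 10 regions per level), fits
#' the calibration line to the recovered mean counts, and averages the
#' fitted coefficients over independent replicate seeds. Crowding losses of
#' the counting protocol are compensated when converting target counts to
#' emitter numbers (see [emitters_for_expected_count()]); negative line
#' values are clamped to zero counts.
#'
#' @param slope,intercept Generating line, counts per decade and counts.
#' @param x_values Concentrations in pM or cell numbers (>= 3 values).
#' @param x_kind `"concentration_pM"` or `"cell_number"`.
#' @param img [imaging_config()] used for every region.
#' @param det [detection_params()].
#' @param n_regions Regions per level (default 10).
#' @param seeds Vector of master seeds, one per replicate (default 3).
#' @return A list (class `smi_experiment`) with the per-replicate fits,
#'   the mean recovered `slope` and `intercept`, the per-level mean counts,
#'   and the problem size `n_movies`.
#' @export
run_calibration_experiment <- function(slope, intercept, x_values,
                                       x_kind = c("concentration_pM",
                                                  "cell_number"),
                                       img = imaging_config(),
                                       det = detection_params(),
                                       n_regions = 10, seeds = 1:3) {
  x_kind <- match.arg(x_kind)
  if (length(x_values) < 3) abort_config("need at least 3 levels")
  targets <- pmax(slope * log10(x_values) + intercept, 0)
  n_emit <- configure_emitter_counts(targets, img, det)
  fits <- vector("list", length(seeds))
  means <- matrix(NA_real_, length(seeds), length(x_values))
  for (r in seq_along(seeds)) {
    for (j in seq_along(x_values)) {
      cnt <- run_counting_pipeline(0, img, n_regions = n_regions,
                                   seed = derive_seed(seeds[r], 7919L * j),
                                   det = det, expected_count = n_emit[j],
                                   label = sprintf("x=%g", x_values[j]))
      means[r, j] <- cnt$mean
    }
    fits[[r]] <- fit_calibration(x_values, means[r, ], x_kind = x_kind)
  }
  structure(list(fits = fits,
                 slope = mean(vapply(fits, `[[`, numeric(1), "slope")),
                 intercept = mean(vapply(fits, `[[`, numeric(1), "intercept")),
                 r_squared = mean(vapply(fits, `[[`, numeric(1), "r_squared")),
                 x_values = x_values, x_kind = x_kind,
                 target_counts = targets, mean_counts = means,
                 n_movies = length(seeds) * length(x_values) * n_regions),
            class = "smi_experiment")
}

#' @export
print.smi_experiment <- function(x, ...) {
  cat(sprintf("Pipeline calibration experiment (%d movies):\n", x$n_movies))
  cat(sprintf("  recovered N = %.4g * log10(x) + %.4g (mean R^2 %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat("  levels:", paste(signif(x$x_values, 4), collapse = " "), "\n")
  cat("  target counts:", paste(signif(x$target_counts, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Measure selectivity fold ratios through the full pipeline
#'
#' Simulates a perfect-match sample and one sample per variant species in
#' the linear low-occupancy regime, where the expected accepted count is
#' proportional to the species' relative capture efficiency, then measures
#' the fold ratios with [selectivity_ratios()] and averages them over
#' replicate seeds.
#'
#' @param reference_count Expected accepted count per field for the
#'   perfect-match sample.
#' @param efficiencies Named vector of relative capture efficiencies in
#'   (0, 1], one per variant species.
#' @param img,det,n_regions,seeds As in [run_calibration_experiment()].
#' @return A list (class `smi_selectivity_experiment`) with the mean `folds`
#'   per variant, the per-replicate selectivity tables, and `n_movies`.
#' @export
run_selectivity_experiment <- function(reference_count, efficiencies,
                                       img = imaging_config(),
                                       det = detection_params(),
                                       n_regions = 10, seeds = 1:3) {
  check_num(reference_count, "reference_count", min = 1)
  if (is.null(names(efficiencies)))
    names(efficiencies) <- paste0("variant", seq_along(efficiencies))
  if (any(efficiencies <= 0) || any(efficiencies > 1))
    abort_config("efficiencies must lie in (0, 1]")
  targets <- c(reference = reference_count, reference_count * efficiencies)
  n_emit <- configure_emitter_counts(targets, img, det)
  tables <- vector("list", length(seeds))
  folds <- matrix(NA_real_, length(seeds), length(efficiencies),
                  dimnames = list(NULL, names(efficiencies)))
  for (r in seq_along(seeds)) {
    counts <- lapply(seq_along(targets), function(j)
      run_counting_pipeline(0, img, n_regions = n_regions,
                            seed = derive_seed(seeds[r], 104729L * j),
                            det = det, expected_count = n_emit[j],
                            label = names(targets)[j]))
    tables[[r]] <- selectivity_ratios(counts[[1]], counts[-1])
    folds[r, ] <- tables[[r]]$fold
  }
  structure(list(folds = colMeans(folds), per_seed = tables,
                 efficiencies = efficiencies,
                 n_movies = length(seeds) * length(targets) * n_regions),
            class = "smi_selectivity_experiment")
}

#' @export
print.smi_selectivity_experiment <- function(x, ...) {
  cat(sprintf("Pipeline selectivity experiment (%d movies):\n", x$n_movies))
  for (nm in names(x$folds))
    cat(sprintf("  %s: measured fold %.3g (configured 1/%.3g)\n", nm,
                x$folds[[nm]], 1 / x$efficiencies[[nm]]))
  invisible(x)
}
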