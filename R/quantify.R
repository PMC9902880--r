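#' Summarize accepted spot counts over imaged regions
#'
#' Collects the accepted-spot totals of the regions imaged for one sample
#' (ten regions in the standard protocol) and reports their mean and sample
#' standard deviation.
#'
#' @param regions A list of `smi_spots` tables with the `accepted` column
#'   filled (one per region), or a vector of non-negative integer counts.
#' @param label Sample label.
#' @return An object of class `smi_counts` with fields `label`, `counts`,
#'   `mean` and `sd`.
#' @export
count_regions <- function(regions, label = "sample") {
  if (is.list(regions) && !is.data.frame(regions)) {
    counts <- vapply(regions, function(s) {
      if (!is.data.frame(s) || is.null(s$accepted))
        abort_config("each region must be a spot table with 'accepted'")
      sum(s$accepted, na.rm = TRUE)
    }, numeric(1))
  } else if (is.numeric(regions)) {
    counts <- regions
  } else abort_config("'regions' must be a list of spot tables or counts")
  if (length(counts) < 1) abort_config("at least one region is required")
  if (any(counts < 0) || any(counts != floor(counts)))
    abort_config("region counts must be non-negative integers")
  structure(list(label = as.character(label), counts = as.integer(counts),
                 mean = mean(counts),
                 sd = if (length(counts) > 1) sd(counts) else NA_real_),
            class = "smi_counts")
}

#' @export
print.smi_counts <- function(x, ...) {
  cat(sprintf("Region counts (%s): n = %d regions, mean %.2f, sd %.2f\n",
              x$label, length(x$counts), x$mean, x$sd))
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Fit a log-linear calibration line
#'
#' Ordinary least squares of mean accepted spot count against the base-10
#' logarithm of the concentration (in pM) or of the cell number:
#' \deqn{N = slope \cdot \log_{10}(x) + intercept.}
#'
#' @param x Concentrations in pM (or cell numbers); at least 3 distinct
#'   values, all > 0.
#' @param mean_counts Mean accepted counts, one per `x`.
#' @param x_kind `"concentration_pM"` or `"cell_number"` (axis bookkeeping).
#' @return An object of class `smi_calfit` with the usual modelling methods
#'   (`print`, `summary`, `coef`, `predict`, `plot`, `residuals`).
#' @examples
#' fit <- fit_calibration(c(0.1, 1, 10, 100), c(10, 121, 232, 343))
#' coef(fit)
#' predict(fit, newdata = c(0.5, 5))
#' @export
fit_calibration <- function(x, mean_counts,
                            x_kind = c("concentration_pM", "cell_number")) {
  x_kind <- match.arg(x_kind)
  if (!is.numeric(x) || !is.numeric(mean_counts) ||
      length(x) != length(mean_counts))
    abort_config("'x' and 'mean_counts' must be numeric of equal length")
  if (length(x) < 3) abort_config("at least 3 calibration points required")
  if (any(x <= 0)) abort_config("calibration x values must be > 0")
  lx <- log10(x)
  if (var(lx) <= 0) abort_config("zero variance in log10(x)")
  fit <- lm(mean_counts ~ lx)
  ssres <- sum(residuals(fit)^2)
  sstot <- sum((mean_counts - mean(mean_counts))^2)
  structure(list(lm = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = 1 - ssres / sstot,
                 x_kind = x_kind, x = x, mean_counts = mean_counts,
                 x_range = range(x)),
            class = "smi_calfit")
}

#' @export
print.smi_calfit <- function(x, ...) {
  lab <- if (x$x_kind == "concentration_pM") "log10(C/pM)" else
    "log10(cell number)"
  cat(sprintf("Calibration fit: N = %.4g * %s + %.4g  (R^2 = %.4f)\n",
              x$slope, lab, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
summary.smi_calfit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d points, x in [%.4g, %.4g]\n", length(object$x),
              object$x_range[1], object$x_range[2]))
  print(summary(object$lm)$coefficients)
  invisible(object)
}

#' @export
coef.smi_calfit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.smi_calfit <- function(object, ...) unname(residuals(object$lm))

#' Predict mean counts at new concentrations or cell numbers
#' @param object An `smi_calfit`.
#' @param newdata Concentrations in pM (or cell numbers); defaults to the
#'   calibration points.
#' @param ... Unused.
#' @export
predict.smi_calfit <- function(object, newdata = NULL, ...) {
  xs <- newdata %||% object$x
  if (any(xs <= 0)) abort_config("predictions require x > 0")
  object$intercept + object$slope * log10(xs)
}

#' @export
plot.smi_calfit <- function(x, ...) {
  lab <- if (x$x_kind == "concentration_pM") "log10(C / pM)" else
    "log10(cell number)"
  plot(log10(x$x), x$mean_counts, xlab = lab, ylab = "mean accepted spots",
       pch = 19, ...)
  abline(x$intercept, x$slope, col = "red3")
}

#' Limit of detection from the calibration line
#'
#' Conventional blank-plus-3-SD rule: the LOD is the x value where the
#' calibration line crosses `blank_mean + 3 * blank_sd`,
#' \deqn{LOD = 10^{(\bar N_{blank} + 3 s_{blank} - intercept)/slope}.}
#'
#' @param fit An `smi_calfit` with positive slope.
#' @param blank An `smi_counts` from a zero-target (blank) run.
#' @return An object of class `smi_lod` with `lod_value` (same units as the
#'   calibration x axis), the criterion string and the blank statistics.
#' @export
estimate_lod <- function(fit, blank) {
  if (!inherits(fit, "smi_calfit")) abort_config("'fit' must be smi_calfit")
  if (!inherits(blank, "smi_counts")) abort_config("'blank' must be smi_counts")
  if (!is.finite(fit$slope) || fit$slope <= 0)
    abort_config("LOD requires a positive calibration slope")
  bsd <- if (is.na(blank$sd)) 0 else blank$sd
  threshold <- blank$mean + 3 * bsd
  lod <- 10^((threshold - fit$intercept) / fit$slope)
  if (!is.null(fit$x_range) && lod < fit$x_range[1])
    abort_data(sprintf(paste0(
      "blank + 3 SD threshold (%.4g) lies below the fitted line over the ",
      "whole calibrated range [%.4g, %.4g]; the implied LOD %.4g is an ",
      "extrapolation below the lowest calibrator"),
      threshold, fit$x_range[1], fit$x_range[2], lod))
  if (!is.null(fit$x_range) && lod > fit$x_range[2])
    warning("LOD above the calibrated range (extrapolation)")
  structure(list(lod_value = lod,
                 criterion = "calibration line crossing of blank mean + 3 SD",
                 blank_mean = blank$mean, blank_sd = bsd,
                 threshold = threshold),
            class = "smi_lod")
}

#' @export
print.smi_lod <- function(x, ...) {
  cat(sprintf("LOD: %.4g (criterion: %s; blank %.3g +/- %.3g, threshold %.3g)\n",
              x$lod_value, x$criterion, x$blank_mean, x$blank_sd, x$threshold))
  invisible(x)
}

#' Selectivity fold ratios against mismatched or non-complementary species
#'
#' Fold = mean accepted count of the perfect-match reference divided by the
#' mean count of each variant species.
#'
#' @param reference An `smi_counts` for the perfect-match target.
#' @param variants A list of `smi_counts` for the variant species.
#' @return An object of class `smi_selectivity`: a data frame with columns
#'   `species`, `mean_count` and `fold`, plus the reference label/mean as
#'   attributes.
#' @export
selectivity_ratios <- function(reference, variants) {
  if (!inherits(reference, "smi_counts"))
    abort_config("'reference' must be smi_counts")
  if (inherits(variants, "smi_counts")) variants <- list(variants)
  if (length(variants) < 1) abort_config("at least one variant is required")
  folds <- vapply(variants, function(v) {
    if (!inherits(v, "smi_counts")) abort_config("variants must be smi_counts")
    if (v$mean == 0) {
      warning("variant mean count is zero; fold reported as Inf")
      return(Inf)
    }
    reference$mean / v$mean
  }, numeric(1))
  res <- data.frame(species = vapply(variants, `[[`, character(1), "label"),
                    mean_count = vapply(variants, `[[`, numeric(1), "mean"),
                    fold = folds)
  structure(res, class = c("smi_selectivity", "data.frame"),
            reference = reference$label, reference_mean = reference$mean)
}

#' @export
print.smi_selectivity <- function(x, ...) {
  cat(sprintf("Selectivity vs %s (mean %.2f):\n", attr(x, "reference"),
              attr(x, "reference_mean")))
  print.data.frame(x)
  invisible(x)
}
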