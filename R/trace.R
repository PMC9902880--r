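#' Extract a background-corrected intensity trace for one spot
#'
#' Aperture photometry per frame: the trace value is the sum of pixels within
#' `aperture_radius` of the (rounded) spot centre minus the aperture pixel
#' count times the median of the background annulus
#' (`annulus_inner < r <= annulus_outer`). Spots whose annulus extends past
#' the image edge are flagged as excluded.
#'
#' @param movie An `smi_movie`.
#' @param spot One row of an `smi_spots` table (or a list with `x`, `y`).
#' @param aperture_radius Photometry aperture radius, px.
#' @param annulus_inner,annulus_outer Background annulus radii, px
#'   (`annulus_outer > annulus_inner >= aperture_radius`).
#' @return An object of class `smi_trace`: `intensities` (counts per frame),
#'   `background_level` (mean annulus median), `excluded` flag, and the spot
#'   coordinates.
#' @export
extract_trace <- function(movie, spot, aperture_radius = 3,
                          annulus_inner = 5, annulus_outer = 8) {
  if (!inherits(movie, "smi_movie")) abort_config("'movie' must be smi_movie")
  check_num(aperture_radius, "aperture_radius", min = 1)
  if (!(annulus_outer > annulus_inner && annulus_inner >= aperture_radius))
    abort_config("need annulus_outer > annulus_inner >= aperture_radius")
  d <- dim(movie$data)
  x0 <- round(spot$x); y0 <- round(spot$y)
  w <- ceiling(annulus_outer)
  excluded <- (x0 - w < 0 || x0 + w > d[3] - 1 ||
                 y0 - w < 0 || y0 + w > d[2] - 1)
  if (excluded) {
    return(structure(list(intensities = rep(NA_real_, d[1]),
                          background_level = NA_real_, excluded = TRUE,
                          x = spot$x, y = spot$y), class = "smi_trace"))
  }
  off <- -w:w
  dist <- sqrt(outer(off^2, off^2, "+"))
  ap <- dist <= aperture_radius
  an <- dist > annulus_inner & dist <= annulus_outer
  sub <- movie$data[, y0 + 1 + off, x0 + 1 + off, drop = FALSE]
  n_ap <- sum(ap)
  ints <- numeric(d[1]); bgs <- numeric(d[1])
  for (f in seq_len(d[1])) {
    fr <- sub[f, , ]
    bgs[f] <- median(fr[an])
    ints[f] <- sum(fr[ap]) - n_ap * bgs[f]
  }
  structure(list(intensities = ints, background_level = mean(bgs),
                 excluded = FALSE, x = spot$x, y = spot$y),
            class = "smi_trace")
}

#' Extract traces for all spots of a region
#'
#' @inheritParams extract_trace
#' @param spots An `smi_spots` table.
#' @return A list of `smi_trace` objects, one per spot row.
#' @export
extract_traces <- function(movie, spots, aperture_radius = 3,
                           annulus_inner = 5, annulus_outer = 8) {
  lapply(seq_len(nrow(spots)), function(i)
    extract_trace(movie, spots[i, ], aperture_radius, annulus_inner,
                  annulus_outer))
}

#' Robust trace noise estimate
#'
#' Noise SD estimated from the median absolute successive difference, which
#' is insensitive to a small number of photobleaching steps:
#' `sigma = median(|diff(x)|) / (qnorm(0.75) * sqrt(2))`.
#'
#' @param x Numeric trace.
#' @return Estimated per-frame noise SD.
#' @export
trace_noise_sd <- function(x) {
  if (length(x) < 2) abort_config("trace too short for a noise estimate")
  median(abs(diff(x))) / (qnorm(0.75) * sqrt(2))
}

#' Count photobleaching steps in an intensity trace
#'
#' Piecewise-constant fit by penalized binary segmentation: change points are
#' added greedily at the split with the largest residual-sum-of-squares
#' reduction, as long as the reduction exceeds the penalty
#' `penalty_beta * sigma^2 * log(n)`. A single fluorophore yields a one-level
#' or two-level (one downward step) trace; co-located fluorophores bleach
#' successively and yield additional levels.
#'
#' @param trace An `smi_trace` or a plain numeric vector (length >= 4).
#' @param penalty_beta Penalty multiplier per change point.
#' @param noise_sd Per-frame noise SD; estimated with [trace_noise_sd()] when
#'   omitted.
#' @return An object of class `smi_stepfit`: `n_levels`, `change_frames`
#'   (0-based first frames of the later segments), `level_means`, and
#'   `reaches_baseline` (final level within 2 noise SD of zero).
#' @export
count_steps <- function(trace, penalty_beta = 4, noise_sd = NULL) {
  x <- if (inherits(trace, "smi_trace")) trace$intensities else trace
  if (!is.numeric(x) || anyNA(x)) abort_config("trace must be numeric, no NA")
  n <- length(x)
  if (n < 4) abort_config("trace must have at least 4 frames")
  check_num(penalty_beta, "penalty_beta", min = 0)
  sigma <- noise_sd %||% trace_noise_sd(x)
  pen <- penalty_beta * sigma^2 * log(n)
  cps <- binseg_changepoints(x, pen)
  bounds <- c(0L, cps, n)
  means <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  structure(list(n_levels = length(means), change_frames = cps,
                 level_means = means,
                 reaches_baseline = abs(means[length(means)]) <= 2 * sigma,
                 noise_sd = sigma, penalty = pen),
            class = "smi_stepfit")
}

# Global-greedy binary segmentation, L2 cost, O(1) segment costs via
# cumulative sums. Returns sorted 0-based change points (first index of each
# new segment).
binseg_changepoints <- function(x, pen) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {        # frames a..b, 1-based inclusive
    s <- cs[b + 1] - cs[a]
    cs2[b + 1] - cs2[a] - s^2 / (b - a + 1)
  }
  best_split <- function(a, b) {
    if (b <= a) return(c(NA, -Inf))
    tot <- segcost(a, b)
    ks <- a:(b - 1)
    gains <- vapply(ks, function(k) tot - segcost(a, k) - segcost(k + 1, b),
                    numeric(1))
    i <- which.max(gains)
    c(ks[i], gains[i])
  }
  segs <- list(c(1L, n))
  cps <- integer(0)
  repeat {
    splits <- lapply(segs, function(s) best_split(s[1], s[2]))
    gains <- vapply(splits, `[`, numeric(1), 2)
    i <- which.max(gains)
    if (!is.finite(gains[i]) || gains[i] <= pen) break
    k <- splits[[i]][1]
    s <- segs[[i]]
    segs[[i]] <- c(s[1], as.integer(k))
    segs[[length(segs) + 1]] <- c(as.integer(k) + 1L, s[2])
    cps <- sort(c(cps, as.integer(k)))
  }
  cps   # 0-based first frame of following segment == 1-based last of previous
}

#' @export
print.smi_stepfit <- function(x, ...) {
  cat(sprintf("Step fit: %d level(s)", x$n_levels))
  if (length(x$change_frames))
    cat(", change frames ", paste(x$change_frames, collapse = ", "), sep = "")
  cat(sprintf("; levels %s; baseline %s\n",
              paste(sprintf("%.4g", x$level_means), collapse = " -> "),
              if (x$reaches_baseline) "reached" else "not reached"))
  invisible(x)
}

#' Accept spots whose traces are consistent with a single molecule
#'
#' Applies the photobleaching single-molecule filter: a spot is accepted when
#' its trace has no upward step and at most one downward step. In
#' `"validation"` mode the final level must additionally reach the baseline
#' (the fluorophore is seen to bleach completely); in the default
#' `"counting"` mode a constant trace is also accepted, because over a short
#' counting movie many fluorophores out-last the acquisition.
#'
#' @param spots An `smi_spots` table.
#' @param fits A list of [count_steps()] results (or `smi_trace` objects,
#'   which are fitted with default settings), one per spot.
#' @param mode `"counting"` or `"validation"`.
#' @return The `spots` table with the `accepted` column filled in.
#' @export
filter_single_molecules <- function(spots, fits,
                                    mode = c("counting", "validation")) {
  mode <- match.arg(mode)
  if (length(fits) != nrow(spots))
    abort_config("need exactly one trace/step fit per spot")
  acc <- vapply(fits, function(f) {
    if (inherits(f, "smi_trace")) {
      if (isTRUE(f$excluded)) return(FALSE)
      f <- count_steps(f)
    }
    dm <- diff(f$level_means)
    ok <- sum(dm > 0) == 0 && sum(dm < 0) <= 1
    if (mode == "validation") ok <- ok && isTRUE(f$reaches_baseline)
    ok
  }, logical(1))
  spots$accepted <- acc
  spots
}
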