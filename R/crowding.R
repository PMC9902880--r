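# Geometric crowding calibration: at finite surface density some emitters fall
# closer together than the detector's minimum separation and are counted as a
# single spot. The count-configured experiments need the *detected* count, not
# the emitter count, to follow a prescribed value, so the expected detected
# count as a function of the emitter intensity is estimated by Monte-Carlo
# non-maximum suppression on the underlying Poisson point process, and
# inverted.

# Number of survivors of greedy radius-r suppression on a point set.
nms_point_count <- function(x, y, min_sep) {
  n <- length(x)
  if (n <= 1) return(n)
  keep <- logical(n)
  r2 <- min_sep^2
  for (i in seq_len(n)) {
    j <- which(keep)
    if (length(j) == 0 || all((x[j] - x[i])^2 + (y[j] - y[i])^2 >= r2))
      keep[i] <- TRUE
  }
  sum(keep)
}

#' Expected detected spot count at a given emitter intensity
#'
#' Monte-Carlo estimate of the mean number of spots surviving minimum-
#' separation merging when `n_expected` emitters (Poisson) are placed
#' uniformly over the field minus the border margin. This is the crowding
#' (Poisson clumping) loss of the counting protocol, independent of
#' photometric noise.
#'
#' @param n_expected Expected number of emitters in the field.
#' @param img An [imaging_config()] object.
#' @param min_sep Minimum spot separation in pixels (detector setting).
#' @param border_margin Placement margin in pixels.
#' @param reps Monte-Carlo repetitions.
#' @param seed RNG seed (fixed default: the estimate is deterministic).
#' @return Expected detected spot count (a single number).
#' @seealso [emitters_for_expected_count()]
#' @export
expected_spot_count <- function(n_expected, img, min_sep = 4,
                                border_margin = 8, reps = 48, seed = 760131L) {
  check_num(n_expected, "n_expected", min = 0)
  if (n_expected == 0) return(0)
  w <- img$width - 1 - 2 * border_margin
  h <- img$height - 1 - 2 * border_margin
  with_seed(seed, {
    mean(vapply(seq_len(reps), function(r) {
      n <- rpois(1, n_expected)
      nms_point_count(runif(n, 0, w), runif(n, 0, h), min_sep)
    }, numeric(1)))
  })
}

#' Emitter intensity that yields a prescribed expected detected count
#'
#' Inverts [expected_spot_count()]: finds the expected emitter number whose
#' crowding-thinned detected count equals `target`. Used by the experiment
#' drivers to configure the simulator so that expected *accepted* spot counts
#' follow a prescribed concentration- or cell-number-response line. Non-
#' positive targets return 0.
#'
#' @param target Desired expected detected spot count per field.
#' @inheritParams expected_spot_count
#' @return Expected emitter count per field (a single number).
#' @export
emitters_for_expected_count <- function(target, img, min_sep = 4,
                                        border_margin = 8, reps = 48,
                                        seed = 760131L) {
  if (!is.numeric(target) || length(target) != 1 || is.na(target))
    abort_config("'target' must be a single number")
  if (target <= 0) return(0)
  # second-order analytic start: target = n - c n^2 with pair-merge constant
  area <- (img$width - 1 - 2 * border_margin) *
    (img$height - 1 - 2 * border_margin)
  cc <- pi * min_sep^2 / (2 * area)
  disc <- 1 - 4 * cc * target
  n <- if (disc > 0) (1 - sqrt(disc)) / (2 * cc) else 2 * target
  # multiplicative Monte-Carlo refinement (common random numbers); detected
  # spots can never exceed emitters, so the result is floored at the target
  for (k in 1:3) {
    e <- expected_spot_count(n, img, min_sep, border_margin, reps, seed)
    n <- n * target / e
  }
  max(n, target)
}
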