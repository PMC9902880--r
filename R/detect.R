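#' Spot-detection parameters
#'
#' Settings of the diffraction-limited spot detector: detection runs on the
#' average of the first `averaging_frames` frames, band-pass filtered with a
#' difference of Gaussians; local maxima above `median + threshold_k * MAD`
#' of the filtered image are kept, maxima closer than `min_separation` are
#' merged keeping the brighter one, and positions are refined to sub-pixel
#' precision by an intensity-weighted 3x3 centroid.
#'
#' @param dog_sigma_small,dog_sigma_large Band-pass Gaussian widths in px
#'   (`small < large`); the small sigma should approximate the PSF width.
#' @param threshold_k Threshold in robust-SD units above the robust background.
#' @param min_separation Minimum distance between reported spots, px.
#' @param border_margin Detections closer than this to the field edge are
#'   discarded, px.
#' @param averaging_frames Number of initial frames averaged for detection.
#' @return An object of class `smi_detection`.
#' @export
detection_params <- function(dog_sigma_small = 1.2, dog_sigma_large = 2.4,
                             threshold_k = 5, min_separation = 4,
                             border_margin = 8, averaging_frames = 5) {
  check_num(dog_sigma_small, "dog_sigma_small", min = 0.1)
  check_num(dog_sigma_large, "dog_sigma_large", min = 0.1)
  if (dog_sigma_small >= dog_sigma_large)
    abort_config("dog_sigma_small must be < dog_sigma_large")
  check_num(threshold_k, "threshold_k", min = 1e-9)
  check_num(min_separation, "min_separation", min = 1)
  check_num(border_margin, "border_margin", min = 0)
  check_num(averaging_frames, "averaging_frames", min = 1, integer = TRUE)
  structure(list(dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 threshold_k = threshold_k, min_separation = min_separation,
                 border_margin = border_margin,
                 averaging_frames = as.integer(averaging_frames)),
            class = "smi_detection")
}

#' Detect diffraction-limited spots in a movie
#'
#' Deterministic detector reproducing the fluorescent-spot counting
#' primitive: difference-of-Gaussians band-pass on the early-frame average,
#' robust thresholding (median + k * MAD), 8-connected local maxima,
#' minimum-separation merging (brighter spot wins; ties broken towards the
#' smaller row, then column), and sub-pixel localization by the
#' intensity-weighted centroid of the 3x3 neighbourhood of the filtered
#' image.
#'
#' @param movie An [render_movie()] movie (or any `smi_movie`).
#' @param params A [detection_params()] object.
#' @return An object of class `smi_spots`: a data frame with columns
#'   `region_id`, `x`, `y` (0-based sub-pixel coordinates), `peak_intensity`
#'   (averaged-image counts at the peak) and `accepted` (NA until trace
#'   filtering).
#' @export
detect_spots <- function(movie, params = detection_params()) {
  if (!inherits(movie, "smi_movie")) abort_config("'movie' must be smi_movie")
  if (!inherits(params, "smi_detection"))
    abort_config("'params' must be smi_detection")
  d <- dim(movie$data)
  if (d[1] < params$averaging_frames)
    abort_config("movie shorter than averaging_frames")
  m <- params$averaging_frames
  avg <- colMeans(movie$data[seq_len(m), , , drop = FALSE])
  dog <- dog_filter(avg, params$dog_sigma_small, params$dog_sigma_large)
  bg <- median(dog)
  thr <- bg + params$threshold_k * mad(dog)
  cand <- local_maxima(dog, thr)
  cand <- cand[cand$row - 1 >= params$border_margin &
                 cand$row - 1 <= d[2] - 1 - params$border_margin &
                 cand$col - 1 >= params$border_margin &
                 cand$col - 1 <= d[3] - 1 - params$border_margin, ,
               drop = FALSE]
  kept <- nms_spots(cand, params$min_separation)
  res <- data.frame(region_id = rep(movie$metadata$region_id %||% 1L,
                                    nrow(kept)),
                    x = numeric(nrow(kept)), y = numeric(nrow(kept)),
                    peak_intensity = numeric(nrow(kept)),
                    accepted = rep(NA, nrow(kept)))
  for (i in seq_len(nrow(kept))) {
    r <- kept$row[i]; cl <- kept$col[i]
    cen <- centroid_3x3(dog, r, cl, bg)
    res$x[i] <- cl - 1 + cen[1]
    res$y[i] <- r - 1 + cen[2]
    res$peak_intensity[i] <- avg[r, cl]
  }
  structure(res[order(res$y, res$x), , drop = FALSE],
            class = c("smi_spots", "data.frame"))
}

# Difference-of-Gaussians band-pass (EBImage separable Gaussian smoothing).
dog_filter <- function(img, s_small, s_large) {
  a <- as.matrix(EBImage::gblur(img, sigma = s_small))
  b <- as.matrix(EBImage::gblur(img, sigma = s_large))
  a - b
}

# 8-connected local maxima above a threshold. A pixel qualifies when it is >=
# all eight neighbours; plateau duplicates are resolved by the subsequent
# minimum-separation merge with its row/column tie-break.
local_maxima <- function(im, thr) {
  nr <- nrow(im); nc <- ncol(im)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- im
  ok <- im >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (im >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  idx <- which(ok, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2], value = im[idx])
}

# Greedy minimum-separation merge: brightest first, ties towards smaller row
# then smaller column.
nms_spots <- function(cand, min_sep) {
  if (nrow(cand) <= 1) return(cand)
  ord <- order(-cand$value, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  r2 <- min_sep^2
  for (i in seq_len(nrow(cand))) {
    j <- which(keep)
    if (length(j) == 0 ||
        all((cand$row[j] - cand$row[i])^2 +
              (cand$col[j] - cand$col[i])^2 >= r2))
      keep[i] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

# Intensity-weighted centroid of the background-subtracted 3x3 neighbourhood;
# returns the (dx, dy) sub-pixel offset relative to the peak pixel.
centroid_3x3 <- function(im, r, cl, bg) {
  rows <- max(1, r - 1):min(nrow(im), r + 1)
  cols <- max(1, cl - 1):min(ncol(im), cl + 1)
  w <- pmax(im[rows, cols, drop = FALSE] - bg, 0)
  if (sum(w) <= 0) return(c(0, 0))
  dx <- sum(t(w) * (cols - cl)) / sum(w)
  dy <- sum(w * (rows - r)) / sum(w)
  c(dx, dy)
}

#' Match detected spots to ground-truth emitters
#'
#' Greedy nearest-neighbour matching within a radius: candidate pairs are
#' processed in order of increasing distance and each spot and each true
#' emitter is used at most once. Precision is matched/detected, recall is
#' matched/true.
#'
#' @param spots A [detect_spots()] table.
#' @param truth An [sample_emitters()] ground truth.
#' @param radius Matching radius in pixels (> 0).
#' @return A list (class `smi_match`) with `matches` (data frame of spot
#'   index, truth index, distance), `precision` and `recall`.
#' @export
match_to_truth <- function(spots, truth, radius = 2) {
  check_num(radius, "radius", min = 1e-9)
  ns <- nrow(spots); nt <- nrow(truth)
  matches <- data.frame(spot = integer(0), truth = integer(0),
                        dist = numeric(0))
  if (ns > 0 && nt > 0) {
    dd <- outer(spots$x, truth$x, "-")^2 + outer(spots$y, truth$y, "-")^2
    pairs <- which(dd <= radius^2, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      pd <- sqrt(dd[pairs])
      ord <- order(pd)
      used_s <- logical(ns); used_t <- logical(nt)
      for (k in ord) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (!used_s[i] && !used_t[j]) {
          used_s[i] <- TRUE; used_t[j] <- TRUE
          matches <- rbind(matches,
                           data.frame(spot = i, truth = j, dist = pd[k]))
        }
      }
    }
  }
  structure(list(matches = matches,
                 precision = if (ns > 0) nrow(matches) / ns else NA_real_,
                 recall = if (nt > 0) nrow(matches) / nt else NA_real_),
            class = "smi_match")
}

#' @export
print.smi_match <- function(x, ...) {
  cat(sprintf("Spot matching: %d matches, precision %.3f, recall %.3f\n",
              nrow(x$matches), x$precision, x$recall))
  invisible(x)
}
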