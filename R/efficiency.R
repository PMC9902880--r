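#' Single-emitter acceptance efficiency of the counting pipeline
#'
#' Probability that one isolated emitter ends up as an accepted spot under a
#' given imaging configuration and analysis settings. Even with no crowding,
#' an emitter can be lost because it photobleaches before or during the
#' detection average, falls below the detection threshold, or its trace is
#' rejected by the single-molecule filter. The efficiency is estimated by
#' Monte Carlo: fields of widely separated emitters on a jittered grid are
#' rendered with the full noise and bleaching model and pushed through
#' detection and trace filtering.
#'
#' The count-configured experiment drivers divide their target counts by this
#' efficiency so that the expected *accepted* count matches the requested
#' response (see [run_calibration_experiment()]).
#'
#' @param img [imaging_config()].
#' @param det [detection_params()].
#' @param trace_params,mode As in [analyze_movie()].
#' @param n_fields Number of calibration fields to render.
#' @param spacing Grid spacing between calibration emitters, px.
#' @param seed RNG seed (fixed default: the estimate is deterministic).
#' @return Acceptance probability in [0, 1].
#' @export
pipeline_efficiency <- function(img, det = detection_params(),
                                trace_params = list(), mode = "counting",
                                n_fields = 2, spacing = 16, seed = 424243L) {
  m <- det$border_margin + 2
  gx <- seq(m, img$width - 1 - m, by = spacing)
  gy <- seq(m, img$height - 1 - m, by = spacing)
  grid <- expand.grid(x = gx, y = gy)
  n_tot <- 0L
  n_acc <- 0L
  with_seed(seed, {
    for (f in seq_len(n_fields)) {
      truth <- data.frame(x = grid$x + runif(nrow(grid), -0.5, 0.5),
                          y = grid$y + runif(nrow(grid), -0.5, 0.5),
                          species = "calibration", n_fluorophores = 1L)
      truth$bleach_frames <- lapply(seq_len(nrow(truth)), function(i)
        draw_bleach_frames(1L, img))
      truth <- structure(truth, class = c("smi_truth", "data.frame"),
                         width = img$width, height = img$height,
                         n_frames = img$n_frames)
      movie <- render_movie(truth, img, seed = NULL)
      spots <- analyze_movie(movie, det, trace_params, mode)
      mt <- match_to_truth(spots[spots$accepted, , drop = FALSE], truth,
                           radius = 2)
      n_tot <- n_tot + nrow(truth)
      n_acc <- n_acc + nrow(mt$matches)
    }
  })
  n_acc / n_tot
}

#' Acceptance efficiency at a working density
#'
#' At finite density the single-molecule filter loses slightly more spots
#' than it does for isolated emitters, mainly because a photobleaching
#' neighbour injects a small secondary step into the photometry aperture of
#' a nearby spot. This function measures the acceptance efficiency at a
#' given expected emitter count by a matched-pairs Monte Carlo: for each
#' calibration field the accepted-spot count is divided by the
#' geometric (minimum-separation) survivor count of the *same* emitter
#' placement, so placement randomness cancels and only photometric and
#' filtering losses remain.
#'
#' @inheritParams pipeline_efficiency
#' @param n_emitters Expected emitter count per field at which to measure.
#' @param n_fields Number of calibration fields.
#' @return Acceptance probability in [0, 1] relative to the geometric
#'   survivor count.
#' @seealso [pipeline_efficiency()] for the isolated-emitter limit.
#' @export
density_acceptance <- function(img, det = detection_params(),
                               trace_params = list(), mode = "counting",
                               n_emitters, n_fields = 6, seed = 424247L) {
  check_num(n_emitters, "n_emitters", min = 1)
  n <- round(n_emitters)
  m <- det$border_margin
  w <- img$width - 1 - 2 * m
  h <- img$height - 1 - 2 * m
  with_seed(seed, {
    ratios <- vapply(seq_len(n_fields), function(f) {
      x <- runif(n, 0, w) + m
      y <- runif(n, 0, h) + m
      geom <- nms_point_count(x - m, y - m, det$min_separation)
      truth <- data.frame(x = x, y = y, species = "calibration",
                          n_fluorophores = 1L)
      truth$bleach_frames <- lapply(seq_len(n), function(i)
        draw_bleach_frames(1L, img))
      truth <- structure(truth, class = c("smi_truth", "data.frame"),
                         width = img$width, height = img$height,
                         n_frames = img$n_frames)
      movie <- render_movie(truth, img, seed = NULL)
      spots <- analyze_movie(movie, det, trace_params, mode)
      sum(spots$accepted) / geom
    }, numeric(1))
    mean(ratios)
  })
}

# Linear-in-density acceptance model between the isolated-emitter limit and a
# reference density; used by the count-configured experiment drivers.
acceptance_model <- function(img, det, n_ref, trace_params = list(),
                             mode = "counting") {
  eff0 <- pipeline_efficiency(img, det, trace_params, mode)
  if (n_ref < 25) {
    eff_ref <- eff0
    n_ref <- max(n_ref, 1)
  } else {
    eff_ref <- density_acceptance(img, det, trace_params, mode,
                                  n_emitters = n_ref)
  }
  function(n) eff0 + (eff_ref - eff0) * pmin(n / n_ref, 1.5)
}
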