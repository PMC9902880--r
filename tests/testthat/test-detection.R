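test_that("detector finds isolated and paired emitters at sub-pixel accuracy", {
  img <- tiny_imaging()
  # blank movie: offset + noise only
  blank <- render_movie(sample_emitters(0, img, seed = 1), img, seed = 2)
  expect_equal(nrow(detect_spots(blank)), 0)

  # single emitter near SNR 10
  img1 <- tiny_imaging(photons_per_frame = 700, bleach_rate = 0)
  mv1 <- render_movie(manual_truth(20.3, 30.7, img1), img1, seed = 3)
  sp1 <- detect_spots(mv1)
  expect_equal(nrow(sp1), 1)
  expect_lt(sqrt((sp1$x - 20.3)^2 + (sp1$y - 30.7)^2), 1)

  # two emitters 10 px apart resolve as two spots
  mv2 <- render_movie(manual_truth(c(25, 35), c(40, 40), img1), img1, seed = 4)
  expect_equal(nrow(detect_spots(mv2)), 2)

  # determinism
  expect_identical(detect_spots(mv1), detect_spots(mv1))
})

test_that("detections shift with whole-pixel image translations", {
  img <- tiny_imaging(n_frames = 5, bleach_rate = 0)
  mv <- render_movie(manual_truth(c(24.4, 40.6), c(22.3, 38.9), img), img,
                     seed = 5)
  sp <- detect_spots(mv)
  # circularly shift every frame by (dx = 3, dy = 2)
  dx <- 3L; dy <- 2L
  rows <- ((seq_len(64) - 1 - dy) %% 64) + 1
  cols <- ((seq_len(64) - 1 - dx) %% 64) + 1
  mvs <- mv
  mvs$data <- mv$data[, rows, cols]
  sps <- detect_spots(mvs)
  expect_gt(nrow(sp), 0)
  expect_equal(nrow(sps), nrow(sp))
  expect_equal(sps$x, sp$x + dx, tolerance = 1e-9)
  expect_equal(sps$y, sp$y + dy, tolerance = 1e-9)
})

test_that("raising the threshold never increases the detection count", {
  img <- tiny_imaging(photons_per_frame = 250)
  mv <- render_movie(sample_emitters(0.08, img, border_margin = 8, seed = 6),
                     img, seed = 7)
  ks <- c(2, 3, 5, 8, 12)
  ns <- vapply(ks, function(k)
    nrow(detect_spots(mv, detection_params(threshold_k = k))), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("truth matching computes greedy precision and recall", {
  img <- tiny_imaging()
  truth <- manual_truth(c(10, 30, 50), c(12, 32, 52), img)
  perfect <- data.frame(x = truth$x, y = truth$y)
  m <- match_to_truth(perfect, truth, radius = 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  none <- match_to_truth(data.frame(x = numeric(0), y = numeric(0)), truth,
                         radius = 1)
  expect_equal(none$recall, 0)
  # each truth emitter is used at most once
  dup <- data.frame(x = c(10, 10.4), y = c(12, 12.2))
  m2 <- match_to_truth(dup, truth, radius = 2)
  expect_equal(nrow(m2$matches), 1)
})
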