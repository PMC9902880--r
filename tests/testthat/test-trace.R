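test_that("aperture photometry cancels background and recovers PSF mass", {
  img <- tiny_imaging(n_frames = 6)
  # uniform image: aperture sum minus annulus estimate is exactly zero
  uni <- structure(list(data = array(37, dim = c(6, 64, 64)),
                        metadata = list(region_id = 1)), class = "smi_movie")
  tr <- extract_trace(uni, list(x = 30, y = 30))
  expect_true(all(tr$intensities == 0))

  # noise-free emitter: trace recovers photons x aperture mass
  imgp <- tiny_imaging(n_frames = 6, bleach_rate = 0, em_gain = 1,
                       background_photons = 3, offset = 50,
                       photons_per_frame = 500)
  mv <- noise_free_movie(manual_truth(31.3, 29.8, imgp), imgp)
  trp <- extract_trace(mv, list(x = 31.3, y = 29.8), aperture_radius = 3)
  mass <- aperture_mass_oracle(31.3, 29.8, imgp$psf_sigma, 3)
  expect_equal(mean(trp$intensities), 500 * mass, tolerance = 0.02)

  # bleach at frame 3: high level then ~zero
  mvb <- noise_free_movie(manual_truth(31.3, 29.8, imgp, bleach = 3), imgp)
  trb <- extract_trace(mvb, list(x = 31.3, y = 29.8))
  expect_gt(min(trb$intensities[1:3]), 300)
  expect_lt(max(abs(trb$intensities[4:6])), 5)

  # spots whose annulus leaves the field are flagged excluded
  tre <- extract_trace(mv, list(x = 3, y = 30))
  expect_true(tre$excluded)
})

test_that("step counting recovers constructed bleaching staircases", {
  expect_equal(count_steps(rep(150, 20))$n_levels, 1)
  stair <- c(rep(200, 10), rep(100, 10), rep(0, 10))
  fit <- count_steps(stair, noise_sd = 2)
  expect_equal(fit$n_levels, 3)
  expect_equal(fit$change_frames, c(10, 20))
  expect_equal(fit$level_means, c(200, 100, 0))
  expect_true(fit$reaches_baseline)

  # scaling invariance of the classification
  set.seed(7)
  noisy <- stair + rnorm(30, 0, 8)
  f1 <- count_steps(noisy, noise_sd = 8)
  f2 <- count_steps(noisy * 1000, noise_sd = 8000)
  expect_equal(f1$n_levels, f2$n_levels)
  expect_equal(f1$change_frames, f2$change_frames)

  # larger penalty never yields more change points
  pens <- c(0.5, 1, 2, 4, 8, 16)
  ncp <- vapply(pens, function(b)
    length(count_steps(noisy, penalty_beta = b, noise_sd = 8)$change_frames),
    numeric(1))
  expect_true(all(diff(ncp) <= 0))
  expect_error(count_steps(c(1, 2, 3)), class = "smi_config_error")
})

test_that("binary segmentation matches exhaustive optimal segmentation on short traces", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(6:12, 1)
    k <- sample(0:2, 1)
    cps_true <- sort(sample(2:(n - 2), k))
    levels <- cumsum(c(200, -runif(k, 80, 150)))
    x <- rep(levels, diff(c(0, cps_true, n))) + rnorm(n, 0, 5)
    pen <- 4 * 25 * log(n)
    fit <- count_steps(x, penalty_beta = 4, noise_sd = 5)
    expect_equal(fit$change_frames, dp_optimal_changepoints(x, pen))
  }
})

test_that("the single-molecule filter implements the one-level-trace rule", {
  img <- tiny_imaging()
  mk <- function(x) count_steps(x, noise_sd = 3)
  flat <- rep(150, 30)
  one <- c(rep(150, 12), rep(0, 18))
  two <- c(rep(300, 10), rep(150, 10), rep(0, 10))
  blink <- c(rep(150, 10), rep(0, 10), rep(150, 10))
  spots <- data.frame(region_id = 1, x = 1:4, y = 1:4,
                      peak_intensity = 1, accepted = NA)
  fits <- lapply(list(flat, one, two, blink), mk)
  counting <- filter_single_molecules(spots, fits, mode = "counting")
  expect_equal(counting$accepted, c(TRUE, TRUE, FALSE, FALSE))
  validation <- filter_single_molecules(spots, fits, mode = "validation")
  # flat positive trace never reaches baseline -> rejected in validation mode
  expect_equal(validation$accepted, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("a mixed population yields the configured accepted fraction", {
  set.seed(23)
  n_tr <- 400
  is_double <- rbinom(n_tr, 1, 0.2) == 1
  acc <- vapply(seq_len(n_tr), function(i) {
    b <- sort(sample(5:55, if (is_double[i]) 2 else 1), decreasing = TRUE)
    x <- numeric(60)
    for (bf in b) x[seq_len(bf)] <- x[seq_len(bf)] + 150
    x <- x + rnorm(60, 0, 12)
    f <- count_steps(x, noise_sd = 12)
    dm <- diff(f$level_means)
    sum(dm > 0) == 0 && sum(dm < 0) <= 1 && f$reaches_baseline
  }, logical(1))
  p_acc <- mean(acc)
  se <- sqrt(0.8 * 0.2 / n_tr)
  expect_lt(abs(p_acc - 0.8), 4 * se + 0.02)
})
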