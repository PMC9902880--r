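test_that("emitter sampling follows the Poisson density model", {
  img <- imaging_config(width = 512, height = 512, pixel_size = 0.16)
  # zero density -> empty ground truth
  expect_equal(nrow(sample_emitters(0, img, seed = 1)), 0)
  # every emitter doubled when the multi-emitter fraction is 1
  tr2 <- sample_emitters(0.02, img, multi_emitter_fraction = 1, seed = 2)
  expect_true(all(tr2$n_fluorophores == 2))
  expect_true(all(lengths(tr2$bleach_frames) == 2))
  # Poisson mean: density 0.1/um^2 over 512^2 px at 0.16 um/px = 6710.9 um^2
  counts <- vapply(1:200, function(s)
    nrow(sample_emitters(0.1, img, seed = s)), numeric(1))
  expected <- 0.1 * 512^2 * 0.16^2
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # positions respect the border margin
  tr <- sample_emitters(0.1, img, border_margin = 8, seed = 3)
  expect_true(all(tr$x >= 8 & tr$x <= 503 & tr$y >= 8 & tr$y <= 503))
})

test_that("rendering conserves photons and respects the noise model", {
  # empty field, no background/read noise -> flat offset image
  img0 <- tiny_imaging(background_photons = 0, read_noise_sd = 0, offset = 7)
  blank <- render_movie(sample_emitters(0, img0, seed = 1), img0, seed = 2)
  expect_true(all(blank$data == 7))
  expect_equal(dim(blank$data), c(30, 64, 64))

  # photon conservation, noisy path: one never-bleaching fluorophore at
  # gain 1, no background/offset; mean frame sum estimates photons_per_frame
  imgp <- tiny_imaging(n_frames = 500, bleach_rate = 0, em_gain = 1,
                       read_noise_sd = 0, offset = 0, background_photons = 0,
                       photons_per_frame = 400)
  truth <- manual_truth(31.5, 30.2, imgp, bleach = 500)
  mv <- render_movie(truth, imgp, seed = 9)
  sums <- apply(mv$data, 1, sum)
  se <- sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums) - 400), 3 * se)

  # exact pre-noise expectation: signal mass + background, amplified + offset
  imge <- tiny_imaging(n_frames = 3, bleach_rate = 0, em_gain = 5,
                       background_photons = 2, offset = 10,
                       photons_per_frame = 300)
  mve <- render_movie(manual_truth(32, 32, imge, bleach = 3), imge,
                      noise = FALSE)
  frame_sum <- sum(mve$data[1, , ])
  expect_equal(frame_sum, 5 * (300 + 2 * 64^2) + 10 * 64^2, tolerance = 1e-6)
})

test_that("photobleaching survival follows the exponential model", {
  img <- imaging_config(width = 128, height = 128, n_frames = 100,
                        bleach_rate = 0.05)
  tr <- sample_emitters(0, img, expected_count = 3000, border_margin = 2,
                        seed = 4)
  b <- unlist(tr$bleach_frames)
  for (t in c(10, 30)) {
    p_hat <- mean(b > t)
    p_exp <- exp(-0.05 * t)
    se <- sqrt(p_exp * (1 - p_exp) / length(b))
    expect_lt(abs(p_hat - p_exp), 4 * se)
  }
})

test_that("region sets are deterministic and sized to protocol", {
  img <- tiny_imaging(n_frames = 8)
  a <- simulate_region_set(0.05, img, n_regions = 10, seed = 77)
  expect_length(a, 10)
  b <- simulate_region_set(0.05, img, n_regions = 10, seed = 77)
  expect_identical(lapply(a, function(r) r$movie$data),
                   lapply(b, function(r) r$movie$data))
  # default protocol movie length is 30 frames
  expect_equal(imaging_config()$n_frames, 30L)
  blank <- simulate_region_set(0, tiny_imaging(), n_regions = 1, seed = 1)
  expect_length(blank, 1)
  expect_equal(nrow(blank[[1]]$truth), 0)
})
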