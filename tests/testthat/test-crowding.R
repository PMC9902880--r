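test_that("crowding model is monotone and inverts consistently", {
  img <- imaging_config()
  expect_equal(expected_spot_count(0, img), 0)
  ns <- c(50, 150, 300, 450)
  es <- vapply(ns, expected_spot_count, numeric(1), img = img)
  expect_true(all(diff(es) > 0))
  expect_true(all(es <= ns))
  # losses grow with density
  expect_true(all(diff(es / ns) < 0))
  # inversion round trip
  for (target in c(10, 120, 340)) {
    n <- emitters_for_expected_count(target, img)
    expect_gte(n, target)
    # round trip within Monte-Carlo error (48 reps) plus 2% model slack
    mc_se <- sqrt(target / 48)
    expect_lt(abs(expected_spot_count(n, img) - target),
              3 * mc_se + 0.02 * target)
  }
  expect_equal(emitters_for_expected_count(0, img), 0)
  expect_equal(emitters_for_expected_count(-5, img), 0)
})

test_that("isolated-emitter pipeline efficiency is high but below one", {
  eff <- pipeline_efficiency(imaging_config(width = 128, height = 128),
                             n_fields = 1)
  expect_gt(eff, 0.85)
  expect_lte(eff, 1)
})
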