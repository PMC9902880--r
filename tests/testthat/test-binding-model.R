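test_that("equilibrium occupancy matches closed-form anchors and the numerical oracle", {
  # no target, no baseline, no nonspecific -> dark surface
  dark <- solve_competitive_occupancy(assay_config(
    target_conc = 0, unquenched_baseline_fraction = 0, nonspecific_density = 0))
  expect_equal(dark$theta_target, 0)
  expect_equal(dark$fluorescent_density, 0)

  # Langmuir half-saturation without competitor
  half <- solve_competitive_occupancy(assay_config(
    probe2_conc = 0, target_conc = 1e-11, kd_target = 1e-11,
    relative_capture_efficiency = 1))
  expect_equal(half$theta_target, 0.5)

  # competitive case against the mass-action fixed-point oracle
  cfg <- assay_config(target_conc = 1e-10, kd_target = 1e-11,
                      probe2_conc = 9e-9, kd_probe2 = 1e-9)
  occ <- solve_competitive_occupancy(cfg)
  expect_equal(occ$theta_target, 0.5)   # a = 10, b = 9 -> 10/20
  oracle <- equilibrium_oracle(1e-10, 1e-11, 9e-9, 1e-9)
  expect_equal(occ$theta_target, unname(oracle["theta_target"]),
               tolerance = 1e-10)
  expect_equal(occ$theta_probe2, unname(oracle["theta_probe2"]),
               tolerance = 1e-10)
})

test_that("occupancy fractions conserve to 1 and respond monotonically", {
  set.seed(41)
  for (i in 1:50) {
    cfg <- assay_config(target_conc = 10^runif(1, -14, -8),
                        probe2_conc = 10^runif(1, -12, -7),
                        kd_target = 10^runif(1, -13, -10),
                        kd_probe2 = 10^runif(1, -10, -7),
                        relative_capture_efficiency = runif(1))
    occ <- solve_competitive_occupancy(cfg)
    expect_lt(abs(occ$theta_target + occ$theta_probe2 + occ$theta_free - 1),
              1e-9)
    expect_true(all(c(occ$theta_target, occ$theta_probe2, occ$theta_free) >= 0))
    # strictly increasing in target concentration
    up <- cfg; up$target_conc <- cfg$target_conc * 2
    expect_gt(solve_competitive_occupancy(up)$theta_target, occ$theta_target)
    # strictly decreasing in competitor concentration
    comp <- cfg; comp$probe2_conc <- cfg$probe2_conc * 2
    expect_lt(solve_competitive_occupancy(comp)$theta_target, occ$theta_target)
  }
})

test_that("displacement kinetics start at zero, saturate to equilibrium, and are near-complete at 60 min", {
  cfg <- assay_config()
  eq <- solve_competitive_occupancy(cfg)
  tc <- occupancy_time_course(cfg, c(0, 1, 5, 15, 30, 60, 1e5))
  expect_equal(tc$theta_target[1], 0)
  expect_true(all(diff(tc$theta_target) >= 0))
  # asymptote equals the equilibrium solution
  expect_lt(abs(tc$theta_target[nrow(tc)] - eq$theta_target), 1e-8)
  # fractions conserve along the trajectory
  expect_true(all(abs(tc$theta_target + tc$theta_probe2 + tc$theta_free - 1) <
                    1e-9))
  # standard conditions approach saturation within the 60 min incubation
  at60 <- tc$theta_target[tc$time == 60]
  expect_gte(at60 / eq$theta_target, 0.95)
})

test_that("invalid assay inputs are rejected", {
  expect_error(assay_config(target_conc = -1), class = "smi_config_error")
  expect_error(assay_config(relative_capture_efficiency = 1.2),
               class = "smi_config_error")
  cfg <- assay_config()
  cfg$kd_target <- 0
  expect_error(solve_competitive_occupancy(cfg), class = "smi_config_error")
  expect_error(occupancy_time_course(assay_config(), c(-1, 5)),
               class = "smi_config_error")
  expect_error(occupancy_time_course(assay_config(), c(5, 1)),
               class = "smi_config_error")
})
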