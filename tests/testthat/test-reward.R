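test_that("band rewards match direct evaluation of the printed formulas", {
  # frozen values computed with the independent band_oracle
  expect_equal(r_map(75), 0.99981840, tolerance = 1e-5)
  expect_lt(abs(r_map(65)), 1e-8)
  expect_equal(r_map(100), -0.99999938, tolerance = 1e-5)
  expect_equal(r_sas(3.5), -0.51016401, tolerance = 1e-5)
  expect_equal(r_sas(3.0), -0.53788284, tolerance = 1e-5)
  expect_equal(r_sas(7.0), -0.94112054, tolerance = 1e-5)
  grid_map <- seq(40, 120, by = 0.25)
  expect_equal(r_map(grid_map), band_oracle(grid_map, 65, 85),
               tolerance = 1e-12)
  grid_sas <- seq(1, 7, by = 0.05)
  expect_equal(r_sas(grid_sas), band_oracle(grid_sas, 3, 4),
               tolerance = 1e-12)
})

test_that("band rewards are symmetric about the band center and unimodal", {
  x <- seq(0, 50, by = 0.5)
  expect_equal(r_map(75 - x), r_map(75 + x), tolerance = 1e-12)
  xs <- seq(0, 2.5, by = 0.05)
  expect_equal(r_sas(3.5 - xs), r_sas(3.5 + xs), tolerance = 1e-12)
  # restricted to the range where the logistic gradient is representable
  up <- r_map(seq(35, 75, by = 0.1))
  down <- r_map(seq(75, 115, by = 0.1))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
})

test_that("band rewards reject invalid input", {
  expect_error(r_map(NaN), "non-finite")
  expect_error(r_sas(0.5), "within")
  expect_error(r_sas(7.5), "within")
})

test_that("deviation follows the printed case structure", {
  expect_equal(deviation(60, 65, 85), 5)    # below band: LTB - value
  expect_equal(deviation(90, 65, 85), -5)   # above band: UTB - value
  expect_equal(deviation(70, 65, 85), 0)
  expect_equal(deviation(65, 65, 85), 0)    # boundaries inclusive
  expect_equal(deviation(85, 65, 85), 0)
  expect_error(deviation(70, 85, 65))
})

test_that("window error sums magnitudes by default, signed on request", {
  expect_equal(window_error(5, 0), 5)
  expect_equal(window_error(-5, 1), 6)
  expect_equal(window_error(-5, 1, signed = TRUE), -4)
  expect_equal(window_error(0, 0), 0)
})

test_that("gated reward reproduces the printed arithmetic", {
  cfg <- reward_config()
  bd <- reward_breakdown(sas = 3.5, map_mmHg = 75, propofol = 10,
                         fentanyl = 5, config = cfg)
  expect_equal(bd$r_dosage, 15)
  expect_equal(bd$error, 0)
  # improvement from a previous error of 1 -> gate passes
  r <- compute_reward(bd, error_prev = 1, config = cfg)
  expect_equal(r, r_sas(3.5) + r_map(75) - 0.02 * 15, tolerance = 1e-12)
  expect_equal(r, 0.1896544, tolerance = 1e-4)
  # no previous error (first window) -> gate treated as passed
  expect_equal(compute_reward(bd, NULL, cfg), r)
  # strict gate: equal zero errors do not count as improvement
  expect_identical(compute_reward(bd, error_prev = 0, config = cfg), 0)
  # perfect-control carve-out rewards maintained zero error when enabled
  cfg2 <- reward_config(gate_zero_pass = TRUE)
  expect_equal(compute_reward(bd, error_prev = 0, config = cfg2), r)
})

test_that("reward is exactly zero whenever the gate fails", {
  cfg <- reward_config()
  set.seed(42)
  for (i in 1:200) {
    err_prev <- runif(1, 0, 10)
    bd <- reward_breakdown(sas = runif(1, 1, 7),
                           map_mmHg = runif(1, 40, 120),
                           propofol = runif(1, 0, 20),
                           fentanyl = runif(1, 0, 10), config = cfg)
    r <- compute_reward(bd, err_prev, cfg)
    if (bd$error >= err_prev) expect_identical(r, 0)
  }
})

test_that("reward strictly decreases in dose when the gate passes", {
  cfg <- reward_config()
  bd1 <- reward_breakdown(3.5, 75, propofol = 2, fentanyl = 1, config = cfg)
  bd2 <- reward_breakdown(3.5, 75, propofol = 5, fentanyl = 1, config = cfg)
  bd3 <- reward_breakdown(3.5, 75, propofol = 5, fentanyl = 4, config = cfg)
  r <- vapply(list(bd1, bd2, bd3), compute_reward, numeric(1),
              error_prev = 99, config = cfg)
  expect_true(all(diff(r) < 0))
  expect_equal(r[1] - r[2], 0.02 * 3, tolerance = 1e-12)
})

test_that("trajectory_rewards agrees with window-by-window compute_reward", {
  set.seed(7)
  n <- 30
  sas <- runif(n, 1.5, 6.5)
  map <- runif(n, 50, 110)
  prop <- runif(n, 0, 15)
  fent <- runif(n, 0, 8)
  for (cfg in list(reward_config(),
                   reward_config(gate_zero_pass = TRUE, sas_scale = 0.25),
                   reward_config(gate_on_improvement = FALSE))) {
    tab <- trajectory_rewards(sas, map, prop, fent, cfg)
    expected <- numeric(n)
    err_prev <- NULL
    for (t in seq_len(n)) {
      bd <- reward_breakdown(sas[t], map[t], prop[t], fent[t], cfg)
      expected[t] <- compute_reward(bd, err_prev, cfg)
      err_prev <- bd$error
    }
    expect_equal(tab$reward, expected, tolerance = 1e-12)
    expect_equal(tab$error,
                 abs(deviation(map, 65, 85)) + abs(deviation(sas, 3, 4)),
                 tolerance = 1e-12)
  }
})

test_that("width-rescaled band variant sharpens the SAS band", {
  cfg <- reward_config(sas_scale = 0.25)
  expect_gt(r_sas(3.5, cfg), 0.5)           # interior approaches 1
  expect_lt(r_sas(6, cfg), -0.9)            # exterior clearly negative
  expect_equal(r_sas(3.5, cfg), band_oracle(3.5 / 0.25, 12, 16),
               tolerance = 1e-12)
})
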