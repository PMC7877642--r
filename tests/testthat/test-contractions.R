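test_that("baseline equals the data on a constant matrix", {
  dm <- make_dip_matrix(n_pos = 20, n_frames = 300)
  expect_equal(estimate_baseline(dm), dm$values)
  expect_error(estimate_baseline(dm, detection_config(baseline_window_s = 1)),
               "3 frames")
})

test_that("baseline ignores transients but tracks slow drift", {
  dip <- list(t0 = 60, dur = 10, x0 = 15, v = 0, depth = 0.2)
  dm <- make_dip_matrix(n_pos = 120, n_frames = 200, dips = list(dip))
  base <- estimate_baseline(dm)
  row <- which.min(abs(positions_mm(dm) - 15))
  expect_lt(max(abs(base[row, ] - 5)) / 5, 0.01)
  # slow linear drift: baseline follows within one window's change
  dmd <- make_dip_matrix(n_pos = 10, n_frames = 600)
  drift <- seq(0, 2, length.out = 600)
  dmd$values <- sweep(dmd$values, 2, drift, "+")
  based <- estimate_baseline(dmd)
  win_change <- 2 / 600 * (120 / dmd$frame_interval_s)
  expect_lt(max(abs(based - dmd$values)), win_change + 1e-9)
})

test_that("detection finds isolated events and nothing below threshold", {
  one <- make_dip_matrix(dips = list(list(t0 = 60, dur = 10, x0 = 15, v = 0,
                                          depth = 0.2)))
  ev <- detect_contractions(one)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$distance_mm, 1)
  expect_equal(ev$kind, "standing")
  expect_equal(ev$amplitude_pct, 20, tolerance = 0.05)
  expect_equal(ev$duration_s, 10, tolerance = 2 * one$frame_interval_s / 10)
  faint <- make_dip_matrix(dips = list(list(t0 = 60, dur = 10, x0 = 15,
                                            v = 0, depth = 0.05)))
  expect_equal(nrow(detect_contractions(faint)), 0)
  two <- make_dip_matrix(dips = list(list(t0 = 60, dur = 10, x0 = 5, v = 0,
                                          depth = 0.2),
                                     list(t0 = 60, dur = 10, x0 = 25, v = 0,
                                          depth = 0.3)))
  ev2 <- detect_contractions(two)
  expect_equal(nrow(ev2), 2)
})

test_that("propagation fit matches exact lines and the OLS oracle", {
  t <- seq(0, 10, by = 1)
  f1 <- fit_propagation(t, 3 + 0.2 * t)
  expect_equal(f1$slope_mm_s, 0.2)
  expect_equal(f1$r_squared, 1)
  f2 <- fit_propagation(t, 8 - 0.05 * t)
  expect_equal(f2$slope_mm_s, -0.05)
  expect_equal(f2$r_squared, 1)
  # the zig-zag example, against explicit normal equations
  path <- c(0, 1, 0, 2, 0, 3)
  tt <- 0:5
  f3 <- fit_propagation(tt, path)
  o3 <- ols_oracle(tt, path)
  expect_equal(f3$slope_mm_s, o3$slope, tolerance = 1e-12)
  expect_equal(f3$r_squared, o3$r_squared, tolerance = 1e-12)
  expect_identical(fit_propagation(c(1, 1), c(0, 2))$r_squared, NA_real_)
})

test_that("classification follows the distance and linearity rules", {
  cfg <- detection_config()
  lin <- list(slope_mm_s = 0.2, r_squared = 0.95)
  expect_equal(classify_event(0.9, lin, cfg)$kind, "standing")
  c1 <- classify_event(3, lin, cfg)
  expect_equal(c1$kind, "ripple")
  expect_equal(c1$direction, "anterograde")
  c2 <- classify_event(3, list(slope_mm_s = -0.01, r_squared = 0.5), cfg)
  expect_equal(c2$kind, "slow_propulsive")
  expect_equal(c2$direction, "retrograde")
  c3 <- classify_event(3, list(slope_mm_s = 0, r_squared = 0.5), cfg)
  expect_equal(c3$direction, "none")
  # exactly at the boundaries: ties go to standing / ripple
  expect_equal(classify_event(1.0, lin, cfg)$kind, "standing")
  expect_equal(classify_event(3, list(slope_mm_s = 1, r_squared = 0.8),
                              cfg)$kind, "ripple")
})

test_that("every detected event gets exactly one kind", {
  p <- default_params("cellulose")
  p$rates_cpm_mm[] <- 0
  p$rates_cpm_mm[, "standing"] <- 0.15
  p$rates_cpm_mm[, "ripple"] <- 0.04
  p$rates_cpm_mm[, "slow_propulsive"] <- 0.03
  p$horizon_s <- 1800
  scen <- generate_scenario(p, 1, seed = 5, lengths_mm = 70)
  ev <- detect_scenario_events(scen)
  expect_gt(nrow(ev), 50)
  expect_true(all(ev$kind %in% c("standing", "ripple", "slow_propulsive")))
  expect_equal(sum(table(ev$kind)), nrow(ev))
  expect_true(all(ev$velocity_mm_s[!is.na(ev$velocity_mm_s)] >= 0))
  expect_true(all(ev$direction[ev$kind == "standing"] == "none"))
  expect_true(all(ev$direction[ev$kind != "standing"] %in%
                    c("anterograde", "retrograde", "none")))
  expect_true(all(ev$distance_mm[ev$kind == "standing"] <= 1))
  expect_true(all(ev$distance_mm[ev$kind != "standing"] > 1))
  r2 <- ev$r_squared
  expect_true(all(r2[ev$kind == "ripple"] >= 0.8))
  expect_true(all(r2[ev$kind == "slow_propulsive"] < 0.8))
})

test_that("component labelling agrees with an independent graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:12) {
    mask <- matrix(runif(30 * 40) < 0.12, 30, 40)
    gap <- sample(0:2, 1)
    ours <- gutmotion:::.label_events(mask, gap)
    oracle <- label_oracle(mask, gap)
    expect_true(same_partition(ours, oracle))
  }
})
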