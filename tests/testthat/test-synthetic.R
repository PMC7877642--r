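test_that("truncated-lognormal calibration hits the target medians", {
  triples <- list(c(0.077, 0.474, 0.779), c(0.127, 0.553, 0.790),
                  c(1.7, 1.8, 23.4), c(1.72, 15.3, 506.6),
                  c(0.04, 0.22, 0.67), c(0.001, 0.04, 0.70))
  set.seed(41)
  for (tr in triples) {
    d <- calibrate_lognormal(tr[1], tr[2], tr[3], n = 1e5)
    x <- rtrunclnorm(1e5, d)
    expect_lt(abs(median(x) - tr[2]) / tr[2], 0.01)
    expect_true(all(x >= tr[1] & x <= tr[3]))
  }
  d2 <- calibrate_lognormal(1.72, 15.3, 506.6, 1e5, lower = 3.43)
  x2 <- rtrunclnorm(1e5, d2)
  expect_lt(abs(median(x2) - 15.3) / 15.3, 0.01)
  expect_gte(min(x2), 3.43)
  expect_error(calibrate_lognormal(2, 1, 3), "median")
})

test_that("scenarios are deterministic in their seed", {
  p <- default_params("lipid")
  p$horizon_s <- 1200
  s1 <- generate_scenario(p, 2, seed = 99)
  s2 <- generate_scenario(p, 2, seed = 99)
  expect_identical(s1, s2)
  m1 <- render_diameter_matrix(s1, 1, p$frame_rate_detect, 0, 600)
  m2 <- render_diameter_matrix(s2, 1, p$frame_rate_detect, 0, 600)
  expect_identical(m1$values, m2$values)
  s3 <- generate_scenario(p, 2, seed = 100)
  expect_false(identical(s1$preparations[[1]]$events,
                         s3$preparations[[1]]$events))
})

test_that("a rate-free noiseless scenario reduces to evacuation geometry", {
  p <- default_params("cellulose")
  p$rates_cpm_mm[] <- 0
  p$noise_sd_mm <- 0
  p$horizon_s <- 4 * 3600
  scen <- generate_scenario(p, 1, seed = 51, lengths_mm = 60)
  scen$preparations[[1]]$evacuation_s <- 2 * 3600
  dm <- render_diameter_matrix(scen, 1, noise = FALSE)   # 0.35 fps
  part <- partition_segments(dm)
  aw1 <- average_width_segment1(dm, part)
  # AW1 matches the closed-form profile: rest mean + bolus gain before
  # evacuation, rest mean after the decay
  x1 <- positions_mm(dm)[part$segment_of == 1]
  rest_mean <- mean(resting_profile(p, 60, x1))
  shape_mean <- mean(plogis((0.45 - x1 / 60) / 0.025))
  tms <- frame_times(dm)
  pre <- tms < 2 * 3600
  post <- tms > 2 * 3600 + p$bolus_decay_s
  expect_lt(max(abs(aw1[pre] - (rest_mean + p$bolus_gain_mm * shape_mean))),
            1e-6)
  expect_lt(max(abs(aw1[post] - rest_mean)), 1e-6)
  bet <- compute_bet(aw1, bew_threshold(aw1), dm$t0_offset_s,
                     dm$frame_interval_s)
  expect_equal(bet$bet_h, 2, tolerance = 2 * dm$frame_interval_s / 7200)
})

test_that("realized event counts follow the Poisson draw", {
  scen <- event_farm("standing", seed = 61, n_events = 2200)
  gt <- ground_truth_events(scen)
  expect_lt(abs(nrow(gt) - 2200), 4 * sqrt(2200))
  expect_gte(scen$preparations[[1]]$placement["placed"] /
               scen$preparations[[1]]$placement["target"], 0.99)
})

test_that("ground truth round-trips through its annotation file", {
  p <- default_params("cellulose")
  p$horizon_s <- 900
  scen <- generate_scenario(p, 1, seed = 71, lengths_mm = 65)
  path <- file.path(tempdir(), "gt.tsv")
  write_ground_truth(scen, path)
  back <- read_ground_truth(path)
  gt <- ground_truth_events(scen)
  expect_equal(nrow(back), nrow(gt))
  for (cn in c("kind", "segment", "period", "direction"))
    expect_identical(back[[cn]], gt[[cn]])
  for (cn in c("onset_s", "duration_s", "amplitude_pct", "distance_mm",
               "velocity_mm_s"))
    expect_equal(back[[cn]], gt[[cn]], tolerance = 1e-12)
  # zero-event scenario: header-only file
  p0 <- p; p0$rates_cpm_mm[] <- 0
  scen0 <- generate_scenario(p0, 1, seed = 72)
  write_ground_truth(scen0, path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_ground_truth(path)), 0)
})

test_that("detection closes the loop on a noiseless well-separated mix", {
  p <- default_params("cellulose")
  p$rates_cpm_mm[] <- 0
  p$rates_cpm_mm[, "standing"] <- 0.2
  p$rates_cpm_mm[, "ripple"] <- 0.05
  p$rates_cpm_mm[, "slow_propulsive"] <- 0.04
  p$noise_sd_mm <- 0
  p$horizon_s <- 2400
  scen <- generate_scenario(p, 1, seed = 81, lengths_mm = 70)
  gt <- ground_truth_events(scen)
  ev <- detect_scenario_events(scen, chunk_s = 2400)
  sc <- detection_scores(ev, gt)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
  expect_gte(sc$kind_accuracy, 0.95)
  m <- sc$matched
  hit <- !is.na(m$det_id)
  # amplitude within 2 percentage points, ripple velocity within 10%
  amp_err <- ev$amplitude_pct[m$det_id[hit]] - m$amplitude_pct[hit]
  expect_lt(median(abs(amp_err)), 2)
  ri <- hit & m$kind == "ripple" & m$det_kind == "ripple"
  vel_rel <- abs(ev$velocity_mm_s[m$det_id[ri]] - m$velocity_mm_s[ri]) /
    m$velocity_mm_s[ri]
  expect_lt(median(vel_rel), 0.1)
})
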