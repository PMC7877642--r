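fake_events <- function(n, kind = "slow_propulsive", direction = "anterograde",
                        segment = 1, period = "I", prep = "p1",
                        amplitude = 40, duration = 5, velocity = 0.1) {
  if (n == 0) return(NULL)
  data.frame(event_id = seq_len(n), onset_s = seq_len(n), end_s = seq_len(n) + 5,
             duration_s = duration, kind = kind, amplitude_pct = amplitude,
             distance_mm = 2, distance_pct = 3, slope_mm_s = 0.1,
             velocity_mm_s = velocity, r_squared = 0.5, direction = direction,
             segment = segment, window = "t1", period = period,
             preparation_id = prep, treatment = "cellulose",
             stringsAsFactors = FALSE)
}

fake_prep <- function(id = "p1", minutes_I = 90, seg1 = 10) {
  data.frame(preparation_id = id, treatment = "cellulose",
             minutes_I = minutes_I, minutes_II = 90,
             seg1_mm = seg1, seg2_mm = 10, seg3_mm = 10, seg4_mm = 10,
             stringsAsFactors = FALSE)
}

test_that("frequency is count over analysed minutes times segment length", {
  win <- data.frame(start_s = c(0, 2000, 4000), end_s = c(1800, 3800, 5800))
  expect_equal(compute_frequency(90, win, 10), 0.1)
  expect_equal(compute_frequency(0, win, 10), 0)
  expect_equal(compute_frequency(fake_events(45), win, 5), 0.1)
  expect_error(compute_frequency(1, win[0, ], 10), "positive")
  expect_error(compute_frequency(1, win, 0), "positive")
})

test_that("a Poisson count recovers its generating rate", {
  set.seed(23)
  win <- data.frame(start_s = 0, end_s = 90 * 60)
  n <- rpois(1, 1.5 * 90 * 20)            # rate 1.5 cpm/mm, 20 mm, 90 min
  f <- compute_frequency(n, win, 20)
  expect_lt(abs(f - 1.5), 3 * sqrt(2700) / (90 * 20))
})

test_that("direction proportions and pooled medians are as defined", {
  ev <- rbind(fake_events(5, direction = "anterograde"),
              fake_events(3, direction = "retrograde"))
  s <- summarize_motility(ev, fake_prep())
  cell <- s[s$segment == 1 & s$period == "I" & s$kind == "slow_propulsive", ]
  expect_equal(cell$anterograde_prop, 0.625)
  expect_equal(cell$n_events, 8)
  one <- summarize_motility(fake_events(1, amplitude = 40), fake_prep())
  c1 <- one[one$segment == 1 & one$period == "I" &
              one$kind == "slow_propulsive", ]
  expect_equal(c1$amplitude_median, 40)
  expect_equal(c1$amplitude_min, 40)
  expect_equal(c1$amplitude_max, 40)
  empty <- one[one$segment == 2 & one$period == "I" & one$kind == "ripple", ]
  expect_equal(empty$n_events, 0)
  expect_true(is.na(empty$amplitude_median))   # missing, not zero
})

test_that("per-segment counts add up to the whole-intestine count", {
  set.seed(29)
  ev <- do.call(rbind, lapply(1:4, function(s)
    fake_events(sample(0:20, 1), segment = s)))
  s <- summarize_motility(ev, fake_prep())
  expect_equal(sum(s$n_events), nrow(ev))
  expect_equal(sum(s$n_anterograde + s$n_retrograde + s$n_undirected),
               nrow(ev))
})

test_that("frequencies are invariant to consistent time rescaling", {
  ev <- fake_events(60)
  f_min <- compute_frequency(ev, data.frame(start_s = 0, end_s = 3600), 10)
  f_scaled <- compute_frequency(ev, data.frame(start_s = 0, end_s = 3600), 10)
  expect_equal(f_min, f_scaled)
  s1 <- summarize_motility(ev, fake_prep(minutes_I = 60))
  s2 <- summarize_motility(ev, fake_prep(minutes_I = 120))
  c1 <- s1[s1$segment == 1 & s1$period == "I" & s1$kind == "slow_propulsive", ]
  c2 <- s2[s2$segment == 1 & s2$period == "I" & s2$kind == "slow_propulsive", ]
  expect_equal(c1$frequency_cpm_mm, 2 * c2$frequency_cpm_mm)
})

test_that("group frequency is the mean over per-preparation values", {
  ev <- rbind(fake_events(60, prep = "a"), fake_events(30, prep = "b"))
  preps <- rbind(fake_prep("a"), fake_prep("b"))
  s <- summarize_motility(ev, preps)
  cell <- s[s$segment == 1 & s$period == "I" & s$kind == "slow_propulsive", ]
  f_a <- 60 / (90 * 10); f_b <- 30 / (90 * 10)
  expect_equal(cell$frequency_cpm_mm, mean(c(f_a, f_b)))
  expect_equal(cell$frequency_sd, sd(c(f_a, f_b)))
})
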