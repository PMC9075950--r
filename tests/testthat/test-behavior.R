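test_that("instantaneous lick rate is the inverse interlick interval", {
  r <- instantaneous_lick_rate(c(0, 0.125, 0.250))
  expect_equal(r$rate_hz, c(8, 8))
  r2 <- instantaneous_lick_rate(c(0, 0.1, 0.3))
  expect_equal(r2$rate_hz, c(10, 5))
  expect_equal(nrow(instantaneous_lick_rate(1.0)), 0L)
  expect_error(instantaneous_lick_rate(c(1, 1, 2)), "duplicate")
})

test_that("bout segmentation partitions licks and flags isolation", {
  licks <- c(0, 0.13, 0.26, 5, 5.13)
  b <- segment_bouts(licks, bout_break_s = 1)
  expect_equal(nrow(b), 2L)
  expect_equal(b$first_lick_s, c(0, 5))
  expect_equal(b$last_lick_s, c(0.26, 5.13))
  expect_true(b$isolated[2])  # 4.74 s gap >= 2 s

  one <- segment_bouts(seq(0, 2, by = 0.15), bout_break_s = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$first_lick_s, 0)
  expect_equal(one$last_lick_s, max(seq(0, 2, by = 0.15)))

  # partition property over random lick trains
  set.seed(42)
  for (rep in 1:20) {
    licks <- sort(runif(60, 0, 120))
    b <- segment_bouts(licks, bout_break_s = 1)
    expect_equal(sum(b$n_licks), length(licks))
    # isolation definition: gap to previous lick >= 2 s
    for (k in seq_len(nrow(b))[-1]) {
      gap <- b$first_lick_s[k] - b$last_lick_s[k - 1]
      expect_equal(b$isolated[k], gap >= 2)
    }
    # idempotence of re-segmentation on the same parameters
    expect_identical(b, segment_bouts(licks, bout_break_s = 1))
  }
})

test_that("bout trial assignment and context labels match ground truth", {
  cfg <- sim_config(n_trials = 120, p_bout = 1, p_pre_water_bout = 0.6,
                    seed = 31L)
  tr <- generate_trials(cfg)
  lk <- generate_licks(tr, cfg)
  b <- segment_bouts(sort(lk$licks$time_s), trials = tr)
  m <- merge(lk$bouts, b, by = "trial_id", suffixes = c(".t", ".s"))
  expect_equal(nrow(m), nrow(lk$bouts))
  expect_equal(m$first_lick_s.t, m$first_lick_s.s)
  expect_equal(m$last_lick_s.t, m$last_lick_s.s)
  # context exact for bouts starting away from the water time
  sched <- tr$start_s + cfg$interval_s
  far <- abs(m$first_lick_s.t - sched[match(m$trial_id, tr$trial_id)]) > 0.1
  expect_true(all(m$context.t[far] == m$context.s[far]))
})

test_that("lick PSTH is flat for metronomic licking and linear over trial sets", {
  trials <- data.frame(trial_id = 1L, start_s = 0, water_s = 10,
                       rewarded = TRUE, opto_on_s = NA_real_,
                       opto_off_s = NA_real_)
  licks <- data.frame(trial_id = 1L, time_s = seq(6, 14, by = 0.125))
  s <- list(trials = trials, licks = licks)
  p <- trial_averaged_lick_psth(s, align = "water", window = c(-2, 2),
                                bin = 0.5)
  expect_true(all(abs(p$rate_hz - 8) < 1e-9))

  # linearity: the PSTH of a union of disjoint trial sets equals the
  # trial-count-weighted mean of the two PSTHs, exactly
  cfg <- sim_config(n_trials = 30, p_unrewarded = 0, seed = 23L)
  tr <- generate_trials(cfg)
  lk <- generate_licks(tr, cfg)
  sel1 <- tr$trial_id <= 15
  s1 <- list(trials = tr[sel1, ],
             licks = lk$licks[lk$licks$trial_id %in% tr$trial_id[sel1], ])
  s2 <- list(trials = tr[!sel1, ],
             licks = lk$licks[lk$licks$trial_id %in% tr$trial_id[!sel1], ])
  sall <- list(trials = tr, licks = lk$licks)
  p1 <- trial_averaged_lick_psth(s1, "water", c(-3, 2), 0.1)
  p2 <- trial_averaged_lick_psth(s2, "water", c(-3, 2), 0.1)
  pa <- trial_averaged_lick_psth(sall, "water", c(-3, 2), 0.1)
  n1 <- attr(p1, "n_trials"); n2 <- attr(p2, "n_trials")
  expect_equal(pa$rate_hz, (n1 * p1$rate_hz + n2 * p2$rate_hz) / (n1 + n2))

  # first-lick alignment: all fully-pre-event bins are silent for
  # isolated bouts, and the peak stays in the rhythmic band
  b <- segment_bouts(sort(lk$licks$time_s), trials = tr)
  pf <- trial_averaged_lick_psth(sall, "first_lick", c(-2, 1), 0.1,
                                 bouts = b[b$isolated, ])
  expect_true(all(pf$rate_hz[pf$time_s < -0.05] == 0))
  expect_true(max(pf$rate_hz) <= 10 + 1e-9)
  expect_gt(max(pf$rate_hz), 5)
})

test_that("empty alignment selections are reported, not fatal", {
  trials <- data.frame(trial_id = 1:2, start_s = c(0, 10),
                       water_s = c(NA_real_, NA_real_), rewarded = FALSE,
                       opto_on_s = NA_real_, opto_off_s = NA_real_)
  s <- list(trials = trials,
            licks = data.frame(trial_id = 1L, time_s = 5))
  p <- trial_averaged_lick_psth(s, align = "water")
  expect_equal(attr(p, "n_trials"), 0L)
  expect_equal(attr(p, "n_excluded"), 2L)
  expect_match(attr(p, "reason"), "no trials")
})

test_that("bout initiation histogram splits pre and post water", {
  trials <- data.frame(trial_id = 1:4, start_s = c(0, 10, 20, 30),
                       water_s = c(10, 20, 30, 40), rewarded = TRUE,
                       opto_on_s = NA_real_, opto_off_s = NA_real_)
  bouts <- data.frame(trial_id = 1:4,
                      first_lick_s = c(10, 20, 30, 40),
                      last_lick_s = c(11, 21, 31, 41))
  h <- bout_initiation_histogram(bouts, trials, bin = 0.5, window = c(-2, 2))
  expect_equal(sum(h$histogram$count), 4L)
  expect_equal(h$histogram$count[h$histogram$time_s == 0.25], 4L)
  expect_equal(h$n_pre, 0L)
  expect_equal(h$n_post, 4L)

  empty <- bout_initiation_histogram(bouts[0, ], trials)
  expect_true(all(empty$histogram$count == 0))

  cfg <- sim_config(n_trials = 1000, p_unrewarded = 0, p_bout = 1,
                    p_pre_water_bout = 0.7, seed = 29L)
  tr <- generate_trials(cfg)
  lk <- generate_licks(tr, cfg)
  h2 <- bout_initiation_histogram(lk$bouts, tr)
  frac <- h2$n_pre / (h2$n_pre + h2$n_post)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.21 / 1000))
})

test_that("opto lick metrics are null when the stimulus has no effect", {
  # long bouts spanning both the prestimulus and the stimulus window, so
  # that under a no-effect stimulus both windows sample the same licking
  cfg <- sim_config(n_trials = 200, p_unrewarded = 0.3, p_bout = 1,
                    p_pre_water_bout = 1, pre_water_lead_s = 5.0,
                    pre_water_lead_sd_s = 0.2, bout_len_range = c(6, 80),
                    seed = 37L)
  base <- simulate_session(cfg, units = list())
  null_s <- generate_opto(base, window_rel_s = c(7, 9), stim_frac = 0.5,
                          suppression = 1, rebound_prob = 0, seed = 38L)
  m0 <- opto_lick_metrics(null_s)
  expect_gt(m0$variance_ratio, 0.5)
  expect_lt(m0$variance_ratio, 2.0)
  expect_lt(abs(m0$rate_stim_hz - m0$rate_control_hz), 1.0)
})

test_that("opto lick metrics recover suppression and rebound", {
  # short bouts contained in the stimulus window: full suppression then
  # silences the whole trial, so rebound bouts are the only post-offset
  # initiations
  cfg <- sim_config(n_trials = 300, p_unrewarded = 0.3, p_bout = 1,
                    p_pre_water_bout = 1, pre_water_lead_s = 3.0,
                    pre_water_lead_sd_s = 0.3, bout_len_range = c(6, 12),
                    seed = 47L)
  base <- simulate_session(cfg, units = list())
  sup <- generate_opto(base, window_rel_s = c(5.5, 9.5), stim_frac = 0.5,
                       suppression = 0, rebound_prob = 0.5, seed = 39L)
  m1 <- opto_lick_metrics(sup)
  expect_equal(m1$rate_stim_hz, 0)
  expect_gt(m1$rate_control_hz, 0.5)
  expect_lt(abs(m1$rebound_prob - 0.5), 3 * sqrt(0.25 / m1$n_stim) + 0.05)
  expect_gt(m1$rate_rebound_stim_hz, m1$rate_rebound_control_hz)

  no_ctrl <- sup
  no_ctrl$trials$opto_on_s <- 1
  no_ctrl$trials$opto_off_s <- 2
  expect_error(opto_lick_metrics(no_ctrl), "control")
})
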