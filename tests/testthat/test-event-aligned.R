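# Build an aligned_response with prescribed bin values over [-1, 0.5].
make_resp <- function(values) {
  edges <- seq(-1, 0.5, by = 0.1)
  structure(list(bin_edges = edges, time_s = edges[-16] + 0.05,
                 delta_rate_hz = values, sem_hz = rep(0, 15),
                 baseline_rate_hz = 0, n_events = 1L),
            class = "aligned_response")
}

test_that("nonlicking baseline recovers the quiescent rate", {
  set.seed(51)
  st <- rpois_train(50, 600)
  licks <- sort(runif(30, 50, 550))
  b <- baseline_rate(st, licks, t_range = c(0, 600))
  expect_lt(abs(b - 50), 3 * sqrt(50 / 400))
  expect_equal(baseline_rate(st, numeric(), t_range = c(0, 600)),
               length(st) / 600)
  dense <- seq(0, 600, by = 1)   # licking everywhere: no baseline epochs
  expect_error(baseline_rate(st, dense, t_range = c(0, 600)),
               "insufficient nonlicking")
})

test_that("baseline ignores lick-locked firing", {
  s <- std_session()
  u <- unit_spec(1, baseline_rate_hz = 60, phase_depth_hz = 30,
                 init_ramp = c(0.3, 40), bout_peak_hz = 60)
  st <- generate_spike_train(u, s, 71L)
  b <- baseline_rate(st, sort(s$licks$time_s),
                     t_range = c(0, session_t_end(s)))
  expect_lt(abs(b - 60), 2)
})

test_that("aligned delta rate matches analytic expectations", {
  set.seed(53)
  events <- seq(20, 580, by = 5)
  st <- sort(c(rpois_train(50, 600),
               unlist(lapply(events, function(e)
                 e + sort(runif(rpois(1, 10 * 0.5), 0, 0.5))))))
  r <- aligned_delta_rate(st, events, window = c(-1, 0.5), baseline = 50)
  pre <- r$time_s < 0
  expect_true(all(abs(r$delta_rate_hz[pre]) < 3 * r$sem_hz[pre] + 1e-9))
  post <- r$time_s > 0
  expect_lt(max(abs(r$delta_rate_hz[post] - 10) - 3 * r$sem_hz[post]), 0)

  one <- aligned_delta_rate(5.05, 5, window = c(-1, 0.5), baseline = 7)
  expect_equal(one$delta_rate_hz[one$time_s > 0 & one$time_s < 0.1],
               10 - 7)
  expect_equal(sum(one$delta_rate_hz == -7), 14L)

  empty <- aligned_delta_rate(st, numeric())
  expect_equal(empty$n_events, 0L)
  expect_match(empty$reason, "no alignment events")
})

test_that("aligned results are invariant under a common time shift", {
  set.seed(57)
  st <- rpois_train(40, 300)
  events <- seq(10, 290, by = 10)
  r0 <- aligned_delta_rate(st, events, baseline = 40)
  r1 <- aligned_delta_rate(st + 123.456, events + 123.456, baseline = 40)
  expect_equal(r1$delta_rate_hz, r0$delta_rate_hz)
  expect_equal(r1$sem_hz, r0$sem_hz)
})

test_that("initiation-ramp rule fires on constructed ramps with the right onset", {
  r <- make_resp(c(0, 0, 1, 2, 3, 4, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  cls <- classify_first_lick_modulation(r)
  expect_equal(cls$modulation, "positive")
  expect_equal(cls$onset_s, -0.8)   # left edge of the bin where 0 -> 1

  expect_equal(classify_first_lick_modulation(make_resp(rep(2, 15)))$modulation,
               "none")

  neg <- classify_first_lick_modulation(
    make_resp(-c(0, 0, 1, 2, 3, 4, 0, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_equal(neg$modulation, "negative")
  expect_equal(neg$onset_s, -0.8)

  # when both patterns exist the earlier one wins
  both <- classify_first_lick_modulation(
    make_resp(c(5, 4, 3, 2, 2, 2, 2, 2, 2, 2, 3, 4, 5, 6, 7)))
  expect_equal(both$modulation, "negative")
  expect_equal(both$onset_s, -0.9)

  bad <- make_resp(rep(0, 15)); bad$bin_edges <- seq(-2, 1, by = 0.2)
  expect_error(classify_first_lick_modulation(bad), "100-ms bins")
})

test_that("termination rule detects constructed steps and spares the null", {
  events <- seq(30, 570, by = 6)
  set.seed(61)
  quiet <- rpois_train(20, 600)
  burst <- unlist(lapply(events, function(e)
    e - 0.3 + sort(runif(30, 0, 0.3))))
  pos <- classify_termination_modulation(sort(c(quiet, burst)), events)
  expect_equal(pos$modulation, "positive")
  expect_gte(pos$onset_s, -0.3)

  # mirrored: silence the final 300 ms of an otherwise steady train
  steady <- rpois_train(40, 600)
  gap <- steady
  for (e in events) gap <- gap[gap < e - 0.3 | gap >= e]
  neg <- classify_termination_modulation(sort(gap), events)
  expect_equal(neg$modulation, "negative")

  n_sim <- 150
  calls <- vapply(seq_len(n_sim), function(i) {
    classify_termination_modulation(rpois_train(40, 600), events)$modulation
  }, character(1))
  expect_gte(mean(calls == "none"), 0.95)
})

test_that("context-specific ramps yield the right tuning categories", {
  # deterministic spike placement: exact per-bin counts around each event,
  # so the classification reflects the wiring, not sampling noise
  spikes_at <- function(events, counts) {
    edges <- seq(-1, 0.5, by = 0.1)
    unlist(lapply(events, function(e)
      unlist(lapply(which(counts > 0), function(b)
        e + edges[b] + seq_len(counts[b]) / (counts[b] + 1) * 0.1))))
  }
  bouts <- data.frame(
    trial_id = 1:40,
    first_lick_s = seq(50, by = 50, length.out = 40),
    last_lick_s = seq(50, by = 50, length.out = 40) + 8,
    n_licks = 20L, isolated = TRUE,
    context = rep(c("pre_water", "post_water"), 20))
  pre_f <- bouts$first_lick_s[bouts$context == "pre_water"]
  post_f <- bouts$first_lick_s[bouts$context == "post_water"]
  ramp <- c(2, 2, 2, 2, 2, 2, 3, 5, 8, 12, 14, 15, 15, 15, 15)
  flat <- rep(2L, 15)

  # unit ramping only before exploratory (pre-water) bouts
  st <- sort(c(spikes_at(pre_f, ramp), spikes_at(post_f, flat)))
  cls <- classify_by_context(st, bouts, baseline = 20)
  expect_equal(cls$pre_water$modulation, "positive")
  expect_equal(cls$pre_water$onset_s, -0.4)
  expect_equal(cls$post_water$modulation, "none")
  expect_equal(cls$category, "pre_init")

  # unit ramping in both contexts and before termination
  term_burst <- unlist(lapply(bouts$last_lick_s, function(e)
    e - 0.3 + seq(0.01, 0.29, length.out = 12)))
  st2 <- sort(c(spikes_at(pre_f, ramp), spikes_at(post_f, ramp),
                term_burst))
  cls2 <- classify_by_context(st2, bouts, baseline = 20)
  expect_equal(cls2$pre_water$modulation, "positive")
  expect_equal(cls2$post_water$modulation, "positive")
  expect_equal(cls2$termination$modulation, "positive")
  expect_equal(cls2$category, "pre_init+post_init+term")

  # any negative transition pools the unit into the negative group
  st3 <- sort(c(spikes_at(pre_f, rev(ramp)), spikes_at(post_f, flat)))
  cls3 <- classify_by_context(st3, bouts, baseline = 20)
  expect_equal(cls3$pre_water$modulation, "negative")
  expect_equal(cls3$category, "negative")

  # a context with too few bouts is unavailable
  cls4 <- classify_by_context(st, bouts[bouts$context == "pre_water", ],
                              baseline = 20)
  expect_null(cls4$post_water)
})

test_that("population onset follows the analytic mixture", {
  ramp_bins <- function(onset, slope) {
    edges <- seq(-1, 0.5, by = 0.1)
    vapply(seq_len(15), function(b) {
      f <- function(t) pmax(t - onset, 0) * slope
      stats::integrate(f, edges[b], edges[b + 1])$value / 0.1
    }, numeric(1))
  }
  same <- replicate(6, make_resp(ramp_bins(-0.3, 40)), simplify = FALSE)
  pop <- population_onset_time(same)
  expect_equal(pop$onset_s, -0.3)

  flat <- replicate(5, make_resp(rep(1, 15)), simplify = FALSE)
  expect_equal(population_onset_time(flat)$modulation, "none")
  expect_true(is.na(population_onset_time(flat)$onset_s))

  # equal mixture of early and late ramps: onset between the two, and at
  # the earliest rise of the mixed trace by the rule's construction
  mix <- c(replicate(3, make_resp(ramp_bins(-0.4, 40)), simplify = FALSE),
           replicate(3, make_resp(ramp_bins(-0.1, 40)), simplify = FALSE))
  pmix <- population_onset_time(mix)
  expect_gte(pmix$onset_s, -0.4)
  expect_lte(pmix$onset_s, -0.1)
  expect_error(population_onset_time(same[1:3]), "at least 5")
})

test_that("lick-rate/spike-rate regression recovers a linear rate code", {
  interval <- 10
  n_tr <- 12
  trials <- data.frame(trial_id = seq_len(n_tr),
                       start_s = (seq_len(n_tr) - 1) * interval,
                       water_s = seq_len(n_tr) * interval, rewarded = TRUE,
                       opto_on_s = NA_real_, opto_off_s = NA_real_)
  set.seed(91)
  lick_rows <- list(); spike_times <- numeric()
  for (i in seq_len(n_tr)) {
    lo <- trials$start_s[i]
    tl <- numeric()
    for (b in 0:8) {
      n_licks <- if (b < 2) 0 else sample(4:8, 1)
      if (n_licks > 0)
        tl <- c(tl, lo + b + seq(0.05, 0.95, length.out = n_licks))
      n_spikes <- 5 + 2 * n_licks   # exact linear rate code
      spike_times <- c(spike_times,
                       lo + b + seq(0.01, 0.99, length.out = n_spikes))
    }
    lick_rows[[i]] <- data.frame(trial_id = i, time_s = tl)
  }
  session <- list(trials = trials, licks = do.call(rbind, lick_rows))
  fit <- lickrate_spikerate_correlation(session, sort(spike_times))
  expect_false(fit$degenerate)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$intercept, 5, tolerance = 1e-6)
  expect_gt(fit$r, 0.999)

  # lick-independent unit: slope indistinguishable from zero
  set.seed(92)
  st0 <- rpois_train(50, n_tr * interval)
  fit0 <- lickrate_spikerate_correlation(session, st0)
  expect_lt(abs(fit0$slope), 1.5)

  # constant lick rate in every bin is a degenerate regression
  lconst <- data.frame(trial_id = 1L,
                       time_s = seq(0.0625, 18, by = 0.125))
  sess2 <- list(trials = trials[1:2, ], licks = lconst)
  fit2 <- lickrate_spikerate_correlation(sess2, st0, min_prelick_s = 0)
  expect_true(fit2$degenerate)
  expect_true(is.na(fit2$slope))

  expect_error(
    lickrate_spikerate_correlation(list(trials = trials[1, ],
                                        licks = lick_rows[[1]][0, ]),
                                   st0),
    "qualifying")
})
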