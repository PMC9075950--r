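#' Configuration for a synthetic interval-timing session
#'
#' Bundles every parameter of the session generator: the trial structure
#' (fixed inter-reward interval, probability of water omission under the
#' no-two-consecutive-omissions constraint), the licking model (one bout per
#' trial, rhythmic interlick intervals, exploratory onsets leading water and
#' reactive onsets trailing it, a consummatory rate boost after water), and
#' the random seed.
#'
#' @param n_trials number of trials in the session.
#' @param interval_s fixed time from trial start to (scheduled) water
#'   delivery, in seconds.
#' @param p_unrewarded marginal probability that water is withheld on a
#'   trial. Must be below 0.5 so that the no-consecutive-omission constraint
#'   can be satisfied without biasing the marginal (see Details).
#' @param intra_bout_ili_range_ms two-element numeric, low and high bound of
#'   the intra-bout interlick interval in milliseconds. The default
#'   \code{c(100, 175)} corresponds to rhythmic licking at 5.7--10 Hz.
#' @param p_bout probability that a trial contains a licking bout.
#' @param p_pre_water_bout probability that a rewarded trial's bout starts
#'   before water delivery (exploratory) rather than after (reactive).
#' @param pre_water_lead_s mean lead of an exploratory bout onset before the
#'   scheduled water time, seconds.
#' @param pre_water_lead_sd_s standard deviation of that lead.
#' @param reactive_latency_s mean latency of a reactive bout onset after
#'   water delivery, seconds.
#' @param reactive_latency_sd_s standard deviation of that latency.
#' @param consummatory_s mean duration of licking after water delivery
#'   before the bout ends, seconds.
#' @param consummatory_sd_s standard deviation of that duration.
#' @param postgiveup_s mean duration of licking past the scheduled water
#'   time on unrewarded trials, seconds.
#' @param bout_len_range two-element integer, minimum and maximum number of
#'   licks per bout.
#' @param consummatory_rate_boost multiplicative lick-rate factor applied
#'   after water delivery; realized intervals are clipped back into
#'   \code{intra_bout_ili_range_ms}.
#' @param seed integer random seed; identical configuration and seed give
#'   byte-identical sessions.
#'
#' @details Water omissions are drawn from a stationary first-order Markov
#' chain in which an omission is never followed by another omission and
#' \eqn{P(\mathrm{omit} \mid \mathrm{rewarded}) = p/(1-p)}. The stationary
#' marginal omission probability is then exactly \code{p_unrewarded}, so the
#' constraint does not bias the realized omission fraction.
#'
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_trials = 100,
                       interval_s = 10,
                       p_unrewarded = 0.20,
                       intra_bout_ili_range_ms = c(100, 175),
                       p_bout = 0.95,
                       p_pre_water_bout = 0.75,
                       pre_water_lead_s = 1.5,
                       pre_water_lead_sd_s = 0.4,
                       reactive_latency_s = 0.36,
                       reactive_latency_sd_s = 0.11,
                       consummatory_s = 1.37,
                       consummatory_sd_s = 0.25,
                       postgiveup_s = 1.0,
                       bout_len_range = c(6, 40),
                       consummatory_rate_boost = 1.25,
                       seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials), interval_s = interval_s,
              p_unrewarded = p_unrewarded,
              intra_bout_ili_range_ms = intra_bout_ili_range_ms,
              p_bout = p_bout, p_pre_water_bout = p_pre_water_bout,
              pre_water_lead_s = pre_water_lead_s,
              pre_water_lead_sd_s = pre_water_lead_sd_s,
              reactive_latency_s = reactive_latency_s,
              reactive_latency_sd_s = reactive_latency_sd_s,
              consummatory_s = consummatory_s,
              consummatory_sd_s = consummatory_sd_s,
              postgiveup_s = postgiveup_s,
              bout_len_range = as.integer(bout_len_range),
              consummatory_rate_boost = consummatory_rate_boost,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$n_trials) || cfg$n_trials < 1L)
    stop("invalid config: n_trials must be a positive integer")
  probs <- c(cfg$p_unrewarded, cfg$p_bout, cfg$p_pre_water_bout)
  if (any(probs < 0 | probs > 1))
    stop("invalid config: probabilities must lie in [0, 1]")
  if (cfg$p_unrewarded >= 0.5)
    stop("invalid config: p_unrewarded must be < 0.5 for the ",
         "no-consecutive-omission structure to be unbiased")
  ili <- cfg$intra_bout_ili_range_ms
  if (length(ili) != 2L || ili[1] > ili[2])
    stop("invalid config: intra_bout_ili_range_ms must be [low, high] ",
         "with low <= high")
  if (ili[1] <= 0 || ili[2] / 1000 >= cfg$interval_s)
    stop("invalid config: ILI range must lie within (0, interval)")
  if (cfg$bout_len_range[1] < 2L || cfg$bout_len_range[1] > cfg$bout_len_range[2])
    stop("invalid config: bout_len_range must be [min, max] with min >= 2")
  invisible(cfg)
}

# Evaluate expr with a local, restorable RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate the trial table of a synthetic session
#'
#' Trials are laid out back-to-back, each spanning one inter-reward interval;
#' water (when not withheld) is delivered at the end of the interval. The
#' rewarded/unrewarded flags follow a stationary Markov chain that forbids
#' two consecutive omissions while keeping the marginal omission probability
#' at exactly \code{p_unrewarded}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns \code{trial_id}, \code{start_s},
#'   \code{water_s} (\code{NA} on unrewarded trials), \code{rewarded},
#'   \code{opto_on_s}, \code{opto_off_s} (\code{NA} until
#'   \code{\link{generate_opto}} annotates them).
#' @export
generate_trials <- function(config) {
  validate_sim_config(config)
  n <- config$n_trials
  p <- config$p_unrewarded
  q <- if (p > 0) p / (1 - p) else 0   # P(omit | previous rewarded)
  unrew <- with_seed(config$seed, {
    u <- runif(n)
    flags <- logical(n)
    flags[1] <- u[1] < p                 # stationary initial draw
    if (n > 1L) for (i in 2:n) {
      flags[i] <- if (flags[i - 1L]) FALSE else u[i] < q
    }
    flags
  })
  start <- (seq_len(n) - 1) * config$interval_s
  water <- ifelse(unrew, NA_real_, start + config$interval_s)
  data.frame(trial_id = seq_len(n), start_s = start, water_s = water,
             rewarded = !unrew, opto_on_s = NA_real_, opto_off_s = NA_real_)
}

# Draw one run of licks from `from`, ILIs uniform in ili_s (optionally
# rate-boosted, clipped back into range), stopping at the first lick at or
# past `until` or at len_max licks, whichever comes first.
lick_run <- function(from, until, ili_s, boost = 1, len_max = Inf) {
  times <- from
  repeat {
    if (length(times) >= len_max) break
    if (times[length(times)] >= until) break
    ili <- runif(1, ili_s[1], ili_s[2]) / boost
    ili <- min(max(ili, ili_s[1]), ili_s[2])
    times <- c(times, times[length(times)] + ili)
  }
  times
}

#' Generate licks and ground-truth bouts for a trial table
#'
#' Each trial holds at most one licking bout. Exploratory bouts start ahead
#' of the scheduled water time (Gaussian lead), reactive bouts start shortly
#' after water delivery; on rewarded trials licking continues through a
#' consummatory segment at a boosted rate before terminating, on unrewarded
#' trials the animal gives up shortly after the scheduled time passes.
#' Interlick intervals are drawn uniformly within the configured range, so
#' instantaneous lick rates stay inside the rhythmic band.
#'
#' @param trials trial table from \code{\link{generate_trials}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with \code{licks} (data.frame \code{trial_id},
#'   \code{time_s}) and \code{bouts}, the ground-truth bout table
#'   (\code{trial_id}, \code{first_lick_s}, \code{last_lick_s},
#'   \code{n_licks}, \code{context} in \code{pre_water}/\code{post_water}).
#' @export
generate_licks <- function(trials, config) {
  validate_sim_config(config)
  ili_s <- config$intra_bout_ili_range_ms / 1000
  len <- config$bout_len_range
  with_seed(config$seed + 1000L, {
    lick_list <- vector("list", nrow(trials))
    bout_rows <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      if (runif(1) > config$p_bout) next
      sched <- trials$start_s[i] + config$interval_s  # scheduled water time
      rewarded <- trials$rewarded[i]
      pre <- !rewarded || runif(1) < config$p_pre_water_bout
      if (pre) {
        lead <- max(rnorm(1, config$pre_water_lead_s,
                          config$pre_water_lead_sd_s), 0.2)
        onset <- sched - lead
        if (rewarded) {
          pre_licks <- lick_run(onset, sched, ili_s)
          stop_at <- sched + max(rnorm(1, config$consummatory_s,
                                       config$consummatory_sd_s), 0.2)
          gap <- runif(1, ili_s[1], ili_s[2]) /
            config$consummatory_rate_boost
          gap <- min(max(gap, ili_s[1]), ili_s[2])
          post <- lick_run(pre_licks[length(pre_licks)] + gap,
                           stop_at, ili_s,
                           boost = config$consummatory_rate_boost,
                           len_max = len[2] - length(pre_licks))
          licks <- c(pre_licks, post)
        } else {
          stop_at <- sched + max(rnorm(1, config$postgiveup_s, 0.3), 0)
          licks <- lick_run(onset, stop_at, ili_s, len_max = len[2])
        }
      } else {
        onset <- sched + max(rnorm(1, config$reactive_latency_s,
                                   config$reactive_latency_sd_s), 0.05)
        stop_at <- sched + max(rnorm(1, config$consummatory_s,
                                     config$consummatory_sd_s), 0.3)
        licks <- lick_run(onset, stop_at, ili_s,
                          boost = config$consummatory_rate_boost,
                          len_max = len[2])
      }
      while (length(licks) < len[1])   # enforce the minimum bout length
        licks <- c(licks, licks[length(licks)] + runif(1, ili_s[1], ili_s[2]))
      licks <- licks[seq_len(min(length(licks), len[2]))]
      lick_list[[i]] <- data.frame(trial_id = trials$trial_id[i],
                                   time_s = licks)
      bout_rows[[i]] <- data.frame(
        trial_id = trials$trial_id[i],
        first_lick_s = licks[1], last_lick_s = licks[length(licks)],
        n_licks = length(licks),
        context = if (licks[1] < sched) "pre_water" else "post_water")
    }
    licks <- do.call(rbind, lick_list)
    bouts <- do.call(rbind, bout_rows)
    if (is.null(licks))
      licks <- data.frame(trial_id = integer(), time_s = numeric())
    if (is.null(bouts))
      bouts <- data.frame(trial_id = integer(), first_lick_s = numeric(),
                          last_lick_s = numeric(), n_licks = integer(),
                          context = character())
    list(licks = licks, bouts = bouts)
  })
}

#' Specify a simulated unit
#'
#' Generative parameters of one unit's firing: baseline rate, sinusoidal
#' lick-phase tuning during rhythmic licking, signed linear intensity ramps
#' ending at the first and last licks of each bout, and an additive response
#' in the second following water delivery. The realized intensity is clipped
#' at zero.
#'
#' @param unit_id identifier.
#' @param cell_class one of \code{"PC_unambiguous"}, \code{"PC_putative"},
#'   \code{"MLI"}, \code{"other"}.
#' @param baseline_rate_hz baseline firing rate, Hz (> 0).
#' @param phase_depth_hz amplitude of the cosine lick-phase modulation, Hz
#'   (>= 0); active only between consecutive licks closer than 200 ms.
#' @param preferred_phase radians in [0, 2*pi); tongue contact is phase 0.
#' @param init_ramp c(onset_s, amplitude_hz): a linear intensity change
#'   starting \code{onset_s} seconds before each bout's first lick, reaching
#'   the signed \code{amplitude_hz} at the lick. Without a bout response the
#'   intensity steps back toward baseline at the lick; with one it blends
#'   into the bout envelope.
#' @param init_ramp_post optional c(onset_s, amplitude_hz) used for bouts
#'   initiated after water delivery; defaults to \code{init_ramp}. Use
#'   \code{c(0, 0)} for a unit that ramps only before exploratory bouts.
#' @param term_ramp same form, relative to each bout's last lick.
#' @param bout_peak_hz peak of the bout-response envelope, Hz. Firing that
#'   tracks the lick rate keeps rising after the first lick; the envelope is
#'   piecewise linear from the initiation-ramp amplitude at the first lick
#'   to \code{bout_peak_hz} at \code{bout_peak_t_s}, then falls back to
#'   baseline over \code{bout_decay_s}. Zero disables it.
#' @param bout_peak_t_s time of the envelope peak after the first lick.
#' @param bout_decay_s decay time of the envelope after its peak.
#' @param water_response_hz additive rate for 1 s after water delivery.
#' @return an object of class \code{unit_spec}.
#' @export
unit_spec <- function(unit_id, cell_class = "PC_putative",
                      baseline_rate_hz = 60,
                      phase_depth_hz = 0, preferred_phase = 0,
                      init_ramp = c(0, 0), init_ramp_post = init_ramp,
                      term_ramp = c(0, 0),
                      bout_peak_hz = 0, bout_peak_t_s = 0.3,
                      bout_decay_s = 1.0,
                      water_response_hz = 0) {
  stopifnot(baseline_rate_hz > 0, phase_depth_hz >= 0,
            init_ramp[1] >= 0, init_ramp_post[1] >= 0, term_ramp[1] >= 0,
            bout_peak_hz >= 0, bout_peak_t_s > 0, bout_decay_s > 0,
            cell_class %in% c("PC_unambiguous", "PC_putative", "MLI", "other"))
  structure(list(unit_id = unit_id, cell_class = cell_class,
                 baseline_rate_hz = baseline_rate_hz,
                 phase_depth_hz = phase_depth_hz,
                 preferred_phase = preferred_phase %% (2 * pi),
                 init_ramp = init_ramp, init_ramp_post = init_ramp_post,
                 term_ramp = term_ramp,
                 bout_peak_hz = bout_peak_hz,
                 bout_peak_t_s = bout_peak_t_s,
                 bout_decay_s = bout_decay_s,
                 water_response_hz = water_response_hz),
            class = "unit_spec")
}

# Lick phase by linear interpolation between consecutive licks; NA outside
# lick cycles or when the bracketing interval exceeds max_ili_s.
lick_phase_at <- function(times, licks, max_ili_s = 0.2) {
  if (length(licks) < 2L) return(rep(NA_real_, length(times)))
  idx <- findInterval(times, licks)
  phase <- rep(NA_real_, length(times))
  ok <- idx >= 1L & idx < length(licks)
  if (any(ok)) {
    lo <- licks[idx[ok]]
    hi <- licks[idx[ok] + 1L]
    gap <- hi - lo
    ph <- 2 * pi * (times[ok] - lo) / gap
    ph[gap > max_ili_s] <- NA_real_
    phase[ok] <- ph
  }
  phase
}

# Evaluate a unit's generative intensity at sorted times.
unit_intensity <- function(times, unit, licks, bouts, water_times,
                           water_window_s = 1) {
  lambda <- rep(unit$baseline_rate_hz, length(times))
  if (unit$phase_depth_hz > 0) {
    ph <- lick_phase_at(times, licks)
    mod <- unit$phase_depth_hz * cos(ph - unit$preferred_phase)
    mod[is.na(mod)] <- 0
    lambda <- lambda + mod
  }
  # index range of `times` (sorted) within [lo, hi)
  slice <- function(lo, hi) {
    j1 <- findInterval(lo, times) + 1L
    if (j1 > 1L && times[j1 - 1L] == lo) j1 <- j1 - 1L
    j2 <- findInterval(hi, times)
    if (j2 >= 1L && times[j2] == hi) j2 <- j2 - 1L
    if (j2 < j1) integer() else seq.int(j1, j2)
  }
  add_ramp <- function(lambda, events, onset, amp) {
    if (onset <= 0 || amp == 0 || length(events) == 0L) return(lambda)
    for (ev in events) {
      j <- slice(ev - onset, ev)
      lambda[j] <- lambda[j] + amp * (times[j] - (ev - onset)) / onset
    }
    lambda
  }
  pre <- !is.null(bouts$context) & bouts$context == "pre_water"
  lambda <- add_ramp(lambda, bouts$first_lick_s[pre],
                     unit$init_ramp[1], unit$init_ramp[2])
  lambda <- add_ramp(lambda, bouts$first_lick_s[!pre],
                     unit$init_ramp_post[1], unit$init_ramp_post[2])
  if (unit$bout_peak_hz > 0) {
    for (k in seq_len(nrow(bouts))) {
      f <- bouts$first_lick_s[k]
      amp0 <- if (pre[k]) unit$init_ramp[2] else unit$init_ramp_post[2]
      amp0 <- max(amp0, 0)
      j <- slice(f, f + unit$bout_peak_t_s)
      lambda[j] <- lambda[j] + amp0 +
        (unit$bout_peak_hz - amp0) * (times[j] - f) / unit$bout_peak_t_s
      j <- slice(f + unit$bout_peak_t_s,
                 f + unit$bout_peak_t_s + unit$bout_decay_s)
      lambda[j] <- lambda[j] + unit$bout_peak_hz *
        (1 - (times[j] - f - unit$bout_peak_t_s) / unit$bout_decay_s)
    }
  }
  lambda <- add_ramp(lambda, bouts$last_lick_s,
                     unit$term_ramp[1], unit$term_ramp[2])
  if (unit$water_response_hz != 0 && length(water_times) > 0L) {
    for (w in water_times[!is.na(water_times)]) {
      j <- slice(w, w + water_window_s)
      lambda[j] <- lambda[j] + unit$water_response_hz
    }
  }
  pmax(lambda, 0)
}

#' Sample a spike train from a unit specification
#'
#' Draws an inhomogeneous Poisson process by thinning: candidate events are
#' sampled homogeneously at the intensity's documented upper bound
#' (baseline + tuning depth + positive ramp amplitudes + water response) and
#' retained with probability intensity/bound.
#'
#' @param unit a \code{\link{unit_spec}}.
#' @param session a simulated session (or any list with \code{trials},
#'   \code{licks} and ground-truth \code{bouts}).
#' @param seed integer seed for this unit's draw.
#' @return numeric vector of spike times, strictly increasing.
#' @export
generate_spike_train <- function(unit, session, seed) {
  trials <- session$trials
  licks <- session$licks$time_s
  bouts <- session$ground_truth$bouts
  t_end <- max(trials$start_s) + session$config$interval_s + 5
  lmax <- unit$baseline_rate_hz + unit$phase_depth_hz +
    max(unit$init_ramp[2], unit$init_ramp_post[2], unit$bout_peak_hz, 0) +
    max(unit$term_ramp[2], 0) +
    max(unit$water_response_hz, 0) + 1e-9
  with_seed(seed, {
    n_cand <- rpois(1, lmax * t_end)
    if (n_cand == 0L) return(numeric())
    cand <- sort(runif(n_cand, 0, t_end))
    lam <- unit_intensity(cand, unit, licks, bouts, trials$water_s)
    keep <- runif(n_cand) < lam / lmax
    spikes <- cand[keep]
    spikes[!duplicated(spikes)]
  })
}

#' Generate per-channel spike-peak amplitude profiles
#'
#' Emulates the spatial footprint of each unit on a multichannel probe:
#' Purkinje cells, being large, register mean spike peaks above the noise
#' floor on many channels (at least 7), while molecular layer interneurons
#' and other small cells appear on at most 3. Above-floor amplitudes are
#' drawn with a margin of at least twice the floor so that footprint
#' classification is unambiguous.
#'
#' @param units list of \code{\link{unit_spec}} objects.
#' @param n_channels number of probe channels per unit profile.
#' @param noise_floor_uv the noise floor, microvolts.
#' @param seed integer seed.
#' @return data.frame \code{unit_id}, \code{channel}, \code{peak_uv},
#'   \code{has_cs} (complex spikes observed; true only for unambiguous PCs).
#' @export
generate_channel_profiles <- function(units, n_channels = 16,
                                      noise_floor_uv = 30, seed = 1L) {
  with_seed(seed, {
    rows <- lapply(units, function(u) {
      is_pc <- u$cell_class %in% c("PC_unambiguous", "PC_putative")
      n_above <- if (is_pc) sample(7:min(12, n_channels), 1) else sample(1:3, 1)
      peaks <- runif(n_channels, 2, noise_floor_uv * 0.6)
      hot <- sample.int(n_channels, n_above)
      peaks[hot] <- runif(n_above, noise_floor_uv * 2, noise_floor_uv * 4)
      data.frame(unit_id = u$unit_id, channel = seq_len(n_channels),
                 peak_uv = peaks,
                 has_cs = u$cell_class == "PC_unambiguous")
    })
    do.call(rbind, rows)
  })
}

#' Specify simulated Purkinje-cell dendrites for calcium-event generation
#'
#' @param n number of dendrites.
#' @param region_id region label shared by the group.
#' @param responsive logical, recycled: whether each dendrite adds a
#'   peri-initiation transient.
#' @param baseline_hz baseline climbing-fiber event rate, recycled; the
#'   physiological range is 1--2 Hz.
#' @param onset_s true ramp onset, seconds before the first lick.
#' @param boost_hz added event rate from the onset until 0.5 s after the
#'   first lick.
#' @param water_boost_hz added event rate in the 0.5 s around water delivery
#'   (drives region responsiveness).
#' @return data.frame of dendrite specifications.
#' @export
dendrite_specs <- function(n, region_id = 1L, responsive = TRUE,
                           baseline_hz = 1.5, onset_s = 0.1, boost_hz = 4.5,
                           water_boost_hz = boost_hz) {
  data.frame(dendrite_id = seq_len(n), region_id = region_id,
             responsive = rep_len(responsive, n),
             baseline_hz = rep_len(baseline_hz, n),
             onset_s = rep_len(onset_s, n),
             boost_hz = rep_len(boost_hz, n),
             water_boost_hz = rep_len(water_boost_hz, n))
}

#' Sample dendritic calcium-event trains
#'
#' Poisson events at each dendrite's baseline rate; responsive dendrites add
#' a rate transient from their true onset before each bout's first lick
#' until 0.5 s after it, and around water delivery on rewarded trials.
#'
#' @param session simulated session containing ground-truth bouts.
#' @param specs data.frame from \code{\link{dendrite_specs}}.
#' @param seed integer seed.
#' @return data.frame \code{dendrite_id}, \code{region_id}, \code{time_s}.
#' @export
generate_calcium <- function(session, specs, seed = 1L) {
  bouts <- session$ground_truth$bouts
  water <- session$trials$water_s
  water <- water[!is.na(water)]
  t_end <- max(session$trials$start_s) + session$config$interval_s + 5
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      s <- specs[i, ]
      lmax <- s$baseline_hz +
        if (s$responsive) max(s$boost_hz, s$water_boost_hz) else 0
      n_cand <- rpois(1, lmax * t_end)
      if (n_cand == 0L) return(NULL)
      cand <- sort(runif(n_cand, 0, t_end))
      lam <- rep(s$baseline_hz, n_cand)
      if (s$responsive) {
        for (f in bouts$first_lick_s) {
          sel <- cand >= f - s$onset_s & cand < f + 0.5
          lam[sel] <- lam[sel] + s$boost_hz
        }
        for (w in water) {
          sel <- cand >= w - 0.25 & cand < w + 0.25
          lam[sel] <- pmax(lam[sel], s$baseline_hz + s$water_boost_hz)
        }
      }
      keep <- runif(n_cand) < lam / lmax
      if (!any(keep)) return(NULL)
      data.frame(dendrite_id = s$dendrite_id, region_id = s$region_id,
                 time_s = cand[keep])
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(dendrite_id = integer(), region_id = integer(),
                        time_s = numeric())
    out
  })
}

#' Apply an optogenetic perturbation to a subset of trials
#'
#' On each stimulated trial, licks inside the stimulus window are retained
#' with probability \code{suppression} (1 leaves licking untouched, 0
#' silences the window completely) and, when thinning occurs, surviving
#' in-window licks are jittered to degrade rhythmicity. After the stimulus
#' ends, a rebound bout is inserted with probability \code{rebound_prob}.
#'
#' @param session a simulated session.
#' @param window_rel_s c(on, off) of the stimulus relative to trial start,
#'   seconds; must lie inside the trial interval.
#' @param stim_frac fraction of eligible trials stimulated.
#' @param only_unrewarded restrict stimulation to water-omission trials.
#' @param suppression multiplicative lick-retention factor in [0, 1].
#' @param rebound_prob probability of a rebound bout after stimulus offset.
#' @param rebound_delay_s mean delay from offset to the rebound bout onset.
#' @param jitter_sd_s standard deviation of the timing jitter applied to
#'   surviving in-window licks when \code{suppression < 1}.
#' @param seed integer seed.
#' @return the session with trials annotated (\code{opto_on_s},
#'   \code{opto_off_s}), licks modified, and ground truth extended with
#'   \code{opto} (stimulated trial ids and true rebound flags).
#' @export
generate_opto <- function(session, window_rel_s = c(6.5, 9.5),
                          stim_frac = 0.5, only_unrewarded = TRUE,
                          suppression = 0, rebound_prob = 0.5,
                          rebound_delay_s = 0.25, jitter_sd_s = 0.02,
                          seed = 1L) {
  cfg <- session$config
  if (window_rel_s[1] < 0 || window_rel_s[2] > cfg$interval_s ||
      window_rel_s[1] >= window_rel_s[2])
    stop("invalid config: stimulus window must lie inside the trial")
  if (suppression < 0 || suppression > 1)
    stop("invalid config: suppression must be in [0, 1]")
  trials <- session$trials
  eligible <- if (only_unrewarded) which(!trials$rewarded)
              else seq_len(nrow(trials))
  ili_s <- cfg$intra_bout_ili_range_ms / 1000
  with_seed(seed, {
    stim <- sort(sample(eligible, round(stim_frac * length(eligible))))
    trials$opto_on_s[stim] <- trials$start_s[stim] + window_rel_s[1]
    trials$opto_off_s[stim] <- trials$start_s[stim] + window_rel_s[2]
    licks <- session$licks
    rebound <- logical(length(stim))
    new_licks <- list()
    for (k in seq_along(stim)) {
      i <- stim[k]
      on <- trials$opto_on_s[i]; off <- trials$opto_off_s[i]
      in_win <- licks$trial_id == trials$trial_id[i] &
        licks$time_s >= on & licks$time_s < off
      if (any(in_win)) {
        keep <- runif(sum(in_win)) < suppression
        drop_idx <- which(in_win)[!keep]
        if (suppression < 1 && any(keep)) {
          jit_idx <- which(in_win)[keep]
          licks$time_s[jit_idx] <- licks$time_s[jit_idx] +
            rnorm(length(jit_idx), 0, jitter_sd_s)
        }
        if (length(drop_idx)) licks <- licks[-drop_idx, ]
      }
      if (runif(1) < rebound_prob) {
        rebound[k] <- TRUE
        onset <- off + max(rnorm(1, rebound_delay_s, 0.08), 0.05)
        rb <- lick_run(onset, onset + 1.2, ili_s, len_max = 15)
        new_licks[[length(new_licks) + 1L]] <-
          data.frame(trial_id = trials$trial_id[i], time_s = rb)
      }
    }
    if (length(new_licks))
      licks <- rbind(licks, do.call(rbind, new_licks))
    licks <- licks[order(licks$time_s), ]
    rownames(licks) <- NULL
    session$trials <- trials
    session$licks <- licks
    session$ground_truth$opto <- list(
      stim_trials = trials$trial_id[stim],
      rebound = data.frame(trial_id = trials$trial_id[stim],
                           rebound = rebound),
      window_rel_s = window_rel_s, suppression = suppression,
      rebound_prob = rebound_prob)
    session
  })
}

#' Build a roster of simulated units
#'
#' Convenience generator drawing heterogeneous unit specifications: counts
#' per cell class, baseline rates uniform in \code{baseline_range_hz},
#' phase-tuning depths and preferred phases, and signed initiation /
#' termination ramps for Purkinje cells.
#'
#' @param n_pc_cs,n_pc_putative,n_mli,n_other counts per class.
#' @param baseline_range_hz range of baseline rates, Hz.
#' @param phase_depth_frac tuning depth as a fraction of baseline.
#' @param init_onset_s,init_amp_hz,term_onset_s,term_amp_hz ramp parameters
#'   applied to PCs (recycled across PC units; amplitudes may be signed).
#' @param bout_peak_hz peak of the PC bout-response envelope, Hz.
#' @param water_response_hz additive post-water rate for PCs.
#' @param seed integer seed.
#' @return list of \code{\link{unit_spec}} objects.
#' @export
unit_roster <- function(n_pc_cs = 4, n_pc_putative = 8, n_mli = 3,
                        n_other = 2, baseline_range_hz = c(40, 80),
                        phase_depth_frac = 0.3,
                        init_onset_s = 0.3, init_amp_hz = 10,
                        term_onset_s = 0.3, term_amp_hz = 8,
                        bout_peak_hz = 20,
                        water_response_hz = 5, seed = 1L) {
  classes <- rep(c("PC_unambiguous", "PC_putative", "MLI", "other"),
                 c(n_pc_cs, n_pc_putative, n_mli, n_other))
  n <- length(classes)
  init_onset <- rep_len(init_onset_s, n); init_amp <- rep_len(init_amp_hz, n)
  term_onset <- rep_len(term_onset_s, n); term_amp <- rep_len(term_amp_hz, n)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      base <- runif(1, baseline_range_hz[1], baseline_range_hz[2])
      is_pc <- classes[i] %in% c("PC_unambiguous", "PC_putative")
      unit_spec(unit_id = i, cell_class = classes[i],
                baseline_rate_hz = base,
                phase_depth_hz = if (is_pc) phase_depth_frac * base else 0,
                preferred_phase = runif(1, 0, 2 * pi),
                init_ramp = if (is_pc) c(init_onset[i], init_amp[i])
                  else c(0, 0),
                term_ramp = if (is_pc) c(term_onset[i], term_amp[i])
                  else c(0, 0),
                bout_peak_hz = if (is_pc) bout_peak_hz else 0,
                water_response_hz = if (is_pc) water_response_hz else 0)
    })
  })
}

#' Simulate a complete session with ground truth
#'
#' Runs the full generator: trials, licks and bouts, one spike train per
#' unit, channel-footprint profiles, optional calcium-event trains, and an
#' optional optogenetic perturbation, all reproducible from the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param units list of \code{\link{unit_spec}}; default a small mixed
#'   roster from \code{\link{unit_roster}}.
#' @param dendrites optional data.frame from \code{\link{dendrite_specs}}.
#' @param opto optional list of arguments passed to
#'   \code{\link{generate_opto}}.
#' @return an object of class \code{lick_session}: list with \code{trials},
#'   \code{licks}, \code{spikes}, \code{channels}, \code{calcium},
#'   \code{ground_truth} (unit specs, bout table, dendrite specs, opto
#'   record) and \code{config}.
#' @export
simulate_session <- function(config = sim_config(), units = NULL,
                             dendrites = NULL, opto = NULL) {
  validate_sim_config(config)
  if (is.null(units)) units <- unit_roster(seed = config$seed + 7L)
  trials <- generate_trials(config)
  lk <- generate_licks(trials, config)
  session <- structure(
    list(trials = trials, licks = lk$licks, spikes = NULL, channels = NULL,
         calcium = NULL,
         ground_truth = list(units = units, bouts = lk$bouts,
                             dendrites = dendrites),
         config = config),
    class = "lick_session")
  spk <- lapply(seq_along(units), function(i) {
    st <- generate_spike_train(units[[i]], session, config$seed + 2000L + i)
    if (length(st) == 0L) return(NULL)
    data.frame(unit_id = units[[i]]$unit_id, time_s = st)
  })
  spk <- do.call(rbind, spk)
  if (is.null(spk)) spk <- data.frame(unit_id = integer(), time_s = numeric())
  session$spikes <- spk
  session$channels <- generate_channel_profiles(units,
                                                seed = config$seed + 5000L)
  if (!is.null(dendrites))
    session$calcium <- generate_calcium(session, dendrites,
                                        seed = config$seed + 6000L)
  else
    session$calcium <- data.frame(dendrite_id = integer(),
                                  region_id = integer(), time_s = numeric())
  if (!is.null(opto))
    session <- do.call(generate_opto,
                       c(list(session = session), opto,
                         list(seed = config$seed + 8000L)))
  session
}

#' @export
print.lick_session <- function(x, ...) {
  cat("Synthetic licking session:", nrow(x$trials), "trials,",
      nrow(x$licks), "licks,", length(unique(x$spikes$unit_id)), "units,",
      nrow(x$calcium), "calcium events\n")
  invisible(x)
}
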