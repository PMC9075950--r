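# Merge a set of [lo, hi] intervals and return their complement within span.
complement_intervals <- function(lo, hi, span) {
  if (length(lo) == 0L) return(cbind(lo = span[1], hi = span[2]))
  o <- order(lo)
  lo <- pmax(lo[o], span[1]); hi <- pmin(hi[o], span[2])
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0L) return(cbind(lo = span[1], hi = span[2]))
  m_lo <- lo[1]; m_hi <- hi[1]
  out_lo <- numeric(); out_hi <- numeric()
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= m_hi) m_hi <- max(m_hi, hi[i])
    else { out_lo <- c(out_lo, m_lo); out_hi <- c(out_hi, m_hi)
           m_lo <- lo[i]; m_hi <- hi[i] }
  }
  out_lo <- c(out_lo, m_lo); out_hi <- c(out_hi, m_hi)
  comp_lo <- c(span[1], out_hi)
  comp_hi <- c(out_lo, span[2])
  keep <- comp_hi > comp_lo
  cbind(lo = comp_lo[keep], hi = comp_hi[keep])
}

#' Baseline firing rate over nonlicking periods
#'
#' The unit's average rate restricted to times at least \code{exclusion_s}
#' away from every lick; with no licks at all this is the whole-session
#' rate.
#'
#' @param spike_times sorted spike times, seconds.
#' @param licks sorted lick times, seconds.
#' @param exclusion_s radius around each lick excluded from the baseline.
#' @param t_range c(start, end) of the recording; defaults to the span of
#'   the supplied events.
#' @param min_nonlicking_s minimum total nonlicking time required.
#' @return baseline rate, Hz.
#' @export
baseline_rate <- function(spike_times, licks, exclusion_s = 2.0,
                          t_range = NULL, min_nonlicking_s = 10) {
  if (is.null(t_range))
    t_range <- range(c(spike_times, licks, 0))
  if (length(licks) == 0L)
    return(length(spike_times) / diff(t_range))
  free <- complement_intervals(licks - exclusion_s, licks + exclusion_s,
                               t_range)
  total <- sum(free[, "hi"] - free[, "lo"])
  if (total <= min_nonlicking_s)
    stop(sprintf(paste0("insufficient nonlicking time: %.1f s available, ",
                        "%.1f s required"), total, min_nonlicking_s))
  n <- sum(vapply(seq_len(nrow(free)), function(i)
    sum(spike_times >= free[i, "lo"] & spike_times < free[i, "hi"]),
    numeric(1)))
  n / total
}

#' Event-aligned change in firing rate
#'
#' Bins spikes around each alignment event, converts to rates, averages
#' across events and subtracts the baseline.
#'
#' @param spike_times sorted spike times, seconds.
#' @param events event times (e.g. bout first licks), seconds.
#' @param window c(lo, hi) seconds around the event, half-open bins.
#' @param bin bin width, seconds (default 100 ms).
#' @param baseline baseline rate subtracted from the aligned rate, Hz.
#' @return object of class \code{aligned_response}: list with
#'   \code{bin_edges}, \code{time_s} (bin centers), \code{delta_rate_hz},
#'   \code{sem_hz}, \code{baseline_rate_hz}, \code{n_events}; zero-event
#'   input yields \code{n_events = 0} and a \code{reason}.
#' @export
aligned_delta_rate <- function(spike_times, events, window = c(-1, 0.5),
                               bin = 0.1, baseline = 0) {
  edges <- seq(window[1], window[2], by = bin)
  if (abs(edges[length(edges)] - window[2]) > 1e-9)
    stop("window is not a whole number of bins")
  centers <- edges[-length(edges)] + bin / 2
  events <- events[!is.na(events)]
  if (length(events) == 0L)
    return(structure(list(bin_edges = edges, time_s = centers,
                          delta_rate_hz = rep(NA_real_, length(centers)),
                          sem_hz = rep(NA_real_, length(centers)),
                          baseline_rate_hz = baseline, n_events = 0L,
                          reason = "no alignment events"),
                     class = "aligned_response"))
  mat <- vapply(events, function(ev) {
    bin_counts(spike_times - ev, edges) / bin
  }, numeric(length(centers)))
  mat <- matrix(mat, nrow = length(centers))
  structure(list(bin_edges = edges, time_s = centers,
                 delta_rate_hz = rowMeans(mat) - baseline,
                 sem_hz = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
                 baseline_rate_hz = baseline, n_events = length(events)),
            class = "aligned_response")
}

# Earliest run of `runlen` consecutive strict changes of the given sign in
# x; returns the index of the first changed bin, or NA.
first_monotone_run <- function(x, sign = 1, runlen = 3L) {
  d <- diff(x) * sign
  good <- d > 0
  if (length(good) < runlen) return(NA_integer_)
  for (i in seq_len(length(good) - runlen + 1L)) {
    if (all(good[i:(i + runlen - 1L)])) return(i + 1L)
  }
  NA_integer_
}

#' Classify firing-rate modulation at bout initiation
#'
#' A unit is positively modulated around the first lick when its aligned
#' rate shows three consecutive strict increases across 100-ms bins within
#' the window running 1 s before to 0.5 s after the first lick; the ramp
#' onset is the left edge of the first incremented bin of the earliest such
#' run. Negative modulation applies the mirrored rule to decreases. When
#' both patterns occur the one with the earlier onset wins (ties go to
#' positive).
#'
#' @param response \code{aligned_response} over the [-1, 0.5] s window in
#'   100-ms bins (15 bins).
#' @param runlen number of consecutive strict changes required.
#' @return data.frame row: \code{modulation} in
#'   \code{positive}/\code{negative}/\code{none}, \code{onset_s} (NA when
#'   none).
#' @export
classify_first_lick_modulation <- function(response, runlen = 3L) {
  x <- response$delta_rate_hz
  edges <- response$bin_edges
  if (length(x) != 15L || abs(edges[1] + 1) > 1e-9 ||
      abs(edges[length(edges)] - 0.5) > 1e-9)
    stop("response must cover [-1, 0.5] s in 100-ms bins")
  if (anyNA(x))
    return(data.frame(modulation = "none", onset_s = NA_real_))
  i_pos <- first_monotone_run(x, 1, runlen)
  i_neg <- first_monotone_run(x, -1, runlen)
  onset <- function(i) edges[i]
  if (is.na(i_pos) && is.na(i_neg))
    return(data.frame(modulation = "none", onset_s = NA_real_))
  if (!is.na(i_pos) && (is.na(i_neg) || i_pos <= i_neg))
    data.frame(modulation = "positive", onset_s = onset(i_pos))
  else
    data.frame(modulation = "negative", onset_s = onset(i_neg))
}

#' Classify firing-rate modulation at bout termination
#'
#' Compares the mean rate in the 300 ms preceding the last lick against the
#' distribution of 100-ms-bin rates in an alternative baseline window 1--5 s
#' before the last lick: above \code{threshold_sd} standard deviations of
#' the baseline bins is positive modulation, below is negative.
#'
#' @param spike_times sorted spike times, seconds.
#' @param last_lick_times bout last licks used as alignment events.
#' @param window_pre_s length of the pre-last-lick test window, seconds.
#' @param alt_baseline_s c(lo, hi) of the baseline window relative to the
#'   last lick (negative, seconds).
#' @param bin bin width, seconds.
#' @param threshold_sd classification threshold in baseline SDs.
#' @return data.frame row: \code{modulation}, \code{onset_s} (first
#'   suprathreshold bin in the test window, NA when none),
#'   \code{delta_rate_hz} (test-window mean minus baseline mean).
#' @export
classify_termination_modulation <- function(spike_times, last_lick_times,
                                            window_pre_s = 0.3,
                                            alt_baseline_s = c(-5, -1),
                                            bin = 0.1, threshold_sd = 2) {
  resp <- aligned_delta_rate(spike_times, last_lick_times,
                             window = c(alt_baseline_s[1], 0), bin = bin,
                             baseline = 0)
  if (resp$n_events == 0L)
    return(data.frame(modulation = "none", onset_s = NA_real_,
                      delta_rate_hz = NA_real_))
  base_sel <- resp$time_s >= alt_baseline_s[1] &
    resp$time_s < alt_baseline_s[2]
  test_sel <- resp$time_s >= -window_pre_s & resp$time_s < 0
  m <- mean(resp$delta_rate_hz[base_sel])
  s <- stats::sd(resp$delta_rate_hz[base_sel])
  test_mean <- mean(resp$delta_rate_hz[test_sel])
  delta <- test_mean - m
  mod <- if (test_mean > m + threshold_sd * s) "positive"
         else if (test_mean < m - threshold_sd * s) "negative"
         else "none"
  onset <- NA_real_
  if (mod != "none") {
    cross <- if (mod == "positive")
      resp$delta_rate_hz > m + threshold_sd * s
    else resp$delta_rate_hz < m - threshold_sd * s
    hit <- which(test_sel & cross)
    if (length(hit)) onset <- resp$bin_edges[hit[1]]
    else onset <- -window_pre_s
  }
  data.frame(modulation = mod, onset_s = onset, delta_rate_hz = delta)
}

#' Split bout events by behavioral context
#'
#' @param bouts bout table with \code{context}, \code{first_lick_s},
#'   \code{last_lick_s}, and optionally \code{isolated}.
#' @param isolated_only restrict to well-separated bouts.
#' @return list with elements \code{pre_water} and \code{post_water}, each
#'   a list of \code{first_licks} and \code{last_licks} event vectors (an
#'   element is marked \code{available = FALSE} when its context has no
#'   bouts).
#' @export
split_by_context <- function(bouts, isolated_only = FALSE) {
  if (isolated_only && "isolated" %in% names(bouts))
    bouts <- bouts[bouts$isolated, ]
  out <- lapply(c(pre_water = "pre_water", post_water = "post_water"),
                function(ctx) {
    b <- bouts[!is.na(bouts$context) & bouts$context == ctx, ]
    list(first_licks = b$first_lick_s, last_licks = b$last_lick_s,
         n = nrow(b), available = nrow(b) > 0L)
  })
  out
}

#' Per-context modulation profile of one unit
#'
#' Classifies initiation ramps separately for bouts started before and
#' after water delivery, classifies termination modulation over all bouts,
#' and assigns a tuning category. Units whose firing decreases during any
#' motor transition are pooled into a single \code{negative} category;
#' otherwise the category lists the transitions with positive ramps
#' (e.g. \code{"pre_init+term"}) or \code{"untuned"}.
#'
#' @param spike_times sorted spike times, seconds.
#' @param bouts labelled bout table.
#' @param baseline nonlicking baseline rate, Hz.
#' @param min_events minimum bouts per context for a classification.
#' @return list: \code{pre_water}, \code{post_water} (initiation
#'   classifications or \code{NULL} when unavailable), \code{termination},
#'   \code{category}.
#' @export
classify_by_context <- function(spike_times, bouts, baseline,
                                min_events = 5L) {
  ctx <- split_by_context(bouts)
  init_cls <- lapply(ctx, function(c0) {
    if (c0$n < min_events) return(NULL)
    resp <- aligned_delta_rate(spike_times, c0$first_licks,
                               window = c(-1, 0.5), bin = 0.1,
                               baseline = baseline)
    classify_first_lick_modulation(resp)
  })
  term <- classify_termination_modulation(spike_times, bouts$last_lick_s)
  mods <- c(pre = if (!is.null(init_cls$pre_water))
              init_cls$pre_water$modulation else "none",
            post = if (!is.null(init_cls$post_water))
              init_cls$post_water$modulation else "none",
            term = term$modulation)
  category <- if (any(mods == "negative")) "negative"
  else {
    pos <- c("pre_init", "post_init", "term")[mods == "positive"]
    if (length(pos)) paste(pos, collapse = "+") else "untuned"
  }
  list(pre_water = init_cls$pre_water, post_water = init_cls$post_water,
       termination = term, category = category)
}

#' Onset of the population-average initiation ramp
#'
#' Averages the aligned rate change across units and applies the
#' initiation-ramp rule to the population trace.
#'
#' @param responses list of \code{aligned_response} objects over the
#'   [-1, 0.5] s window (one per unit, identical bins).
#' @param min_units minimum population size.
#' @return list: \code{onset_s} (NA when the rule is never satisfied),
#'   \code{modulation}, \code{n_units}.
#' @export
population_onset_time <- function(responses, min_units = 5L) {
  if (length(responses) < min_units)
    stop("need at least ", min_units, " units for a population onset")
  mat <- vapply(responses, function(r) r$delta_rate_hz,
                numeric(length(responses[[1]]$time_s)))
  pop <- responses[[1]]
  pop$delta_rate_hz <- rowMeans(matrix(mat, ncol = length(responses)))
  cls <- classify_first_lick_modulation(pop)
  list(onset_s = cls$onset_s, modulation = cls$modulation,
       n_units = length(responses))
}

#' Correlation between lick rate and simple-spike rate
#'
#' Sorts each included trial into 1-s bins and regresses the per-bin spike
#' rate on the per-bin lick rate. Trials are included only when their first
#' lick falls at least \code{min_prelick_s} into the trial and their last
#' lick leaves at least \code{min_postlick_s} of recording.
#'
#' @param session list with \code{trials} and \code{licks}.
#' @param spike_times sorted spike times, seconds.
#' @param bin_s bin width, seconds.
#' @param min_prelick_s,min_postlick_s trial-inclusion margins.
#' @param min_bins minimum number of qualifying bins.
#' @return list: \code{slope}, \code{intercept}, \code{r}, \code{n_bins},
#'   \code{n_trials}, \code{degenerate} (TRUE with an all-constant lick
#'   rate, in which case the fit is NA).
#' @export
lickrate_spikerate_correlation <- function(session, spike_times, bin_s = 1,
                                           min_prelick_s = 2,
                                           min_postlick_s = 1,
                                           min_bins = 10L) {
  trials <- session$trials
  licks <- session$licks
  t_end <- max(trials$start_s) +
    (if (nrow(trials) > 1L) stats::median(diff(trials$start_s)) else 10)
  lick_rate <- numeric(); spike_rate <- numeric(); n_trials <- 0L
  for (i in seq_len(nrow(trials))) {
    tl <- sort(licks$time_s[licks$trial_id == trials$trial_id[i]])
    if (length(tl) == 0L) next
    if (tl[1] - trials$start_s[i] < min_prelick_s) next
    if (tl[length(tl)] + min_postlick_s > t_end) next
    n_trials <- n_trials + 1L
    lo <- trials$start_s[i]
    edges <- seq(lo, tl[length(tl)] + min_postlick_s, by = bin_s)
    if (length(edges) < 2L) next
    for (b in seq_len(length(edges) - 1L)) {
      lick_rate <- c(lick_rate,
                     sum(tl >= edges[b] & tl < edges[b + 1L]) / bin_s)
      spike_rate <- c(spike_rate,
                      sum(spike_times >= edges[b] &
                            spike_times < edges[b + 1L]) / bin_s)
    }
  }
  if (length(lick_rate) < min_bins)
    stop("fewer than ", min_bins, " qualifying 1-s bins (",
         length(lick_rate), " found)")
  if (stats::var(lick_rate) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                n_bins = length(lick_rate), n_trials = n_trials,
                degenerate = TRUE))
  fit <- stats::lm(spike_rate ~ lick_rate)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(lick_rate, spike_rate),
       n_bins = length(lick_rate), n_trials = n_trials, degenerate = FALSE)
}

#' Peak rate change after bout initiation
#'
#' Maximum binned rate change within half a second after the first lick.
#'
#' @param response \code{aligned_response} covering [0, 0.5) s.
#' @return Hz.
#' @export
peak_delta_rate <- function(response) {
  sel <- response$time_s >= 0 & response$time_s < 0.5
  max(response$delta_rate_hz[sel])
}
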