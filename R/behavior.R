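#' Instantaneous lick rate
#'
#' The lick rate at each lick after the first, defined as the inverse of the
#' preceding interlick interval.
#'
#' @param licks strictly increasing lick times, seconds.
#' @return data.frame with \code{time_s} (the lick closing each interval)
#'   and \code{rate_hz}; zero rows for fewer than two licks.
#' @export
instantaneous_lick_rate <- function(licks) {
  licks <- check_event_times(licks, "licks")
  if (length(licks) < 2L)
    return(data.frame(time_s = numeric(), rate_hz = numeric()))
  ili <- diff(licks)
  data.frame(time_s = licks[-1L], rate_hz = 1 / ili)
}

# Half-open binning [edges[i], edges[i+1]): the package-wide convention.
bin_counts <- function(x, edges) {
  idx <- findInterval(x, edges)
  idx <- idx[idx >= 1L & idx < length(edges)]
  tabulate(idx, nbins = length(edges) - 1L)
}

check_event_times <- function(x, what = "event times") {
  if (anyNA(x)) stop(what, " contain NA")
  if (is.unsorted(x)) stop(what, " must be sorted")
  if (any(diff(x) == 0)) stop(what, " contain duplicate times")
  as.numeric(x)
}

#' Segment licks into bouts
#'
#' Partitions a lick train into maximal runs whose internal gaps are below
#' \code{bout_break_s}. A bout is flagged isolated ("well-separated") when
#' at least \code{isolation_s} of nonlicking precedes its first lick; the
#' first bout of a session is isolated by convention. When a trial table is
#' supplied, each bout is assigned to the trial whose scheduled water time
#' it is closest to, and labelled \code{pre_water} or \code{post_water} by
#' comparing its first lick to that time (a first lick exactly at water time
#' is \code{post_water}).
#'
#' @param licks sorted lick times, seconds.
#' @param bout_break_s gap opening a new bout; default 1 s, between the
#'   rhythmic interlick range (<= 175 ms) and the 2-s isolation criterion.
#' @param isolation_s preceding-silence requirement for the isolated flag.
#' @param trials optional trial table with \code{trial_id}, \code{start_s},
#'   \code{water_s} and the session interval implied by consecutive starts.
#' @param interval_s trial interval used to impute the scheduled water time
#'   on unrewarded trials; defaults to the median spacing of trial starts.
#' @return data.frame, one row per bout: \code{bout_id}, \code{trial_id}
#'   (\code{NA} without a trial table), \code{first_lick_s},
#'   \code{last_lick_s}, \code{n_licks}, \code{isolated}, \code{context}.
#' @export
segment_bouts <- function(licks, bout_break_s = 1.0, isolation_s = 2.0,
                          trials = NULL, interval_s = NULL) {
  licks <- check_event_times(licks, "licks")
  n <- length(licks)
  empty <- data.frame(bout_id = integer(), trial_id = integer(),
                      first_lick_s = numeric(), last_lick_s = numeric(),
                      n_licks = integer(), isolated = logical(),
                      context = character())
  if (n == 0L) return(empty)
  new_bout <- c(TRUE, diff(licks) >= bout_break_s)
  bout_id <- cumsum(new_bout)
  first <- tapply(licks, bout_id, min)
  last <- tapply(licks, bout_id, max)
  count <- as.integer(tapply(licks, bout_id, length))
  gap_before <- c(Inf, first[-1L] - last[-length(last)])
  out <- data.frame(bout_id = as.integer(names(first)),
                    trial_id = NA_integer_,
                    first_lick_s = as.numeric(first),
                    last_lick_s = as.numeric(last),
                    n_licks = count,
                    isolated = gap_before >= isolation_s,
                    context = NA_character_)
  if (!is.null(trials)) {
    if (is.null(interval_s))
      interval_s <- if (nrow(trials) > 1L) stats::median(diff(trials$start_s))
                    else max(trials$water_s - trials$start_s, 10, na.rm = TRUE)
    sched <- ifelse(is.na(trials$water_s), trials$start_s + interval_s,
                    trials$water_s)
    idx <- vapply(out$first_lick_s,
                  function(f) which.min(abs(sched - f)), integer(1))
    out$trial_id <- trials$trial_id[idx]
    out$context <- ifelse(out$first_lick_s < sched[idx],
                          "pre_water", "post_water")
  }
  rownames(out) <- NULL
  out
}

#' Trial-averaged peri-event lick-rate histogram
#'
#' Bins each trial's licks relative to an alignment event (water delivery,
#' first lick of the trial's bout, or last lick), converts counts to rates,
#' and averages across trials with a standard error. Trials lacking the
#' event are excluded and counted.
#'
#' @param session list with \code{trials} and \code{licks} (data.frame with
#'   \code{trial_id}, \code{time_s}), e.g. a simulated session or a bundle
#'   read by \code{\link{read_bundle}}.
#' @param align one of \code{"water"}, \code{"first_lick"},
#'   \code{"last_lick"}.
#' @param window c(lo, hi) seconds around the event; bins are half-open
#'   [lo, hi).
#' @param bin bin width, seconds.
#' @param bouts optional bout table (from \code{\link{segment_bouts}}) used
#'   for the lick alignments; computed from the session if missing.
#' @return object of class \code{lick_psth}: data.frame with \code{time_s}
#'   (bin centers), \code{rate_hz}, \code{sem_hz}; attributes \code{n_trials}
#'   and \code{n_excluded}.
#' @export
trial_averaged_lick_psth <- function(session, align = c("water",
                                     "first_lick", "last_lick"),
                                     window = c(-4, 4), bin = 0.1,
                                     bouts = NULL) {
  align <- match.arg(align)
  trials <- session$trials
  licks <- session$licks
  if (align == "water") {
    events <- trials$water_s
    ids <- trials$trial_id
  } else {
    if (is.null(bouts))
      bouts <- segment_bouts(sort(licks$time_s), trials = trials)
    events <- if (align == "first_lick") bouts$first_lick_s
              else bouts$last_lick_s
    ids <- bouts$trial_id
  }
  keep <- !is.na(events)
  n_excluded <- sum(!keep)
  events <- events[keep]; ids <- ids[keep]
  if (length(events) == 0L) {
    out <- data.frame(time_s = numeric(), rate_hz = numeric(),
                      sem_hz = numeric())
    attr(out, "n_trials") <- 0L
    attr(out, "n_excluded") <- n_excluded
    attr(out, "reason") <- "no trials contain the alignment event"
    class(out) <- c("lick_psth", "data.frame")
    return(out)
  }
  edges <- seq(window[1], window[2], by = bin)
  centers <- edges[-length(edges)] + bin / 2
  mat <- vapply(seq_along(events), function(i) {
    bin_counts(licks$time_s - events[i], edges) / bin
  }, numeric(length(centers)))
  mat <- matrix(mat, nrow = length(centers))
  out <- data.frame(time_s = centers,
                    rate_hz = rowMeans(mat),
                    sem_hz = apply(mat, 1, stats::sd) / sqrt(ncol(mat)))
  attr(out, "n_trials") <- length(events)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("lick_psth", "data.frame")
  out
}

#' Histogram of bout-initiation times relative to water
#'
#' @param bouts bout table with \code{first_lick_s} and \code{trial_id}.
#' @param trials trial table supplying per-trial water times (scheduled
#'   water imputed on unrewarded trials from the trial interval).
#' @param bin bin width, seconds.
#' @param window c(lo, hi) seconds around water.
#' @return list: \code{histogram} data.frame (\code{time_s} bin centers,
#'   \code{count}), \code{n_pre}, \code{n_post}.
#' @export
bout_initiation_histogram <- function(bouts, trials, bin = 0.25,
                                      window = c(-5, 3)) {
  edges <- seq(window[1], window[2], by = bin)
  centers <- edges[-length(edges)] + bin / 2
  if (nrow(bouts) == 0L)
    return(list(histogram = data.frame(time_s = centers,
                                       count = rep(0L, length(centers))),
                n_pre = 0L, n_post = 0L))
  interval_s <- if (nrow(trials) > 1L) stats::median(diff(trials$start_s))
                else 10
  sched <- ifelse(is.na(trials$water_s), trials$start_s + interval_s,
                  trials$water_s)
  rel <- bouts$first_lick_s -
    sched[match(bouts$trial_id, trials$trial_id)]
  counts <- bin_counts(rel, edges)
  list(histogram = data.frame(time_s = centers, count = counts),
       n_pre = sum(rel < 0), n_post = sum(rel >= 0))
}

#' Lick metrics on optogenetic-stimulation trials
#'
#' Compares licking on stimulated and control trials: the variance of the
#' binned lick rate during the stimulus window normalized to the equal-length
#' prestimulus window on the same trials, mean lick rates during the
#' stimulus and the rebound window for both groups, and the rebound
#' probability -- the fraction of stimulated trials with a well-separated
#' bout initiation (at least 2 s of prior nonlicking) inside the rebound
#' window.
#'
#' @param session list with \code{trials} (annotated with \code{opto_on_s},
#'   \code{opto_off_s}) and \code{licks}.
#' @param rebound_window_s length of the window after stimulus offset
#'   scanned for rebound bout initiations, seconds.
#' @param bin bin width for the variance computation, seconds.
#' @param isolation_s prior-nonlicking requirement for a rebound bout.
#' @return list with \code{variance_ratio}, \code{rate_stim_hz},
#'   \code{rate_control_hz}, \code{rate_rebound_stim_hz},
#'   \code{rate_rebound_control_hz}, \code{rebound_prob},
#'   \code{n_stim}, \code{n_control}.
#' @export
opto_lick_metrics <- function(session, rebound_window_s = 1.5, bin = 0.1,
                              isolation_s = 2.0) {
  trials <- session$trials
  licks <- session$licks
  stim <- which(!is.na(trials$opto_on_s))
  ctrl <- setdiff(seq_len(nrow(trials)), stim)
  if (length(stim) == 0L) stop("no stimulated trials in session")
  if (length(ctrl) == 0L) stop("no control trials in session")
  win_len <- trials$opto_off_s[stim] - trials$opto_on_s[stim]
  # control trials are scored over the same window relative to trial start
  rel_on <- stats::median(trials$opto_on_s[stim] - trials$start_s[stim])
  rel_off <- stats::median(trials$opto_off_s[stim] - trials$start_s[stim])

  binned_rates <- function(idx, lo, hi) {
    unlist(lapply(seq_along(idx), function(k) {
      i <- idx[k]
      tl <- licks$time_s[licks$trial_id == trials$trial_id[i]]
      edges <- seq(lo[k], hi[k], by = bin)
      if (length(edges) < 2L) return(numeric())
      bin_counts(tl, edges) / bin
    }))
  }
  mean_rate <- function(idx, lo, hi) {
    tot <- 0; dur <- 0
    for (k in seq_along(idx)) {
      i <- idx[k]
      tl <- licks$time_s[licks$trial_id == trials$trial_id[i]]
      tot <- tot + sum(tl >= lo[k] & tl < hi[k])
      dur <- dur + (hi[k] - lo[k])
    }
    tot / dur
  }
  on_s <- trials$opto_on_s[stim]; off_s <- trials$opto_off_s[stim]
  pre_lo <- on_s - win_len
  v_dur <- stats::var(binned_rates(stim, on_s, off_s))
  v_pre <- stats::var(binned_rates(stim, pre_lo, on_s))
  ctrl_on <- trials$start_s[ctrl] + rel_on
  ctrl_off <- trials$start_s[ctrl] + rel_off
  res <- list(
    variance_ratio = if (isTRUE(v_pre > 0)) v_dur / v_pre else NA_real_,
    rate_stim_hz = mean_rate(stim, on_s, off_s),
    rate_control_hz = mean_rate(ctrl, ctrl_on, ctrl_off),
    rate_rebound_stim_hz = mean_rate(stim, off_s, off_s + rebound_window_s),
    rate_rebound_control_hz = mean_rate(ctrl, ctrl_off,
                                        ctrl_off + rebound_window_s),
    n_stim = length(stim), n_control = length(ctrl))
  bouts <- segment_bouts(sort(licks$time_s), isolation_s = isolation_s)
  reb <- vapply(seq_along(stim), function(k) {
    i <- stim[k]
    any(bouts$isolated &
          bouts$first_lick_s >= off_s[k] &
          bouts$first_lick_s < off_s[k] + rebound_window_s)
  }, logical(1))
  res$rebound_prob <- mean(reb)
  ctrl_reb <- vapply(seq_along(ctrl), function(k) {
    any(bouts$isolated &
          bouts$first_lick_s >= ctrl_off[k] &
          bouts$first_lick_s < ctrl_off[k] + rebound_window_s)
  }, logical(1))
  res$rebound_prob_control <- mean(ctrl_reb)
  res
}
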