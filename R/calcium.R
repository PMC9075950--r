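# Event rate of a pooled set of event trains aligned to reference times.
aligned_event_rate <- function(event_times, refs, window, bin,
                               n_trains = 1L) {
  edges <- seq(window[1], window[2], by = bin)
  centers <- edges[-length(edges)] + bin / 2
  counts <- numeric(length(centers))
  for (r in refs) {
    counts <- counts + bin_counts(event_times - r, edges)
  }
  data.frame(time_s = centers,
             rate_hz = counts / (bin * length(refs) * n_trains))
}

#' Water responsiveness of imaged regions
#'
#' A region is water responsive when the peri-water peak of its pooled
#' dendritic calcium-event rate (within \code{peak_window_s} of water
#' delivery) exceeds the baseline mean by more than \code{threshold_sd}
#' baseline standard deviations, computed over 100-ms bins in the baseline
#' window before water.
#'
#' @param calcium data.frame \code{dendrite_id}, \code{region_id},
#'   \code{time_s}.
#' @param water_times water-delivery times, seconds (NA entries dropped).
#' @param peak_window_s half-width of the peri-water peak search window.
#' @param baseline_window_s c(lo, hi) relative to water, seconds.
#' @param bin bin width, seconds.
#' @param threshold_sd detection threshold in baseline SDs.
#' @param min_dendrites regions with fewer dendrites are skipped.
#' @return data.frame: \code{region_id}, \code{n_dendrites},
#'   \code{responsive} (NA for skipped regions), \code{peak_rate_hz},
#'   \code{baseline_hz}.
#' @export
region_responsiveness <- function(calcium, water_times,
                                  peak_window_s = 0.5,
                                  baseline_window_s = c(-3, -1),
                                  bin = 0.1, threshold_sd = 3,
                                  min_dendrites = 5L) {
  water_times <- water_times[!is.na(water_times)]
  regions <- sort(unique(calcium$region_id))
  rows <- lapply(regions, function(rg) {
    sub <- calcium[calcium$region_id == rg, ]
    nd <- length(unique(sub$dendrite_id))
    if (nd < min_dendrites)
      return(data.frame(region_id = rg, n_dendrites = nd,
                        responsive = NA, peak_rate_hz = NA_real_,
                        baseline_hz = NA_real_))
    psth <- aligned_event_rate(sub$time_s, water_times,
                               window = c(baseline_window_s[1],
                                          peak_window_s),
                               bin = bin, n_trains = nd)
    base_sel <- psth$time_s >= baseline_window_s[1] &
      psth$time_s < baseline_window_s[2]
    peak_sel <- psth$time_s >= -peak_window_s &
      psth$time_s < peak_window_s
    m <- mean(psth$rate_hz[base_sel])
    s <- stats::sd(psth$rate_hz[base_sel])
    peak <- max(psth$rate_hz[peak_sel])
    data.frame(region_id = rg, n_dendrites = nd,
               responsive = peak > m + threshold_sd * s,
               peak_rate_hz = peak, baseline_hz = m)
  })
  do.call(rbind, rows)
}

#' Calcium-event ramp onset at bout initiation
#'
#' Aligns one dendrite's events to bout first licks in 100-ms bins; the
#' ramp onset is the first bin between 1 s before and 0.5 s after the first
#' lick whose rate exceeds the baseline mean by more than
#' \code{threshold_sd} baseline SDs. The baseline distribution is taken
#' from the bins 3 to 1 s before the first lick.
#'
#' @param event_times sorted calcium-event times of one dendrite, seconds.
#' @param first_lick_times bout first licks, seconds.
#' @param window c(lo, hi) of the detection window relative to the first
#'   lick.
#' @param baseline_window_s c(lo, hi) of the baseline bins.
#' @param bin bin width, seconds.
#' @param threshold_sd detection threshold in baseline SDs.
#' @param min_bouts minimum aligned bouts for a valid onset estimate.
#' @return list: \code{onset_s} (NA when never crossed), \code{n_bouts},
#'   \code{threshold_hz}.
#' @export
calcium_ramp_onset <- function(event_times, first_lick_times,
                               window = c(-1, 0.5),
                               baseline_window_s = c(-3, -1),
                               bin = 0.1, threshold_sd = 3,
                               min_bouts = 20L) {
  first_lick_times <- first_lick_times[!is.na(first_lick_times)]
  if (length(first_lick_times) < min_bouts)
    stop("need at least ", min_bouts, " aligned bouts (",
         length(first_lick_times), " supplied)")
  if (length(event_times) == 0L)
    return(list(onset_s = NA_real_, n_bouts = length(first_lick_times),
                threshold_hz = NA_real_))
  psth <- aligned_event_rate(event_times, first_lick_times,
                             window = c(baseline_window_s[1], window[2]),
                             bin = bin)
  base_sel <- psth$time_s >= baseline_window_s[1] &
    psth$time_s < baseline_window_s[2]
  det_sel <- psth$time_s >= window[1] & psth$time_s < window[2]
  m <- mean(psth$rate_hz[base_sel])
  s <- stats::sd(psth$rate_hz[base_sel])
  thr <- m + threshold_sd * s
  hit <- which(det_sel & psth$rate_hz > thr)
  onset <- if (length(hit)) psth$time_s[hit[1]] - bin / 2 else NA_real_
  list(onset_s = onset, n_bouts = length(first_lick_times),
       threshold_hz = thr)
}

#' Calcium-event rate change at bout termination
#'
#' Compares the event rate in the second before and the second after the
#' last lick of qualifying bouts, with a paired Wilcoxon signed-rank
#' comparison across trials. On rewarded trials a bout qualifies only when
#' its last lick falls at least \code{min_post_water_s} after water
#' delivery; bouts on water-omission trials qualify unconditionally.
#'
#' @param event_times sorted calcium-event times, seconds.
#' @param bouts bout table with \code{last_lick_s} and \code{trial_id}.
#' @param trials trial table with \code{trial_id}, \code{water_s}.
#' @param window_s window length on each side of the last lick, seconds.
#' @param min_post_water_s rewarded-trial qualification margin.
#' @return list: \code{rate_before_hz}, \code{rate_after_hz},
#'   \code{p_value} (NA and \code{underpowered = TRUE} with fewer than two
#'   qualifying trials), \code{n_trials}.
#' @export
termination_rate_change <- function(event_times, bouts, trials,
                                    window_s = 1, min_post_water_s = 2) {
  water <- trials$water_s[match(bouts$trial_id, trials$trial_id)]
  qual <- is.na(water) | (bouts$last_lick_s - water >= min_post_water_s)
  b <- bouts[qual, ]
  if (nrow(b) == 0L)
    return(list(rate_before_hz = NA_real_, rate_after_hz = NA_real_,
                p_value = NA_real_, n_trials = 0L, underpowered = TRUE))
  before <- vapply(b$last_lick_s, function(ll)
    sum(event_times >= ll - window_s & event_times < ll) / window_s,
    numeric(1))
  after <- vapply(b$last_lick_s, function(ll)
    sum(event_times >= ll & event_times < ll + window_s) / window_s,
    numeric(1))
  underpowered <- nrow(b) < 2L || all(after == before)
  p <- if (underpowered) NA_real_
       else suppressWarnings(stats::wilcox.test(after, before,
                                                paired = TRUE)$p.value)
  list(rate_before_hz = mean(before), rate_after_hz = mean(after),
       p_value = p, n_trials = nrow(b), underpowered = underpowered)
}
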