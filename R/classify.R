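#' Count probe channels on which a unit's spikes stand above the noise
#'
#' @param profile data.frame for one unit with columns \code{peak_uv}
#'   (per-channel mean spike-peak amplitude, microvolts) and optionally
#'   \code{channel}.
#' @param noise_floor_uv the noise floor; channels strictly above it count.
#' @return integer channel count.
#' @export
channel_count <- function(profile, noise_floor_uv = 30) {
  stopifnot(nrow(profile) >= 1L, all(profile$peak_uv >= 0))
  sum(profile$peak_uv > noise_floor_uv)
}

#' Classify a unit from its channel footprint
#'
#' Two-stage rule: a unit with observed complex spikes is an unambiguous
#' Purkinje cell regardless of footprint; otherwise a footprint spanning at
#' least \code{channel_threshold} above-noise channels marks a putative
#' Purkinje cell (PCs are large relative to probe pad spacing); anything
#' else is labelled \code{other}. Molecular layer interneurons are only
#' identified positively by opto-tagging
#' (\code{\link{optotag_short_latency}}).
#'
#' @param profile per-channel profile of one unit: \code{unit_id},
#'   \code{peak_uv}, and a logical \code{has_cs} column (constant within
#'   the unit).
#' @param channel_threshold minimum above-noise channel count for the
#'   putative-PC call.
#' @param noise_floor_uv noise floor passed to \code{\link{channel_count}}.
#' @return data.frame row: \code{unit_id}, \code{label}, \code{channel_count}.
#' @export
classify_unit <- function(profile, channel_threshold = 7,
                          noise_floor_uv = 30) {
  cc <- channel_count(profile, noise_floor_uv)
  has_cs <- isTRUE(profile$has_cs[1])
  label <- if (has_cs) "PC_unambiguous"
           else if (cc >= channel_threshold) "PC_putative"
           else "other"
  data.frame(unit_id = profile$unit_id[1], label = label,
             channel_count = cc)
}

#' Classify a roster of units and summarize the Purkinje-cell set
#'
#' @param profiles long data.frame of channel profiles for many units
#'   (\code{unit_id}, \code{channel}, \code{peak_uv}, \code{has_cs}).
#' @param channel_threshold,noise_floor_uv passed to
#'   \code{\link{classify_unit}}.
#' @return list: \code{classification} (one row per unit), \code{counts}
#'   (named per-label table), \code{pc_units} (ids of unambiguous plus
#'   putative PCs), \code{n_pc}.
#' @export
classify_roster <- function(profiles, channel_threshold = 7,
                            noise_floor_uv = 30) {
  stopifnot(nrow(profiles) >= 1L)
  ids <- unique(profiles$unit_id)
  per_unit <- split(profiles, factor(profiles$unit_id, levels = ids))
  if (any(vapply(per_unit, function(p) anyDuplicated(p$channel) > 0,
                 logical(1))))
    stop("duplicate unit_id/channel rows in profile table")
  cls <- do.call(rbind, lapply(per_unit, classify_unit,
                               channel_threshold = channel_threshold,
                               noise_floor_uv = noise_floor_uv))
  rownames(cls) <- NULL
  counts <- table(factor(cls$label,
                         levels = c("PC_unambiguous", "PC_putative",
                                    "MLI", "other")))
  pc <- cls$unit_id[cls$label %in% c("PC_unambiguous", "PC_putative")]
  list(classification = cls, counts = counts, pc_units = pc,
       n_pc = length(pc))
}

#' Opto-tag a unit by short-latency responses to light pulses
#'
#' A unit is tagged (e.g. as a ChR2-expressing molecular layer interneuron)
#' when the fraction of light pulses followed by at least one spike within
#' the latency window significantly exceeds the chance level expected from
#' the unit's own baseline rate, by a one-sided binomial test.
#'
#' @param spike_times sorted spike times, seconds.
#' @param pulse_times sorted light-pulse onset times, seconds (>= 10).
#' @param latency_window_ms response window after each pulse, milliseconds.
#' @param baseline_rate_hz unit baseline rate used for the chance level;
#'   estimated from the whole train if missing.
#' @param alpha test level.
#' @return list: \code{tagged}, \code{p_value}, \code{response_prob},
#'   \code{chance_prob}, \code{median_latency_ms} (NA when no responses).
#' @export
optotag_short_latency <- function(spike_times, pulse_times,
                                  latency_window_ms = 10,
                                  baseline_rate_hz = NULL, alpha = 0.05) {
  if (length(pulse_times) == 0L) stop("no light pulses supplied")
  if (length(pulse_times) < 10L)
    stop("need at least 10 pulses for the opto-tag test")
  w <- latency_window_ms / 1000
  if (is.null(baseline_rate_hz)) {
    span <- diff(range(c(spike_times, pulse_times)))
    baseline_rate_hz <- if (span > 0) length(spike_times) / span else 0
  }
  lat <- vapply(pulse_times, function(p) {
    nxt <- spike_times[spike_times >= p & spike_times < p + w]
    if (length(nxt)) nxt[1] - p else NA_real_
  }, numeric(1))
  hits <- sum(!is.na(lat))
  chance <- 1 - exp(-baseline_rate_hz * w)
  p <- if (hits == 0L) 1
       else stats::binom.test(hits, length(pulse_times), p = max(chance, 1e-12),
                              alternative = "greater")$p.value
  list(tagged = hits > 0L && p < alpha, p_value = p,
       response_prob = hits / length(pulse_times), chance_prob = chance,
       median_latency_ms = if (hits) stats::median(lat, na.rm = TRUE) * 1000
                           else NA_real_)
}
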