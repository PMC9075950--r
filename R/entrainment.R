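#' Select rhythmic licks
#'
#' Retains licks occurring in sequences of at least three consecutive licks
#' whose every internal interlick interval lies in the rhythmic band
#' (inclusive bounds). These runs define the lick cycles to which spike
#' phases are referenced.
#'
#' @param licks sorted lick times, seconds.
#' @param ili_range_s inclusive interlick-interval bounds, seconds.
#' @param min_run minimum number of licks per retained run.
#' @return list of numeric vectors, one per retained run (possibly empty).
#' @export
select_rhythmic_licks <- function(licks, ili_range_s = c(0.100, 0.175),
                                  min_run = 3L) {
  licks <- check_event_times(licks, "licks")
  if (length(licks) < min_run) return(list())
  # inclusive bounds, with a nanosecond tolerance for float round-off
  d <- diff(licks)
  ok <- d >= ili_range_s[1] - 1e-9 & d <= ili_range_s[2] + 1e-9
  runs <- rle(ok)
  out <- list()
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i] && len + 1L >= min_run)
      out[[length(out) + 1L]] <- licks[pos:(pos + len)]
    pos <- pos + len
  }
  out
}

#' Lick-cycle phase of spikes
#'
#' Assigns each spike the phase of the lick cycle it falls in, by linear
#' interpolation between the bracketing licks of a retained rhythmic run;
#' tongue contact defines phase 0 (= 2*pi). Spikes outside retained lick
#' pairs are dropped.
#'
#' @param spike_times sorted spike times, seconds.
#' @param rhythmic_runs list of lick runs from
#'   \code{\link{select_rhythmic_licks}}.
#' @return numeric vector of phases in [0, 2*pi).
#' @export
spike_phases <- function(spike_times, rhythmic_runs) {
  if (length(rhythmic_runs) == 0L || length(spike_times) == 0L)
    return(numeric())
  phases <- lapply(rhythmic_runs, function(run) {
    idx <- findInterval(spike_times, run)
    ok <- idx >= 1L & idx < length(run)
    s <- spike_times[ok]; i <- idx[ok]
    2 * pi * (s - run[i]) / (run[i + 1L] - run[i])
  })
  ph <- unlist(phases)
  ph %% (2 * pi)
}

#' Mean resultant of circular data
#'
#' @param phases radians.
#' @return list with \code{length} in [0, 1] and \code{angle} in [0, 2*pi).
#' @export
mean_resultant <- function(phases) {
  if (length(phases) == 0L) stop("mean resultant of an empty phase sample")
  z <- mean(exp(1i * phases))
  list(length = Mod(z), angle = Arg(z) %% (2 * pi))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of uniform phases with the statistic Z = n * Rbar^2 and
#' the standard finite-sample corrected approximation to its tail
#' probability (Zar's series in 1/n and 1/n^2).
#'
#' @param phases radians.
#' @return list: \code{p_value}, \code{z}, \code{r_bar}, \code{n}.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n == 0L) stop("Rayleigh test of an empty phase sample")
  r_bar <- mean_resultant(phases)$length
  z <- n * r_bar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(p_value = min(max(p, 0), 1), z = z, r_bar = r_bar, n = n)
}

#' Benjamini-Hochberg screening of entrained units
#'
#' Applies the step-up false-discovery-rate procedure to a panel of
#' Rayleigh p-values.
#'
#' @param p_values numeric in [0, 1].
#' @param fdr target false discovery rate.
#' @return data.frame: \code{p_value}, \code{q_value}, \code{entrained}.
#' @export
bh_select_entrained <- function(p_values, fdr = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  q <- stats::p.adjust(p_values, method = "BH")
  data.frame(p_value = p_values, q_value = q, entrained = q <= fdr)
}

#' Circular kernel density of spike phases
#'
#' Wrapped-kernel estimate on a regular phase grid, normalized to unit mass
#' over the circle. The default kernel is a wrapped Gaussian with standard
#' deviation \code{kernel_width} radians; a von Mises kernel with matched
#' dispersion (concentration 1/kernel_width^2) is available.
#'
#' @param phases radians.
#' @param kernel_width kernel width, radians.
#' @param kernel \code{"wrapped_gaussian"} or \code{"von_mises"}.
#' @param n_grid number of grid points over [0, 2*pi).
#' @return data.frame: \code{phase} (grid centers), \code{density}.
#' @export
circular_density <- function(phases, kernel_width = 0.3,
                             kernel = c("wrapped_gaussian", "von_mises"),
                             n_grid = 360L) {
  kernel <- match.arg(kernel)
  if (length(phases) == 0L) stop("density of an empty phase sample")
  grid <- (seq_len(n_grid) - 0.5) * 2 * pi / n_grid
  dens <- vapply(grid, function(g) {
    d <- ((g - phases + pi) %% (2 * pi)) - pi
    if (kernel == "wrapped_gaussian") {
      mean(stats::dnorm(d, 0, kernel_width) +
             stats::dnorm(d - 2 * pi, 0, kernel_width) +
             stats::dnorm(d + 2 * pi, 0, kernel_width))
    } else {
      kappa <- 1 / kernel_width^2
      mean(exp(kappa * cos(d)) / (2 * pi * besselI(kappa, 0,
                                                   expon.scaled = TRUE) *
                                    exp(kappa)))
    }
  }, numeric(1))
  dens <- dens / (sum(dens) * 2 * pi / n_grid)   # exact unit mass on grid
  data.frame(phase = grid, density = dens)
}

#' Phase histogram with pi/10 bins
#'
#' @param phases radians in [0, 2*pi).
#' @param bin_width bin width in radians (default pi/10, giving 20 bins).
#' @return data.frame: \code{phase} (bin centers), \code{count}.
#' @export
phase_histogram <- function(phases, bin_width = pi / 10) {
  n_bins <- round(2 * pi / bin_width)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  idx <- pmin(findInterval(phases %% (2 * pi), edges,
                           rightmost.closed = TRUE), n_bins)
  data.frame(phase = edges[-(n_bins + 1L)] + bin_width / 2,
             count = tabulate(idx, nbins = n_bins))
}

#' Threshold a circular density at the near-uniform level
#'
#' Flags phase-grid points where the spike-phase density exceeds
#' 1.02/(2*pi), i.e. 2\% above the uniform density, marking the portion of
#' the lick cycle over which a unit fires preferentially.
#'
#' @param density data.frame from \code{\link{circular_density}}.
#' @param threshold density cutoff.
#' @return logical mask along the grid.
#' @export
threshold_density <- function(density, threshold = 1.02 / (2 * pi)) {
  density$density > threshold
}

#' Entrainment statistics for one unit
#'
#' The full per-unit pipeline: restrict to rhythmic lick runs, interpolate
#' spike phases, and compute the mean resultant, Rayleigh test, phase
#' histogram, circular density and suprathreshold mask.
#'
#' @param spike_times sorted spike times, seconds.
#' @param licks sorted session lick times, seconds.
#' @param kernel_width,kernel,n_grid passed to
#'   \code{\link{circular_density}}.
#' @return list of class \code{entrainment_result}: \code{n_spikes},
#'   \code{resultant_length}, \code{resultant_angle}, \code{rayleigh_p},
#'   \code{histogram}, \code{density}, \code{suprathreshold_mask}; NULL
#'   fields and \code{n_spikes = 0} when no spike falls in a rhythmic run.
#' @export
unit_entrainment <- function(spike_times, licks, kernel_width = 0.3,
                             kernel = "wrapped_gaussian", n_grid = 360L) {
  runs <- select_rhythmic_licks(licks)
  ph <- spike_phases(spike_times, runs)
  if (length(ph) == 0L)
    return(structure(list(n_spikes = 0L, resultant_length = NA_real_,
                          resultant_angle = NA_real_, rayleigh_p = NA_real_,
                          histogram = NULL, density = NULL,
                          suprathreshold_mask = NULL),
                     class = "entrainment_result"))
  res <- mean_resultant(ph)
  dens <- circular_density(ph, kernel_width, kernel, n_grid)
  structure(list(n_spikes = length(ph),
                 resultant_length = res$length,
                 resultant_angle = res$angle,
                 rayleigh_p = rayleigh_test(ph)$p_value,
                 histogram = phase_histogram(ph),
                 density = dens,
                 suprathreshold_mask = threshold_density(dens)),
            class = "entrainment_result")
}

#' Entrainment screen across a unit population
#'
#' Runs \code{\link{unit_entrainment}} per unit and controls the false
#' discovery rate across units with the Benjamini-Hochberg procedure. Units
#' without phase-assignable spikes are reported but not tested. Rows are
#' ordered by unit id; re-orderings by resultant length or angle break ties
#' by unit id.
#'
#' @param spikes data.frame \code{unit_id}, \code{time_s}.
#' @param licks sorted session lick times, seconds.
#' @param fdr target false discovery rate.
#' @param ... passed to \code{\link{unit_entrainment}}.
#' @return data.frame: \code{unit_id}, \code{n_spikes},
#'   \code{resultant_length}, \code{resultant_angle}, \code{rayleigh_p},
#'   \code{q_value}, \code{entrained}.
#' @export
entrainment_screen <- function(spikes, licks, fdr = 0.05, ...) {
  ids <- sort(unique(spikes$unit_id))
  rows <- lapply(ids, function(id) {
    r <- unit_entrainment(sort(spikes$time_s[spikes$unit_id == id]),
                          licks, ...)
    data.frame(unit_id = id, n_spikes = r$n_spikes,
               resultant_length = r$resultant_length,
               resultant_angle = r$resultant_angle,
               rayleigh_p = r$rayleigh_p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$entrained <- NA
  tested <- !is.na(out$rayleigh_p)
  if (any(tested)) {
    bh <- bh_select_entrained(out$rayleigh_p[tested], fdr)
    out$q_value[tested] <- bh$q_value
    out$entrained[tested] <- bh$entrained
  }
  out
}
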