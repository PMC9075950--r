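#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline. Unknown
#' keys are rejected up front, and every parameter is echoed into the run
#' log.
#'
#' @param seed integer seed driving the simulation (when requested).
#' @param sim a \code{\link{sim_config}}, or NULL to analyse a bundle read
#'   from \code{input_dir}.
#' @param input_dir directory holding a session bundle (used when
#'   \code{sim} is NULL).
#' @param out_dir optional output directory for result tables.
#' @param bout_break_s,isolation_s bout segmentation parameters.
#' @param channel_threshold,noise_floor_uv unit-classification parameters.
#' @param fdr,kernel_width entrainment parameters.
#' @param dendrites optional \code{\link{dendrite_specs}} data.frame for
#'   simulated calcium data.
#' @param opto optional list of \code{\link{generate_opto}} arguments.
#' @param min_bouts_calcium minimum bouts for calcium onset estimation.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, sim = sim_config(seed = seed),
                       input_dir = NULL, out_dir = NULL,
                       bout_break_s = 1.0, isolation_s = 2.0,
                       channel_threshold = 7, noise_floor_uv = 30,
                       fdr = 0.05, kernel_width = 0.3,
                       dendrites = NULL, opto = NULL,
                       min_bouts_calcium = 20L) {
  cfg <- as.list(environment())
  known <- c("seed", "sim", "input_dir", "out_dir", "bout_break_s",
             "isolation_s", "channel_threshold", "noise_floor_uv", "fdr",
             "kernel_width", "dendrites", "opto", "min_bouts_calcium")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (is.null(sim) && is.null(input_dir))
    stop("either a simulation config or an input bundle directory is required")
  class(cfg) <- "run_config"
  cfg
}

bundle_schemas <- list(
  trials = c("trial_id", "start_s", "water_s", "rewarded",
             "opto_on_s", "opto_off_s"),
  licks = c("trial_id", "time_s"),
  spikes = c("unit_id", "time_s"),
  channels = c("unit_id", "channel", "peak_uv", "has_cs"),
  calcium = c("dendrite_id", "region_id", "time_s"))

#' Write a session bundle as comma-separated tables
#'
#' Writes \code{trials.csv}, \code{licks.csv}, \code{spikes.csv},
#' \code{channels.csv}, \code{calcium.csv} and, for simulated sessions, the
#' generator configuration as \code{config.json}.
#'
#' @param session session list (simulated or previously read).
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle_schemas)) {
    tab <- session[[nm]]
    if (is.null(tab)) tab <- stats::setNames(
      as.data.frame(replicate(length(bundle_schemas[[nm]]), numeric(0),
                              simplify = FALSE)), bundle_schemas[[nm]])
    utils::write.csv(tab[, bundle_schemas[[nm]], drop = FALSE],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  if (!is.null(session$config))
    jsonlite::write_json(unclass(session$config),
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(dir)
}

#' Read and validate a session bundle
#'
#' Reads the comma-separated tables written by \code{\link{write_bundle}},
#' checks column schemas and types, verifies that event times are finite
#' and sorted (licks and calcium globally, spikes within unit), and that
#' every \code{trial_id} referenced by a lick exists in the trial table;
#' validation errors name the offending file and rows.
#'
#' @param dir bundle directory.
#' @return session list with \code{trials}, \code{licks}, \code{spikes},
#'   \code{channels}, \code{calcium}.
#' @export
read_bundle <- function(dir) {
  tabs <- list()
  for (nm in names(bundle_schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm == "calcium") {
        tabs[[nm]] <- stats::setNames(
          as.data.frame(replicate(length(bundle_schemas[[nm]]), numeric(0),
                                  simplify = FALSE)), bundle_schemas[[nm]])
        next
      }
      stop("bundle table missing: ", path)
    }
    tab <- utils::read.csv(path)
    miss <- setdiff(bundle_schemas[[nm]], names(tab))
    if (length(miss))
      stop(nm, ".csv: missing columns ", paste(miss, collapse = ", "))
    tabs[[nm]] <- tab[, bundle_schemas[[nm]], drop = FALSE]
  }
  check_col <- function(tab, file, col) {
    bad <- which(!is.finite(tab[[col]]) & !is.na(tab[[col]]))
    if (length(bad))
      stop(file, ": non-finite ", col, " at rows ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  for (col in c("time_s")) {
    check_col(tabs$licks, "licks.csv", col)
    check_col(tabs$spikes, "spikes.csv", col)
  }
  if (anyNA(tabs$licks$time_s))
    stop("licks.csv: NA time_s at rows ",
         paste(utils::head(which(is.na(tabs$licks$time_s)), 5),
               collapse = ", "))
  if (is.unsorted(tabs$licks$time_s))
    stop("licks.csv: time_s not sorted (first violation at row ",
         which(diff(tabs$licks$time_s) < 0)[1] + 1L, ")")
  for (uid in unique(tabs$spikes$unit_id)) {
    st <- tabs$spikes$time_s[tabs$spikes$unit_id == uid]
    if (anyNA(st) || is.unsorted(st))
      stop("spikes.csv: times of unit ", uid, " contain NA or are unsorted")
  }
  orphan <- which(!(tabs$licks$trial_id %in% tabs$trials$trial_id))
  if (length(orphan))
    stop("licks.csv: trial_id not present in trials.csv at rows ",
         paste(utils::head(orphan, 5), collapse = ", "))
  if (nrow(tabs$calcium)) {
    for (did in unique(tabs$calcium$dendrite_id)) {
      ct <- tabs$calcium$time_s[tabs$calcium$dendrite_id == did]
      if (anyNA(ct) || is.unsorted(ct) || any(ct < 0))
        stop("calcium.csv: times of dendrite ", did,
             " contain NA, negatives, or are unsorted")
    }
  }
  tabs$trials$water_s <- as.numeric(tabs$trials$water_s)
  tabs$trials$rewarded <- as.logical(tabs$trials$rewarded)
  tabs$channels$has_cs <- as.logical(tabs$channels$has_cs)
  tabs
}

log_add <- function(log, ...) c(log, paste0(...))

#' Run the full analysis pipeline
#'
#' Simulates a session (or reads a bundle), classifies units, segments
#' bouts, screens lick-cycle entrainment over the Purkinje-cell set,
#' classifies initiation and termination ramps per behavioral context,
#' estimates the population ramp onset, analyses calcium events and
#' optogenetic trials when present, and returns all result tables together
#' with a run log recording every parameter and filter count. Outputs are
#' deterministic given the configuration and seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{pipeline_result}: \code{session},
#'   \code{classification}, \code{bouts}, \code{entrainment},
#'   \code{ramps} (per-unit per-context classification table),
#'   \code{population_onset}, \code{calcium}, \code{opto}, \code{summary},
#'   \code{log}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  for (k in c("seed", "bout_break_s", "isolation_s", "channel_threshold",
              "noise_floor_uv", "fdr", "kernel_width",
              "min_bouts_calcium"))
    log <- log_add(log, "param ", k, " = ", config[[k]])
  if (!is.null(config$sim)) {
    session <- simulate_session(config$sim, dendrites = config$dendrites,
                                opto = config$opto)
    log <- log_add(log, "simulated session: ", nrow(session$trials),
                   " trials, ", nrow(session$licks), " licks")
  } else {
    session <- read_bundle(config$input_dir)
    log <- log_add(log, "read bundle from ", config$input_dir)
  }
  cls <- classify_roster(session$channels,
                         channel_threshold = config$channel_threshold,
                         noise_floor_uv = config$noise_floor_uv)
  log <- log_add(log, "units classified: ", nrow(cls$classification),
                 " total, ", cls$n_pc, " PCs")
  lick_times <- sort(session$licks$time_s)
  bouts <- segment_bouts(lick_times, bout_break_s = config$bout_break_s,
                         isolation_s = config$isolation_s,
                         trials = session$trials)
  log <- log_add(log, "bouts: ", nrow(bouts), " (",
                 sum(bouts$isolated), " well-separated; ",
                 sum(bouts$context == "pre_water", na.rm = TRUE), " pre-water, ",
                 sum(bouts$context == "post_water", na.rm = TRUE),
                 " post-water)")
  pc_spikes <- session$spikes[session$spikes$unit_id %in% cls$pc_units, ]
  entr <- if (nrow(pc_spikes))
    entrainment_screen(pc_spikes, lick_times, fdr = config$fdr,
                       kernel_width = config$kernel_width)
  else NULL
  if (!is.null(entr))
    log <- log_add(log, "entrainment: ", sum(entr$entrained, na.rm = TRUE),
                   " of ", sum(!is.na(entr$entrained)), " tested units flagged")
  iso <- bouts[bouts$isolated, ]
  t_end <- max(session$trials$start_s) +
    (if (nrow(session$trials) > 1L)
       stats::median(diff(session$trials$start_s)) else 10)
  ramp_rows <- list(); responses <- list()
  for (uid in cls$pc_units) {
    st <- sort(session$spikes$time_s[session$spikes$unit_id == uid])
    if (length(st) == 0L) next
    base <- baseline_rate(st, lick_times, t_range = c(0, t_end))
    ctx_cls <- classify_by_context(st, iso, base)
    for (ctx in c("pre_water", "post_water")) {
      cc <- ctx_cls[[ctx]]
      if (is.null(cc)) next
      ramp_rows[[length(ramp_rows) + 1L]] <- data.frame(
        unit_id = uid, event = "first_lick", context = ctx,
        modulation = cc$modulation, onset_s = cc$onset_s)
    }
    ramp_rows[[length(ramp_rows) + 1L]] <- data.frame(
      unit_id = uid, event = "last_lick", context = "any",
      modulation = ctx_cls$termination$modulation,
      onset_s = ctx_cls$termination$onset_s)
    ramp_rows[[length(ramp_rows) + 1L]] <- data.frame(
      unit_id = uid, event = "category", context = "any",
      modulation = ctx_cls$category, onset_s = NA_real_)
    responses[[length(responses) + 1L]] <-
      aligned_delta_rate(st, iso$first_lick_s, window = c(-1, 0.5),
                         baseline = base)
  }
  ramps <- if (length(ramp_rows)) do.call(rbind, ramp_rows) else NULL
  pop <- if (length(responses) >= 5L) population_onset_time(responses)
         else NULL
  if (!is.null(pop))
    log <- log_add(log, "population onset: ", pop$onset_s, " s (",
                   pop$modulation, ", n = ", pop$n_units, ")")
  calcium_res <- NULL
  if (nrow(session$calcium)) {
    resp <- region_responsiveness(session$calcium, session$trials$water_s)
    onsets <- lapply(sort(unique(session$calcium$dendrite_id)),
                     function(did) {
      ev <- sort(session$calcium$time_s[session$calcium$dendrite_id == did])
      on <- tryCatch(calcium_ramp_onset(ev, iso$first_lick_s,
                                        min_bouts = config$min_bouts_calcium),
                     error = function(e) list(onset_s = NA_real_,
                                              n_bouts = nrow(iso)))
      data.frame(dendrite_id = did, onset_s = on$onset_s,
                 n_bouts = on$n_bouts)
    })
    calcium_res <- list(regions = resp, onsets = do.call(rbind, onsets))
    log <- log_add(log, "calcium: ", nrow(resp), " regions, ",
                   sum(resp$responsive, na.rm = TRUE), " responsive")
  }
  opto_res <- NULL
  if (any(!is.na(session$trials$opto_on_s))) {
    opto_res <- opto_lick_metrics(session)
    log <- log_add(log, "opto: ", opto_res$n_stim, " stimulated trials, ",
                   "rebound probability ", round(opto_res$rebound_prob, 3))
  }
  summary <- list(
    n_trials = nrow(session$trials),
    n_units = length(unique(session$spikes$unit_id)),
    n_pc = cls$n_pc,
    n_bouts = nrow(bouts),
    frac_entrained = if (!is.null(entr))
      mean(entr$entrained, na.rm = TRUE) else NA,
    population_onset_s = if (!is.null(pop)) pop$onset_s else NA,
    rebound_prob = if (!is.null(opto_res)) opto_res$rebound_prob else NA)
  res <- structure(list(session = session, classification = cls,
                        bouts = bouts, entrainment = entr, ramps = ramps,
                        population_onset = pop, calcium = calcium_res,
                        opto = opto_res, summary = summary, log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bundle(session, file.path(config$out_dir, "bundle"))
    utils::write.csv(bouts, file.path(config$out_dir, "bouts.csv"),
                     row.names = FALSE)
    utils::write.csv(cls$classification,
                     file.path(config$out_dir, "classification.csv"),
                     row.names = FALSE)
    if (!is.null(entr))
      utils::write.csv(entr, file.path(config$out_dir, "entrainment.csv"),
                       row.names = FALSE)
    if (!is.null(ramps))
      utils::write.csv(ramps, file.path(config$out_dir, "ramps.csv"),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(config$out_dir, "run.log"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
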