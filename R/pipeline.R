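#' Default pipeline configuration
#' @keywords internal
.default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "spikewm_out",
    cohort_dir = NULL,            # read sessions from disk when set
    generator = list(),           # overrides for generator_config()
    stages = list(irregularity = TRUE, popburst = TRUE, fano = TRUE,
                  decoding = TRUE),
    lvr = list(R_s = 0.005, window_s = 2.0, step_s = 0.05, min_spikes = 5),
    rtcorr = list(window_s = 2.0, step_s = 0.25, n_perm = 1000,
                  combo_orders = 1, n_subsamples = 100),
    popburst = list(bandwidth_s = 0.025, step_s = 0.010,
                    min_duration_s = 0.1, proximity_s = 0.15, n_boot = 1000),
    fano = list(window_s = 0.5, step_s = 0.05, n_repeats = 50, bin = 0.5),
    decoding = list(class_def = "setsize", n_cycles = 50, n_shuffles = 500,
                    folds = 10),
    filters = list(min_rate_hz = 1.0, crosstalk_threshold = 0.3))
}

# recursively merge user values into defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults)) stop("unknown configuration key: ", full)
    if (is.list(defaults[[k]]) && !length(defaults[[k]])) {
      # free-form section (generator overrides), validated by its constructor
      defaults[[k]] <- user[[k]]
    } else if (is.list(defaults[[k]]) && !is.null(user[[k]])) {
      if (!is.list(user[[k]])) stop("expected a mapping for key: ", full)
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], full)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in the analysis defaults
#' (refractoriness 5 ms, 2-s LvR windows, 25-ms burst kernel with 100/150-ms
#' duration/proximity, 500/50-ms FF windows with 50 repeats, 250-ms decoding
#' bins with 50 cycles and 500 shuffles, 1000 bootstrap resamples) and
#' rejects unknown keys.
#'
#' @param path YAML file path, or a list of overrides.
#' @return Normalized configuration list (class `spikewm_pipeline_config`).
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (is.list(path)) path
  else {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  cfg <- .merge_config(.default_pipeline_config(), user)
  stopifnot(is.numeric(cfg$seed), cfg$lvr$R_s >= 0, cfg$lvr$window_s > 0)
  class(cfg) <- "spikewm_pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) a cohort, applies the unit-quality filters, then
#' runs the enabled stages in order — irregularity (per-unit LvR table and
#' time-resolved LvR/response-time correlation), population bursts (events
#' and density), mean-matched Fano factors, and pseudo-population decoding —
#' writing each stage's outputs as CSV/JSON under the output directory.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [validate_config()] result (or overrides list).
#' @return Run report: list with `manifest` (named file paths), `config`
#'   echo and per-stage wall-clock seconds.
#' @export
run_pipeline <- function(config = validate_config()) {
  if (!inherits(config, "spikewm_pipeline_config"))
    config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(); timing <- list()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }

  # cohort
  st <- tick({
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)$sessions
    else {
      gcfg <- do.call(generator_config,
                      c(config$generator, list(seed = config$seed)))
      synth_cohort(gcfg)$sessions
    }
  })
  sessions <- st$value; timing$cohort <- st$secs

  # quality filters
  st <- tick(lapply(sessions, function(s) {
    s <- filter_units_by_rate(s, config$filters$min_rate_hz)
    crosstalk_filter(s, threshold = config$filters$crosstalk_threshold)$session
  }))
  sessions <- st$value; timing$filters <- st$secs
  sessions <- sessions[vapply(sessions, function(s) nrow(s$units) > 0, TRUE)]
  if (!length(sessions)) stop("stage 'filters' failed: no units survive")

  run_stage <- function(name, expr) {
    st <- tick(tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED:", conditionMessage(e)),
                 file.path(config$out_dir, paste0(name, ".FAILED")))
      stop("stage '", name, "' failed: ", conditionMessage(e))
    }))
    timing[[name]] <<- st$secs
    st$value
  }

  if (isTRUE(config$stages$irregularity)) {
    lv_tab <- run_stage("irregularity", {
      rows <- list()
      for (s in sessions) for (u in s$units$unit_id) {
        lv <- vapply(as.character(s$trials$trial_id), function(tid)
          lvr_gated(get_spikes(s, u, tid), R_s = config$lvr$R_s,
                    min_spikes = config$lvr$min_spikes), 0)
        rows[[paste(s$session_id, u)]] <- data.frame(
          session_id = s$session_id, unit_id = u,
          region = s$units$region[s$units$unit_id == u],
          mean_lvr = mean(lv, na.rm = TRUE),
          n_trials = sum(is.finite(lv)))
      }
      do.call(rbind, rows)
    })
    p <- file.path(config$out_dir, "lvr.csv")
    utils::write.csv(lv_tab, p, row.names = FALSE)
    manifest$lvr <- p

    rc <- run_stage("rtcorr", timeresolved_rt_correlation(
      sessions, window_s = config$rtcorr$window_s,
      step_s = config$rtcorr$step_s, combo_orders = config$rtcorr$combo_orders,
      n_perm = config$rtcorr$n_perm,
      n_subsamples = config$rtcorr$n_subsamples))
    p <- file.path(config$out_dir, "rtcorr.csv")
    utils::write.csv(rc, p, row.names = FALSE)
    manifest$rtcorr <- p
  }

  if (isTRUE(config$stages$popburst)) {
    ev_all <- run_stage("popburst", {
      do.call(rbind, lapply(sessions, function(s) {
        ev <- session_bursts(s, bandwidth_s = config$popburst$bandwidth_s,
                             step_s = config$popburst$step_s,
                             min_duration_s = config$popburst$min_duration_s,
                             proximity_s = config$popburst$proximity_s)
        if (nrow(ev)) cbind(session_id = s$session_id, ev) else NULL
      }))
    })
    p <- file.path(config$out_dir, "bursts.csv")
    utils::write.csv(ev_all, p, row.names = FALSE)
    manifest$bursts <- p

    dens <- run_stage("density", {
      # pool trials across sessions under globally unique ids
      evp <- NULL; trp <- NULL; offset <- 0L
      for (s in sessions) {
        remap <- stats::setNames(offset + seq_len(nrow(s$trials)),
                                 s$trials$trial_id)
        trp <- rbind(trp, data.frame(trial_id = unname(remap),
                                     response_time = s$trials$response_time))
        if (!is.null(ev_all)) {
          ev <- ev_all[ev_all$session_id == s$session_id, , drop = FALSE]
          if (nrow(ev))
            evp <- rbind(evp, data.frame(
              trial_id = unname(remap[as.character(ev$trial_id)]),
              start = ev$start, end = ev$end))
        }
        offset <- offset + nrow(s$trials)
      }
      if (is.null(evp)) evp <- data.frame(trial_id = integer(0),
                                          start = numeric(0), end = numeric(0))
      burst_density(evp, trp, align = "trial_start",
                    n_boot = config$popburst$n_boot)
    })
    p <- file.path(config$out_dir, "density.csv")
    utils::write.csv(data.frame(time = dens$time, density = dens$density,
                                lo = dens$lo, hi = dens$hi),
                     p, row.names = FALSE)
    manifest$density <- p
  }

  if (isTRUE(config$stages$fano)) {
    ff <- run_stage("fano", {
      # pool unit x condition points across sessions, as the points of one
      # common mean-count distribution
      pts <- do.call(rbind, lapply(sessions, function(s)
        window_counts(s, window_s = config$fano$window_s,
                      step_s = config$fano$step_s)))
      mean_matched_ff(pts, n_repeats = config$fano$n_repeats,
                      bin = config$fano$bin)$series
    })
    p <- file.path(config$out_dir, "ff.csv")
    utils::write.csv(ff, p, row.names = FALSE)
    manifest$ff <- p
  }

  if (isTRUE(config$stages$decoding)) {
    dec <- run_stage("decoding", bootstrap_decode(
      sessions, class_def = config$decoding$class_def,
      n_cycles = config$decoding$n_cycles,
      n_shuffles = config$decoding$n_shuffles,
      folds = config$decoding$folds))
    p <- file.path(config$out_dir, "decode.json")
    jsonlite::write_json(list(accuracies = dec$accuracies,
                              p_per_cycle = dec$p_per_cycle,
                              p_summary = dec$p_summary, n_T = dec$n_T),
                         p, auto_unbox = TRUE, digits = NA)
    manifest$decode <- p
  }

  report <- list(manifest = manifest,
                 config = unclass(config),
                 timing_s = timing,
                 r_version = as.character(getRversion()))
  p <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
  manifest$report <- p
  report$manifest <- manifest
  invisible(report)
}
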