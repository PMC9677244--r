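#' @keywords internal
"_PACKAGE"

REGIONS <- c("hippocampus", "amygdala", "entorhinal")
TRIAL_DURATION_S <- 8

#' Construct a recording session
#'
#' A session bundles the simultaneously recorded units of one recording, the
#' trial metadata of the task, and the per-unit, per-trial spike times.  All
#' spike times are in seconds relative to trial start; every trial spans a
#' fixed 8-s window beginning with 1 s of fixation, followed by 2 s of
#' encoding, 3 s of maintenance and the probe/retrieval period, which ends at
#' the response (truncated at 8 s when the response comes later than 2 s
#' after probe onset).
#'
#' @param session_id,subject_id Character scalars identifying the recording.
#' @param units Data frame with columns `unit_id` (unique character) and
#'   `region` (one of `"hippocampus"`, `"amygdala"`, `"entorhinal"`).
#' @param trials Data frame with columns `trial_id` (integer), `set_size`
#'   (4, 6 or 8), `correct` (logical) and `response_time` (seconds from probe
#'   onset, positive).
#' @param spikes Named list; `spikes[[unit_id]][[as.character(trial_id)]]` is
#'   a non-decreasing numeric vector of spike times in `[0, 8]`.  Missing
#'   entries are treated as empty trains.
#' @return An object of class `spikewm_session`.
#' @export
new_session <- function(session_id, subject_id, units, trials, spikes = list()) {
  s <- structure(
    list(session_id = as.character(session_id),
         subject_id = as.character(subject_id),
         units = as.data.frame(units, stringsAsFactors = FALSE),
         trials = as.data.frame(trials, stringsAsFactors = FALSE),
         spikes = spikes),
    class = "spikewm_session")
  validate_session(s)
  s
}

#' Validate a session object
#'
#' Checks the structural invariants: unique unit ids, known region labels,
#' trial metadata columns, spike times within `[0, 8]` and sorted, and that
#' every spike entry refers to a declared unit and trial.
#'
#' @param session A `spikewm_session`.
#' @return The session, invisibly; errors on violation.
#' @export
validate_session <- function(session) {
  u <- session$units
  tr <- session$trials
  stopifnot(is.data.frame(u), is.data.frame(tr))
  need_u <- c("unit_id", "region")
  if (!all(need_u %in% names(u)))
    stop("units must have columns: ", paste(need_u, collapse = ", "))
  need_t <- c("trial_id", "set_size", "correct", "response_time")
  if (!all(need_t %in% names(tr)))
    stop("trials must have columns: ", paste(need_t, collapse = ", "))
  if (anyDuplicated(u$unit_id))
    stop("duplicate unit_id within session")
  bad_region <- setdiff(unique(u$region), REGIONS)
  if (length(bad_region))
    stop("unknown region label: ", paste(bad_region, collapse = ", "))
  if (nrow(tr)) {
    if (!all(tr$set_size %in% c(4L, 6L, 8L)))
      stop("set_size must be 4, 6 or 8")
    if (any(tr$response_time <= 0))
      stop("response_time must be positive")
    if (anyDuplicated(tr$trial_id)) stop("duplicate trial_id")
  }
  tids <- as.character(tr$trial_id)
  for (uid in names(session$spikes)) {
    if (!uid %in% u$unit_id) stop("spikes for undeclared unit: ", uid)
    for (tid in names(session$spikes[[uid]])) {
      if (!tid %in% tids) stop("spikes for undeclared trial: ", tid)
      st <- session$spikes[[uid]][[tid]]
      if (length(st)) {
        if (is.unsorted(st)) stop("spike times not sorted (unit ", uid, ", trial ", tid, ")")
        if (st[1] < 0 || st[length(st)] > TRIAL_DURATION_S)
          stop("spike time outside [0, 8] (unit ", uid, ", trial ", tid, ")")
      }
    }
  }
  invisible(session)
}

#' @export
print.spikewm_session <- function(x, ...) {
  cat("<spikewm_session> ", x$session_id, " (subject ", x$subject_id, ")\n", sep = "")
  cat("  units:  ", nrow(x$units), " (", paste(sprintf("%s: %d",
      REGIONS, vapply(REGIONS, function(r) sum(x$units$region == r), 0L)),
      collapse = ", "), ")\n", sep = "")
  cat("  trials: ", nrow(x$trials), "\n", sep = "")
  n_spk <- sum(vapply(x$spikes, function(u) sum(lengths(u)), 0))
  cat("  spikes: ", n_spk, "\n", sep = "")
  invisible(x)
}

#' Spike train of one unit in one trial
#'
#' @param session A `spikewm_session`.
#' @param unit_id,trial_id Identifiers; unknown pairs yield an empty train.
#' @return Numeric vector of spike times (possibly empty).
#' @export
get_spikes <- function(session, unit_id, trial_id) {
  st <- session$spikes[[as.character(unit_id)]][[as.character(trial_id)]]
  if (is.null(st)) numeric(0) else st
}

#' Trial-period boundaries
#'
#' Fixation occupies `[0, 1)`, encoding `[1, 3)`, maintenance `[3, 6)` and
#' the probe period `[6, min(6 + response_time, 8))`; all intervals are
#' half-open.  When the response comes later than 2 s after probe onset the
#' recording is truncated at 8 s.
#'
#' @param response_time Response time in seconds from probe onset.
#' @return Data frame with columns `period`, `start`, `end`.
#' @export
trial_periods <- function(response_time) {
  data.frame(
    period = c("fixation", "encoding", "maintenance", "probe"),
    start = c(0, 1, 3, 6),
    end = c(1, 3, 6, min(6 + response_time, TRIAL_DURATION_S)),
    stringsAsFactors = FALSE)
}

#' Read a session from disk
#'
#' Expects the plain-text on-disk layout written by [write_session()]:
#' `spikes.csv` (`unit_id, region, trial_id, spike_time_s`), `trials.csv`
#' (`trial_id, set_size, correct, response_time_s`) and `session.json`
#' (`session_id`, `subject_id`).
#'
#' @param dir_path Directory containing the three files, or the three paths
#'   given individually via `spikes_path`, `trials_path`, `meta_path`.
#' @param spikes_path,trials_path,meta_path Optional explicit file paths.
#' @return A validated `spikewm_session`.
#' @export
read_session <- function(dir_path = NULL, spikes_path = NULL,
                         trials_path = NULL, meta_path = NULL) {
  if (!is.null(dir_path)) {
    spikes_path <- file.path(dir_path, "spikes.csv")
    trials_path <- file.path(dir_path, "trials.csv")
    meta_path <- file.path(dir_path, "session.json")
  }
  spk <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  need <- c("unit_id", "region", "trial_id", "spike_time_s")
  miss <- setdiff(need, names(spk))
  if (length(miss)) stop("spikes file missing column: ", paste(miss, collapse = ", "))
  tr <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  need_t <- c("trial_id", "set_size", "correct", "response_time_s")
  miss <- setdiff(need_t, names(tr))
  if (length(miss)) stop("trials file missing column: ", paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(meta_path)

  if (nrow(spk) && any(spk$spike_time_s < 0 | spk$spike_time_s > TRIAL_DURATION_S))
    stop("spike_time_s outside [0, 8]")

  units <- unique(spk[, c("unit_id", "region")])
  units <- units[order(units$unit_id), , drop = FALSE]
  rownames(units) <- NULL
  if (!nrow(units)) units <- data.frame(unit_id = character(0), region = character(0))

  trials <- data.frame(trial_id = as.integer(tr$trial_id),
                       set_size = as.integer(tr$set_size),
                       correct = as.logical(tr$correct),
                       response_time = as.numeric(tr$response_time_s))

  spikes <- list()
  if (nrow(spk)) {
    spk <- spk[order(spk$unit_id, spk$trial_id, spk$spike_time_s), ]
    spikes <- lapply(split(spk, spk$unit_id), function(d)
      lapply(split(d$spike_time_s, as.character(d$trial_id)), as.numeric))
  }
  new_session(meta$session_id, meta$subject_id, units, trials, spikes)
}

#' Write a session to disk
#'
#' Inverse of [read_session()]; round-trips up to floating-point text
#' representation (15 significant digits).
#'
#' @param session A `spikewm_session`.
#' @param dir_path Output directory (created if absent).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_session <- function(session, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  region_of <- stats::setNames(session$units$region, session$units$unit_id)
  rows <- list()
  for (uid in names(session$spikes)) {
    for (tid in names(session$spikes[[uid]])) {
      st <- session$spikes[[uid]][[tid]]
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, region = unname(region_of[uid]),
          trial_id = as.integer(tid), spike_time_s = st)
    }
  }
  spk <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), region = character(0),
               trial_id = integer(0), spike_time_s = numeric(0))
  spk <- spk[order(spk$unit_id, spk$trial_id, spk$spike_time_s), ]
  paths <- file.path(dir_path, c("spikes.csv", "trials.csv", "session.json"))
  old <- options(digits = 15); on.exit(options(old))
  utils::write.csv(spk, paths[1], row.names = FALSE, quote = FALSE)
  tr_out <- data.frame(trial_id = session$trials$trial_id,
                       set_size = session$trials$set_size,
                       correct = session$trials$correct,
                       response_time_s = session$trials$response_time)
  utils::write.csv(tr_out, paths[2], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(session_id = session$session_id,
                            subject_id = session$subject_id),
                       paths[3], auto_unbox = TRUE)
  invisible(paths)
}

#' Total recorded time of a session
#'
#' Number of trials times the fixed 8-s trial length; used by the rate
#' filter's pooled-count convention.
#' @param session A `spikewm_session`.
#' @return Seconds.
#' @keywords internal
session_recorded_time <- function(session) {
  nrow(session$trials) * TRIAL_DURATION_S
}

#' Mean firing rate of each unit across all trials
#'
#' @param session A `spikewm_session`.
#' @param per_trial If `TRUE`, average the per-trial rates; the default pools
#'   all spike counts over the total recorded time.  With the fixed 8-s trial
#'   length the two conventions coincide.
#' @return Named numeric vector (Hz), one entry per declared unit.
#' @export
unit_rates <- function(session, per_trial = FALSE) {
  n_tr <- nrow(session$trials)
  vapply(session$units$unit_id, function(uid) {
    counts <- vapply(as.character(session$trials$trial_id),
                     function(tid) length(get_spikes(session, uid, tid)), 0)
    if (n_tr == 0) return(NA_real_)
    if (per_trial) mean(counts / TRIAL_DURATION_S)
    else sum(counts) / (n_tr * TRIAL_DURATION_S)
  }, 0)
}

#' Restrict a session to a subset of units
#' @param session A `spikewm_session`.
#' @param unit_ids Units to keep.
#' @return A `spikewm_session` with only those units and their spikes.
#' @export
subset_units <- function(session, unit_ids) {
  keep <- session$units$unit_id %in% unit_ids
  session$units <- session$units[keep, , drop = FALSE]
  rownames(session$units) <- NULL
  session$spikes <- session$spikes[names(session$spikes) %in% unit_ids]
  session
}
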