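#' Logit schedule for adaptive change-point detection
#' @keywords internal
CP_LOGIT_SCHEDULE <- seq(1.3, 5.9, by = 0.2)

# recursive CP search on one window at a fixed p threshold
.cp_recurse <- function(spike_times, a, b, p_thresh) {
  st <- spike_times[spike_times >= a & spike_times < b]
  m <- length(st)
  if (m < 2) return(numeric(0))
  # deviation of empirical cumulative spike count from the uniform expectation
  dev <- seq_len(m) - m * (st - a) / (b - a)
  i <- which.max(abs(dev))
  i <- which(abs(dev) >= abs(dev[i]) - 1e-12)[1]  # earliest maximal point
  cand <- st[i]
  frac <- (cand - a) / (b - a)
  if (frac <= 0 || frac >= 1) return(numeric(0))
  p <- stats::binom.test(i, m, p = frac)$p.value
  if (p < p_thresh)
    c(cand, .cp_recurse(spike_times, cand, b, p_thresh))
  else numeric(0)
}

#' Detect firing-rate change points in a spike train
#'
#' Compares the empirical cumulative spike count with the uniform (perfectly
#' regular, count-matched) expectation.  The earliest time of maximal
#' absolute deviation is a candidate change point, accepted when a two-sided
#' binomial test on the spike counts before versus after it (success
#' probability = the fraction of the window before the candidate) falls
#' below the p-value threshold implied by `logit` (`P = 1/(1 + exp(logit))`).
#' On acceptance the search recurses on the segment after the change point.
#'
#' @param spike_times Sorted spike times.
#' @param window Two-element analysis window `[a, b)` (default the full
#'   8-s trial).
#' @param logit Confidence threshold on the decimal-logit scale,
#'   `logit = log10((1-P)/P)`; the adaptive schedule spans 1.3 to 5.9 in
#'   steps of 0.2, i.e. P from about 0.05 down to 1e-6.
#' @return List with `change_points` (increasing times) and `logit`.
#' @export
change_points <- function(spike_times, window = c(0, TRIAL_DURATION_S),
                          logit = 1.3) {
  p_thresh <- 1 / (1 + 10^logit)
  cps <- .cp_recurse(spike_times, window[1], window[2], p_thresh)
  list(change_points = cps, logit = logit)
}

#' Adapt the change-point threshold on fixation activity
#'
#' Raises the logit along the schedule until none of the unit's fixation
#' periods (pooled over trials) yields a change point; fixation is baseline
#' activity, so any detection there is a false positive.  Returns the final
#' logit (the schedule's last value if fixation never becomes clean).
#'
#' @param fixation_trains List of spike-time vectors, one per trial,
#'   restricted to the fixation window `[0, 1)`.
#' @param schedule Candidate logits, ascending.
#' @return The adapted logit.
#' @export
adapt_cp_logit <- function(fixation_trains, schedule = CP_LOGIT_SCHEDULE) {
  for (lg in schedule) {
    any_cp <- FALSE
    for (st in fixation_trains) {
      if (length(change_points(st, window = c(0, 1), logit = lg)$change_points)) {
        any_cp <- TRUE; break
      }
    }
    if (!any_cp) return(lg)
  }
  schedule[length(schedule)]
}

#' Per-unit change-point counts with the adapted threshold
#'
#' For each unit the logit is adapted on its pooled fixation periods, then
#' change points are counted per trial over the full trial window.
#'
#' @param session A `spikewm_session`.
#' @return Data frame with columns `unit_id`, `trial_id`, `n_cp`, `logit`.
#' @export
session_change_points <- function(session) {
  tids <- as.character(session$trials$trial_id)
  rows <- list()
  for (uid in session$units$unit_id) {
    fix <- lapply(tids, function(tid) {
      st <- get_spikes(session, uid, tid)
      st[st < 1]
    })
    lg <- adapt_cp_logit(fix)
    n_cp <- vapply(tids, function(tid)
      length(change_points(get_spikes(session, uid, tid),
                           logit = lg)$change_points), 0L)
    rows[[uid]] <- data.frame(unit_id = uid, trial_id = as.integer(tids),
                              n_cp = n_cp, logit = lg,
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correlation between change-point counts and LvR across units
#'
#' Per unit, the mean change-point count and the mean gated LvR across
#' trials are computed; per region, their Pearson correlation with the
#' t-statistic and p-value.  Burstier units show more detected rate
#' changes, so a positive correlation validates LvR as an irregularity
#' measure.
#'
#' @param sessions List of `spikewm_session`.
#' @param R_s Refractoriness constant for the per-trial LvR.
#' @return Data frame with columns `region`, `n_units`, `r`, `t`, `df`, `p`;
#'   regions with fewer than 3 units are dropped with a message.
#' @export
cp_lvr_correlation <- function(sessions, R_s = 0.005) {
  per_unit <- list()
  for (s in sessions) {
    cp <- session_change_points(s)
    for (uid in s$units$unit_id) {
      tids <- as.character(s$trials$trial_id)
      lv <- vapply(tids, function(tid)
        lvr_gated(get_spikes(s, uid, tid), R_s = R_s), 0)
      per_unit[[paste(s$session_id, uid)]] <- data.frame(
        region = s$units$region[s$units$unit_id == uid],
        mean_cp = mean(cp$n_cp[cp$unit_id == uid]),
        mean_lvr = mean(lv, na.rm = TRUE))
    }
  }
  d <- do.call(rbind, per_unit)
  d <- d[is.finite(d$mean_lvr), , drop = FALSE]
  out <- lapply(split(d, d$region), function(g) {
    if (nrow(g) < 3) return(NULL)
    ct <- stats::cor.test(g$mean_cp, g$mean_lvr)
    data.frame(region = g$region[1], n_units = nrow(g),
               r = unname(ct$estimate), t = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) stop("fewer than 3 units in every region")
  rownames(out) <- NULL
  out
}
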