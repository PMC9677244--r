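#' Smoothed instantaneous firing rates for one trial
#'
#' Each unit's spike raster is convolved with a Gaussian kernel (default
#' bandwidth 25 ms) and sampled on a regular grid (default 10-ms step); the
#' population rate is the across-unit average.  The kernel is truncated at
#' the trial edges without renormalization (naive convolution), which
#' depresses estimates within a couple of bandwidths of 0 and 8 s.
#'
#' @param session A `spikewm_session` with at least one unit.
#' @param trial_id Trial to smooth.
#' @param bandwidth_s Gaussian kernel s.d. (default 0.025).
#' @param step_s Grid step (default 0.010).
#' @return List with `time` (grid), `unit_rates` (units x time matrix, Hz)
#'   and `population` (mean across units).
#' @export
instantaneous_rates <- function(session, trial_id, bandwidth_s = 0.025,
                                step_s = 0.010) {
  uids <- session$units$unit_id
  if (!length(uids)) stop("session has no units")
  grid <- seq(0, TRIAL_DURATION_S, by = step_s)
  m <- matrix(0, nrow = length(uids), ncol = length(grid),
              dimnames = list(uids, NULL))
  for (u in seq_along(uids)) {
    st <- get_spikes(session, uids[u], trial_id)
    if (length(st))
      m[u, ] <- vapply(grid, function(t)
        sum(stats::dnorm(t - st, sd = bandwidth_s)), 0)
  }
  list(time = grid, unit_rates = m, population = colMeans(m))
}

#' Population-burst detection threshold for a session
#'
#' Per trial, the single-unit firing rates are averaged over the whole
#' trial window, then across units; the threshold is the mean plus three
#' sample standard deviations (n-1 denominator) of these per-trial
#' population averages.
#'
#' @param session A `spikewm_session` with at least 2 trials.
#' @param bandwidth_s,step_s Smoothing parameters, as in
#'   [instantaneous_rates()].
#' @param rates Optional precomputed list of [instantaneous_rates()]
#'   results, one per trial (avoids re-smoothing).
#' @param sd_source `"trial_means"` (default): the s.d. of the per-trial
#'   averages; `"rate_series"`: the s.d. of the pooled population-rate
#'   samples across time and trials, a conservative alternative for data
#'   whose trial means barely vary (see the methods vignette).
#' @return Threshold in Hz.
#' @export
burst_threshold <- function(session, bandwidth_s = 0.025, step_s = 0.010,
                            rates = NULL,
                            sd_source = c("trial_means", "rate_series")) {
  sd_source <- match.arg(sd_source)
  tids <- as.character(session$trials$trial_id)
  if (is.null(rates))
    rates <- lapply(tids, function(tid)
      instantaneous_rates(session, tid, bandwidth_s, step_s))
  if (length(rates) < 2) stop("at least 2 trials required")
  per_trial <- vapply(rates, function(r) mean(rowMeans(r$unit_rates)), 0)
  s <- if (sd_source == "trial_means") stats::sd(per_trial)
       else stats::sd(unlist(lapply(rates, `[[`, "population")))
  th <- mean(per_trial) + 3 * s
  if (th <= 0) warning("threshold is not positive; every excursion will be a burst")
  th
}

#' Detect population bursts in one trial's population-rate series
#'
#' Maximal runs of grid samples where the population rate exceeds the
#' threshold become candidate events when they last at least
#' `min_duration_s`; an event spans from its first sample to one step past
#' its last.  If two consecutive events are closer (tail to head) than
#' `proximity_s`, the one with the lower peak rate is discarded; the scan
#' restarts after each removal.
#'
#' @param rate_series Result of [instantaneous_rates()] (or any list with
#'   `time` and `population`).
#' @param threshold Rate threshold in Hz.
#' @param min_duration_s Minimum event duration (default 0.1).
#' @param proximity_s Tail-to-head exclusion distance (default 0.15).
#' @return Data frame of events: `start, end, peak_hz` (possibly 0 rows).
#' @export
detect_bursts <- function(rate_series, threshold, min_duration_s = 0.1,
                          proximity_s = 0.15) {
  tm <- rate_series$time; pop <- rate_series$population
  step <- if (length(tm) > 1) tm[2] - tm[1] else 0.01
  above <- pop > threshold
  ev <- list()
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    dur <- r$lengths[k] * step
    if (dur >= min_duration_s - 1e-12)
      ev[[length(ev) + 1L]] <- data.frame(
        start = tm[starts[k]], end = tm[ends[k]] + step,
        peak_hz = max(pop[starts[k]:ends[k]]))
  }
  if (!length(ev))
    return(data.frame(start = numeric(0), end = numeric(0), peak_hz = numeric(0)))
  d <- do.call(rbind, ev)
  repeat {
    if (nrow(d) < 2) break
    gaps <- d$start[-1] - d$end[-nrow(d)]
    bad <- which(gaps < proximity_s - 1e-12)
    if (!length(bad)) break
    k <- bad[1]
    drop <- if (d$peak_hz[k] <= d$peak_hz[k + 1]) k else k + 1L
    d <- d[-drop, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Assign a burst event to a trial period
#'
#' The event is assigned to the unique period containing at least 80% of
#' its duration (boundary inclusive); the probe period's right edge is the
#' response time (capped at 8 s).  Events not reaching 80% in any period
#' are `"unassigned"`.
#'
#' @param start,end Event boundaries in seconds.
#' @param response_time The trial's response time (seconds from probe
#'   onset).
#' @param min_fraction Assignment threshold (default 0.8).
#' @return Period name or `"unassigned"`.
#' @export
assign_period <- function(start, end, response_time, min_fraction = 0.8) {
  per <- trial_periods(response_time)
  dur <- end - start
  if (dur <= 0) return("unassigned")
  frac <- pmax(0, pmin(end, per$end) - pmax(start, per$start)) / dur
  k <- which(frac >= min_fraction - 1e-12)
  if (length(k) == 1) per$period[k] else "unassigned"
}

#' Sparsity of a burst composition vector
#'
#' With `w` scaled to unit Euclidean length,
#' `sparsity = 1 - (sqrt(n) - sum(|w_hat|)) / (sqrt(n) - 1)`.
#' 0 means a single unit dominates the burst (one-hot composition); 1 means
#' all units contribute equally.  Invariant to positive rescaling of `w`.
#'
#' @param w Non-negative composition vector, length >= 2, not all zero.
#' @return Value in `[0, 1]`.
#' @export
sparsity <- function(w) {
  n <- length(w)
  if (n < 2) stop("composition needs at least 2 units")
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("all-zero composition")
  what <- w / nrm
  1 - (sqrt(n) - sum(abs(what))) / (sqrt(n) - 1)
}

#' Unit composition of a burst event
#'
#' Per-unit mean of the smoothed firing rates over the event window
#' `[start, end)`.
#'
#' @param rate_series Result of [instantaneous_rates()].
#' @param start,end Event boundaries.
#' @return Named numeric vector `w`, one entry per unit.
#' @export
burst_composition <- function(rate_series, start, end) {
  ix <- rate_series$time >= start & rate_series$time < end
  if (!any(ix)) stop("event window contains no grid samples")
  rowMeans(rate_series$unit_rates[, ix, drop = FALSE])
}

#' Composition-weighted LvR of a burst
#'
#' Weighted mean of the single-unit LvR values using the composition
#' entries as weights; units with missing LvR are dropped and the weights
#' renormalized.
#'
#' @param per_unit_lvr Named LvR values (`NA` = missing).
#' @param w Composition weights, same units.
#' @return Weighted mean, or `NA` when all weight lies on missing units.
#' @export
burst_weighted_lvr <- function(per_unit_lvr, w) {
  ok <- is.finite(per_unit_lvr) & w > 0
  if (!any(ok) || sum(w[ok]) == 0) return(NA_real_)
  sum(w[ok] * per_unit_lvr[ok]) / sum(w[ok])
}

#' Detect and characterize population bursts across a session
#'
#' Smooths every trial, derives the session threshold, detects events, and
#' annotates each with peak rate, composition, sparsity, weighted LvR (from
#' per-trial single-unit gated LvR) and the assigned trial period.
#'
#' @param session A `spikewm_session`.
#' @param bandwidth_s,step_s Smoothing parameters.
#' @param min_duration_s,proximity_s Detection parameters.
#' @param R_s Refractoriness for the per-unit LvR.
#' @param sd_source Threshold convention, see [burst_threshold()].
#' @return Data frame: `trial_id, start, end, peak_hz, sparsity,
#'   weighted_lvr, period`.
#' @export
session_bursts <- function(session, bandwidth_s = 0.025, step_s = 0.010,
                           min_duration_s = 0.1, proximity_s = 0.15,
                           R_s = 0.005, sd_source = "trial_means") {
  tids <- as.character(session$trials$trial_id)
  rates <- lapply(tids, function(tid)
    instantaneous_rates(session, tid, bandwidth_s, step_s))
  th <- burst_threshold(session, rates = rates, sd_source = sd_source)
  rows <- list()
  for (k in seq_along(tids)) {
    ev <- detect_bursts(rates[[k]], th, min_duration_s, proximity_s)
    if (!nrow(ev)) next
    rt <- session$trials$response_time[k]
    lv <- vapply(session$units$unit_id, function(u)
      lvr_gated(get_spikes(session, u, tids[k]), R_s = R_s), 0)
    for (j in seq_len(nrow(ev))) {
      w <- burst_composition(rates[[k]], ev$start[j], ev$end[j])
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = as.integer(tids[k]), start = ev$start[j], end = ev$end[j],
        peak_hz = ev$peak_hz[j],
        sparsity = if (length(w) >= 2 && any(w > 0)) sparsity(w) else NA_real_,
        weighted_lvr = burst_weighted_lvr(lv, w),
        period = assign_period(ev$start[j], ev$end[j], rt),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(trial_id = integer(0), start = numeric(0),
                      end = numeric(0), peak_hz = numeric(0),
                      sparsity = numeric(0), weighted_lvr = numeric(0),
                      period = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Burst density across trials with bootstrap confidence band
#'
#' Per 10-ms bin, the fraction of trials with an ongoing burst, with a
#' percentile bootstrap confidence interval from resampling trials.  With
#' `align = "response"` the time axis is relative to the response and
#' trials with response times above 2 s (truncated probe recordings) are
#' discarded.
#'
#' @param events Data frame of events as from [session_bursts()] (columns
#'   `trial_id, start, end`), possibly concatenated across sessions with a
#'   session-unique `trial` key.
#' @param trials Data frame with `trial_id` and `response_time` covering
#'   every analysed trial (including burst-free ones).
#' @param align `"trial_start"` or `"response"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param step_s Bin width (default 0.010).
#' @param window Time span of the density axis; defaults to `[0, 8]` for
#'   trial-start alignment and `[-3, 1]` for response alignment.
#' @return List with `time`, `density`, `lo`, `hi`, `n_trials`.
#' @export
burst_density <- function(events, trials, align = c("trial_start", "response"),
                          n_boot = 1000, step_s = 0.010, window = NULL) {
  align <- match.arg(align)
  tr <- trials
  if (align == "response") tr <- tr[tr$response_time <= 2, , drop = FALSE]
  if (is.null(window))
    window <- if (align == "trial_start") c(0, TRIAL_DURATION_S) else c(-3, 1)
  grid <- seq(window[1], window[2], by = step_s)
  n_tr <- nrow(tr)
  ind <- matrix(0L, nrow = n_tr, ncol = length(grid))
  if (n_tr) for (k in seq_len(n_tr)) {
    tid <- tr$trial_id[k]
    off <- if (align == "response") 6 + tr$response_time[k] else 0
    ev <- events[events$trial_id == tid, , drop = FALSE]
    for (j in seq_len(nrow(ev)))
      ind[k, grid >= ev$start[j] - off & grid < ev$end[j] - off] <- 1L
  }
  dens <- if (n_tr) colMeans(ind) else rep(0, length(grid))
  if (n_tr) {
    boot <- matrix(0, nrow = n_boot, ncol = length(grid))
    for (b in seq_len(n_boot))
      boot[b, ] <- colMeans(ind[sample.int(n_tr, n_tr, replace = TRUE), ,
                                drop = FALSE])
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  } else ci <- matrix(0, 2, length(grid))
  list(time = grid, density = dens, lo = ci[1, ], hi = ci[2, ], n_trials = n_tr)
}
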