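#' Remove units with low average firing rate
#'
#' Keeps only units whose pooled spike count divided by the total recorded
#' time across trials is strictly greater than `min_rate_hz`.
#'
#' @param session A `spikewm_session`.
#' @param min_rate_hz Rate threshold in Hz (default 1).
#' @param per_trial Passed to [unit_rates()]: average per-trial rates instead
#'   of pooling counts (equivalent here because trials have fixed length).
#' @return The filtered session.
#' @export
filter_units_by_rate <- function(session, min_rate_hz = 1.0, per_trial = FALSE) {
  r <- unit_rates(session, per_trial = per_trial)
  keep <- names(r)[!is.na(r) & r > min_rate_hz]
  subset_units(session, keep)
}

#' Binarize a spike train
#'
#' Bin `i` covers the half-open interval
#' `[t_start + i*bin, t_start + (i+1)*bin)`; a bin is 1 iff it contains at
#' least one spike.  A spike exactly on a boundary belongs to the later bin.
#'
#' @param spike_times Numeric vector of spike times (seconds).
#' @param bin_width_s Bin width in seconds (> 0).
#' @param t_start,t_end Analysis interval; `t_end` must exceed `t_start`.
#' @return Integer 0/1 vector of length `ceiling((t_end - t_start)/bin)`.
#' @export
binarize <- function(spike_times, bin_width_s, t_start, t_end) {
  if (bin_width_s <= 0) stop("bin_width_s must be > 0")
  if (t_end <= t_start) stop("t_end must be greater than t_start")
  n_bins <- ceiling((t_end - t_start) / bin_width_s - 1e-9)
  out <- integer(n_bins)
  st <- spike_times[spike_times >= t_start & spike_times < t_end]
  if (length(st)) {
    idx <- floor((st - t_start) / bin_width_s) + 1L
    idx <- pmin(idx, n_bins)
    out[unique(idx)] <- 1L
  }
  out
}

#' Jaccard similarity of two binary sequences
#'
#' Intersection over union of the 1-entries.  Defined as 0 when both
#' sequences are all-zero.
#'
#' @param binary_a,binary_b Equal-length 0/1 vectors.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(binary_a, binary_b) {
  if (length(binary_a) != length(binary_b)) stop("length mismatch")
  a <- binary_a != 0; b <- binary_b != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Remove cross-talk units by pairwise Jaccard screening
#'
#' All trials are concatenated, spike trains binarized at 1 ms, and pairwise
#' Jaccard similarities computed between simultaneously recorded units.  The
#' unit participating in the largest number of supra-threshold pairs is
#' removed (ties broken by lower firing rate, then by `unit_id` order) and
#' the screen repeated until no pair exceeds the threshold.
#'
#' @param session A `spikewm_session`.
#' @param bin_width_s Binarization bin (default 1 ms).
#' @param threshold Suspicious-similarity threshold (default 0.3).
#' @return List with `session` (filtered) and `removed` (character vector of
#'   discarded unit ids, in removal order).
#' @export
crosstalk_filter <- function(session, bin_width_s = 0.001, threshold = 0.3) {
  uids <- session$units$unit_id
  removed <- character(0)
  if (length(uids) < 2)
    return(list(session = session, removed = removed))

  tids <- as.character(session$trials$trial_id)
  n_per_trial <- ceiling(TRIAL_DURATION_S / bin_width_s - 1e-9)
  # concatenated binarized trains, one row per unit
  bin_of <- lapply(uids, function(uid) {
    v <- integer(n_per_trial * length(tids))
    for (k in seq_along(tids)) {
      st <- get_spikes(session, uid, tids[k])
      if (length(st))
        v[(k - 1L) * n_per_trial +
            which(binarize(st, bin_width_s, 0, TRIAL_DURATION_S) == 1L)] <- 1L
    }
    which(v == 1L)  # store 1-bin indices only
  })
  names(bin_of) <- uids
  rates <- unit_rates(session)

  jac <- function(i, j) {
    ai <- bin_of[[i]]; aj <- bin_of[[j]]
    u <- length(union(ai, aj))
    if (u == 0) 0 else length(intersect(ai, aj)) / u
  }

  active <- uids
  repeat {
    if (length(active) < 2) break
    m <- length(active)
    over <- matrix(FALSE, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      over[i, j] <- over[j, i] <- jac(active[i], active[j]) > threshold
    n_over <- rowSums(over)
    if (all(n_over == 0)) break
    worst <- which(n_over == max(n_over))
    if (length(worst) > 1) {
      r <- rates[active[worst]]
      worst <- worst[r == min(r)]
      if (length(worst) > 1)
        worst <- worst[order(active[worst])][1]
    }
    removed <- c(removed, active[worst])
    active <- active[-worst]
  }
  list(session = subset_units(session, active), removed = removed)
}

#' Flag units with elevated activity in a trial period
#'
#' Per unit, the per-trial spike counts in the requested period are compared
#' with the fixation-period counts (rates normalised for the unequal period
#' lengths) with a one-sided paired Wilcoxon signed-rank test at
#' `alpha = 0.05`.  Units recorded in fewer than 5 trials are indeterminate
#' (`NA`).
#'
#' @param session A `spikewm_session`.
#' @param period `"maintenance"` or `"probe"`.
#' @param alpha Significance level (default 0.05).
#' @return Named logical vector per unit (`NA` = indeterminate).
#' @export
flag_period_elevated_units <- function(session, period, alpha = 0.05) {
  if (!period %in% c("maintenance", "probe"))
    stop("period must be 'maintenance' or 'probe'")
  tids <- as.character(session$trials$trial_id)
  rts <- session$trials$response_time
  out <- stats::setNames(rep(NA, nrow(session$units)), session$units$unit_id)
  if (length(tids) < 5) return(out)
  for (uid in session$units$unit_id) {
    rate_p <- rate_f <- numeric(length(tids))
    for (k in seq_along(tids)) {
      per <- trial_periods(rts[k])
      pr <- per[per$period == period, ]
      fx <- per[per$period == "fixation", ]
      st <- get_spikes(session, uid, tids[k])
      dur_p <- pr$end - pr$start
      rate_p[k] <- if (dur_p > 0) sum(st >= pr$start & st < pr$end) / dur_p else NA
      rate_f[k] <- sum(st >= fx$start & st < fx$end) / (fx$end - fx$start)
    }
    ok <- !is.na(rate_p)
    if (sum(ok) < 5 || all(rate_p[ok] == rate_f[ok])) {
      out[uid] <- if (sum(ok) < 5) NA else FALSE
      next
    }
    p <- suppressWarnings(
      stats::wilcox.test(rate_p[ok], rate_f[ok], paired = TRUE,
                         alternative = "greater", exact = FALSE)$p.value)
    out[uid] <- !is.na(p) && p < alpha
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input values must lie in
#' `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
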