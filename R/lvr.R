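#' Refractoriness-corrected local variation (LvR)
#'
#' For a sequence of inter-spike intervals \eqn{I_1, \dots, I_n},
#' \deqn{LvR = \frac{3}{n-1}\sum_{i=1}^{n-1}
#'   \left(1 - \frac{4 I_i I_{i+1}}{(I_i + I_{i+1})^2}\right)
#'   \left(1 + \frac{4R}{I_i + I_{i+1}}\right),}
#' where \eqn{R} is the refractoriness constant (5 ms for single units;
#' 0 for combined trains, where the correction is dropped).  LvR is about 1
#' for Poisson firing, below 1 for regular and above 1 for bursty trains,
#' and is invariant to rescaling all intervals and \eqn{R} by a common
#' factor.
#'
#' @param isis Positive inter-spike intervals in seconds (at least 2).
#' @param R_s Refractoriness constant in seconds (default 5 ms).
#' @return The LvR value (non-negative scalar).
#' @export
lvr <- function(isis, R_s = 0.005) {
  if (any(isis <= 0)) stop("all inter-spike intervals must be > 0")
  n <- length(isis)
  if (n < 2) return(NA_real_)
  i1 <- isis[-n]; i2 <- isis[-1]
  s <- i1 + i2
  3 / (n - 1) * sum((1 - 4 * i1 * i2 / s^2) * (1 + 4 * R_s / s))
}

#' LvR of a spike train with a minimum-spike gate
#'
#' Computes [lvr()] on the consecutive inter-spike intervals of a sorted
#' spike train, returning `NA` when the train holds fewer than `min_spikes`
#' spikes (such windows are discarded downstream rather than set to zero).
#'
#' @param spike_times Sorted spike times in seconds.
#' @param R_s Refractoriness constant in seconds.
#' @param min_spikes Minimum spike count for a valid value (default 5).
#' @return LvR value or `NA`.
#' @export
lvr_gated <- function(spike_times, R_s = 0.005, min_spikes = 5) {
  if (length(spike_times) < min_spikes) return(NA_real_)
  isis <- diff(spike_times)
  isis <- isis[isis > 0]
  if (length(isis) < 2) return(NA_real_)
  lvr(isis, R_s)
}

#' Merge the spike trains of simultaneously recorded units
#'
#' Sorted union of 2 or 3 trains from the same trial; exact duplicate times
#' are collapsed to one spike so no zero intervals arise.  Combined-train
#' LvR is conventionally computed with `R_s = 0`.
#'
#' @param trains List of numeric spike-time vectors.
#' @return Sorted merged spike times.
#' @export
combine_trains <- function(trains) {
  sort(unique(unlist(trains, use.names = FALSE)))
}

#' Sliding-window LvR series
#'
#' LvR computed in right-aligned half-open windows `[t - window_s, t)`; the
#' time index of each value is the right edge of its window.  Windows
#' failing the minimum-spike gate are `NA`.
#'
#' @param spike_times Sorted spike times in seconds.
#' @param window_s Window length (default 2 s).
#' @param step_s Step between consecutive right edges (> 0).
#' @param R_s Refractoriness constant.
#' @param t_start,t_end Span of the analysed trial (defaults `[0, 8]`).
#' @param min_spikes Gate for a valid window.
#' @return Data frame with columns `time` (window right edge) and `lvr`.
#' @export
sliding_lvr <- function(spike_times, window_s = 2.0, step_s = 0.05,
                        R_s = 0.005, t_start = 0, t_end = TRIAL_DURATION_S,
                        min_spikes = 5) {
  if (step_s <= 0) stop("step_s must be > 0")
  edges <- seq(t_start + window_s, t_end + 1e-9, by = step_s)
  vals <- vapply(edges, function(e) {
    w <- spike_times[spike_times >= e - window_s & spike_times < e]
    lvr_gated(w, R_s = R_s, min_spikes = min_spikes)
  }, 0)
  data.frame(time = edges, lvr = vals)
}

#' Sliding-window firing rate series
#'
#' Companion to [sliding_lvr()]: spike count divided by window length, on
#' the same right-aligned grid.
#'
#' @inheritParams sliding_lvr
#' @return Data frame with columns `time` and `rate` (Hz).
#' @export
sliding_rate <- function(spike_times, window_s = 2.0, step_s = 0.05,
                         t_start = 0, t_end = TRIAL_DURATION_S) {
  if (step_s <= 0) stop("step_s must be > 0")
  edges <- seq(t_start + window_s, t_end + 1e-9, by = step_s)
  vals <- vapply(edges, function(e)
    sum(spike_times >= e - window_s & spike_times < e) / window_s, 0)
  data.frame(time = edges, rate = vals)
}
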