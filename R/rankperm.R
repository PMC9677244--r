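#' Rank-based dissimilarity between two classes of values
#'
#' Pooled values are rank-transformed ascending (ties receive average
#' ranks); each class's empirical CDF is evaluated at every integer rank
#' 1..N, and the statistic is the sum of the point-wise differences
#' `F_A(r) - F_B(r)` — the signed area between the two rank-CDF curves
#' (unlike the earth-mover's distance, the sign of the difference is kept).
#' Rank transformation makes the statistic invariant to any strictly
#' monotone transform of the values.  Negative values mean class A tends to
#' the larger values (its CDF lags).
#'
#' @param values Numeric vector.
#' @param class_labels Vector with exactly two distinct labels.
#' @param positive Label taken as class A (default the alphabetically
#'   first); by convention the "high workload" or "wrong response" class.
#' @return List with `statistic`, `positive`, `n`.
#' @export
rank_dissimilarity <- function(values, class_labels, positive = NULL) {
  labs <- as.character(class_labels)
  ul <- sort(unique(labs))
  if (length(ul) != 2) stop("exactly 2 classes required")
  if (is.null(positive)) positive <- ul[1]
  if (!positive %in% ul) stop("positive label not present")
  if (!all(table(labs) >= 1)) stop("each class needs at least 1 value")
  N <- length(values)
  r <- rank(values, ties.method = "average")
  ra <- r[labs == positive]; rb <- r[labs != positive]
  grid <- seq_len(N)
  Fa <- vapply(grid, function(g) mean(ra <= g), 0)
  Fb <- vapply(grid, function(g) mean(rb <= g), 0)
  list(statistic = sum(Fa - Fb), positive = positive, n = N)
}

#' Trial-structure-preserving permutation p-value
#'
#' The null distribution of a statistic of pooled (unit x trial) points is
#' generated by permuting the trial-variable assignment within each session:
#' one permutation of the session's trial variables is drawn per iteration
#' and shared by all simultaneously recorded units, preserving both the
#' trial structure and the subject identity.  Two-sided p-value with +1
#' smoothing: `(1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' @param data Data frame with columns `session`, `trial`, `value` — one row
#'   per pooled point (a unit x trial observation).
#' @param trial_var Data frame with columns `session`, `trial`, `var` giving
#'   each trial's variable (response time, class label, ...).
#' @param statistic_fn Function `(values, vars) -> scalar` computed on the
#'   pooled points and their matched trial variables.
#' @param n_perm Number of permutations (default 1000).
#' @return List with `observed`, `p`, `null` (the permuted statistics).
#' @export
permutation_null <- function(data, trial_var, statistic_fn, n_perm = 1000) {
  key <- paste(data$session, data$trial, sep = "\r")
  vkey <- paste(trial_var$session, trial_var$trial, sep = "\r")
  map <- match(key, vkey)
  if (anyNA(map)) stop("data refers to trials absent from trial_var")
  obs <- statistic_fn(data$value, trial_var$var[map])
  by_sess <- split(seq_len(nrow(trial_var)), trial_var$session)
  null <- vapply(seq_len(n_perm), function(i) {
    pv <- trial_var$var
    for (ix in by_sess) pv[ix] <- pv[sample(ix)]
    statistic_fn(data$value, pv[map])
  }, 0)
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(observed = obs, p = p, null = null)
}

#' Subsampled test for combined-unit statistics
#'
#' Combined (2- or 3-unit) LvR pools hold many more points than the
#' single-unit pool; to keep the test comparable, each session's combined
#' points are subsampled (without replacement) to the session's single-unit
#' point count, the permutation test run on the subsample, and the whole
#' process repeated; the summary is the median of the subsample p-values.
#'
#' @param single_data,combined_data Data frames as in [permutation_null()];
#'   `single_data` fixes the per-session point counts.
#' @param trial_var Trial-variable table as in [permutation_null()].
#' @param statistic_fn Statistic `(values, vars) -> scalar`.
#' @param n_subsamples Number of subsampling repetitions (default 100).
#' @param n_perm Permutations inside each repetition (default 1000).
#' @return List with `p_median`, `p_values`, `observed_median`.
#' @export
subsampled_combination_test <- function(single_data, combined_data, trial_var,
                                        statistic_fn, n_subsamples = 100,
                                        n_perm = 1000) {
  n_single <- table(single_data$session)
  by_sess <- split(seq_len(nrow(combined_data)), combined_data$session)
  if (!length(by_sess)) stop("no combined points available")
  ps <- numeric(n_subsamples); obs <- numeric(n_subsamples)
  for (k in seq_len(n_subsamples)) {
    idx <- unlist(lapply(names(by_sess), function(s) {
      ix <- by_sess[[s]]
      m <- if (s %in% names(n_single)) min(length(ix), n_single[[s]]) else length(ix)
      if (m == length(ix)) ix else sample(ix, m)
    }), use.names = FALSE)
    res <- permutation_null(combined_data[idx, , drop = FALSE], trial_var,
                            statistic_fn, n_perm = n_perm)
    ps[k] <- res$p; obs[k] <- res$observed
  }
  list(p_median = stats::median(ps), p_values = ps,
       observed_median = stats::median(obs))
}

#' Pooled LvR points per sliding window
#'
#' For every right-aligned window, the gated LvR of each unit (or unit
#' combination) in each trial, pooled across the given sessions.  Combined
#' orders merge the trains of all pairs/triples of simultaneously recorded
#' units within a region (LvR with `R = 0`).
#'
#' @param sessions List of `spikewm_session`.
#' @param region Restrict to one region (default all units).
#' @param combo_order 1 (single units), 2 or 3 (merged trains).
#' @param window_s,step_s Window geometry (right-aligned).
#' @param R_s Refractoriness; forced to 0 for `combo_order > 1`.
#' @param max_combos Cap on combinations per session (draws this many at
#'   random when exceeded) to bound work on large sessions.
#' @return Data frame `session, trial, member, time, value`.
#' @export
windowed_lvr_points <- function(sessions, region = NULL, combo_order = 1,
                                window_s = 2.0, step_s = 0.25, R_s = 0.005,
                                max_combos = 50) {
  if (combo_order > 1) R_s <- 0
  rows <- list()
  for (s in sessions) {
    uids <- s$units$unit_id
    if (!is.null(region)) uids <- uids[s$units$region == region]
    if (length(uids) < combo_order) next
    groups <- if (combo_order == 1) as.list(uids) else {
      cm <- utils::combn(uids, combo_order, simplify = FALSE)
      if (length(cm) > max_combos) cm[sample.int(length(cm), max_combos)] else cm
    }
    tids <- as.character(s$trials$trial_id)
    for (g in groups) {
      gname <- paste(g, collapse = "+")
      for (tid in tids) {
        st <- if (length(g) == 1) get_spikes(s, g, tid) else
          combine_trains(lapply(g, function(u) get_spikes(s, u, tid)))
        sl <- sliding_lvr(st, window_s = window_s, step_s = step_s, R_s = R_s)
        ok <- is.finite(sl$lvr)
        if (any(ok))
          rows[[length(rows) + 1L]] <- data.frame(
            session = s$session_id, trial = as.integer(tid), member = gname,
            time = sl$time[ok], value = sl$lvr[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(session = character(0), trial = integer(0),
                      member = character(0), time = numeric(0),
                      value = numeric(0)))
  do.call(rbind, rows)
}

#' Time-resolved correlation between LvR and response time
#'
#' Per right-aligned window, the Pearson correlation between the pooled
#' (unit x trial) LvR values and the trials' response times, with a
#' trial-structure-preserving permutation p-value; p-values are BH-adjusted
#' across regions within each window.  Combined orders (2, 3) use the
#' subsampled-combination contract.
#'
#' @param sessions List of `spikewm_session`.
#' @param window_s,step_s Window geometry (defaults 2 s / 250 ms).
#' @param combo_orders Subset of `c(1, 2, 3)`.
#' @param n_perm Permutations per window.
#' @param n_subsamples Subsampling repetitions for combined orders.
#' @param regions Regions to analyse (default all three).
#' @param drop_truncated_rt Drop trials with response time > 2 s (whose
#'   probe window is truncated) before correlating.
#' @return Data frame `region, combo_order, time, n, r, p, p_bh`.
#' @export
timeresolved_rt_correlation <- function(sessions, window_s = 2.0, step_s = 0.25,
                                        combo_orders = 1, n_perm = 1000,
                                        n_subsamples = 100, regions = REGIONS,
                                        drop_truncated_rt = FALSE) {
  rt_tab <- do.call(rbind, lapply(sessions, function(s)
    data.frame(session = s$session_id, trial = s$trials$trial_id,
               var = s$trials$response_time)))
  if (drop_truncated_rt) rt_tab <- rt_tab[rt_tab$var <= 2, , drop = FALSE]
  pearson <- function(v, x) {
    if (stats::sd(v) == 0 || stats::sd(x) == 0) return(NA_real_)
    stats::cor(v, x)
  }
  out <- list()
  for (reg in regions) {
    pts1 <- windowed_lvr_points(sessions, region = reg, combo_order = 1,
                                window_s = window_s, step_s = step_s)
    for (ord in combo_orders) {
      pts <- if (ord == 1) pts1 else
        windowed_lvr_points(sessions, region = reg, combo_order = ord,
                            window_s = window_s, step_s = step_s)
      keep <- paste(pts$session, pts$trial) %in% paste(rt_tab$session, rt_tab$trial)
      pts <- pts[keep, , drop = FALSE]
      for (tm in sort(unique(pts$time))) {
        w <- pts[pts$time == tm, , drop = FALSE]
        if (nrow(w) < 4) next
        if (ord == 1) {
          res <- permutation_null(w, rt_tab, pearson, n_perm = n_perm)
          r_val <- res$observed; p_val <- res$p
        } else {
          w1 <- pts1[pts1$time == tm &
                     paste(pts1$session, pts1$trial) %in%
                       paste(rt_tab$session, rt_tab$trial), , drop = FALSE]
          if (!nrow(w1)) next
          res <- subsampled_combination_test(w1, w, rt_tab, pearson,
                                             n_subsamples = n_subsamples,
                                             n_perm = n_perm)
          r_val <- res$observed_median; p_val <- res$p_median
        }
        if (is.na(r_val)) next
        out[[length(out) + 1L]] <- data.frame(
          region = reg, combo_order = ord, time = tm, n = nrow(w),
          r = r_val, p = p_val, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame())
  d <- do.call(rbind, out)
  d$p_bh <- NA_real_
  for (ord in unique(d$combo_order)) for (tm in unique(d$time)) {
    ix <- d$combo_order == ord & d$time == tm
    if (any(ix)) d$p_bh[ix] <- bh_adjust(d$p[ix])
  }
  d
}

#' First-order partial correlation of LvR and response time given rate
#'
#' Pearson correlation between LvR and response time with the linear effect
#' of firing rate removed from both:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param lvr_values,response_times,firing_rates Equal-length vectors;
#'   incomplete triples are dropped.
#' @return The partial correlation, or `NA` when any variable has zero
#'   variance.
#' @export
partial_correlation_lvr_rt <- function(lvr_values, response_times, firing_rates) {
  ok <- is.finite(lvr_values) & is.finite(response_times) & is.finite(firing_rates)
  x <- lvr_values[ok]; y <- response_times[ok]; z <- firing_rates[ok]
  if (length(x) < 4) stop("at least 4 complete triples required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) return(NA_real_)
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) return(NA_real_)
  (rxy - rxz * ryz) / den
}
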