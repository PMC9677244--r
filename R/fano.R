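#' Spike-count mean/variance points per unit, condition and window
#'
#' Sliding right-aligned windows (default 500 ms, 50-ms step); per
#' unit x condition x window, the across-trial mean and variance of the
#' spike count, plus the normal-theory standard error of the variance,
#' `var * sqrt(2 / (n - 1))`, used as regression weight downstream.
#' Conditions with fewer than 2 trials are omitted.
#'
#' @param session A `spikewm_session`.
#' @param window_s,step_s Window geometry (defaults 0.5 / 0.05).
#' @param conditions Named list mapping condition label to the set sizes it
#'   covers (default one condition per set size); or `NULL` to pool all
#'   trials into one condition.
#' @param t_start,t_end Analysis span (default `[0, 8]`).
#' @param trial_subset Optional integer trial ids restricting the trials
#'   used (the undersampling hook).
#' @return Data frame `unit_id, condition, time, mean, var, se_var, n`.
#' @export
window_counts <- function(session, window_s = 0.5, step_s = 0.05,
                          conditions = list(`4` = 4, `6` = 6, `8` = 8),
                          t_start = 0, t_end = TRIAL_DURATION_S,
                          trial_subset = NULL) {
  tr <- session$trials
  if (!is.null(trial_subset)) tr <- tr[tr$trial_id %in% trial_subset, , drop = FALSE]
  if (is.null(conditions)) conditions <- list(all = c(4, 6, 8))
  edges <- seq(t_start + window_s, t_end + 1e-9, by = step_s)
  rows <- list()
  for (uid in session$units$unit_id) {
    # counts matrix: trials x windows
    cnt <- t(vapply(as.character(tr$trial_id), function(tid) {
      st <- get_spikes(session, uid, tid)
      vapply(edges, function(e) sum(st >= e - window_s & st < e), 0)
    }, numeric(length(edges))))
    for (cond in names(conditions)) {
      ix <- tr$set_size %in% conditions[[cond]]
      n <- sum(ix)
      if (n < 2) next
      mu <- colMeans(cnt[ix, , drop = FALSE])
      vv <- apply(cnt[ix, , drop = FALSE], 2, stats::var)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = uid, condition = cond, time = edges,
        mean = mu, var = vv, se_var = vv * sqrt(2 / (n - 1)), n = n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(unit_id = character(0), condition = character(0),
                      time = numeric(0), mean = numeric(0), var = numeric(0),
                      se_var = numeric(0), n = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# histogram bin index of a mean count (bin width 0.5)
.mm_bin <- function(m, bin = 0.5) floor(m / bin)

#' Greatest common distribution of mean spike counts
#'
#' Histogram (bin width 0.5 by default) of the mean counts in every window;
#' the target distribution keeps, per bin, the minimum count over windows,
#' so every window can be downsampled to it.
#'
#' @param points Data frame from [window_counts()].
#' @param bin Histogram bin width (default 0.5).
#' @param by_condition If `TRUE`, every condition x window cell must be able
#'   to match the target on its own (used when conditions are compared
#'   directly); the default pools all points of a time window, the
#'   unit x condition bookkeeping of the standard calculation.
#' @return Named integer vector: target count per bin index.
#' @export
greatest_common_distribution <- function(points, bin = 0.5,
                                         by_condition = FALSE) {
  if (!nrow(points)) stop("no points")
  points$bin <- .mm_bin(points$mean, bin)
  wkey <- if (by_condition && "condition" %in% names(points))
    paste(points$condition, points$time) else as.character(points$time)
  windows <- unique(wkey)
  bins <- sort(unique(points$bin))
  tab <- matrix(0L, nrow = length(windows), ncol = length(bins),
                dimnames = list(NULL, as.character(bins)))
  for (k in seq_along(windows)) {
    t <- table(points$bin[wkey == windows[k]])
    tab[k, names(t)] <- as.integer(t)
  }
  target <- apply(tab, 2, min)
  target <- target[target > 0]
  if (!length(target))
    warning("no mean-count bin is populated in every window; ",
            "mean matching leaves no points")
  target
}

#' Mean-matched Fano factor series
#'
#' Per window and repetition, points are randomly discarded so the
#' histogram of mean counts matches the common target; the Fano factor is
#' the slope of the zero-intercept weighted least-squares regression of
#' variance on mean, each point weighted by `1 / (0.01 + SE(variance))`.
#' The mean FF and a 95% percentile interval over the repetitions are
#' reported per window.
#'
#' @param points Data frame from [window_counts()].
#' @param target_hist Target histogram from
#'   [greatest_common_distribution()]; computed from `points` when `NULL`.
#' @param n_repeats Mean-matching repetitions (default 50).
#' @param bin Histogram bin width (default 0.5).
#' @return List with `series` (data frame `time, ff, lo, hi`) and `repeats`
#'   (windows x repetitions matrix, for cluster tests).
#' @export
mean_matched_ff <- function(points, target_hist = NULL, n_repeats = 50,
                            bin = 0.5) {
  if (is.null(target_hist)) target_hist <- greatest_common_distribution(points, bin)
  points$bin <- .mm_bin(points$mean, bin)
  windows <- sort(unique(points$time))
  reps <- matrix(NA_real_, nrow = length(windows), ncol = n_repeats)
  if (!length(target_hist))
    return(list(series = data.frame(time = windows, ff = NA_real_,
                                    lo = NA_real_, hi = NA_real_),
                repeats = reps))
  for (k in seq_along(windows)) {
    w <- points[points$time == windows[k], , drop = FALSE]
    cnt <- table(w$bin)
    for (b in names(target_hist))
      if (is.na(cnt[b]) || cnt[b] < target_hist[[b]])
        stop("window ", windows[k], " cannot match the target histogram")
    for (r in seq_len(n_repeats)) {
      keep <- unlist(lapply(names(target_hist), function(b) {
        ix <- which(w$bin == as.integer(b))
        if (length(ix) == target_hist[[b]]) ix else
          sample(ix, target_hist[[b]])
      }), use.names = FALSE)
      x <- w$mean[keep]; y <- w$var[keep]
      wt <- 1 / (0.01 + w$se_var[keep])
      sxx <- sum(wt * x * x)
      reps[k, r] <- if (sxx > 0) sum(wt * x * y) / sxx else NA_real_
    }
  }
  series <- data.frame(
    time = windows,
    ff = rowMeans(reps, na.rm = TRUE),
    lo = apply(reps, 1, stats::quantile, 0.025, na.rm = TRUE),
    hi = apply(reps, 1, stats::quantile, 0.975, na.rm = TRUE))
  list(series = series, repeats = reps)
}

#' Condition-balanced mean-matched Fano factors
#'
#' When comparing two conditions (set size 4 vs 6-8), the condition with
#' more trials is undersampled per unit x window so both use the same
#' number of trials, then the mean-matched FF is computed per condition
#' against their shared greatest common distribution.
#'
#' @param session A `spikewm_session`.
#' @param condition_split Named list of two set-size groups (default
#'   `list(low = 4, high = c(6, 8))`).
#' @param window_s,step_s,n_repeats,bin As in the component functions.
#' @param t_start,t_end Analysis span.
#' @return Named list of [mean_matched_ff()] results, one per condition.
#' @export
condition_balanced_ff <- function(session,
                                  condition_split = list(low = 4, high = c(6, 8)),
                                  window_s = 0.5, step_s = 0.05,
                                  n_repeats = 50, bin = 0.5,
                                  t_start = 0, t_end = TRIAL_DURATION_S) {
  if (length(condition_split) != 2) stop("exactly 2 conditions required")
  tr <- session$trials
  n_by <- vapply(condition_split, function(ss) sum(tr$set_size %in% ss), 0L)
  if (any(n_by < 2)) stop("a condition has fewer than 2 trials")
  edges <- seq(t_start + window_s, t_end + 1e-9, by = step_s)
  n_use <- min(n_by)
  rows <- list()
  for (uid in session$units$unit_id) {
    cnt_all <- t(vapply(as.character(tr$trial_id), function(tid) {
      st <- get_spikes(session, uid, tid)
      vapply(edges, function(e) sum(st >= e - window_s & st < e), 0)
    }, numeric(length(edges))))
    for (cond in names(condition_split)) {
      ix <- which(tr$set_size %in% condition_split[[cond]])
      for (k in seq_along(edges)) {
        # fresh undersampling per unit x window
        use <- if (length(ix) > n_use) sample(ix, n_use) else ix
        x <- cnt_all[use, k]
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, condition = cond, time = edges[k],
          mean = mean(x), var = stats::var(x),
          se_var = stats::var(x) * sqrt(2 / (n_use - 1)), n = n_use,
          stringsAsFactors = FALSE)
      }
    }
  }
  pts <- do.call(rbind, rows)
  target <- greatest_common_distribution(pts, bin, by_condition = TRUE)
  out <- lapply(names(condition_split), function(cond)
    mean_matched_ff(pts[pts$condition == cond, , drop = FALSE],
                    target_hist = target, n_repeats = n_repeats, bin = bin))
  names(out) <- names(condition_split)
  out
}

#' Cluster-based permutation test on two windowed series
#'
#' Per window, a two-sample t statistic between the two sets of replicate
#' values (e.g. the 50 mean-matching repetitions); windows where |t|
#' exceeds the two-sided alpha critical value form maximal contiguous
#' clusters scored by their summed |t| mass.  The null distribution of the
#' maximum cluster mass is generated by permuting the replicate-column
#' labels between the two series, and each observed cluster gets
#' `p = (1 + #{null max >= mass}) / (n_perm + 1)`.
#'
#' @param repeats_a,repeats_b Matrices windows x replicates on the same
#'   window grid.
#' @param n_perm Permutations (> 0).
#' @param alpha Window-wise clustering threshold (default 0.05).
#' @return Data frame `start_idx, end_idx, mass, p` (0 rows when no window
#'   crosses the threshold).
#' @export
cluster_permutation_test <- function(repeats_a, repeats_b, n_perm = 1000,
                                     alpha = 0.05) {
  if (n_perm <= 0) stop("n_perm must be positive")
  if (nrow(repeats_a) != nrow(repeats_b)) stop("series length mismatch")
  na <- ncol(repeats_a); nb <- ncol(repeats_b)
  crit <- stats::qt(1 - alpha / 2, df = na + nb - 2)
  tstat <- function(a, b) {
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)) *
      sqrt(1 / na + 1 / nb)
    d <- rowMeans(a) - rowMeans(b)
    ifelse(sp > 0, d / sp, 0)
  }
  clusters <- function(tv) {
    above <- abs(tv) > crit
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ix <- which(r$values)
    if (!length(ix)) return(data.frame(start_idx = integer(0),
                                       end_idx = integer(0), mass = numeric(0)))
    data.frame(start_idx = starts[ix], end_idx = ends[ix],
               mass = vapply(ix, function(k)
                 sum(abs(tv[starts[k]:ends[k]])), 0))
  }
  obs <- clusters(tstat(repeats_a, repeats_b))
  pool <- cbind(repeats_a, repeats_b)
  null_max <- vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(na + nb)
    cl <- clusters(tstat(pool[, ix[seq_len(na)], drop = FALSE],
                         pool[, ix[-seq_len(na)], drop = FALSE]))
    if (nrow(cl)) max(cl$mass) else 0
  }, 0)
  obs$p <- vapply(obs$mass, function(m)
    (1 + sum(null_max >= m - 1e-12)) / (n_perm + 1), 0)
  obs
}

#' Fano factors by LvR quartile
#'
#' Units are split into quartiles of their per-unit mean LvR; the
#' mean-matched FF is computed within each quartile and summarised per
#' trial period (a window belongs to a period when it lies entirely
#' inside it).  Under shared trial-level gain fluctuations, burstier
#' quartiles show larger trial-to-trial variability (higher FF).
#'
#' @param session A `spikewm_session` with at least 8 units.
#' @param per_unit_mean_lvr Named vector of per-unit mean LvR; computed
#'   from whole-trial gated LvR when `NULL`.
#' @param window_s,step_s,n_repeats,bin Passed through.
#' @return List with `summary` (data frame `quartile, period, ff`) and
#'   `series` (per-quartile [mean_matched_ff()] results).
#' @export
ff_by_lvr_quartile <- function(session, per_unit_mean_lvr = NULL,
                               window_s = 0.5, step_s = 0.05,
                               n_repeats = 50, bin = 0.5) {
  uids <- session$units$unit_id
  if (length(uids) < 8) stop("at least 8 units required for quartiles")
  if (is.null(per_unit_mean_lvr)) {
    tids <- as.character(session$trials$trial_id)
    per_unit_mean_lvr <- vapply(uids, function(u) {
      lv <- vapply(tids, function(tid) lvr_gated(get_spikes(session, u, tid)), 0)
      mean(lv, na.rm = TRUE)
    }, 0)
  }
  ord <- uids[order(per_unit_mean_lvr[uids], uids)]
  qs <- split(ord, cut(seq_along(ord), 4, labels = FALSE))
  periods <- trial_periods(2)[, c("period", "start", "end")]
  series <- list(); rows <- list()
  for (q in 1:4) {
    sub <- subset_units(session, qs[[q]])
    pts <- window_counts(sub, window_s = window_s, step_s = step_s,
                         conditions = NULL)
    mm <- mean_matched_ff(pts, n_repeats = n_repeats, bin = bin)
    series[[q]] <- mm
    for (k in seq_len(nrow(periods))) {
      ix <- mm$series$time - window_s >= periods$start[k] - 1e-9 &
        mm$series$time <= periods$end[k] + 1e-9
      if (any(ix))
        rows[[length(rows) + 1L]] <- data.frame(
          quartile = q, period = periods$period[k],
          ff = mean(mm$series$ff[ix], na.rm = TRUE))
    }
  }
  list(summary = do.call(rbind, rows), series = series)
}
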