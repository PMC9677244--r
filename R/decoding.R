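#' Maintenance-period features for decoding
#'
#' Spike counts per unit in the 12 non-overlapping 250-ms bins of the 3-s
#' maintenance period (`[3, 6)` s), z-scored per unit over all its
#' bins x trials in the session; no smoothing.  Zero-variance units get
#' all-zero features with a warning.
#'
#' @param session A `spikewm_session`.
#' @return List with `mat` (rows = trial x bin samples, columns = units),
#'   `trial_id` and `bin` row indices.
#' @export
maintenance_features <- function(session) {
  tids <- session$trials$trial_id
  edges <- seq(3, 6, by = 0.25)
  nb <- length(edges) - 1L
  uids <- session$units$unit_id
  mat <- matrix(0, nrow = length(tids) * nb, ncol = length(uids),
                dimnames = list(NULL, uids))
  for (u in seq_along(uids)) {
    col <- numeric(0)
    for (tid in as.character(tids)) {
      st <- get_spikes(session, uids[u], tid)
      col <- c(col, vapply(seq_len(nb), function(b)
        sum(st >= edges[b] & st < edges[b + 1]), 0))
    }
    s <- stats::sd(col)
    if (s == 0) {
      warning("unit ", uids[u], " has zero count variance; features set to 0")
      mat[, u] <- 0
    } else mat[, u] <- (col - mean(col)) / s
  }
  list(mat = mat, trial_id = rep(tids, each = nb), bin = rep(seq_len(nb), length(tids)))
}

# class label per trial for a class definition
.trial_classes <- function(trials, class_def) {
  switch(class_def,
    setsize = ifelse(trials$set_size == 4, "low", "high"),
    correctness = ifelse(trials$correct, "correct", "wrong"),
    stop("class_def must be 'setsize' or 'correctness'"))
}

#' Build a pseudo-population sample for one bootstrap cycle
#'
#' Per session, the per-class trial minimum is computed; sessions where it
#' falls below 5 are discarded, and the minimum across the surviving
#' sessions, `n_T`, fixes the number of trials sampled (uniformly, without
#' replacement) per class per session.  Unit columns of all sessions are
#' concatenated, aligned by sampled-trial index within class, giving
#' `12 * 2 * n_T` samples.
#'
#' @param sessions List of `spikewm_session`.
#' @param class_def `"setsize"` (4 vs 6-8) or `"correctness"`.
#' @param min_per_class Session-discard threshold (default 5).
#' @param features Optional precomputed list of [maintenance_features()]
#'   per session (avoids recomputation across cycles).
#' @return List with `X` (samples x units), `y` (factor), `slot` (trial-slot
#'   index shared by the 12 bins of one trial), `n_T`, and `sampled_trials`
#'   (per session, the trial ids drawn per class).
#' @export
build_pseudopopulation <- function(sessions, class_def = "setsize",
                                   min_per_class = 5, features = NULL) {
  cls <- lapply(sessions, function(s) .trial_classes(s$trials, class_def))
  keep <- vapply(cls, function(cl)
    length(unique(cl)) == 2 && min(table(cl)) >= min_per_class, TRUE)
  if (!any(keep)) stop("all sessions discarded (fewer than ",
                       min_per_class, " trials in a class)")
  sessions <- sessions[keep]; cls <- cls[keep]
  if (!is.null(features)) features <- features[keep]
  levels2 <- sort(unique(unlist(cls)))
  n_T <- min(vapply(cls, function(cl) min(table(cl)), 0L))
  nb <- 12L
  blocks <- list(); sampled <- list()
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    f <- if (is.null(features)) maintenance_features(s) else features[[k]]
    rows <- integer(0); draw <- list()
    for (cl in levels2) {
      tid_pool <- s$trials$trial_id[cls[[k]] == cl]
      pick <- sample(tid_pool, n_T)
      draw[[cl]] <- pick
      rows <- c(rows, unlist(lapply(pick, function(tt)
        which(f$trial_id == tt))))
    }
    blocks[[k]] <- f$mat[rows, , drop = FALSE]
    sampled[[s$session_id]] <- draw
  }
  X <- do.call(cbind, blocks)
  y <- factor(rep(levels2, each = nb * n_T), levels = levels2)
  slot <- rep(seq_len(2L * n_T), each = nb)
  list(X = X, y = y, slot = slot, n_T = n_T, sampled_trials = sampled)
}

# stratified k-fold assignment
.stratified_folds <- function(y, k = 10) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Linear SVM decoding accuracy with stratified cross-validation
#'
#' Balanced linear support-vector machine (cost 1, class weights inverse to
#' class frequency) evaluated by stratified 10-fold cross-validation;
#' features are assumed already z-scored.
#'
#' @param X Samples x units feature matrix.
#' @param y Two-level factor of class labels.
#' @param folds Number of CV folds (default 10) or a precomputed fold
#'   assignment vector.
#' @return List with `accuracy` (mean over folds) and `fold_accuracies`.
#' @export
decode_cv <- function(X, y, folds = 10) {
  if (nrow(X) < 20) stop("at least 20 samples required")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("binary classification only")
  fold <- if (length(folds) == 1) .stratified_folds(y, folds) else folds
  k <- max(fold)
  cw <- length(y) / (2 * table(y))
  acc <- vapply(seq_len(k), function(f) {
    te <- fold == f
    if (length(unique(y[te])) < 2 || length(unique(y[!te])) < 2)
      stop("a fold contains a single class")
    fit <- e1071::svm(X[!te, , drop = FALSE], y[!te], kernel = "linear",
                      cost = 1, scale = FALSE,
                      class.weights = cw)
    mean(stats::predict(fit, X[te, , drop = FALSE]) == y[te])
  }, 0)
  list(accuracy = mean(acc), fold_accuracies = acc)
}

#' Bootstrap decoding with shuffle null
#'
#' Repeats the pseudo-population construction over bootstrap cycles (fresh
#' trial alignments), decodes each, and builds a null by shuffling the
#' class labels at the trial-slot level (all 12 bins of a slot move
#' together) within each cycle.  One-tailed p per cycle with +1 smoothing;
#' the summary p is the median over cycles.
#'
#' @param sessions List of `spikewm_session`.
#' @param class_def `"setsize"` or `"correctness"`.
#' @param n_cycles Bootstrap cycles (default 50).
#' @param n_shuffles Label shuffles per cycle (default 500; must be > 0).
#' @param folds CV folds.
#' @return `spikewm_decoding` list: `accuracies`, `p_per_cycle`,
#'   `p_summary`, `n_T`, `null_mean`.
#' @export
bootstrap_decode <- function(sessions, class_def = "setsize", n_cycles = 50,
                             n_shuffles = 500, folds = 10) {
  if (n_shuffles <= 0) stop("n_shuffles must be positive")
  feats <- lapply(sessions, maintenance_features)
  acc <- numeric(n_cycles); pvals <- numeric(n_cycles)
  null_all <- numeric(0); n_T <- NA_integer_
  for (cyc in seq_len(n_cycles)) {
    pp <- build_pseudopopulation(sessions, class_def, features = feats)
    n_T <- pp$n_T
    acc[cyc] <- decode_cv(pp$X, pp$y)$accuracy
    null <- vapply(seq_len(n_shuffles), function(i) {
      slot_lab <- pp$y[!duplicated(pp$slot)]
      y_sh <- sample(slot_lab)[pp$slot]
      decode_cv(pp$X, y_sh)$accuracy
    }, 0)
    pvals[cyc] <- (1 + sum(null >= acc[cyc] - 1e-12)) / (n_shuffles + 1)
    null_all <- c(null_all, null)
  }
  structure(list(accuracies = acc, p_per_cycle = pvals,
                 p_summary = stats::median(pvals), n_T = n_T,
                 null_mean = mean(null_all)),
            class = "spikewm_decoding")
}

#' @export
print.spikewm_decoding <- function(x, ...) {
  cat("<spikewm_decoding> ", length(x$accuracies), " cycles, n_T = ",
      x$n_T, "\n", sep = "")
  cat("  median accuracy: ", round(stats::median(x$accuracies), 3),
      "   summary p: ", signif(x$p_summary, 3), "\n", sep = "")
  invisible(x)
}

#' Split units into n-tiles by mean LvR
#'
#' Equal-size (plus or minus one) tiles by ascending mean LvR, ties broken
#' by unit id; units with missing LvR go to the lowest tile with a
#' warning.  Tile 1 is the most regular, tile `n_tiles` the burstiest.
#'
#' @param unit_ids Character vector.
#' @param mean_lvr Named per-unit mean LvR over the cycle's sampled trials.
#' @param n_tiles Number of tiles (must not exceed the unit count).
#' @return Named integer vector of tile indices.
#' @export
ntile_split <- function(unit_ids, mean_lvr, n_tiles) {
  n <- length(unit_ids)
  if (n_tiles > n) stop("n_tiles exceeds unit count")
  lv <- mean_lvr[unit_ids]
  if (any(!is.finite(lv))) {
    warning("units with missing LvR assigned to the lowest tile")
    lv[!is.finite(lv)] <- -Inf
  }
  ord <- order(lv, unit_ids)
  sizes <- rep(n %/% n_tiles, n_tiles)
  extra <- n %% n_tiles
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tile <- integer(n)
  tile[ord] <- rep(seq_len(n_tiles), times = sizes)
  stats::setNames(tile, unit_ids)
}

# per-unit mean gated LvR over a set of trials in one session
.cycle_mean_lvr <- function(session, trial_ids, R_s = 0.005) {
  vapply(session$units$unit_id, function(u) {
    lv <- vapply(as.character(trial_ids), function(tid)
      lvr_gated(get_spikes(session, u, tid), R_s = R_s), 0)
    mean(lv, na.rm = TRUE)
  }, 0)
}

#' Decoding sensitivity loss from removing LvR n-tiles
#'
#' Per bootstrap cycle: units are tiled by their mean LvR over the cycle's
#' sampled trials; the full population and each ablated population (one
#' tile removed) are decoded on the same samples and folds, and the d-prime
#' `(mu_Full - mu_Red) / sqrt(0.5 (var_Full + var_Red))` is computed from
#' the 10 fold accuracies.  Per tile: mean and SEM across cycles, a
#' one-sample t test against 0, and BH adjustment across tiles.
#'
#' @param sessions List of `spikewm_session`.
#' @param class_def `"setsize"` or `"correctness"`.
#' @param n_tiles Number of LvR tiles (default 20).
#' @param n_cycles Bootstrap cycles (default 50).
#' @param folds CV folds.
#' @return Data frame `tile, mean_dprime, sem, t, p, p_bh, n_cycles`.
#' @export
dprime_ablation <- function(sessions, class_def = "setsize", n_tiles = 20,
                            n_cycles = 50, folds = 10) {
  feats <- lapply(sessions, maintenance_features)
  dmat <- matrix(NA_real_, nrow = n_cycles, ncol = n_tiles)
  for (cyc in seq_len(n_cycles)) {
    pp <- build_pseudopopulation(sessions, class_def, features = feats)
    fold <- .stratified_folds(pp$y, folds)
    full <- decode_cv(pp$X, pp$y, folds = fold)$fold_accuracies
    mu_f <- mean(full); v_f <- stats::var(full)
    # mean LvR per unit over this cycle's sampled trials
    lv <- unlist(lapply(sessions, function(s) {
      draw <- pp$sampled_trials[[s$session_id]]
      if (is.null(draw)) return(NULL)
      .cycle_mean_lvr(s, unlist(draw))
    }))
    lv <- lv[colnames(pp$X)]
    names(lv) <- colnames(pp$X)
    tiles <- ntile_split(colnames(pp$X), lv, n_tiles)
    for (tl in seq_len(n_tiles)) {
      keep <- names(tiles)[tiles != tl]
      if (length(keep) == ncol(pp$X)) { dmat[cyc, tl] <- 0; next }
      red <- decode_cv(pp$X[, keep, drop = FALSE], pp$y,
                       folds = fold)$fold_accuracies
      den <- sqrt(0.5 * (v_f + stats::var(red)))
      dmat[cyc, tl] <- if (den > 0) (mu_f - mean(red)) / den else NA_real_
    }
  }
  out <- data.frame(tile = seq_len(n_tiles))
  out$mean_dprime <- colMeans(dmat, na.rm = TRUE)
  out$sem <- apply(dmat, 2, function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v))))
  tt <- lapply(seq_len(n_tiles), function(tl) {
    v <- dmat[is.finite(dmat[, tl]), tl]
    if (length(v) < 2 || stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    ht <- stats::t.test(v)
    c(unname(ht$statistic), ht$p.value)
  })
  out$t <- vapply(tt, `[`, 0, 1)
  out$p <- vapply(tt, `[`, 0, 2)
  out$p_bh <- NA_real_
  ok <- is.finite(out$p)
  if (any(ok)) out$p_bh[ok] <- bh_adjust(out$p[ok])
  out$n_cycles <- n_cycles
  out
}

#' Single-unit workload tests
#'
#' Per unit, a two-sample t test between the per-trial mean maintenance
#' firing rates of the two classes; reports the fraction of significant
#' units split by the sign of the t statistic, and a binomial test of the
#' positive vs negative significant counts against 0.5.  Zero-variance
#' units are excluded with a warning.
#'
#' @param sessions List of `spikewm_session`.
#' @param class_def `"setsize"` (4 vs 6-8) or `"correctness"`.
#' @param alpha Per-unit significance level (default 0.05).
#' @return List with `per_unit` (data frame `unit_id, t, p`), `frac_pos`,
#'   `frac_neg` (fractions of all testable units significant with each
#'   sign) and `binom_p`.
#' @export
single_unit_setsize_tests <- function(sessions, class_def = "setsize",
                                      alpha = 0.05) {
  rows <- list()
  for (s in sessions) {
    cl <- .trial_classes(s$trials, class_def)
    if (length(unique(cl)) != 2) next
    pos <- if (class_def == "setsize") "high" else "wrong"
    for (u in s$units$unit_id) {
      rate <- vapply(as.character(s$trials$trial_id), function(tid) {
        st <- get_spikes(s, u, tid)
        sum(st >= 3 & st < 6) / 3
      }, 0)
      a <- rate[cl == pos]; b <- rate[cl != pos]
      if (length(a) < 2 || length(b) < 2 ||
          (stats::sd(a) == 0 && stats::sd(b) == 0)) {
        warning("unit ", u, " excluded (insufficient data or zero variance)")
        next
      }
      ht <- stats::t.test(a, b)
      rows[[paste(s$session_id, u)]] <- data.frame(
        unit_id = u, t = unname(ht$statistic), p = ht$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no testable units")
  d <- do.call(rbind, rows); rownames(d) <- NULL
  sig <- d$p < alpha
  n_pos <- sum(sig & d$t > 0); n_neg <- sum(sig & d$t < 0)
  bp <- if (n_pos + n_neg > 0)
    stats::binom.test(n_pos, n_pos + n_neg, 0.5)$p.value else NA_real_
  list(per_unit = d, frac_pos = n_pos / nrow(d), frac_neg = n_neg / nrow(d),
       binom_p = bp)
}
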