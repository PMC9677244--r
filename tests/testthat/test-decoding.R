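test_that("maintenance features are 12 z-scored bins per trial", {
  set.seed(101)
  s <- poisson_session(rep(8, 3), n_trials = 10)
  f <- maintenance_features(s)
  expect_equal(nrow(f$mat), 120)              # 10 trials x 12 bins
  expect_equal(ncol(f$mat), 3)
  expect_equal(unname(colMeans(f$mat)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(f$mat, 2, sd)), rep(1, 3), tolerance = 1e-10)
  # silent unit: zero-variance rule with warning
  units <- data.frame(unit_id = c("ok", "mute"), region = rep("amygdala", 2))
  trials <- data.frame(trial_id = 1:6, set_size = 4L, correct = TRUE,
                       response_time = 1)
  sp <- list(ok = stats::setNames(lapply(1:6, function(i)
               sort(runif(30, 0, 8))), 1:6),
             mute = stats::setNames(lapply(1:6, function(i) numeric(0)), 1:6))
  s2 <- new_session("m", "m", units, trials, sp)
  expect_warning(f2 <- maintenance_features(s2), "zero")
  expect_true(all(f2$mat[, "mute"] == 0))
})

test_that("pseudo-population sampling follows the n_T and discard rules", {
  set.seed(103)
  mk <- function(id, n4, n68) {
    nT <- n4 + n68
    s <- poisson_session(rep(6, 2), n_trials = nT, session_id = id)
    s$trials$set_size <- c(rep(4L, n4), rep(c(6L, 8L), length.out = n68))
    s
  }
  # class minima 9, 12, 7 -> n_T = 7
  sess <- list(mk("a", 9, 20), mk("b", 12, 15), mk("c", 7, 18))
  pp <- build_pseudopopulation(sess, "setsize")
  expect_equal(pp$n_T, 7)
  expect_equal(nrow(pp$X), 12 * 2 * 7)
  expect_equal(ncol(pp$X), 6)
  expect_equal(as.integer(table(pp$y)), c(84L, 84L))
  # a session with a class minimum below 5 is discarded
  sess2 <- list(mk("a", 9, 20), mk("d", 4, 20))
  pp2 <- build_pseudopopulation(sess2, "setsize")
  expect_equal(ncol(pp2$X), 2)     # only session "a" contributes units
  expect_equal(pp2$n_T, 9)
  # all sessions below the rule: error
  expect_error(build_pseudopopulation(list(mk("e", 3, 20)), "setsize"),
               "discarded")
  # determinism under a fixed seed
  set.seed(1); a <- build_pseudopopulation(sess, "setsize")
  set.seed(1); b <- build_pseudopopulation(sess, "setsize")
  expect_identical(a$X, b$X)
})

test_that("linear SVM decoding hits chance on noise and 1.0 on separation", {
  set.seed(105)
  n <- 120
  y <- factor(rep(c("a", "b"), each = n / 2))
  # labels independent of features: accuracy ~ 0.5
  X0 <- matrix(rnorm(n * 10), n, 10)
  accs <- vapply(1:10, function(i) {
    decode_cv(matrix(rnorm(n * 10), n, 10), y)$accuracy
  }, 0)
  expect_equal(mean(accs), 0.5, tolerance = 0.06)
  # linearly separated classes: accuracy ~ 1
  X1 <- X0; X1[y == "a", 1] <- X1[y == "a", 1] + 6
  expect_gte(decode_cv(X1, y)$accuracy, 0.98)
  # duplicated feature columns leave the accuracy essentially unchanged
  set.seed(3); a1 <- decode_cv(cbind(X1, X1), y)$accuracy
  expect_equal(a1, 1, tolerance = 0.02)
  expect_error(decode_cv(X1[1:10, ], y[1:10]), "20 samples")
  # per-fold accuracies are returned for the d-prime computation
  r <- decode_cv(X1, y)
  expect_length(r$fold_accuracies, 10)
})

test_that("bootstrap decoding separates coding cohorts from null cohorts", {
  co_eff <- synth_cohort(generator_config(
    n_sessions = 2, units_per_region = 3, n_trials = 30,
    setsize_gain = 1.6, setsize_fraction = 0.5, probe_burst_gain = 1,
    seed = 107))
  set.seed(107)
  bd <- bootstrap_decode(co_eff$sessions, "setsize", n_cycles = 3,
                         n_shuffles = 39)
  expect_lt(bd$p_summary, 0.05)
  expect_true(all(bd$accuracies > 0.5))
  expect_error(bootstrap_decode(co_eff$sessions, "setsize", n_shuffles = 0),
               "positive")
  # on a no-effect cohort the shuffle null is centered at chance and the
  # summary p is unremarkable
  co_null <- synth_cohort(generator_config(
    n_sessions = 2, units_per_region = 2, n_trials = 30, setsize_gain = 1,
    probe_burst_gain = 1, seed = 117))
  set.seed(117)
  bd0 <- bootstrap_decode(co_null$sessions, "setsize", n_cycles = 2,
                          n_shuffles = 59)
  expect_equal(bd0$null_mean, 0.5, tolerance = 0.02)
  expect_gt(bd0$p_summary, 0.05)
})

test_that("n-tile splits are balanced, ordered and tie-stable", {
  lv <- stats::setNames(c(0.2, 1.5, 0.8, 0.4, 1.1, 0.6, 1.3, 0.9),
                        sprintf("u%d", 1:8))
  t4 <- ntile_split(names(lv), lv, 4)
  expect_equal(as.integer(table(t4)), rep(2L, 4))
  # lowest-LvR units in tile 1
  expect_equal(sort(names(t4)[t4 == 1]), c("u1", "u4"))
  expect_equal(sort(names(t4)[t4 == 4]), c("u2", "u7"))
  # all-equal LvR: deterministic tie-break by unit id
  lv_eq <- stats::setNames(rep(1, 8), sprintf("u%d", 1:8))
  expect_identical(ntile_split(names(lv_eq), lv_eq, 4),
                   ntile_split(names(lv_eq), lv_eq, 4))
  expect_equal(unname(ntile_split(names(lv_eq), lv_eq, 4)),
               rep(1:4, each = 2))  # id order breaks the ties
  # 100 units, 20 tiles -> tiles of 5
  lv100 <- stats::setNames(runif(100), sprintf("v%03d", 1:100))
  expect_equal(as.integer(table(ntile_split(names(lv100), lv100, 20))),
               rep(5L, 20))
  expect_error(ntile_split(names(lv), lv, 9), "exceeds")
  expect_warning(ntile_split(names(lv), replace(lv, 1, NA), 4), "missing")
})

test_that("d-prime follows its definition and flags the informative tile", {
  # direct evaluation: mu 0.8 vs 0.7 at var 0.01 each -> d' = 1
  expect_equal((0.8 - 0.7) / sqrt(0.5 * (0.01 + 0.01)), 1)
  set.seed(109)
  # one session whose coding units all sit in the bursty tile:
  # high-shape (regular) units carry no signal; low-shape (bursty) units do
  nT <- 30
  trials <- data.frame(trial_id = 1:nT,
                       set_size = rep(c(4L, 6L, 8L), each = nT / 3),
                       correct = TRUE, response_time = 1)
  units <- data.frame(unit_id = sprintf("u%02d", 1:8),
                      region = "hippocampus")
  shapes <- c(rep(0.45, 4), rep(2.5, 4))  # bursty carry the set-size gain
  sp <- lapply(1:8, function(u) {
    l <- lapply(1:nT, function(t) {
      gain <- if (u <= 4 && trials$set_size[t] >= 6) 1.8 else 1
      inhomogeneous_train(rate_profile(c(0, 8), 8 * gain), shapes[u])
    })
    names(l) <- 1:nT; l
  })
  names(sp) <- units$unit_id
  s <- new_session("dp", "dp", units, trials, sp)
  res <- dprime_ablation(list(s), "setsize", n_tiles = 2, n_cycles = 4)
  expect_equal(nrow(res), 2)
  # removing the bursty (coding) tile hurts more than removing the regular one
  expect_gt(res$mean_dprime[res$tile == 2], res$mean_dprime[res$tile == 1])
  expect_true(all(is.finite(res$p_bh) | is.na(res$p_bh)))
})

test_that("single-unit workload tests recover a positive-gain subpopulation", {
  set.seed(111)
  nT <- 48
  trials <- data.frame(trial_id = 1:nT,
                       set_size = rep(c(4L, 6L, 8L), each = nT / 3),
                       correct = TRUE, response_time = 1)
  units <- data.frame(unit_id = sprintf("u%02d", 1:12), region = "hippocampus")
  sp <- lapply(1:12, function(u) {
    l <- lapply(1:nT, function(t) {
      gain <- if (u <= 6 && trials$set_size[t] >= 6) 1.8 else 1
      sort(runif(rpois(1, 6 * 8 * gain), 0, 8))
    })
    names(l) <- 1:nT; l
  })
  names(sp) <- units$unit_id
  s <- new_session("su", "su", units, trials, sp)
  res <- single_unit_setsize_tests(list(s), "setsize")
  expect_gt(res$frac_pos, res$frac_neg)
  expect_lt(res$binom_p, 0.05)
  expect_equal(nrow(res$per_unit), 12)
  # null cohort: significant fraction near alpha, sign balance plausible
  set.seed(113)
  s0 <- poisson_session(rep(6, 30), n_trials = 30)
  res0 <- single_unit_setsize_tests(list(s0), "setsize")
  expect_lt(res0$frac_pos + res0$frac_neg, 0.25)
})
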