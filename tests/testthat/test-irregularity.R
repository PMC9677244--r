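test_that("LvR matches hand-evaluated values and edge cases", {
  # two intervals 0.1, 0.2: cross term 1 - 4*0.02/0.09 = 1/9; times 3/(n-1)
  expect_equal(lvr(c(0.1, 0.2), R_s = 0), 1 / 3, tolerance = 1e-12)
  # refractoriness factor (1 + 4*0.005/0.3) = 16/15
  expect_equal(lvr(c(0.1, 0.2), R_s = 0.005), 16 / 45, tolerance = 1e-12)
  expect_equal(round(lvr(c(0.1, 0.2), R_s = 0.005), 5), 0.35556)
  # perfectly regular trains give 0 at any R
  expect_equal(lvr(rep(0.25, 10), R_s = 0), 0)
  expect_equal(lvr(rep(0.25, 10), R_s = 0.005), 0)
  expect_error(lvr(c(0.1, -0.1)), "> 0")
  expect_true(is.na(lvr(0.3)))
})

test_that("LvR is invariant to common rescaling of intervals and R", {
  set.seed(5)
  for (i in 1:20) {
    isis <- rexp(30, 5)
    r <- runif(1, 0, 0.01)
    k <- runif(1, 0.1, 10)
    expect_equal(lvr(isis, r), lvr(k * isis, k * r), tolerance = 1e-10)
  }
})

test_that("gated LvR discards sparse windows and matches Poisson expectation", {
  expect_true(is.na(lvr_gated(c(1, 2, 3, 4))))          # 4 spikes: below gate
  expect_equal(lvr_gated(seq(0, 8, by = 0.2)), 0)       # regular train
  set.seed(8)
  m <- mean(vapply(1:500, function(i)
    lvr_gated(sort(runif(rpois(1, 40), 0, 8)), R_s = 0), 0), na.rm = TRUE)
  expect_equal(m, 1, tolerance = 0.05)
})

test_that("gamma-renewal LvR recovers 3/(2*shape+1)", {
  set.seed(21)
  for (shape in c(0.5, 1, 2.5)) {
    m <- mean(vapply(1:500, function(i)
      lvr_gated(gamma_renewal_train(5, shape, 8), R_s = 0), 0), na.rm = TRUE)
    expect_equal(m, 3 / (2 * shape + 1), tolerance = 0.05)
  }
})

test_that("combined trains behave like superpositions", {
  # two regular 5-Hz trains offset by half a period merge to a regular 10-Hz train
  a <- regular_train(5); b <- regular_train(5, phase = 0.1)
  m <- combine_trains(list(a, b))
  expect_equal(lvr_gated(m, R_s = 0), 0, tolerance = 1e-9)
  # merging with an empty train is the identity
  expect_equal(combine_trains(list(a, numeric(0))), a)
  # duplicates collapse so no zero intervals arise
  expect_equal(combine_trains(list(c(1, 2), c(2, 3))), c(1, 2, 3))
  # superposed independent Poisson trains stay Poisson (LvR ~ 1), any order
  set.seed(9)
  for (k in 2:3) {
    m <- mean(vapply(1:300, function(i) {
      tr <- lapply(seq_len(k), function(j) sort(runif(rpois(1, 40), 0, 8)))
      lvr_gated(combine_trains(tr), R_s = 0)
    }, 0), na.rm = TRUE)
    expect_equal(m, 1, tolerance = 0.05)
  }
})

test_that("sliding LvR windows are right-aligned with the documented grid", {
  sl <- sliding_lvr(regular_train(10), window_s = 2, step_s = 0.25)
  expect_equal(sl$time, seq(2, 8, by = 0.25))  # 25 windows
  expect_equal(nrow(sl), 25)
  expect_true(all(sl$lvr == 0))
  # silence in the first 3 s leaves early windows below the gate
  st <- regular_train(10)
  st <- st[st >= 3]
  sl2 <- sliding_lvr(st, window_s = 2, step_s = 0.25)
  expect_true(all(is.na(sl2$lvr[sl2$time <= 3])))
  expect_true(all(!is.na(sl2$lvr[sl2$time >= 5.5])))
})

test_that("change-point detector finds a rate step and respects regularity", {
  # perfectly regular train: empirical equals expected, no change points
  expect_length(change_points(regular_train(10), logit = 1.3)$change_points, 0)
  expect_length(change_points(numeric(0))$change_points, 0)
  # a 2->10 Hz step at 4 s is detected nearby in most runs
  set.seed(31)
  found <- vapply(1:100, function(i) {
    st <- sort(c(runif(rpois(1, 8), 0, 4), runif(rpois(1, 40), 4, 8)))
    cp <- change_points(st, logit = 1.3)$change_points
    length(cp) > 0 && min(abs(cp - 4)) <= 0.5
  }, TRUE)
  expect_gte(mean(found), 0.75)
  # detected times are strictly increasing and inside the window
  st <- sort(c(runif(10, 0, 4), runif(50, 4, 8)))
  cp <- change_points(st, logit = 1.3)$change_points
  if (length(cp) > 1) expect_true(all(diff(cp) > 0))
  expect_true(all(cp > 0 & cp < 8))
})

test_that("logit adaptation silences fixation change points by construction", {
  set.seed(33)
  # a unit whose fixation windows trip the most lenient threshold
  fix <- lapply(1:30, function(i) sort(c(runif(3, 0, 0.3), runif(12, 0.3, 1))))
  lg <- adapt_cp_logit(fix)
  expect_true(lg %in% seq(1.3, 5.9, by = 0.2))
  for (st in fix)
    expect_length(change_points(st, window = c(0, 1), logit = lg)$change_points, 0)
})

test_that("change-point counts correlate with LvR across shape-diverse units", {
  set.seed(35)
  cfg <- generator_config(n_sessions = 1, units_per_region = 8, n_trials = 25,
                          probe_burst_gain = 1, seed = 35)
  co <- synth_cohort(cfg)
  res <- cp_lvr_correlation(co$sessions)
  expect_true(all(res$r > 0))
  expect_true(all(res$n_units >= 3))
  # two units only: insufficient data
  small <- subset_units(co$sessions[[1]], co$sessions[[1]]$units$unit_id[1:2])
  expect_error(cp_lvr_correlation(list(small)), "3 units")
})

test_that("rank dissimilarity matches the hand-enumerated CDF area", {
  # values [0.5,0.9,1.2,1.4], labels [B,B,A,A]:
  # F_A over ranks 1..4 = (0,0,.5,1), F_B = (.5,1,1,1), sum of diffs = -2
  rd <- rank_dissimilarity(c(0.5, 0.9, 1.2, 1.4), c("B", "B", "A", "A"))
  expect_equal(rd$statistic, -2)
  # identical class multisets give 0
  rd0 <- rank_dissimilarity(c(1, 2, 1, 2), c("A", "A", "B", "B"))
  expect_equal(rd0$statistic, 0)
  # label swap flips the sign
  rd_sw <- rank_dissimilarity(c(0.5, 0.9, 1.2, 1.4), c("A", "A", "B", "B"))
  expect_equal(rd_sw$statistic, 2)
  # invariance under strictly monotone transforms
  set.seed(4)
  v <- rnorm(30); lab <- rep(c("A", "B"), 15)
  expect_equal(rank_dissimilarity(exp(v), lab)$statistic,
               rank_dissimilarity(v, lab)$statistic)
  expect_error(rank_dissimilarity(1:3, c("A", "A", "A")), "2 classes")
})

test_that("permutation null is calibrated and detects injected effects", {
  set.seed(41)
  mk_data <- function(effect = 0) {
    tv <- data.frame(session = rep(c("s1", "s2"), each = 20),
                     trial = rep(1:20, 2), var = rnorm(40))
    d <- do.call(rbind, lapply(1:3, function(u)
      data.frame(session = tv$session, trial = tv$trial,
                 value = rnorm(40) + effect * tv$var)))
    list(d = d, tv = tv)
  }
  pearson <- function(v, x) stats::cor(v, x)
  # statistic constant under permutation -> p = 1
  x <- mk_data()
  res_const <- permutation_null(x$d, x$tv, function(v, z) 1, n_perm = 50)
  expect_equal(res_const$p, 1)
  # null p-values roughly uniform (coarse check on the lower tail)
  ps <- vapply(1:60, function(i) {
    x <- mk_data(0)
    permutation_null(x$d, x$tv, pearson, n_perm = 79)$p
  }, 0)
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # strong injected effect -> small p
  x1 <- mk_data(1.5)
  expect_lte(permutation_null(x1$d, x1$tv, pearson, n_perm = 199)$p, 0.01)
})

test_that("combined-order subsampling matches the single-unit contract", {
  set.seed(43)
  tv <- data.frame(session = "s1", trial = 1:30, var = rnorm(30))
  single <- data.frame(session = "s1", trial = 1:30,
                       value = rnorm(30) + tv$var)
  combined <- do.call(rbind, lapply(1:4, function(k)
    data.frame(session = "s1", trial = 1:30, value = rnorm(30) + tv$var)))
  pearson <- function(v, x) stats::cor(v, x)
  res <- subsampled_combination_test(single, combined, tv, pearson,
                                     n_subsamples = 20, n_perm = 99)
  expect_lt(res$p_median, 0.05)
  expect_length(res$p_values, 20)
  # subsample equal in size to the single pool: pass-through consistency
  res_full <- subsampled_combination_test(single, single, tv, pearson,
                                          n_subsamples = 3, n_perm = 99)
  expect_equal(stats::var(res_full$p_values), 0)  # no subsampling randomness
})

test_that("time-resolved LvR/RT correlation recovers an injected coupling", {
  cfg <- generator_config(n_sessions = 2, units_per_region = 3, n_trials = 30,
                          rt_lvr_coupling = 0.3, probe_burst_gain = 1,
                          seed = 19)
  co <- synth_cohort(cfg)
  set.seed(19)
  rc <- timeresolved_rt_correlation(co$sessions, combo_orders = 1,
                                    n_perm = 199, regions = "hippocampus")
  maint <- rc[rc$time >= 5 & rc$time <= 6, ]
  expect_true(all(maint$r > 0))
  expect_true(any(maint$p < 0.05))
  # constant response times: correlation undefined, windows dropped
  s <- co$sessions[[1]]
  s$trials$response_time <- rep(1, nrow(s$trials))
  rc0 <- timeresolved_rt_correlation(list(s), combo_orders = 1, n_perm = 19,
                                     regions = "hippocampus")
  expect_equal(nrow(rc0), 0)
})

test_that("partial correlation removes the rate-mediated component", {
  set.seed(47)
  n <- 400
  # RT a pure function of rate, LvR independent -> partial r ~ 0
  rate <- rnorm(n); rt <- 2 * rate + rnorm(n, sd = 0.1); lv <- rnorm(n)
  expect_lt(abs(partial_correlation_lvr_rt(lv, rt, rate)), 0.12)
  # rate independent of both -> partial r ~ raw r
  rate2 <- rnorm(n); rt2 <- rnorm(n); lv2 <- 0.5 * rt2 + rnorm(n)
  expect_equal(partial_correlation_lvr_rt(lv2, rt2, rate2),
               stats::cor(lv2, rt2), tolerance = 0.1)
  expect_error(partial_correlation_lvr_rt(1:3, 1:3, 1:3), "4 complete")
  expect_true(is.na(partial_correlation_lvr_rt(rep(1, 5), rnorm(5), rnorm(5))))
})
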