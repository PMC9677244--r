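test_that("kernel rate estimates conserve spike mass and mean rate", {
  units <- data.frame(unit_id = c("a", "b"), region = rep("amygdala", 2))
  trials <- data.frame(trial_id = 1L, set_size = 4L, correct = TRUE,
                       response_time = 1)
  spikes <- list(a = list(`1` = 4.0), b = list(`1` = numeric(0)))
  s <- new_session("k", "k", units, trials, spikes)
  r <- instantaneous_rates(s, 1)
  # empty train: all-zero series
  expect_true(all(r$unit_rates["b", ] == 0))
  # single spike: series integrates to ~1 spike (kernel mass conservation)
  expect_equal(sum(r$unit_rates["a", ]) * 0.010, 1, tolerance = 0.01)
  expect_error(instantaneous_rates(subset_units(s, character(0)), 1), "units")

  # homogeneous 10-Hz population: mean population rate ~ 10 Hz
  set.seed(71)
  sp <- poisson_session(rep(10, 20), n_trials = 1)
  rp <- instantaneous_rates(sp, 1)
  expect_equal(mean(rp$population[rp$time > 0.2 & rp$time < 7.8]), 10,
               tolerance = 1)
})

test_that("burst threshold follows the mean + 3 sd convention", {
  # hand case: per-trial averages 4 and 6 Hz -> 5 + 3*sd(c(4,6)) = 5 + 3*sqrt(2)
  units <- data.frame(unit_id = "u", region = "hippocampus")
  trials <- data.frame(trial_id = 1:2, set_size = 4L, correct = TRUE,
                       response_time = 1)
  # stub the smoothing: pass precomputed rate lists
  mk <- function(v) list(time = seq(0, 8, 0.01),
                         unit_rates = matrix(v, 1, 801),
                         population = rep(v, 801))
  s <- new_session("t", "t", units, trials,
                   list(u = list(`1` = numeric(0), `2` = numeric(0))))
  th <- burst_threshold(s, rates = list(mk(4), mk(6)))
  expect_equal(th, 5 + 3 * stats::sd(c(4, 6)))
  # identical trials: sd 0, threshold = mean
  expect_equal(burst_threshold(s, rates = list(mk(5), mk(5))), 5)
  # all-silent session: threshold 0 with a warning
  expect_warning(th0 <- burst_threshold(s, rates = list(mk(0), mk(0))),
                 "threshold")
  expect_equal(th0, 0)
  expect_error(burst_threshold(s, rates = list(mk(4))), "2 trials")
})

test_that("burst detection applies duration and proximity rules", {
  grid <- seq(0, 8, 0.01)
  mk_series <- function(pop) list(time = grid, population = pop)
  # always below threshold: nothing
  expect_equal(nrow(detect_bursts(mk_series(rep(1, length(grid))), 5)), 0)
  # a 200-ms excursion is one event; a 50-ms one is dropped
  pop <- rep(1, length(grid))
  pop[grid >= 2 & grid < 2.2] <- 10
  pop[grid >= 5 & grid < 5.05] <- 10
  ev <- detect_bursts(mk_series(pop), 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 2, tolerance = 0.02)
  expect_equal(ev$end, 2.2, tolerance = 0.02)
  # two events 100 ms apart: only the higher peak survives
  pop2 <- rep(1, length(grid))
  pop2[grid >= 2 & grid < 2.2] <- 8
  pop2[grid >= 2.3 & grid < 2.5] <- 12
  ev2 <- detect_bursts(mk_series(pop2), 5)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$peak_hz, 12)
  # surviving events are >= proximity apart and >= min duration long
  set.seed(73)
  pop3 <- 5 + 3 * stats::filter(rnorm(length(grid)), rep(1, 10), sides = 1) / sqrt(10)
  pop3[is.na(pop3)] <- 5
  ev3 <- detect_bursts(mk_series(as.numeric(pop3)), 7)
  if (nrow(ev3) > 1) {
    expect_true(all(ev3$start[-1] - ev3$end[-nrow(ev3)] >= 0.15 - 1e-9))
  }
  expect_true(all(ev3$end - ev3$start >= 0.1 - 1e-9))
})

test_that("injected population elevations are recovered reliably", {
  # 20-unit Poisson population; 200-ms 5x elevation against a fixed threshold
  set.seed(75)
  grid <- seq(0, 8, 0.01)
  n_hit <- 0; n_fp <- 0
  for (i in 1:200) {
    st_base <- sort(runif(rpois(1, 5 * 8 * 20), 0, 8))           # 20 units pooled
    st_inj <- sort(c(st_base, runif(rpois(1, 4 * 5 * 0.2 * 20), 4, 4.2)))
    pop_of <- function(st) vapply(grid, function(t)
      sum(stats::dnorm(t - st, sd = 0.025)) / 20, 0)
    ev <- detect_bursts(list(time = grid, population = pop_of(st_inj)),
                        threshold = 10)
    if (nrow(ev) && any(ev$start < 4.2 & ev$end > 4)) n_hit <- n_hit + 1
    ev0 <- detect_bursts(list(time = grid, population = pop_of(st_base)),
                         threshold = 10)
    if (nrow(ev0)) n_fp <- n_fp + 1
  }
  expect_gte(n_hit / 200, 0.9)
  expect_lt(n_fp / 200, 0.05)
})

test_that("period assignment uses the 80% rule with inclusive boundary", {
  expect_equal(assign_period(3.1, 3.4, 1), "maintenance")
  # 0.4 of 0.5 inside maintenance: exactly 80%, assigned
  expect_equal(assign_period(2.9, 3.4, 1), "maintenance")
  # 50/50 straddle: unassigned
  expect_equal(assign_period(2.75, 3.25, 1), "unassigned")
  # probe right edge set by the response time
  expect_equal(assign_period(6.1, 6.6, 1), "probe")
  expect_equal(assign_period(6.8, 7.3, 0.9), "unassigned")  # probe ends at 6.9
})

test_that("sparsity matches the analytic extremes and the hand value", {
  expect_equal(sparsity(c(1, rep(0, 9))), 0)
  for (n in c(2, 5, 11)) expect_equal(sparsity(rep(3, n)), 1)
  # w = (3, 1): 1 - (sqrt(2) - 4/sqrt(10)) / (sqrt(2) - 1)
  expect_equal(sparsity(c(3, 1)), 1 - (sqrt(2) - 4 / sqrt(10)) / (sqrt(2) - 1))
  expect_equal(round(sparsity(c(3, 1)), 4), 0.6396)
  # invariant to positive rescaling, bounded in [0, 1]
  set.seed(77)
  for (i in 1:20) {
    w <- runif(8)
    expect_equal(sparsity(w), sparsity(runif(1, 0.1, 10) * w))
    expect_gte(sparsity(w), 0); expect_lte(sparsity(w), 1)
  }
  expect_error(sparsity(1), "2 units")
  expect_error(sparsity(c(0, 0)), "zero")
})

test_that("burst composition and weighted LvR behave as weighted means", {
  grid <- seq(0, 8, 0.01)
  ur <- rbind(a = rep(2, length(grid)), b = rep(6, length(grid)))
  rs <- list(time = grid, unit_rates = ur, population = colMeans(ur))
  w <- burst_composition(rs, 3, 3.5)
  expect_equal(unname(w), c(2, 6))
  expect_equal(burst_weighted_lvr(c(a = 1.0, b = 2.0), c(a = 1, b = 3)), 1.75)
  expect_equal(burst_weighted_lvr(c(a = 0.4, b = 1.6), c(a = 1, b = 0)), 0.4)
  expect_equal(burst_weighted_lvr(c(a = 0.7, b = 0.7), c(a = 2, b = 5)), 0.7)
  # missing LvR drops the unit with weight renormalization
  expect_equal(burst_weighted_lvr(c(a = NA, b = 2), c(a = 10, b = 1)), 2)
  expect_true(is.na(burst_weighted_lvr(c(a = NA, b = NA), c(a = 1, b = 1))))
})

test_that("burst density recovers probe-locked bursts and degenerate cases", {
  # no bursts anywhere: zero density with zero-width CI
  trials <- data.frame(trial_id = 1:5, response_time = rep(1, 5))
  empty <- data.frame(trial_id = integer(0), start = numeric(0),
                      end = numeric(0))
  d0 <- burst_density(empty, trials, n_boot = 50)
  expect_true(all(d0$density == 0) && all(d0$hi == 0))
  # single trial: zero-width CI at every bin
  ev1 <- data.frame(trial_id = 1L, start = 2, end = 2.5)
  d1 <- burst_density(ev1, trials[1, ], n_boot = 50)
  expect_equal(d1$lo, d1$density)
  expect_equal(d1$hi, d1$density)
  # probe-locked bursts in the generator show up after probe onset
  cfg <- generator_config(n_sessions = 1, units_per_region = 4, n_trials = 15,
                          probe_burst_gain = 4, seed = 79)
  co <- synth_cohort(cfg)
  s <- subset_units(co$sessions[[1]],
                    co$sessions[[1]]$units$unit_id[
                      co$sessions[[1]]$units$region != "hippocampus"])
  ev <- session_bursts(s)
  dd <- burst_density(ev, s$trials, n_boot = 100)
  probe_ix <- dd$time >= 6 & dd$time < 7
  base_ix <- dd$time >= 1 & dd$time < 6
  expect_gt(max(dd$density[probe_ix]), max(dd$density[base_ix]))
  # response alignment drops truncated trials
  tr2 <- data.frame(trial_id = 1:4, response_time = c(1, 1, 2.5, 3))
  d2 <- burst_density(empty, tr2, align = "response", n_boot = 10)
  expect_equal(d2$n_trials, 2)
})
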