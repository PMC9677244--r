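#' Configuration for the synthetic cohort generator
#'
#' The generator emulates trial-structured recordings of a Sternberg task:
#' 8-s trials (1 s fixation, 2 s encoding, 3 s maintenance, probe until the
#' response), units with heterogeneous rates and irregularity (gamma-renewal
#' shape spanning the regular-to-bursty range), and injectable effects —
#' a workload (set-size) rate gain in a coding subpopulation, probe-locked
#' population bursts in amygdala/entorhinal units, and a trial-level
#' coupling between burstiness and response time.
#'
#' @param n_sessions Number of sessions in the cohort.
#' @param units_per_region Units per anatomical region per session.
#' @param n_trials Trials per session (default 50, one task session).
#' @param base_rate_hz_range Uniform range the per-unit base rates are drawn
#'   from (default 2-15 Hz).
#' @param gamma_shape_range Uniform range for the per-unit gamma-renewal
#'   shape; 0.4-3.0 spans bursty (LvR near 1.7) to regular (near 0.4).
#' @param setsize_gain Multiplicative rate gain for set sizes 6 and 8 in the
#'   coding subpopulation (default 1.3).
#' @param setsize_fraction Fraction of units in the coding subpopulation
#'   (default 0.25).
#' @param probe_burst_gain Multiplicative rate gain in the 0.5 s after probe
#'   onset for amygdala and entorhinal units (default 3).
#' @param rt_lvr_coupling Coefficient linking the trial-level burstiness
#'   latent to response time (default 0 = off).
#' @param latent_shape_scale How strongly the trial latent scales per-unit
#'   burstiness (log-shape deflection per latent s.d., default 0.3).
#' @param wrong_rate Probability of a wrong response (default 0.1).
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters (default
#'   median 0.8 s, sdlog 0.4); draws truncated to `[0.3, 2.5]` s.
#' @param seed Integer seed for [synth_cohort()].
#' @return A `spikewm_config` list.
#' @export
generator_config <- function(n_sessions = 4, units_per_region = 5,
                             n_trials = 50,
                             base_rate_hz_range = c(2, 15),
                             gamma_shape_range = c(0.4, 3.0),
                             setsize_gain = 1.3, setsize_fraction = 0.25,
                             probe_burst_gain = 3.0,
                             rt_lvr_coupling = 0,
                             latent_shape_scale = 0.3,
                             wrong_rate = 0.1,
                             rt_meanlog = log(0.8), rt_sdlog = 0.4,
                             seed = 1L) {
  cfg <- list(n_sessions = n_sessions, units_per_region = units_per_region,
              n_trials = n_trials, base_rate_hz_range = base_rate_hz_range,
              gamma_shape_range = gamma_shape_range,
              setsize_gain = setsize_gain, setsize_fraction = setsize_fraction,
              probe_burst_gain = probe_burst_gain,
              rt_lvr_coupling = rt_lvr_coupling,
              latent_shape_scale = latent_shape_scale,
              wrong_rate = wrong_rate,
              rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
              seed = as.integer(seed))
  stopifnot(cfg$setsize_gain >= 0, cfg$probe_burst_gain >= 0,
            cfg$wrong_rate >= 0, cfg$wrong_rate <= 1,
            all(cfg$gamma_shape_range > 0),
            cfg$setsize_fraction >= 0, cfg$setsize_fraction <= 1)
  class(cfg) <- "spikewm_config"
  cfg
}

#' Simulate a stationary gamma-renewal spike train
#'
#' Inter-spike intervals are i.i.d. gamma with shape `shape` and mean
#' `1/rate_hz`.  The first spike is drawn from the equilibrium residual-time
#' distribution (a uniform fraction of a length-biased interval, which for a
#' gamma ISI is gamma with shape `shape + 1`), so windowed statistics are
#' stationary from time 0.  Shape 1 gives a Poisson process (expected LvR
#' 1); for general shape the expected local variation is `3/(2*shape + 1)`.
#'
#' @param rate_hz Mean firing rate in Hz (> 0).
#' @param shape Gamma shape parameter (> 0); < 1 bursty, > 1 regular.
#' @param duration_s Train length in seconds.
#' @return Sorted spike times in `[0, duration_s]`.
#' @export
gamma_renewal_train <- function(rate_hz, shape, duration_s) {
  stopifnot(rate_hz > 0, shape > 0)
  isi_rate <- shape * rate_hz  # gamma rate parameter for mean ISI 1/rate_hz
  t0 <- stats::runif(1) * stats::rgamma(1, shape + 1, rate = isi_rate)
  if (t0 > duration_s) return(numeric(0))
  times <- t0
  # draw ISIs in blocks until past the end
  repeat {
    n_draw <- max(16L, ceiling((duration_s - times[length(times)]) * rate_hz * 1.5))
    isis <- stats::rgamma(n_draw, shape, rate = isi_rate)
    times <- c(times, times[length(times)] + cumsum(isis))
    if (times[length(times)] > duration_s) break
  }
  times[times <= duration_s]
}

#' Piecewise-constant rate profile
#'
#' @param breaks Increasing time breakpoints covering the trial (length
#'   `k + 1`).
#' @param rates Non-negative rates (Hz) on each of the `k` pieces.
#' @return A `spikewm_rate_profile`.
#' @export
rate_profile <- function(breaks, rates) {
  stopifnot(length(breaks) == length(rates) + 1, !is.unsorted(breaks),
            all(rates >= 0))
  structure(list(breaks = breaks, rates = rates), class = "spikewm_rate_profile")
}

#' Simulate an inhomogeneous gamma-renewal spike train
#'
#' Time-rescaling: a unit-rate equilibrium gamma-renewal process is
#' generated on the rescaled axis of total integrated rate and mapped back
#' through the inverse cumulative rate, so the expected count in any window
#' equals the rate integral over that window while the local interval
#' statistics retain the gamma-renewal irregularity.
#'
#' @param profile A [rate_profile()].
#' @param shape Gamma shape parameter (> 0).
#' @return Sorted spike times within the profile support.
#' @export
inhomogeneous_train <- function(profile, shape) {
  br <- profile$breaks; ra <- profile$rates
  seg <- diff(br)
  cum <- c(0, cumsum(ra * seg))         # cumulative rate at each break
  total <- cum[length(cum)]
  if (total <= 0) return(numeric(0))
  u <- gamma_renewal_train(1, shape, total)
  if (!length(u)) return(numeric(0))
  # invert the piecewise-linear cumulative rate
  idx <- findInterval(u, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(ra))
  t <- br[idx] + ifelse(ra[idx] > 0, (u - cum[idx]) / ra[idx], 0)
  sort(t[t <= br[length(br)]])
}

# draw a truncated log-normal response time
.draw_rt <- function(meanlog, sdlog, lo = 0.3, hi = 2.5) {
  for (i in 1:100) {
    x <- stats::rlnorm(1, meanlog, sdlog)
    if (x >= lo && x <= hi) return(x)
  }
  stats::runif(1, lo, hi)
}

#' Simulate one session
#'
#' Draws trial metadata (set sizes uniform over 4/6/8 but forced to 4 after
#' a wrong response; truncated log-normal response times), per-unit base
#' rates and gamma shapes, a shared standard-normal trial latent `z_t`, and
#' spike trains from inhomogeneous gamma renewal.  The latent scales each
#' unit's log-shape that trial (burstier trials when `z_t > 0`) and, when
#' `rt_lvr_coupling > 0`, multiplies the response time by
#' `exp(rt_lvr_coupling * z_t)`.
#'
#' Uses the current R random-number stream; callers wanting reproducibility
#' set the seed (as [synth_cohort()] does).
#'
#' @param config A [generator_config()].
#' @param session_id,subject_id Identifiers for the generated session.
#' @return List with `session` (a `spikewm_session`) and `truth` (per-unit
#'   shape/rate/coding membership and per-trial latents).
#' @export
synth_session <- function(config, session_id = "S1", subject_id = session_id) {
  cfg <- config
  n_tr <- cfg$n_trials
  nU <- cfg$units_per_region * 3L

  # trial metadata; set size forced to 4 after a wrong response
  correct <- stats::runif(n_tr) > cfg$wrong_rate
  set_size <- integer(n_tr)
  for (t in seq_len(n_tr)) {
    set_size[t] <- if (t > 1 && !correct[t - 1]) 4L else
      sample(c(4L, 6L, 8L), 1)
  }
  z <- stats::rnorm(n_tr)
  rt <- vapply(seq_len(n_tr), function(t)
    .draw_rt(cfg$rt_meanlog, cfg$rt_sdlog) * exp(cfg$rt_lvr_coupling * z[t]), 0)

  units <- data.frame(
    unit_id = sprintf("%s_u%02d", session_id, seq_len(nU)),
    region = rep(REGIONS, each = cfg$units_per_region),
    stringsAsFactors = FALSE)
  base_rate <- stats::runif(nU, cfg$base_rate_hz_range[1], cfg$base_rate_hz_range[2])
  shape <- stats::runif(nU, cfg$gamma_shape_range[1], cfg$gamma_shape_range[2])
  n_code <- round(cfg$setsize_fraction * nU)
  coding <- rep(FALSE, nU)
  if (n_code > 0) coding[sample.int(nU, n_code)] <- TRUE

  spikes <- vector("list", nU)
  names(spikes) <- units$unit_id
  for (u in seq_len(nU)) {
    tr_list <- vector("list", n_tr)
    names(tr_list) <- as.character(seq_len(n_tr))
    burst_unit <- units$region[u] %in% c("amygdala", "entorhinal")
    for (t in seq_len(n_tr)) {
      r <- base_rate[u]
      if (coding[u] && set_size[t] >= 6) r <- r * cfg$setsize_gain
      if (burst_unit && cfg$probe_burst_gain != 1) {
        prof <- rate_profile(c(0, 6, 6.5, 8),
                             c(r, r * cfg$probe_burst_gain, r))
      } else {
        prof <- rate_profile(c(0, 8), r)
      }
      k_t <- shape[u] * exp(-cfg$latent_shape_scale * z[t])
      tr_list[[t]] <- inhomogeneous_train(prof, k_t)
    }
    spikes[[u]] <- tr_list
  }

  trials <- data.frame(trial_id = seq_len(n_tr), set_size = set_size,
                       correct = correct, response_time = rt)
  sess <- new_session(session_id, subject_id, units, trials, spikes)
  truth <- list(session_id = session_id,
                unit_id = units$unit_id, region = units$region,
                base_rate_hz = base_rate, gamma_shape = shape,
                coding = coding, trial_latent = z)
  list(session = sess, truth = truth)
}

#' Simulate a cohort of sessions
#'
#' Seeds the R random-number stream from `config$seed`, generates
#' `config$n_sessions` sessions and collects the ground truth (per-unit
#' shapes, rates and coding membership; per-trial latents) for
#' parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return List with `sessions` (list of `spikewm_session`) and `truth`
#'   (list of per-session truth records).
#' @export
synth_cohort <- function(config) {
  set.seed(config$seed)
  out <- lapply(seq_len(config$n_sessions), function(i)
    synth_session(config, session_id = sprintf("S%02d", i),
                  subject_id = sprintf("P%02d", i)))
  list(sessions = lapply(out, `[[`, "session"),
       truth = lapply(out, `[[`, "truth"))
}

#' Write a cohort and its ground truth to disk
#'
#' One directory per session (see [write_session()]) plus `truth.json`.
#'
#' @param cohort Result of [synth_cohort()].
#' @param dir_path Output directory.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$sessions)
    write_session(s, file.path(dir_path, s$session_id))
  jsonlite::write_json(cohort$truth, file.path(dir_path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir_path)
}

#' Read a cohort written by [write_cohort()]
#' @param dir_path Cohort directory.
#' @return List with `sessions` and `truth` (NULL if no truth file).
#' @export
read_cohort <- function(dir_path) {
  dirs <- list.dirs(dir_path, recursive = FALSE)
  sessions <- lapply(dirs, read_session)
  tf <- file.path(dir_path, "truth.json")
  truth <- NULL
  if (file.exists(tf)) {
    raw <- jsonlite::read_json(tf, simplifyVector = FALSE)
    truth <- lapply(raw, function(rec) lapply(rec, function(f)
      if (is.list(f)) unlist(f) else f))
  }
  list(sessions = sessions, truth = truth)
}
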