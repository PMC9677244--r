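# Small session builders used across the test files.

# a session of homogeneous Poisson units (fixed rates, Hz)
poisson_session <- function(rates_hz, n_trials = 10, region = "hippocampus",
                            session_id = "P", response_time = 1) {
  nU <- length(rates_hz)
  units <- data.frame(unit_id = sprintf("%s_u%02d", session_id, seq_len(nU)),
                      region = rep(region, length.out = nU),
                      stringsAsFactors = FALSE)
  trials <- data.frame(trial_id = seq_len(n_trials),
                       set_size = rep(c(4L, 6L, 8L), length.out = n_trials),
                       correct = TRUE,
                       response_time = response_time)
  spikes <- lapply(seq_len(nU), function(u) {
    l <- lapply(seq_len(n_trials), function(t)
      sort(stats::runif(stats::rpois(1, rates_hz[u] * 8), 0, 8)))
    names(l) <- as.character(seq_len(n_trials))
    l
  })
  names(spikes) <- units$unit_id
  new_session(session_id, session_id, units, trials, spikes)
}

# hand-built two-unit, two-trial toy session (8 spikes total)
toy_session <- function() {
  units <- data.frame(unit_id = c("u1", "u2"),
                      region = c("hippocampus", "amygdala"))
  trials <- data.frame(trial_id = 1:2, set_size = c(4L, 6L),
                       correct = c(TRUE, FALSE), response_time = c(0.8, 1.4))
  spikes <- list(
    u1 = list(`1` = c(0.5, 2.0), `2` = c(1.1, 7.9)),
    u2 = list(`1` = c(3.3, 3.4), `2` = c(0.2, 6.5)))
  new_session("toy", "subj1", units, trials, spikes)
}

# regular (equally spaced) spike train at a given rate
regular_train <- function(rate_hz, duration_s = 8, phase = 0) {
  seq(phase, duration_s, by = 1 / rate_hz)
}
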