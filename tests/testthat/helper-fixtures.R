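# Shared fixtures, built once per test run and memoized.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache, inherits = FALSE))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

tiny_space <- function() fx("tiny_space", function()
  build_source_space(n_cortical = 60, n_subcortical = 12, n_regions = 6,
                     seed = 11))

tiny_leadfield <- function() fx("tiny_lf", function()
  build_leadfield(tiny_space(), n_sensors = 16, seed = 12))

tiny_design <- function() fx("tiny_design", function()
  cohort_design(n_group_a = 3, n_group_b = 3, n_trials = 12,
                sampling_rate = 250, n_cortical = 60, n_subcortical = 12,
                n_regions = 6, n_sensors = 16, n_volumes = 80,
                gswd_rate = c(a = 0, b = 0), master_seed = 42))

# per-trial band-limited oscillation recording: two channels with a fixed
# phase lag, used by the coherency identity tests
lagged_trialset <- function(n_trials = 50, rate = 250, f = 6, lag = pi / 2,
                            noise = 0, seed = 5) {
  len <- 2 * rate
  tt <- seq_len(len) / rate
  withr::with_seed(seed, {
    trials <- array(0, dim = c(n_trials, 2, len))
    for (j in seq_len(n_trials)) {
      ph <- runif(1, 0, 2 * pi)
      trials[j, 1, ] <- sin(2 * pi * f * tt + ph) + noise * rnorm(len)
      trials[j, 2, ] <- sin(2 * pi * f * tt + ph - lag) + noise * rnorm(len)
    }
    trial_set(trials, rate, seq(0, by = 2, length.out = n_trials))
  })
}

# white-noise trial set
noise_trialset <- function(n_trials, n_ch, rate = 250, seed = 6) {
  len <- 2 * rate
  withr::with_seed(seed, {
    trials <- array(rnorm(n_trials * n_ch * len), c(n_trials, n_ch, len))
    trial_set(trials, rate, seq(0, by = 2, length.out = n_trials))
  })
}

# mean event-locked-average power (variance of the locked average waveform)
locked_power <- function(rec, times_s, len_s) {
  rate <- rec$rate
  len <- round(len_s * rate)
  samp <- round(times_s * rate) + 1L
  samp <- samp[samp + len - 1L <= ncol(rec$data)]
  avg <- 0
  for (s in samp) avg <- avg + rec$data[, s:(s + len - 1L)]
  avg <- avg / length(samp)
  mean(apply(avg, 1, var))
}
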