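test_that("CSD of independent white channels is near-diagonal", {
  ts <- noise_trialset(500, 4, seed = 61)
  cs <- estimate_csd(ts, "alpha")
  d <- Re(diag(cs$matrix))
  off <- abs(cs$matrix[upper.tri(cs$matrix)])
  expect_lt(max(off), 0.05 * min(d))   # Monte-Carlo oracle bound
})

test_that("duplicated channels give unit coherence in every band", {
  ts <- noise_trialset(50, 1, seed = 62)
  trials <- array(0, c(50, 2, dim(ts$trials)[3]))
  trials[, 1, ] <- ts$trials[, 1, ]
  trials[, 2, ] <- ts$trials[, 1, ]
  ts2 <- trial_set(trials, ts$rate, ts$trial_onsets_s)
  for (bn in c("theta", "alpha", "gamma")) {
    cs <- estimate_csd(ts2, bn)
    coh <- abs(cs$matrix[1, 2]) / sqrt(Re(cs$matrix[1, 1]) * Re(cs$matrix[2, 2]))
    expect_equal(coh, 1, tolerance = 1e-10)
  }
})

test_that("band-integrated CSD diagonal matches band-filtered variance", {
  ts <- noise_trialset(200, 1, rate = 250, seed = 63)
  band <- default_bands()$alpha
  cs <- estimate_csd(ts, band)
  df <- ts$rate / dim(ts$trials)[3]
  band_power <- Re(cs$matrix[1, 1]) * cs$meta$n_bins * df
  # Parseval-check oracle: boxcar periodogram energy in the band, computed
  # independently per trial (no taper, direct definition)
  len <- dim(ts$trials)[3]
  freq <- (0:(len - 1)) * ts$rate / len
  bins <- which(freq > 0 & freq >= band$f_lo & freq <= band$f_hi &
                  freq <= ts$rate / 2)
  v <- mean(apply(ts$trials[, 1, ], 1, function(x)
    2 * sum(abs(fft(x)[bins])^2) / (len^2)))
  expect_equal(band_power, v, tolerance = 0.1 * v)
})

test_that("CSD estimation validates its inputs", {
  ts <- noise_trialset(1, 2)
  expect_error(estimate_csd(ts, "theta"), class = "rc_error")
  ts2 <- noise_trialset(5, 2, rate = 250)
  expect_error(estimate_csd(ts2, band_spec("hf", 130, 140)), class = "rc_error")
  # a band narrower than the 0.5 Hz resolution of 2-s trials
  expect_error(estimate_csd(ts2, band_spec("sliver", 10.1, 10.2)),
               class = "rc_error_resolution")
})

test_that("DICS weights equal an explicit dense-solve oracle", {
  withr::with_seed(71, {
    A <- matrix(rnorm(16), 4) + 1i * matrix(rnorm(16), 4)
    C <- A %*% Conj(t(A)) + diag(4)
    C <- (C + Conj(t(C))) / 2
    L <- matrix(rnorm(4 * 6), 4, 6)
  })
  cs <- cross_spectrum(C, "theta", 10, "sensor")
  lf <- list(gain = L, sensor_labels = sprintf("E%03d", 1:4))
  class(lf) <- "leadfield"
  filt <- dics_filters(cs, lf, lambda_fraction = 0.05)
  # oracle: per-vertex explicit regularized inverse solve
  Cr <- Re(C) + 0.05 * mean(diag(Re(C))) * diag(4)
  for (v in 1:6) {
    wv <- solve(Cr, L[, v]) / as.numeric(t(L[, v]) %*% solve(Cr, L[, v]))
    expect_equal(unname(filt$weights[v, ]), as.vector(wv), tolerance = 1e-10)
  }
  # unit-gain identity
  expect_equal(unname(rowSums(filt$weights * t(L))), rep(1, 6),
               tolerance = 1e-8)
  # lambda = 0 on a well-conditioned CSD equals the unregularized beamformer
  filt0 <- dics_filters(cs, lf, lambda_fraction = 0)
  for (v in 1:6) {
    wv <- solve(Re(C), L[, v]) /
      as.numeric(t(L[, v]) %*% solve(Re(C), L[, v]))
    expect_equal(unname(filt0$weights[v, ]), as.vector(wv), tolerance = 1e-10)
  }
})

test_that("source power localizes a single active source", {
  sp <- build_source_space(100, 0, 4, seed = 81)
  lf <- build_leadfield(sp, 32)
  v_star <- 57
  rate <- 250; len <- 2 * rate; n_tr <- 60
  withr::with_seed(82, {
    trials <- array(0, c(n_tr, 32, len))
    for (j in seq_len(n_tr)) {
      src <- signal::filtfilt(signal::butter(4, c(8, 12) / 125, "pass"),
                              rnorm(len + 200))[101:(len + 100)]
      trials[j, , ] <- outer(lf$gain[, v_star], src) +
        matrix(rnorm(32 * len, sd = 0.01), 32, len)
    }
  })
  ts <- trial_set(trials, rate, seq(0, by = 2, length.out = n_tr))
  cs <- estimate_csd(ts, "alpha")
  filt <- dics_filters(cs, lf)
  pm <- source_power_map(filt, cs)
  expect_equal(which.max(pm$values), v_star)   # exhaustive-scan oracle
})

test_that("source power scales quadratically and zero data maps to zero", {
  ts <- noise_trialset(20, 4, seed = 83)
  cs <- estimate_csd(ts, "beta1")
  lf <- list(gain = matrix(rnorm(4 * 10), 4, 10),
             sensor_labels = sprintf("E%03d", 1:4))
  class(lf) <- "leadfield"
  filt <- dics_filters(cs, lf)
  pm <- source_power_map(filt, cs)
  cs2 <- cross_spectrum(4 * cs$matrix, cs$band, cs$n_trials_used, "sensor")
  pm2 <- source_power_map(filt, cs2)
  expect_equal(pm2$values, 4 * pm$values, tolerance = 1e-10)
  cs0 <- cross_spectrum(matrix(0 + 0i, 4, 4), cs$band, 1, "sensor")
  expect_equal(source_power_map(filt, cs0)$values, rep(0, 10))
})

test_that("source CSD is Hermitian with diagonal equal to the power map", {
  ts <- noise_trialset(30, 6, seed = 84)
  cs <- estimate_csd(ts, "theta")
  lf <- list(gain = matrix(rnorm(6 * 15), 6, 15),
             sensor_labels = sprintf("E%03d", 1:6))
  class(lf) <- "leadfield"
  filt <- dics_filters(cs, lf)
  src <- source_cross_spectrum(filt, cs)
  expect_lt(max(abs(src$matrix - Conj(t(src$matrix)))), 1e-12)
  pm <- source_power_map(filt, cs)
  expect_equal(Re(diag(src$matrix)), pm$values, tolerance = 1e-10)
  expect_error(source_cross_spectrum(filt, cs, max_vertices = 10),
               class = "rc_error_memory")
})

test_that("filters are invariant to trial order", {
  ts <- noise_trialset(20, 4, seed = 85)
  perm <- sample(20)
  ts2 <- trial_set(ts$trials[perm, , ], ts$rate, ts$trial_onsets_s)
  cs1 <- estimate_csd(ts, "alpha")
  cs2 <- estimate_csd(ts2, "alpha")
  expect_equal(cs1$matrix, cs2$matrix, tolerance = 1e-12)
})

test_that("a non-leadfield artifact topography is suppressed in source space", {
  sp <- build_source_space(80, 0, 4, seed = 91)
  lf <- build_leadfield(sp, 24)
  rate <- 250; len <- 2 * rate; n_tr <- 50
  withr::with_seed(92, {
    art_topo <- rnorm(24)
    art_topo <- art_topo / sqrt(sum(art_topo^2))
    brain <- array(0, c(n_tr, 24, len))
    art <- array(0, c(n_tr, 24, len))
    for (j in seq_len(n_tr)) {
      S <- matrix(rnorm(80 * len), 80, len)
      brain[j, , ] <- lf$gain %*% S
      art[j, , ] <- outer(art_topo, rnorm(len, sd = 30))
    }
  })
  ts <- trial_set(brain + art, rate, seq(0, by = 2, length.out = n_tr))
  cs <- estimate_csd(ts, "alpha")
  filt <- dics_filters(cs, lf)
  # sensor-level artifact share vs its share after beamforming
  cs_art <- estimate_csd(trial_set(art, rate, ts$trial_onsets_s), "alpha")
  cs_brain <- estimate_csd(trial_set(brain, rate, ts$trial_onsets_s), "alpha")
  sens_ratio <- sum(Re(diag(cs_art$matrix))) / sum(Re(diag(cs_brain$matrix)))
  src_ratio <- sum(source_power_map(filt, cs_art)$values) /
    sum(source_power_map(filt, cs_brain)$values)
  expect_gt(10 * log10(sens_ratio / src_ratio), 10)
})
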