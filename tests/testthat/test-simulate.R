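test_that("zero coupling gives an empty coupled-pair list", {
  des <- cohort_design(n_group_a = 2, n_group_b = 2, coupling_gain_a = 0,
                       coupling_gain_b = 0, n_trials = 4, sampling_rate = 250,
                       n_cortical = 60, n_subcortical = 12, n_regions = 6,
                       n_sensors = 8, gswd_rate = c(a = 0, b = 0),
                       master_seed = 1)
  sim <- simulate_eeg_subject(tiny_space(), build_leadfield(tiny_space(), 8),
                              des, 1, "outside")
  expect_equal(nrow(sim$ground_truth$coupled_pairs), 0)
})

test_that("EEG simulation is byte-identical for a fixed seed", {
  des <- tiny_design()
  sp <- tiny_space(); lf <- tiny_leadfield()
  a <- simulate_eeg_subject(sp, lf, des, 2, "inside")
  b <- simulate_eeg_subject(sp, lf, des, 2, "inside")
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$recording$events, b$recording$events)
  c_ <- simulate_eeg_subject(sp, lf, des, 2, "inside", seed = 999)
  expect_false(identical(a$recording$data, c_$recording$data))
})

test_that("sensor data equal leadfield times sources plus noise (linearity)", {
  des <- cohort_design(n_group_a = 2, n_group_b = 2, n_trials = 4,
                       sampling_rate = 250, n_cortical = 60,
                       n_subcortical = 12, n_regions = 6, n_sensors = 8,
                       noise_sd = 0, gswd_rate = c(a = 0, b = 0),
                       master_seed = 3)
  sp <- tiny_space(); lf <- build_leadfield(sp, 8)
  sim <- simulate_eeg_subject(sp, lf, des, 1, "outside",
                              return_sources = TRUE)
  pred <- lf$gain %*% sim$ground_truth$sources
  expect_lt(max(abs(pred - sim$recording$data)) / max(abs(pred)), 1e-10)
})

test_that("coupled pairs receive elevated band imaginary coherency", {
  des <- cohort_design(n_group_a = 2, n_group_b = 2, coupling_gain_a = 2.5,
                       gain_jitter = 0, n_trials = 40, sampling_rate = 250,
                       n_cortical = 60, n_subcortical = 12, n_regions = 6,
                       n_sensors = 16, gswd_rate = c(a = 0, b = 0),
                       master_seed = 5)
  sp <- tiny_space(); lf <- tiny_leadfield()
  sim <- simulate_eeg_subject(sp, lf, des, 1, "outside",
                              return_sources = TRUE)
  gt <- sim$ground_truth
  expect_gt(nrow(gt$coupled_pairs), 0)
  # oracle on the true sources: band ImCoh of coupled vs uncoupled pairs
  S <- gt$sources
  len <- 500
  ntr <- ncol(S) %/% len
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(len - 1)) / len)
  freq <- (0:(len - 1)) * 250 / len
  bins <- which(freq >= 4 & freq <= 8)
  band_imcoh <- function(x, y) {
    sxy <- sxx <- syy <- 0
    for (j in seq_len(ntr)) {
      ii <- ((j - 1) * len + 1):(j * len)
      X <- fft(x[ii] * w); Y <- fft(y[ii] * w)
      sxy <- sxy + sum(X[bins] * Conj(Y[bins]))
      sxx <- sxx + sum(abs(X[bins])^2); syy <- syy + sum(abs(Y[bins])^2)
    }
    abs(Im(sxy / sqrt(sxx * syy)))
  }
  cp <- gt$coupled_pairs[1:5, , drop = FALSE]
  coupled <- mapply(function(a, b) band_imcoh(S[a, ], S[b, ]),
                    cp[, 1], cp[, 2])
  bg <- replicate(5, {
    v <- sample(which(!(seq_len(n_vertices(sp)) %in% unlist(gt$coupled_pairs))), 2)
    band_imcoh(S[v[1], ], S[v[2], ])
  })
  expect_gt(min(coupled), max(bg))
})

test_that("artifact injection is additive, event-complete and guarded", {
  rate <- 500
  rec0 <- sensor_recording(matrix(0, 4, 20 * rate), rate)
  out <- inject_scanner_artifacts(rec0, tr = 2, ga_amplitude = 0,
                                  bcg_amplitude = 0, seed = 1)
  expect_identical(out$data, rec0$data)        # identity when disabled
  expect_length(out$events$tr_triggers_s, 10)

  withr::with_seed(2, {
    brain <- matrix(rnorm(4 * 20 * rate, sd = 10), 4, 20 * rate)
  })
  recb <- sensor_recording(brain, rate)
  ga <- inject_scanner_artifacts(recb, tr = 2, ga_amplitude = 5000,
                                 bcg_amplitude = 0, seed = 3)
  expect_gt(var(as.vector(ga$data)), 100 * var(as.vector(brain)))

  expect_error(inject_scanner_artifacts(recb, tr = 0, 10, 10),
               class = "rc_error_config")
  expect_error(inject_scanner_artifacts(recb, tr = 2, 10, 10,
                                        ga_template_s = 3),
               class = "rc_error_config")
  expect_error(inject_scanner_artifacts(ga, tr = 2, 10, 10),
               class = "rc_error_validation")  # already has scanner events
})

test_that("beat intervals follow the cardiac rate within 2%", {
  rec0 <- sensor_recording(matrix(0, 2, 300 * 500), 500)
  out <- inject_scanner_artifacts(rec0, tr = 2, ga_amplitude = 0,
                                  bcg_amplitude = 50, cardiac_rate = 1.0,
                                  cardiac_jitter = 0.05, seed = 8)
  ibi <- diff(out$events$cardiac_s)
  expect_gt(length(ibi), 200)
  expect_lt(abs(mean(ibi) - 1.0), 0.02)        # sample-mean oracle
})

test_that("BOLD simulation is deterministic, planted and guarded", {
  des <- tiny_design()
  sp <- tiny_space()
  a <- simulate_bold_subject(sp, des, 1)
  b <- simulate_bold_subject(sp, des, 1)
  expect_identical(a$series, b$series)
  expect_equal(nrow(a$confounds), des$n_volumes)
  expect_setequal(unique(a$location_kind), c("brain", "wm", "csf"))

  des_bad <- des; des_bad$n_volumes <- 5L
  expect_error(simulate_bold_subject(sp, des_bad, 1),
               class = "rc_error_invalid_design")
})

test_that("null BOLD coupling leaves seed-target correlation near zero", {
  des <- cohort_design(n_group_a = 2, n_group_b = 2, n_trials = 4,
                       sampling_rate = 250, n_cortical = 60,
                       n_subcortical = 12, n_regions = 6, n_sensors = 8,
                       n_volumes = 300, bold_coupling_gain_a = 0,
                       bold_coupling_gain_b = 0, spike_prob = 0,
                       gswd_rate = c(a = 0, b = 0), master_seed = 9)
  sp <- tiny_space()
  sv <- region_vertices(sp, "thalamus_l")
  tv <- region_vertices(sp, "precuneus_pcc")
  rs <- replicate(20, {
    i <- sample(4, 1)
    b <- simulate_bold_subject(sp, des, i, seed = sample.int(1e6, 1))
    b <- bandpass_bold(regress_confounds(flag_outlier_volumes(b)))
    cor(colMeans(b$series[sv, , drop = FALSE]),
        colMeans(b$series[tv, , drop = FALSE]))
  })
  expect_lt(median(abs(rs)), 0.1)
})

test_that("cohort simulation covers all subjects and is reproducible", {
  expect_equal(cohort_design()$n_group_a + cohort_design()$n_group_b, 31)
  des <- cohort_design(n_group_a = 2, n_group_b = 2, n_trials = 6,
                       sampling_rate = 250, n_cortical = 40,
                       n_subcortical = 8, n_regions = 6, n_sensors = 8,
                       n_volumes = 30, gswd_rate = c(a = 0, b = 0),
                       master_seed = 4)
  bundle <- simulate_cohort(des)
  expect_length(bundle$subjects, 4)
  expect_equal(sum(vapply(bundle$subjects, function(s)
    (!is.null(s$eeg_inside)) + (!is.null(s$eeg_outside)), 0)), 8)
  bundle2 <- simulate_cohort(des)
  expect_identical(bundle$subjects[[3]]$eeg_inside$data,
                   bundle2$subjects[[3]]$eeg_inside$data)
})
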