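# EEG forward simulation: band-limited stochastic sources projected through
# the leadfield, with phase-lagged coupling planted between designated
# regions, plus inside-scanner gradient and ballistocardiogram artifacts.

# Frequency-domain synthesis of band-limited noise columns with spectral
# weight w(f); returns a real matrix (n_samp x ncols) with unit expected
# variance per column. Optionally applies a phase rotation (for building a
# lagged copy of a shared component from the same spectral draw).
.synth_spectrum <- function(n_samp, rate, ncols, f_lo, f_hi,
                            weight = function(f) 1 / sqrt(f)) {
  k <- seq_len(floor((n_samp - 1) / 2))
  freq <- k * rate / n_samp
  keep <- freq >= f_lo & freq <= f_hi
  rc_assert(any(keep), sprintf("no frequency bins in [%g, %g] Hz", f_lo, f_hi),
            "resolution")
  k <- k[keep]; freq <- freq[keep]
  w <- weight(pmax(freq, 1e-6))
  nb <- length(k)
  Z <- matrix(complex(real = rnorm(nb * ncols), imaginary = rnorm(nb * ncols)),
              nb, ncols) * w
  list(k = k, Z = Z, scale = n_samp / (2 * sqrt(sum(w^2))))
}

.spectrum_to_time <- function(spec, n_samp, phase_shift = 0) {
  ncols <- ncol(spec$Z)
  FF <- matrix(0 + 0i, n_samp, ncols)
  Z <- spec$Z * exp(-1i * phase_shift)
  FF[spec$k + 1L, ] <- Z
  FF[n_samp - spec$k + 1L, ] <- Conj(Z)
  Re(stats::mvfft(FF, inverse = TRUE)) / n_samp * spec$scale
}

# 1-s generalized spike-wave burst waveform (3 Hz sharp spike + slow wave).
.gswd_waveform <- function(rate) {
  t <- seq(0, 1, by = 1 / rate)[-1]
  env <- sin(pi * t)^2
  spike <- exp(-((t %% (1 / 3)) / 0.02)^2)
  wave <- sin(2 * pi * 3 * t - pi / 2)
  env * (2.5 * spike + wave)
}

#' Simulate one subject's EEG recording
#'
#' Sensor data are leadfield-projected band-limited (1 Hz to 60 Hz, 1/f
#' weighted) stochastic source signals plus white sensor noise. Vertices of
#' the designated seed/target region pairs additionally receive a shared
#' band-limited component in the effect band; the target-region copy is
#' phase-lagged (default pi/4) so that imaginary coherency, which nulls
#' zero-lag mixing, is sensitive to the planted coupling. Patient-like
#' recordings may carry generalized spike-wave bursts. The inside condition
#' is additionally passed through [inject_scanner_artifacts()].
#'
#' @param space a `source_space`.
#' @param leadfield a matching `leadfield`.
#' @param design a [cohort_design()].
#' @param subject_index subject number (1-based).
#' @param condition `"outside"` or `"inside"`.
#' @param seed integer seed; defaults to a seed derived from the design's
#'   master seed, the subject and the condition.
#' @param return_sources keep the full source time courses in the ground
#'   truth (memory-heavy; default FALSE).
#' @return List with `recording` (a `sensor_recording`) and `ground_truth`
#'   (coupled vertex pairs, planted gain, event times, artifact templates,
#'   and the seeds sufficient to regenerate everything).
#' @export
simulate_eeg_subject <- function(space, leadfield, design, subject_index,
                                 condition = c("outside", "inside"),
                                 seed = NULL, return_sources = FALSE) {
  condition <- match.arg(condition)
  rc_assert(subject_index >= 1 && subject_index <= n_subjects(design),
            "subject_index outside the design", "invalid_design")
  band <- as_band(design$effect_band)
  rc_assert(design$sampling_rate >= 2 * band$f_hi,
            "sampling rate below twice the effect band edge", "invalid_design")
  regions <- unique(unlist(design$effect_regions))
  rc_assert(all(regions %in% space$region_label),
            "effect regions missing from the source space", "invalid_design")
  rc_assert(nrow(leadfield$gain) >= 1 &&
              ncol(leadfield$gain) == n_vertices(space),
            "leadfield does not match the source space", "invalid_design")
  if (is.null(seed))
    seed <- derive_seed(design$master_seed, "eeg", subject_index, condition)

  group <- subject_group(design, subject_index)
  g_group <- if (group == "patient") design$coupling_gain_a else
    design$coupling_gain_b
  rate <- design$sampling_rate
  n_samp <- as.integer(round(design$n_trials * design$tr * rate))
  V <- n_vertices(space)
  S <- nrow(leadfield$gain)

  out <- with_rc_seed(seed, {
    g_subj <- g_group * (1 + design$gain_jitter * runif(1, -1, 1))
    # Shared coupled components, restricted to the band interior so the
    # planted effect does not straddle a neighbouring band's edge bin. Each
    # region pair uses several independent components with a per-vertex
    # assignment: cross-region vertex pairs on the same component are
    # phase-lagged coupled, while within-region coherence stays moderate
    # (region-wide coherence would make the adaptive beamformer cancel the
    # correlated sources and hide the effect).
    pad <- min(0.5, (band$f_hi - band$f_lo) / 4)
    m_comp <- design$n_coupling_components %||% 6L
    n_pairs <- length(design$effect_regions)
    add_seed <- vector("list", n_pairs)   # per pair: component per vertex
    add_targ <- vector("list", n_pairs)
    comp_t <- vector("list", n_pairs)     # time courses (plain + lagged)
    seed_verts <- lapply(design$effect_regions,
                         function(p) region_vertices(space, p[1]))
    targ_verts <- lapply(design$effect_regions,
                         function(p) region_vertices(space, p[2]))
    if (g_subj > 0) {
      for (i in seq_len(n_pairs)) {
        cspec <- .synth_spectrum(n_samp, rate, m_comp, band$f_lo + pad,
                                 band$f_hi - pad,
                                 weight = function(f) rep(1, length(f)))
        comp_t[[i]] <- list(
          plain = .spectrum_to_time(cspec, n_samp),
          lag = .spectrum_to_time(cspec, n_samp,
                                  phase_shift = design$coupling_lag))
        add_seed[[i]] <- sample.int(m_comp, length(seed_verts[[i]]),
                                    replace = TRUE)
        add_targ[[i]] <- sample.int(m_comp, length(targ_verts[[i]]),
                                    replace = TRUE)
      }
    }

    Y <- matrix(0, S, n_samp)
    keep_sources <- if (return_sources) matrix(0, V, n_samp) else NULL
    chunk <- 32L
    for (lo in seq(1L, V, by = chunk)) {
      idx <- lo:min(lo + chunk - 1L, V)
      spec <- .synth_spectrum(n_samp, rate, length(idx), 1,
                              min(60, rate / 2 - 1))
      X <- .spectrum_to_time(spec, n_samp)          # n_samp x k
      if (g_subj > 0) {
        for (i in seq_len(n_pairs)) {
          hit <- which(idx %in% seed_verts[[i]])
          for (h in hit) {
            k <- add_seed[[i]][match(idx[h], seed_verts[[i]])]
            X[, h] <- X[, h] + g_subj * comp_t[[i]]$plain[, k]
          }
          hit <- which(idx %in% targ_verts[[i]])
          for (h in hit) {
            k <- add_targ[[i]][match(idx[h], targ_verts[[i]])]
            X[, h] <- X[, h] + g_subj * comp_t[[i]]$lag[, k]
          }
        }
      }
      X <- X * (design$source_amplitude %||% 1)
      Y <- Y + leadfield$gain[, idx, drop = FALSE] %*% t(X)
      if (return_sources) keep_sources[idx, ] <- t(X)
    }

    # generalized spike-wave discharges (patient-like recordings)
    gr <- if (group == "patient") design$gswd_rate[["a"]] else
      design$gswd_rate[["b"]]
    gswd_s <- numeric(0)
    n_gswd <- if (gr > 0) rpois(1, gr) else 0L
    if (n_gswd > 0) {
      span <- n_samp / rate
      gswd_s <- sort(runif(n_gswd, 2, max(2.001, span - 3)))
      wav <- .gswd_waveform(rate)
      topo <- abs(rnorm(S, 1, 0.3))
      for (t0 in gswd_s) {
        i0 <- round(t0 * rate) + 1L
        ii <- i0:min(i0 + length(wav) - 1L, n_samp)
        Y[, ii] <- Y[, ii] + 150 * topo %o% wav[seq_along(ii)]
      }
    }

    noise <- matrix(rnorm(S * n_samp, sd = design$noise_sd), S, n_samp)
    rec <- sensor_recording(Y + noise, rate,
                            channel_labels = leadfield$sensor_labels,
                            events = list(gswd_s = gswd_s),
                            condition = condition,
                            meta = list(subject_index = subject_index,
                                        group = group, seed = seed))

    coupled <- NULL
    if (g_subj > 0) {
      coupled <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
        g <- as.matrix(expand.grid(sv = seq_along(seed_verts[[i]]),
                                   tv = seq_along(targ_verts[[i]])))
        same <- add_seed[[i]][g[, "sv"]] == add_targ[[i]][g[, "tv"]]
        cbind(seed_verts[[i]][g[same, "sv"]], targ_verts[[i]][g[same, "tv"]])
      }))
      colnames(coupled) <- c("seed_vertex", "target_vertex")
      coupled <- coupled[coupled[, 1] != coupled[, 2], , drop = FALSE]
    } else {
      coupled <- matrix(integer(0), 0, 2,
                        dimnames = list(NULL, c("seed_vertex", "target_vertex")))
    }
    gt <- list(coupled_pairs = coupled, effect_band = design$effect_band,
               coupling_gain = g_subj, coupling_lag = design$coupling_lag,
               gswd_s = gswd_s, seed = seed, noise_sd = design$noise_sd,
               sources = keep_sources)
    list(recording = rec, ground_truth = gt)
  })

  if (condition == "inside") {
    art <- inject_scanner_artifacts(
      out$recording, tr = design$tr,
      ga_amplitude = design$artifact_amplitudes$ga,
      bcg_amplitude = design$artifact_amplitudes$bcg,
      cardiac_rate = design$cardiac_rate,
      cardiac_jitter = design$cardiac_jitter,
      seed = derive_seed(seed, "artifacts"))
    out$ground_truth$artifacts <- art$meta$artifacts
    art$meta$artifacts <- NULL
    out$recording <- art
  }
  out
}

#' Add scanner gradient and ballistocardiogram artifacts
#'
#' Injects (i) a gradient artifact: a fixed multi-harmonic waveform repeated
#' exactly at every TR trigger with a channel-specific amplitude profile and
#' a slight slow amplitude drift, and (ii) a ballistocardiogram: cardiac-
#' locked transients built from a fixed basis of 3 waveforms with per-beat
#' random amplitude mixing and jittered beat times. TR-trigger and cardiac
#' event times are recorded in the event sidecar.
#'
#' @param rec a `sensor_recording` without prior scanner events.
#' @param tr repetition time in seconds (> 0).
#' @param ga_amplitude gradient-artifact scale in microvolts (0 disables).
#' @param bcg_amplitude ballistocardiogram scale in microvolts (0 disables).
#' @param cardiac_rate mean heart rate in Hz.
#' @param cardiac_jitter relative beat-interval jitter (default 5%).
#' @param ga_drift relative linear amplitude drift of the gradient template
#'   over the recording.
#' @param ga_template_s gradient template length in seconds (default: one TR;
#'   longer than TR is a configuration error).
#' @param n_slices number of slice-frequency harmonics composing the gradient
#'   waveform's fundamental (slice frequency = n_slices / TR).
#' @param seed integer seed.
#' @return The recording with artifacts added and events populated; the
#'   injected templates are kept under `meta$artifacts`.
#' @export
inject_scanner_artifacts <- function(rec, tr, ga_amplitude, bcg_amplitude,
                                     cardiac_rate = 1.1, cardiac_jitter = 0.05,
                                     ga_drift = 0.02, ga_template_s = NULL,
                                     n_slices = 20, seed = 1) {
  rc_assert(inherits(rec, "sensor_recording"), "rec must be a sensor_recording")
  rc_assert(tr > 0, "tr must be positive", "config")
  rc_assert(length(rec$events$tr_triggers_s) == 0 &&
              length(rec$events$cardiac_s) == 0,
            "recording already carries scanner events", "validation")
  ga_template_s <- ga_template_s %||% tr
  rc_assert(ga_template_s <= tr + 1e-9,
            "gradient template longer than the TR", "config")
  rate <- rec$rate
  n_samp <- ncol(rec$data)
  S <- nrow(rec$data)
  len <- as.integer(round(ga_template_s * rate))
  rc_assert(len >= 2, "gradient template shorter than 2 samples", "config")

  with_rc_seed(seed, {
    data <- rec$data
    n_ep <- floor(n_samp / round(tr * rate))
    triggers <- (seq_len(n_ep) - 1) * tr
    art <- list()

    if (ga_amplitude > 0 && n_ep > 0) {
      tt <- seq_len(len) / rate
      f_slice <- n_slices / tr
      nh <- max(1, floor((rate / 2 - 1) / f_slice))
      ph <- runif(nh, 0, 2 * pi)
      wav <- rowSums(vapply(seq_len(nh), function(k)
        sin(2 * pi * k * f_slice * tt + ph[k]) / k, numeric(len)))
      wav <- wav / sqrt(mean(wav^2))
      profile <- runif(S, 0.5, 1)
      tpl <- ga_amplitude * profile %o% wav       # S x len
      for (k in seq_len(n_ep)) {
        i0 <- as.integer(round(triggers[k] * rate)) + 1L
        ii <- i0:min(i0 + len - 1L, n_samp)
        fac <- 1 + ga_drift * ((k - 1) / max(1, n_ep - 1) - 0.5)
        data[, ii] <- data[, ii] + fac * tpl[, seq_along(ii), drop = FALSE]
      }
      art$ga_template <- tpl
    }

    beats <- numeric(0)
    if (bcg_amplitude > 0) {
      t_end <- n_samp / rate
      ibi_mean <- 1 / cardiac_rate
      t0 <- 0.5
      while (t0 < t_end - 1) {
        beats <- c(beats, t0)
        t0 <- t0 + ibi_mean * (1 + cardiac_jitter * rnorm(1))
      }
      wlen <- as.integer(round(0.6 * rate))
      tw <- seq_len(wlen) / rate
      basis <- rbind(
        exp(-((tw - 0.15) / 0.05)^2) * sin(2 * pi * 7 * tw),
        exp(-((tw - 0.30) / 0.08)^2) * sin(2 * pi * 4 * tw + 1),
        exp(-((tw - 0.45) / 0.06)^2) * sin(2 * pi * 10 * tw + 2))
      basis <- basis / sqrt(rowMeans(basis^2))
      mix <- matrix(runif(S * 3, -1, 1), S, 3)     # channel loadings
      coef <- matrix(1 + 0.3 * rnorm(length(beats) * 3), length(beats), 3)
      for (b in seq_along(beats)) {
        i0 <- as.integer(round(beats[b] * rate)) + 1L
        ii <- i0:min(i0 + wlen - 1L, n_samp)
        add <- bcg_amplitude * (mix %*% (coef[b, ] * basis[, seq_along(ii),
                                                           drop = FALSE]))
        data[, ii] <- data[, ii] + add
      }
      art$bcg_basis <- basis
      art$bcg_mix <- mix
      art$bcg_coef <- coef
    }

    ev <- rec$events
    ev$tr_triggers_s <- triggers
    ev$cardiac_s <- beats
    meta <- rec$meta
    meta$artifacts <- art
    sensor_recording(data, rate, rec$channel_labels, ev,
                     condition = "inside", meta = meta)
  })
}
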