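# Scanner-artifact removal and epoching: average-template gradient-artifact
# subtraction, optimal-basis-set ballistocardiogram removal, band-pass /
# notch filtering with downsampling, trial cutting with robust automated
# rejection, and seeded trial selection.

#' Set of fixed-length EEG trials
#'
#' @param trials trial x channel x sample array (microvolts).
#' @param rate sampling rate in Hz.
#' @param trial_onsets_s onset of each trial in seconds (strictly increasing).
#' @param rejected logical flag per trial.
#' @param reject_reason character reason per trial (`""` if kept).
#' @param band optional band name.
#' @param channel_labels channel names.
#' @param meta metadata list.
#' @return A `trial_set` object.
#' @export
trial_set <- function(trials, rate, trial_onsets_s, rejected = NULL,
                      reject_reason = NULL, band = NULL,
                      channel_labels = NULL, meta = list()) {
  rc_assert(is.array(trials) && length(dim(trials)) == 3,
            "trials must be a 3-d array (trial x channel x sample)")
  n_tr <- dim(trials)[1]
  rc_assert(length(trial_onsets_s) == n_tr, "one onset per trial required")
  rc_assert(n_tr < 2 || all(diff(trial_onsets_s) > 0),
            "trial onsets must be strictly increasing")
  if (is.null(rejected)) rejected <- rep(FALSE, n_tr)
  if (is.null(reject_reason)) reject_reason <- rep("", n_tr)
  if (is.null(channel_labels)) channel_labels <- sprintf("E%03d",
                                                         seq_len(dim(trials)[2]))
  structure(list(trials = trials, rate = as.numeric(rate),
                 trial_length_s = dim(trials)[3] / rate,
                 trial_onsets_s = trial_onsets_s, rejected = rejected,
                 reject_reason = reject_reason, band = band,
                 channel_labels = channel_labels, meta = meta),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials (%d rejected) x %d ch x %d samples @ %g Hz\n",
              dim(x$trials)[1], sum(x$rejected), dim(x$trials)[2],
              dim(x$trials)[3], x$rate))
  invisible(x)
}

#' Accepted trials of a trial set
#' @param ts a `trial_set`.
#' @return integer indices of accepted (non-rejected) trials.
#' @export
accepted_trials <- function(ts) which(!ts$rejected)

#' Average-template gradient-artifact subtraction
#'
#' For each channel, epochs of one TR length locked to the TR triggers are
#' averaged into a gradient-artifact template (a sliding window of the `k`
#' nearest epochs, robust to slow amplitude drift) and the template is
#' subtracted at each trigger. Samples outside trigger coverage are left
#' untouched.
#'
#' @param rec a `sensor_recording` with at least 2 TR triggers at uniform
#'   spacing (within one sample).
#' @param k sliding-window size in epochs (default 30; all epochs if fewer).
#' @param fit_scale least-squares fit a per-channel, per-epoch amplitude of
#'   the template before subtracting (default TRUE); absorbs slow artifact
#'   amplitude drift that a plain average cannot follow.
#' @return The corrected `sensor_recording`; events and channel order are
#'   unchanged.
#' @export
average_artifact_subtraction <- function(rec, k = 30, fit_scale = TRUE) {
  trig <- rec$events$tr_triggers_s
  if (length(trig) == 0)
    rc_abort("no TR trigger events in the recording", "missing_event")
  rc_assert(length(trig) >= 2, "need at least 2 TR triggers", "missing_event")
  rate <- rec$rate
  samp <- round(trig * rate) + 1L
  spacing <- diff(samp)
  if (max(spacing) - min(spacing) > 1)
    rc_abort("TR trigger spacing irregular beyond one sample",
             "event_spacing")
  len <- min(spacing)
  n_samp <- ncol(rec$data)
  keep <- samp + len - 1L <= n_samp
  samp <- samp[keep]
  n_ep <- length(samp)
  rc_assert(n_ep >= 2, "fewer than 2 complete TR epochs", "missing_event")
  k <- min(k, n_ep)

  S <- nrow(rec$data)
  # epochs as a (channels*len) x n_ep matrix; sliding means are one matrix
  # multiplication with a window-average operator
  idx <- outer(0:(len - 1L), samp, `+`)            # len x n_ep
  E <- matrix(rec$data[, as.vector(idx)], nrow = S * len)
  W <- matrix(0, n_ep, n_ep)
  half <- k %/% 2
  for (j in seq_len(n_ep)) {
    lo <- max(1L, min(j - half, n_ep - k + 1L))
    hi <- lo + k - 1L
    W[lo:hi, j] <- 1 / k
  }
  tmpl <- E %*% W
  if (fit_scale) {
    # per-channel, per-epoch template amplitude (rows are channel-major
    # within each sample, so group rows by channel)
    ch_of_row <- rep(seq_len(S), len)
    num <- rowsum(E * tmpl, ch_of_row)
    den <- rowsum(tmpl * tmpl, ch_of_row)
    alpha <- ifelse(den > 0, num / den, 1)
    tmpl <- tmpl * alpha[ch_of_row, , drop = FALSE]
  }
  data <- rec$data
  data[, as.vector(idx)] <- matrix(as.vector(E - tmpl), nrow = S)
  sensor_recording(data, rate, rec$channel_labels, rec$events, rec$condition,
                   rec$meta)
}

#' Optimal-basis-set ballistocardiogram removal
#'
#' Per channel, beat-locked epochs around each cardiac event are collected
#' into a matrix, the principal components of the (uncentred) epoch matrix
#' are computed, the top `n_components` (ranked by explained variance) form
#' an optimal basis set, and a least-squares fit of the basis is subtracted
#' from every beat epoch. Samples outside beat windows are untouched.
#'
#' @param rec a `sensor_recording` with at least 10 cardiac events in the
#'   sidecar.
#' @param n_components basis size (default 4). `0` returns the input
#'   unchanged. If negative, the smallest basis explaining at least
#'   `var_explained` of the epoch variance is used per channel.
#' @param window_s beat epoch length in seconds.
#' @param var_explained cumulative-variance rule used when
#'   `n_components < 0`.
#' @return The corrected `sensor_recording`.
#' @export
obs_bcg_removal <- function(rec, n_components = 4, window_s = 0.6,
                            var_explained = 0.8) {
  beats <- rec$events$cardiac_s
  if (length(beats) < 10)
    rc_abort(sprintf("need >= 10 cardiac events, got %d", length(beats)),
             "insufficient_events")
  if (n_components == 0) return(rec)
  rate <- rec$rate
  n_samp <- ncol(rec$data)
  len <- as.integer(round(window_s * rate))
  samp <- round(beats * rate) + 1L
  samp <- samp[samp + len - 1L <= n_samp]
  n_ep <- length(samp)
  rc_assert(n_ep >= 10, "fewer than 10 complete beat epochs",
            "insufficient_events")
  if (n_components > 0 && n_components >= n_ep)
    rc_abort("n_components must be smaller than the number of beat epochs",
             "rank")
  idx <- outer(0:(len - 1L), samp, `+`)            # len x n_ep
  data <- rec$data
  for (ch in seq_len(nrow(data))) {
    X <- matrix(data[ch, as.vector(idx)], nrow = len)   # len x n_ep
    sv <- svd(X)
    if (n_components < 0) {
      ev <- sv$d^2 / sum(sv$d^2)
      nc <- which(cumsum(ev) >= var_explained)[1]
    } else nc <- n_components
    nc <- min(nc, length(sv$d))
    B <- sv$u[, seq_len(nc), drop = FALSE]         # optimal basis set
    X <- X - B %*% (t(B) %*% X)
    data[ch, as.vector(idx)] <- as.vector(X)
  }
  sensor_recording(data, rate, rec$channel_labels, rec$events, rec$condition,
                   rec$meta)
}

#' Band-pass filter, notch line noise and downsample
#'
#' Zero-phase Butterworth band-pass (1-70 Hz: order-2 high-pass plus order-4
#' low-pass, applied forward-backward), band-stop notches at 50 Hz and its
#' harmonics within the Nyquist range (default width +/- 2 Hz), then
#' downsampling to `target_rate`. Event times (seconds) are preserved.
#'
#' @param rec a `sensor_recording`.
#' @param f_hp,f_lp band edges in Hz.
#' @param notch_freqs line-noise frequencies to remove.
#' @param notch_width half-width of each notch in Hz.
#' @param target_rate output sampling rate (must divide the input rate).
#' @return The filtered, downsampled `sensor_recording`.
#' @export
filter_resample <- function(rec, f_hp = 1, f_lp = 70,
                            notch_freqs = c(50, 100, 150), notch_width = 2,
                            target_rate = 250) {
  rate <- rec$rate
  if (rate < 2 * f_lp)
    rc_abort(sprintf("sampling rate %g below twice the low-pass edge %g",
                     rate, f_lp), "aliasing")
  nyq <- rate / 2
  hp <- signal::butter(2, f_hp / nyq, type = "high")
  lp <- signal::butter(4, f_lp / nyq, type = "low")
  notches <- lapply(notch_freqs[notch_freqs + notch_width < nyq], function(f0)
    signal::butter(2, c(f0 - notch_width, f0 + notch_width) / nyq,
                   type = "stop"))
  filt_one <- function(x) {
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    for (nf in notches) x <- signal::filtfilt(nf, x)
    x
  }
  data <- t(apply(rec$data, 1, filt_one))
  if (!isTRUE(all.equal(rate %% target_rate, 0)))
    rc_abort("input rate must be an integer multiple of the target rate",
             "config")
  dec <- rate / target_rate
  if (dec > 1) data <- data[, seq(1, ncol(data), by = dec), drop = FALSE]
  sensor_recording(data, target_rate, rec$channel_labels, rec$events,
                   rec$condition, rec$meta)
}

#' Cut trials and reject artifact-contaminated ones
#'
#' Inside-scanner recordings are epoched at the TR triggers; outside
#' recordings are cut contiguously on a virtual grid from the recording
#' start. A trial is rejected when its peak-to-peak amplitude or its
#' variance exceeds a robust z threshold (median/MAD over trials; automated
#' stand-in for visual inspection), and any trial overlapping a generalized
#' spike-wave discharge is rejected together with its immediate predecessor
#' and successor.
#'
#' @param rec a `sensor_recording`.
#' @param z_max robust z threshold (default 4).
#' @param trial_length_s trial length in seconds (default 2).
#' @return A `trial_set` with rejection flags and reasons.
#' @export
epoch_and_reject <- function(rec, z_max = 4, trial_length_s = 2) {
  rate <- rec$rate
  len <- as.integer(round(trial_length_s * rate))
  n_samp <- ncol(rec$data)
  if (rec$condition == "inside") {
    trig <- rec$events$tr_triggers_s
    rc_assert(length(trig) >= 1,
              "inside-condition epoching requires TR triggers",
              "missing_event")
    onsets <- trig
  } else {
    onsets <- seq(0, by = trial_length_s,
                  length.out = floor(n_samp / len))
  }
  start <- round(onsets * rate) + 1L
  keep <- start + len - 1L <= n_samp
  onsets <- onsets[keep]; start <- start[keep]
  n_tr <- length(onsets)
  if (n_tr == 0) rc_abort("no usable trials", "empty_output")

  S <- nrow(rec$data)
  trials <- array(0, dim = c(n_tr, S, len))
  for (j in seq_len(n_tr))
    trials[j, , ] <- rec$data[, start[j]:(start[j] + len - 1L)]

  ptp <- apply(trials, 1, function(tr) mean(apply(tr, 1, function(x)
    diff(range(x)))))
  vr <- apply(trials, 1, function(tr) mean(apply(tr, 1, var)))
  robust_z <- function(x) {
    m <- median(x); s <- mad(x)
    (x - m) / max(s, 1e-12)
  }
  rej <- rep(FALSE, n_tr)
  reason <- rep("", n_tr)
  amp_bad <- robust_z(ptp) > z_max
  var_bad <- robust_z(vr) > z_max
  rej[amp_bad] <- TRUE; reason[amp_bad] <- "amplitude"
  rej[var_bad & !amp_bad] <- TRUE; reason[var_bad & !amp_bad] <- "variance"

  for (g in rec$events$gswd_s) {
    hit <- which(onsets < g & g < onsets + trial_length_s)
    for (j in hit) {
      jj <- intersect((j - 1):(j + 1), seq_len(n_tr))
      rej[jj] <- TRUE
      reason[jj] <- ifelse(reason[jj] == "", "gswd", reason[jj])
    }
  }
  if (all(rej)) rc_abort("all trials rejected", "empty_output")
  trial_set(trials, rate, onsets, rej, reason,
            channel_labels = rec$channel_labels,
            meta = list(condition = rec$condition))
}

#' Randomly select accepted trials
#'
#' Uniform random subset without replacement among the accepted trials,
#' deterministic for a seed, original trial order preserved.
#'
#' @param ts a `trial_set`.
#' @param n number of trials to keep (default 200, i.e. 400 s of 2-s trials).
#' @param seed integer seed.
#' @return A `trial_set` containing only the selected trials.
#' @export
select_trials <- function(ts, n = 200, seed = 1) {
  acc <- accepted_trials(ts)
  if (length(acc) < n)
    rc_abort(sprintf("only %d accepted trials, %d requested (short by %d)",
                     length(acc), n, n - length(acc)), "insufficient_trials")
  pick <- sort(with_rc_seed(seed, sample(acc, n)))
  trial_set(ts$trials[pick, , , drop = FALSE], ts$rate,
            ts$trial_onsets_s[pick], band = ts$band,
            channel_labels = ts$channel_labels,
            meta = c(ts$meta, list(selected_from = dim(ts$trials)[1],
                                   selection_seed = seed)))
}
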