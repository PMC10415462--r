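# BOLD cleaning and seed-based correlation maps: outlier flagging, partial
# confound regression (motion + component-based physiological noise + spike
# regressors, no global-signal regression), slow band-pass, Pearson seed FC.

#' Flag outlier BOLD volumes
#'
#' A volume is flagged when (i) the standardized volume-to-volume global
#' mean-signal change exceeds 3 SD, (ii) the framewise displacement (sum of
#' absolute translation differences plus rotation differences times a 50 mm
#' sphere radius) exceeds 0.5 mm, or (iii) it coincides with a generalized
#' spike-wave discharge or any of the nine volumes following one (18 s at
#' TR 2 s).
#'
#' @param b a `bold_recording` with populated confounds.
#' @param gswd_events_s GSWD event times in seconds (possibly empty).
#' @param gs_z_max global-signal-change threshold in SD.
#' @param fd_max framewise-displacement threshold in mm.
#' @param gswd_extend number of volumes after a GSWD volume to flag.
#' @return The recording with `outlier_flags` and `flag_reason` set.
#' @export
flag_outlier_volumes <- function(b, gswd_events_s = numeric(0), gs_z_max = 3,
                                 fd_max = 0.5, gswd_extend = 9) {
  rc_assert(inherits(b, "bold_recording"), "b must be a bold_recording")
  n_vol <- ncol(b$series)
  brain <- b$location_kind == "brain"
  gs <- colMeans(b$series[brain, , drop = FALSE])
  dgs <- c(0, diff(gs))
  sd_dgs <- sd(dgs)
  z <- if (sd_dgs > 0) (dgs - mean(dgs)) / sd_dgs else rep(0, n_vol)
  m <- as.matrix(b$confounds[, c("trans_x", "trans_y", "trans_z",
                                 "rot_x", "rot_y", "rot_z")])
  dm <- rbind(0, abs(apply(m, 2, diff)))
  fd <- rowSums(dm[, 1:3, drop = FALSE]) +
    50 * rowSums(dm[, 4:6, drop = FALSE])

  flags <- rep(FALSE, n_vol)
  reason <- rep("", n_vol)
  sig <- abs(z) > gs_z_max
  mot <- fd > fd_max
  flags[sig] <- TRUE; reason[sig] <- "global_signal"
  flags[mot] <- TRUE
  reason[mot] <- ifelse(reason[mot] == "", "motion",
                        paste(reason[mot], "motion", sep = "+"))
  for (g in gswd_events_s) {
    v0 <- floor(g / b$tr) + 1L
    vv <- intersect(v0:(v0 + gswd_extend), seq_len(n_vol))
    flags[vv] <- TRUE
    reason[vv] <- ifelse(reason[vv] == "", "gswd",
                         paste(reason[vv], "gswd", sep = "+"))
  }
  b$outlier_flags <- flags
  b$flag_reason <- reason
  b$meta$fd <- fd
  b$meta$gs_z <- z
  b
}

# Top-k principal-component time courses of a set of nuisance locations
# (uncentred rows are demeaned over time; PCs of the time x location matrix).
.noise_pcs <- function(series_rows, k) {
  X <- t(series_rows)                              # volumes x locations
  X <- scale(X, center = TRUE, scale = FALSE)
  k <- min(k, ncol(X), nrow(X) - 1)
  pr <- prcomp(X, center = FALSE)
  pr$x[, seq_len(k), drop = FALSE]
}

#' Regress nuisance confounds out of a BOLD recording
#'
#' Per location, least-squares removal of: the six motion parameters, three
#' principal-component regressors from the white-matter-like locations and
#' three from the CSF-like locations, and one spike regressor per flagged
#' volume. The global mean signal is deliberately not regressed. The
#' nuisance design is stored in the recording and reused on repeated calls,
#' making the operation an exact projection (idempotent).
#'
#' @param b a `bold_recording`; run [flag_outlier_volumes()] first.
#' @param n_pcs number of noise PCs per tissue class (default 3).
#' @return The residualized recording (confound model under
#'   `meta$confound_model`).
#' @export
regress_confounds <- function(b, n_pcs = 3) {
  rc_assert(inherits(b, "bold_recording"), "b must be a bold_recording")
  n_vol <- ncol(b$series)
  if (!is.null(b$meta$confound_model)) {
    X <- b$meta$confound_model
  } else {
    motion <- as.matrix(b$confounds[, c("trans_x", "trans_y", "trans_z",
                                        "rot_x", "rot_y", "rot_z")])
    wm <- b$series[b$location_kind == "wm", , drop = FALSE]
    csf <- b$series[b$location_kind == "csf", , drop = FALSE]
    X <- cbind(1, motion)
    if (nrow(wm) > 0) X <- cbind(X, .noise_pcs(wm, n_pcs))
    if (nrow(csf) > 0) X <- cbind(X, .noise_pcs(csf, n_pcs))
    for (v in which(b$outlier_flags)) {
      spike <- rep(0, n_vol); spike[v] <- 1
      X <- cbind(X, spike)
    }
    colnames(X) <- NULL
  }
  qx <- qr(X)
  if (qx$rank < ncol(X))
    rc_abort("confound regressor matrix is rank deficient", "collinearity")
  resid_t <- t(qr.resid(qx, t(b$series)))
  b$series <- resid_t
  b$meta$confound_model <- X
  b$meta$confounds_regressed <- TRUE
  b
}

#' Band-pass filter BOLD series
#'
#' Zero-phase Butterworth band-pass of the slow fluctuations
#' (default 0.008-0.09 Hz), applied after confound regression.
#'
#' @param b a `bold_recording`.
#' @param f_lo,f_hi band edges in Hz.
#' @param order Butterworth order (per pass).
#' @return The filtered recording.
#' @export
bandpass_bold <- function(b, f_lo = 0.008, f_hi = 0.09, order = 2) {
  rc_assert(inherits(b, "bold_recording"), "b must be a bold_recording")
  fs <- 1 / b$tr
  if (f_hi >= fs / 2)
    rc_abort(sprintf("band edge %g Hz infeasible at TR %g s", f_hi, b$tr),
             "resolution")
  bw <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  # remove the per-location linear trend first: a ramp leaks through the
  # filter's edge transients even though its spectrum is far below the band
  n_vol <- ncol(b$series)
  tt <- cbind(1, seq_len(n_vol))
  qt <- qr(tt)
  b$series <- t(apply(b$series, 1, function(x)
    signal::filtfilt(bw, qr.resid(qt, x))))
  b$meta$bandpassed <- c(f_lo, f_hi)
  b
}

#' Seed-based fMRI correlation map
#'
#' The seed time course is the mean over the seed-region locations; the map
#' value at each brain location is the Pearson correlation with the seed
#' course, computed over non-flagged volumes. Fisher z values are stored in
#' the metadata for group statistics; the map itself holds r.
#'
#' @param b a cleaned, filtered `bold_recording`.
#' @param space the aligned `source_space`.
#' @param seed_region region label of the seed.
#' @return A `vertex_map` of kind `"seed_fc"` (length = brain locations).
#' @export
seed_fc_fmri <- function(b, space, seed_region) {
  rc_assert(inherits(b, "bold_recording"), "b must be a bold_recording")
  brain_rows <- which(b$location_kind == "brain")
  rc_assert(length(brain_rows) == n_vertices(space),
            "brain locations and space size differ")
  sv <- region_vertices(space, seed_region)
  use <- which(!b$outlier_flags)
  rc_assert(length(use) >= 10, "fewer than 10 usable volumes")
  series <- b$series[brain_rows, use, drop = FALSE]
  seed_tc <- colMeans(series[sv, , drop = FALSE])
  if (sd(seed_tc) < .Machine$double.eps)
    rc_abort("seed time course has zero variance", "degenerate_seed")
  r <- as.numeric(cor(seed_tc, t(series)))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -0.999999), 0.999999)
  vertex_map(r, "seed_fc", space_id = space$space_id,
             meta = list(seed_region = seed_region, seed_vertices = sv,
                         fisher_z = atanh(r), n_volumes_used = length(use)))
}
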