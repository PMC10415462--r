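# BOLD simulation: HRF-convolved neural drive with a planted seed-target
# shared drive in the patient-like group, slow drift, motion-coupled
# components, physiological nuisance locations and occasional spikes.

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style double gamma (peak 6 s, undershoot 16 s, undershoot ratio 1/6),
#' sampled at `dt` seconds over `duration` seconds.
#'
#' @param dt sampling step in seconds.
#' @param duration kernel length in seconds.
#' @return numeric vector, peak-normalized.
#' @export
hrf_double_gamma <- function(dt, duration = 30) {
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

.convolve_hrf <- function(x, h) {
  n <- length(x)
  stats::convolve(x, rev(h), type = "open")[seq_len(n)]
}

#' Simulate one subject's BOLD recording
#'
#' Vertex-wise BOLD is haemodynamic-response-convolved neural drive plus slow
#' drift, a motion-correlated component and white noise. In the patient-like
#' group the seed regions of the design's effect pairs share drive with the
#' target regions at the group's BOLD coupling gain. White-matter-like and
#' CSF-like nuisance locations (no neural drive, shared physiological signal)
#' are appended for component-based confound regression, six motion
#' parameters are written to the confound table, and random spike volumes
#' carry both a large signal deviation and a motion jump.
#'
#' @param space a `source_space`.
#' @param design a [cohort_design()].
#' @param subject_index subject number (1-based).
#' @param seed integer seed; defaults to one derived from the master seed.
#' @param n_noise_locations number of WM-like and CSF-like locations each.
#' @return A `bold_recording`; ground truth (true seed-coupling map, spike
#'   volumes) is kept under `meta$ground_truth`.
#' @export
simulate_bold_subject <- function(space, design, subject_index, seed = NULL,
                                  n_noise_locations = 20) {
  rc_assert(subject_index >= 1 && subject_index <= n_subjects(design),
            "subject_index outside the design", "invalid_design")
  rc_assert(design$n_volumes >= 10, "need at least 10 volumes",
            "invalid_design")
  regions <- unique(unlist(design$effect_regions))
  rc_assert(all(regions %in% space$region_label),
            "effect regions missing from the source space", "invalid_design")
  if (is.null(seed))
    seed <- derive_seed(design$master_seed, "bold", subject_index)
  group <- subject_group(design, subject_index)
  g <- if (group == "patient") design$bold_coupling_gain_a else
    design$bold_coupling_gain_b
  V <- n_vertices(space)
  n_vol <- design$n_volumes
  tr <- design$tr

  with_rc_seed(seed, {
    h <- hrf_double_gamma(tr)
    ar1 <- function(n, phi = 0.3) {
      as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
    }
    drive <- matrix(rnorm(V * n_vol), V, n_vol)
    true_map <- numeric(V)
    if (g > 0) {
      for (p in design$effect_regions) {
        sv <- region_vertices(space, p[1])
        tv <- setdiff(region_vertices(space, p[2]), sv)
        u <- rnorm(n_vol)
        drive[sv, ] <- drive[sv, ] + g * matrix(u, length(sv), n_vol,
                                                byrow = TRUE)
        drive[tv, ] <- drive[tv, ] + g * matrix(u, length(tv), n_vol,
                                                byrow = TRUE)
        true_map[c(sv, tv)] <- g
      }
    }
    bold <- t(apply(drive, 1, .convolve_hrf, h = h))

    # motion: slow random walk; spikes add a sudden jump
    motion <- cbind(
      trans_x = cumsum(rnorm(n_vol, sd = 0.02)),
      trans_y = cumsum(rnorm(n_vol, sd = 0.02)),
      trans_z = cumsum(rnorm(n_vol, sd = 0.02)),
      rot_x = cumsum(rnorm(n_vol, sd = 2e-4)),
      rot_y = cumsum(rnorm(n_vol, sd = 2e-4)),
      rot_z = cumsum(rnorm(n_vol, sd = 2e-4)))
    spikes <- which(runif(n_vol) < design$spike_prob)
    spikes <- spikes[spikes > 1]
    for (sv in spikes)
      motion[sv:n_vol, "trans_x"] <- motion[sv:n_vol, "trans_x"] +
        sample(c(-1, 1), 1) * runif(1, 0.6, 1.2)

    # global physiological signals: shared between grey matter and the
    # nuisance tissue classes, so component regressors can capture them
    # (the pipeline deliberately performs no global-signal regression)
    physio_wm <- ar1(n_vol, 0.5)
    physio_csf <- ar1(n_vol, 0.5)
    tvol <- seq_len(n_vol)
    drift <- outer(runif(V, -1, 1), tvol / n_vol) +
      outer(runif(V, -0.5, 0.5), cos(pi * tvol / n_vol))
    w_mot <- matrix(rnorm(V * 6, sd = 0.15), V, 6)
    bold <- bold + drift + w_mot %*% t(scale(motion)) +
      outer(runif(V, 0.15, 0.35), physio_wm) +
      outer(runif(V, 0.05, 0.15), physio_csf) +
      matrix(rnorm(V * n_vol, sd = 0.5), V, n_vol)
    if (length(spikes) > 0) {
      sds <- apply(bold, 1, sd)
      for (sv in spikes) bold[, sv] <- bold[, sv] + 6 * sds
    }

    # physiological nuisance locations: shared slow signal + motion coupling
    nn <- n_noise_locations
    wm <- matrix(rnorm(nn * n_vol, sd = 0.4), nn, n_vol) +
      outer(runif(nn, 0.5, 1.5), physio_wm) +
      matrix(rnorm(nn * 6, sd = 0.1), nn, 6) %*% t(scale(motion))
    csf <- matrix(rnorm(nn * n_vol, sd = 0.4), nn, n_vol) +
      outer(runif(nn, 0.5, 1.5), physio_csf)

    bold_recording(
      series = rbind(bold, wm, csf), tr = tr,
      confounds = as.data.frame(motion),
      location_kind = c(rep("brain", V), rep("wm", nn), rep("csf", nn)),
      space_tag = "vertex",
      meta = list(subject_index = subject_index, group = group, seed = seed,
                  ground_truth = list(true_seed_coupling = true_map,
                                      spike_volumes = spikes,
                                      bold_gain = g)))
  })
}
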