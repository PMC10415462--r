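# Study design for the synthetic two-group, two-condition cohort.

#' Define a synthetic cohort design
#'
#' Captures the study conditions of a two-group (patient-like vs.
#' control-like), two-condition (outside vs. inside the MR scanner)
#' resting-state EEG-fMRI cohort: 15 + 16 subjects by default, 2-s trials at
#' the fMRI repetition time, a theta-band connectivity increase planted in
#' group A between thalamic and precuneus regions, and inside-condition
#' gradient plus ballistocardiogram artifacts. Ages are drawn uniformly from
#' 19-57 years and sexes as Bernoulli draws matching the study proportions
#' (60% / 43.75% female); both are deterministic functions of `master_seed`.
#'
#' @param n_group_a,n_group_b subject counts (>= 2 each); group A is the
#'   patient-like group.
#' @param effect_band band carrying the planted coupling (default theta).
#' @param effect_regions list of `c(seed_region, target_region)` label pairs
#'   receiving phase-lagged coupling.
#' @param coupling_gain_a,coupling_gain_b dimensionless coupling gains (>= 0)
#'   of the shared band-limited component relative to the unit-variance
#'   intrinsic source signals.
#' @param coupling_lag phase lag (radians) applied to the target-region copy
#'   of the shared component; non-zero so imaginary coherency is sensitive.
#' @param n_coupling_components independent shared components per region
#'   pair; vertices are assigned to components at random, which bounds
#'   within-region coherence (full region-wide coherence would be cancelled
#'   by the adaptive beamformer).
#' @param gain_jitter relative per-subject jitter of the coupling gain.
#' @param artifact_amplitudes list with `ga` and `bcg` scales in microvolts.
#' @param source_amplitude amplitude of each unit source signal (source
#'   units); the default yields a realistic scalp EEG RMS of roughly
#'   50 microvolts through the default leadfield.
#' @param noise_sd white sensor noise (microvolts).
#' @param sampling_rate EEG sampling rate in Hz.
#' @param tr fMRI repetition time in seconds (also the EEG trial length).
#' @param n_trials number of 2-s trials simulated per recording.
#' @param n_sensors,n_cortical,n_subcortical,n_regions geometry of the
#'   simulated space (desk-scale defaults; study-scale 256 sensors and
#'   2004 + 334 vertices remain configurable).
#' @param cardiac_rate,cardiac_jitter mean heartbeat rate (Hz) and relative
#'   beat-interval jitter.
#' @param gswd_rate expected number of generalized spike-wave discharges per
#'   recording, `c(a = ..., b = ...)`.
#' @param n_volumes BOLD volumes per subject.
#' @param bold_coupling_gain_a,bold_coupling_gain_b seed-target shared-drive
#'   gains for the BOLD simulation.
#' @param spike_prob per-volume probability of a motion/signal spike.
#' @param master_seed master seed; all per-subject seeds derive from it.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_group_a = 15, n_group_b = 16,
                          effect_band = "theta",
                          effect_regions = list(
                            c("thalamus_l", "precuneus_pcc"),
                            c("thalamus_r", "precuneus_pcc")),
                          coupling_gain_a = 2.5, coupling_gain_b = 0.25,
                          coupling_lag = pi / 4, gain_jitter = 0.2,
                          n_coupling_components = 6,
                          artifact_amplitudes = list(ga = 5000, bcg = 100),
                          source_amplitude = 3, noise_sd = 2,
                          sampling_rate = 500, tr = 2,
                          n_trials = 220, n_sensors = 64, n_cortical = 260,
                          n_subcortical = 42, n_regions = 10,
                          cardiac_rate = 1.1, cardiac_jitter = 0.05,
                          gswd_rate = c(a = 0.33, b = 0),
                          n_volumes = 300,
                          bold_coupling_gain_a = 0.8,
                          bold_coupling_gain_b = 0,
                          spike_prob = 0.01,
                          master_seed = 1) {
  rc_assert(n_group_a >= 2 && n_group_b >= 2,
            "each group needs at least 2 subjects", "invalid_design")
  rc_assert(coupling_gain_a >= 0 && coupling_gain_b >= 0,
            "coupling gains must be >= 0", "invalid_design")
  rc_assert(effect_band %in% names(default_bands()),
            "effect band must be one of the analysis bands", "invalid_design")
  rc_assert(sampling_rate >= 2 * max(vapply(default_bands(), `[[`, 0, "f_hi")),
            "sampling rate below twice the highest band edge", "invalid_design")
  rc_assert(tr > 0 && n_trials >= 1, "tr and n_trials must be positive",
            "invalid_design")
  n <- n_group_a + n_group_b
  cov <- with_rc_seed(derive_seed(master_seed, "covariates"), {
    data.frame(
      subject_id = sprintf("sub-%02d", seq_len(n)),
      group = rep(c("patient", "control"), c(n_group_a, n_group_b)),
      age = round(runif(n, 19, 57)),
      sex = ifelse(rbinom(n, 1, rep(c(9 / 15, 7 / 16),
                                    c(n_group_a, n_group_b))) == 1, "f", "m"),
      stringsAsFactors = FALSE
    )
  })
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    covariates = cov, effect_band = effect_band,
    effect_regions = effect_regions,
    coupling_gain_a = coupling_gain_a, coupling_gain_b = coupling_gain_b,
    coupling_lag = coupling_lag, gain_jitter = gain_jitter,
    n_coupling_components = as.integer(n_coupling_components),
    artifact_amplitudes = artifact_amplitudes,
    source_amplitude = source_amplitude, noise_sd = noise_sd,
    sampling_rate = sampling_rate, tr = tr, n_trials = as.integer(n_trials),
    n_sensors = as.integer(n_sensors), n_cortical = as.integer(n_cortical),
    n_subcortical = as.integer(n_subcortical), n_regions = as.integer(n_regions),
    cardiac_rate = cardiac_rate, cardiac_jitter = cardiac_jitter,
    gswd_rate = gswd_rate, n_volumes = as.integer(n_volumes),
    bold_coupling_gain_a = bold_coupling_gain_a,
    bold_coupling_gain_b = bold_coupling_gain_b,
    spike_prob = spike_prob, master_seed = as.integer(master_seed)
  ), class = "cohort_design")
}

n_subjects <- function(design) design$n_group_a + design$n_group_b

#' Group membership of a subject
#' @param design a `cohort_design`.
#' @param subject_index subject number (1-based; group A first).
#' @return `"patient"` or `"control"`.
#' @export
subject_group <- function(design, subject_index) {
  rc_assert(subject_index >= 1 && subject_index <= n_subjects(design),
            "subject_index out of range", "invalid_design")
  design$covariates$group[subject_index]
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d + %d subjects, effect %s in %s, gains %.2f/%.2f, %d trials @ %g Hz\n",
    x$n_group_a, x$n_group_b, x$effect_band,
    paste(vapply(x$effect_regions, paste, "", collapse = "-"), collapse = ", "),
    x$coupling_gain_a, x$coupling_gain_b, x$n_trials, x$sampling_rate))
  invisible(x)
}
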