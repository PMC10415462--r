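# Whole-cohort simulation: all subjects x conditions, EEG + BOLD +
# covariates + ground truth, with per-subject seeds derived from the
# design's master seed.

#' Simulate a full cohort
#'
#' Builds the shared source space and leadfield, then simulates every
#' subject's EEG in the requested conditions and (optionally) BOLD. All
#' per-subject seeds derive deterministically from the design's master seed,
#' so two runs with the same design are identical. Pass `path` to also write
#' the on-disk bundle via [write_bundle()].
#'
#' @param design a [cohort_design()].
#' @param conditions which EEG conditions to simulate.
#' @param include_bold simulate BOLD series as well (default TRUE).
#' @param path optional directory to write the bundle to.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return A `cohort_bundle`: list with `design`, `space`, `leadfield`,
#'   `covariates` and per-subject `subjects[[i]]$eeg_<condition>`,
#'   `$gt_<condition>`, `$bold`.
#' @export
simulate_cohort <- function(design, conditions = c("outside", "inside"),
                            include_bold = TRUE, path = NULL,
                            overwrite = FALSE) {
  rc_assert(inherits(design, "cohort_design"), "design must be a cohort_design")
  conditions <- match.arg(conditions, c("outside", "inside"),
                          several.ok = TRUE)
  space <- build_source_space(design$n_cortical, design$n_subcortical,
                              design$n_regions,
                              seed = derive_seed(design$master_seed, "space"))
  lf <- build_leadfield(space, design$n_sensors,
                        seed = derive_seed(design$master_seed, "leadfield"))
  n <- n_subjects(design)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- list()
    for (cond in conditions) {
      sim <- simulate_eeg_subject(space, lf, design, i, cond)
      subj[[paste0("eeg_", cond)]] <- sim$recording
      subj[[paste0("gt_", cond)]] <- sim$ground_truth
    }
    if (include_bold) subj$bold <- simulate_bold_subject(space, design, i)
    subjects[[i]] <- subj
  }
  bundle <- structure(list(design = design, space = space, leadfield = lf,
                           covariates = design$covariates,
                           subjects = subjects,
                           conditions = conditions),
                      class = "cohort_bundle")
  if (!is.null(path)) write_bundle(bundle, path, overwrite = overwrite)
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d subjects (%d patient-like), conditions: %s, BOLD: %s\n",
    length(x$subjects), x$design$n_group_a,
    paste(x$conditions, collapse = "/"),
    if (!is.null(x$subjects[[1]]$bold)) "yes" else "no"))
  invisible(x)
}
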