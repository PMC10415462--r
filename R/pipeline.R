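# End-to-end runner: strings artifact removal, source reconstruction,
# connectivity, group statistics, fMRI seed FC and the cross-modal surrogate
# test into the full two-condition, two-modality analysis.

#' Default run configuration
#'
#' Every stochastic stage has an explicit seed derived from `seed`. Study-
#' scale presets (20000 permutations, 200 selected trials, 50 surrogates x
#' 500 draws) are configurable; desk-scale defaults keep the full run in
#' minutes.
#'
#' @param seed master analysis seed.
#' @return Named list of configuration values.
#' @export
run_config_defaults <- function(seed = 1) {
  list(
    bands = names(default_bands()),
    n_trials_select = NULL,        # NULL: equalize to the cohort minimum
    aas_k = 30,
    obs_components = 4,
    reject_z = 4,
    do_filter_resample = TRUE,
    dics_lambda = 0.05,
    n_perm = 2000,
    tfce = list(height_power = 2, extent_power = 1),
    alpha = 0.05,
    seed_regions = c("mpfc", "dmn_lp_l", "dmn_lp_r", "precuneus_pcc",
                     "intracalcarine_l", "intracalcarine_r",
                     "thalamus_l", "thalamus_r"),
    crossmodal = list(n_surrogates_per_subject = 50, n_draws = 500,
                      n_perm = 500),
    seed = as.integer(seed),
    output_dir = NULL
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected with a pointer-style path so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file.
#' @param seed fallback master seed if the file does not set one.
#' @return Configuration list merged over [run_config_defaults()].
#' @export
read_run_config <- function(path, seed = 1) {
  raw <- yaml::read_yaml(path)
  defaults <- run_config_defaults(seed)
  known <- names(defaults)
  extra <- c("cohort_dir")
  for (k in names(raw))
    if (!(k %in% c(known, extra)))
      rc_abort(paste0("unknown configuration key at /", k), "validation")
  for (sub in c("tfce", "crossmodal"))
    if (!is.null(raw[[sub]]))
      for (k in names(raw[[sub]]))
        if (!(k %in% names(defaults[[sub]])))
          rc_abort(paste0("unknown configuration key at /", sub, "/", k),
                   "validation")
  cfg <- utils::modifyList(defaults, raw)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Clean one recording and return the selected trial set.
.process_eeg <- function(rec, config, n_select, seed) {
  if (rec$condition == "inside") {
    rec <- average_artifact_subtraction(rec, k = config$aas_k)
    if (length(rec$events$cardiac_s) >= 10)
      rec <- obs_bcg_removal(rec, n_components = config$obs_components)
  }
  if (config$do_filter_resample && rec$rate > 250 && rec$rate %% 250 == 0)
    rec <- filter_resample(rec)
  ts <- epoch_and_reject(rec, z_max = config$reject_z)
  if (!is.null(n_select) && n_select < length(accepted_trials(ts)))
    ts <- select_trials(ts, n_select, seed = seed)
  ts
}

#' Run the full two-condition, two-modality analysis
#'
#' Per band and condition: global power/FC with permutation group tests,
#' relative condition differences, vertex power and node-strength maps with
#' TFCE/FWE permutation statistics and Cohen's d maps; the paired condition
#' and condition x group tests on the global metrics; inside/outside
#' spatial-similarity correlations; fMRI seed-FC maps with group statistics;
#' and the cross-modal surrogate decisions for the seed x band combinations
#' passing the significance gate. Writes a machine-readable JSON report (and
#' TSV tables) when `config$output_dir` is set.
#'
#' @param cohort a `cohort_bundle` (from [simulate_cohort()] or
#'   [read_bundle()]) or a bundle directory path.
#' @param config configuration list, see [run_config_defaults()].
#' @return A list with elements `global`, `vertex`, `delta_pct`,
#'   `condition_tests`, `similarity`, `fmri`, `crossmodal`, `provenance`.
#' @export
run_full_analysis <- function(cohort, config = run_config_defaults()) {
  if (is.character(cohort)) cohort <- read_bundle(cohort)
  rc_assert(inherits(cohort, "cohort_bundle"), "cohort must be a cohort_bundle")
  space <- cohort$space
  lf <- cohort$leadfield
  cov <- cohort$covariates
  design <- make_design(cov)
  conditions <- cohort$conditions
  bands <- default_bands()[config$bands]
  n_sub <- length(cohort$subjects)
  grp <- cov$group == "patient"
  seed0 <- config$seed

  # --- EEG cleaning + epoching -------------------------------------------
  trials <- list()
  for (cond in conditions) {
    trials[[cond]] <- lapply(seq_len(n_sub), function(i)
      .process_eeg(cohort$subjects[[i]][[paste0("eeg_", cond)]], config,
                   n_select = NULL,
                   seed = derive_seed(seed0, "select", cond, i)))
  }
  n_min <- min(vapply(unlist(trials, recursive = FALSE), function(ts)
    length(accepted_trials(ts)), 0L))
  n_select <- config$n_trials_select %||% n_min
  for (cond in conditions)
    trials[[cond]] <- lapply(seq_len(n_sub), function(i) {
      ts <- trials[[cond]][[i]]
      if (length(accepted_trials(ts)) > n_select)
        select_trials(ts, n_select,
                      seed = derive_seed(seed0, "select", cond, i))
      else ts
    })

  # --- band-wise source reconstruction and connectivity ------------------
  enh <- c(list(adjacency = space), config$tfce)
  global <- list(); vertex <- list(); delta_pct <- list()
  csds <- list()       # sensor CSDs per condition x band x subject
  g_power <- g_fc <- array(
    NA_real_, c(n_sub, length(bands), length(conditions)),
    dimnames = list(NULL, names(bands), conditions))

  for (cond in conditions) {
    for (bn in names(bands)) {
      band <- bands[[bn]]
      pow_maps <- vector("list", n_sub)
      ns_maps <- vector("list", n_sub)
      csds[[cond]][[bn]] <- vector("list", n_sub)
      for (i in seq_len(n_sub)) {
        cs <- estimate_csd(trials[[cond]][[i]], band)
        csds[[cond]][[bn]][[i]] <- cs
        filt <- dics_filters(cs, lf, config$dics_lambda)
        pow_maps[[i]] <- source_power_map(filt, cs)
        src <- source_cross_spectrum(filt, cs)
        ns_maps[[i]] <- node_strength_map(imcoh_from_csd(src))
        g_power[i, bn, cond] <- global_average(pow_maps[[i]])
        g_fc[i, bn, cond] <- global_average(ns_maps[[i]])
      }
      for (what in c("power", "fc")) {
        maps <- if (what == "power") pow_maps else ns_maps
        gv <- if (what == "power") g_power[, bn, cond] else g_fc[, bn, cond]
        gt <- permutation_test(gv, design, "group", n_perm = config$n_perm,
                               seed = derive_seed(seed0, "global", what,
                                                  cond, bn))
        vt <- permutation_test(maps, design, "group", n_perm = config$n_perm,
                               seed = derive_seed(seed0, "vertex", what,
                                                  cond, bn),
                               enhance = enh)
        M <- do.call(rbind, lapply(maps, map_values))
        global[[cond]][[bn]][[what]] <- list(
          mean_patient = mean(gv[grp]), mean_control = mean(gv[!grp]),
          t = gt$t_map, p = gt$p_uncorrected,
          neglog10_p = -log10(gt$p_uncorrected),
          d = cohens_d(gv[grp], gv[!grp]))
        vertex[[cond]][[bn]][[what]] <- list(
          result = vt, d_map = cohens_d(M[grp, , drop = FALSE],
                                        M[!grp, , drop = FALSE]),
          min_p_fwe = min(vt$p_fwe),
          n_sig_fwe = sum(vt$p_fwe < config$alpha))
      }
    }
  }

  # FDR across bands on global -log10 p (per condition and metric)
  for (cond in conditions)
    for (what in c("power", "fc")) {
      ps <- vapply(names(bands), function(bn)
        global[[cond]][[bn]][[what]]$p, 0)
      fdr <- bh_fdr(ps)
      for (k in seq_along(ps))
        global[[cond]][[names(bands)[k]]][[what]]$p_fdr <- fdr[k]
    }

  # --- condition differences ---------------------------------------------
  condition_tests <- NULL
  similarity <- NULL
  if (all(c("inside", "outside") %in% conditions)) {
    for (what in c("power", "fc")) {
      arr <- if (what == "power") g_power else g_fc
      for (gname in c("patient", "control")) {
        gi <- if (gname == "patient") grp else !grp
        delta_pct[[what]][[gname]] <- vapply(names(bands), function(bn)
          relative_difference(mean(arr[gi, bn, "inside"]),
                              mean(arr[gi, bn, "outside"])), 0)
      }
      safe_sim <- function(a, b) tryCatch(
        spatial_correlation(a, b),
        rc_error_degenerate = function(e) list(r = NA_real_, p = 1))
      ct <- condition_interaction_test(
        arr[, , "inside"], arr[, , "outside"], cov,
        n_perm = config$n_perm,
        seed = derive_seed(seed0, "interaction", what))
      condition_tests[[what]] <- ct
      sim <- lapply(names(bands), function(bn) {
        ri <- vertex[["inside"]][[bn]][[what]]$result
        ro <- vertex[["outside"]][[bn]][[what]]$result
        safe_sim(ri$neglog10_p, ro$neglog10_p)
      })
      simdf <- data.frame(band = names(bands),
                          r = vapply(sim, `[[`, 0, "r"),
                          p = vapply(sim, `[[`, 0, "p"))
      simdf$p_fdr <- bh_fdr(pmin(pmax(simdf$p, 1e-300), 1))
      similarity[[what]] <- simdf
    }
  }

  # --- fMRI seed-based FC -------------------------------------------------
  fmri <- NULL
  has_bold <- !is.null(cohort$subjects[[1]]$bold)
  if (has_bold) {
    seed_regions <- intersect(config$seed_regions,
                              unique(space$region_label))
    zmaps <- list()
    for (i in seq_len(n_sub)) {
      b <- cohort$subjects[[i]]$bold
      gswd <- if ("inside" %in% conditions)
        cohort$subjects[[i]]$gt_inside$gswd_s %||% numeric(0) else numeric(0)
      b <- flag_outlier_volumes(b, gswd_events_s = gswd)
      b <- regress_confounds(b)
      b <- bandpass_bold(b)
      for (sr in seed_regions) {
        m <- seed_fc_fmri(b, space, sr)
        zmaps[[sr]][[i]] <- m$meta$fisher_z
      }
    }
    fmri <- list(seed_results = list())
    for (sr in seed_regions) {
      M <- do.call(rbind, zmaps[[sr]])
      vt <- permutation_test(M, design, "group", n_perm = config$n_perm,
                             seed = derive_seed(seed0, "fmri", sr),
                             enhance = enh)
      fmri$seed_results[[sr]] <- list(
        result = vt, min_p_fwe = min(vt$p_fwe),
        n_sig_fwe = sum(vt$p_fwe < config$alpha),
        d_map = cohens_d(M[grp, , drop = FALSE], M[!grp, , drop = FALSE]))
    }
  }

  # --- cross-modal surrogate test ----------------------------------------
  crossmodal <- NULL
  if (has_bold) {
    eeg_cond <- if ("inside" %in% conditions) "inside" else conditions[1]
    sig_bands <- names(bands)[vapply(names(bands), function(bn)
      vertex[[eeg_cond]][[bn]][["fc"]]$min_p_fwe < config$alpha, TRUE)]
    sig_seeds <- names(fmri$seed_results)[vapply(
      fmri$seed_results, function(x) x$min_p_fwe < config$alpha, TRUE)]
    if (length(sig_bands) > 0 && length(sig_seeds) > 0) {
      cm <- config$crossmodal
      ensembles <- list()
      for (sr in sig_seeds)
        for (bn in sig_bands) {
          target <- vertex_map(fmri$seed_results[[sr]]$result$neglog10_p_fwe,
                               "neglog10p")
          ensembles[[paste(sr, bn, sep = "/")]] <-
            surrogate_null_distribution(
              csds[[eeg_cond]][[bn]], lf, space, target, sr, bn, cov,
              n_surrogates_per_subject = cm$n_surrogates_per_subject,
              n_draws = cm$n_draws, n_perm = cm$n_perm,
              lambda_fraction = config$dics_lambda,
              seed = derive_seed(seed0, "crossmodal", sr, bn))
        }
      crossmodal <- list(decisions = percentile_significance(ensembles,
                                                             config$alpha),
                         ensembles = ensembles,
                         gated_bands = sig_bands, gated_seeds = sig_seeds)
    } else {
      crossmodal <- list(decisions = NULL, gated_bands = sig_bands,
                         gated_seeds = if (has_bold) sig_seeds else character(0))
    }
  }

  result <- list(global = global, vertex = vertex, delta_pct = delta_pct,
                 condition_tests = condition_tests, similarity = similarity,
                 fmri = fmri, crossmodal = crossmodal,
                 n_trials_selected = n_select,
                 provenance = list(seed = seed0, n_perm = config$n_perm,
                                   dics_lambda = config$dics_lambda,
                                   bands = names(bands),
                                   conditions = conditions,
                                   n_subjects = n_sub,
                                   package_version =
                                     as.character(utils::packageVersion("restcouple"))))
  if (!is.null(config$output_dir)) write_report(result, config$output_dir)
  result
}

#' Write the machine-readable analysis report
#'
#' Serializes every number of a [run_full_analysis()] result to
#' `report.json` plus per-table TSVs under `out_dir`.
#'
#' @param result a [run_full_analysis()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(x) {
    if (inherits(x, "stat_result"))
      return(list(min_p_fwe = min(x$p_fwe),
                  max_neglog10_p_fwe = max(-log10(x$p_fwe)),
                  max_t = max(x$t_map), n_permutations = x$n_permutations))
    if (inherits(x, "surrogate_ensemble"))
      return(list(observed_r = x$observed_r, null_median = median(x$null_r),
                  null_q95 = unname(quantile(x$null_r, 0.95)),
                  n_draws = x$n_draws))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(result), file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  if (!is.null(result$similarity))
    for (what in names(result$similarity))
      .write_tsv(result$similarity[[what]],
                 file.path(out_dir, paste0("similarity_", what, ".tsv")))
  if (!is.null(result$crossmodal$decisions))
    .write_tsv(result$crossmodal$decisions,
               file.path(out_dir, "crossmodal_decisions.tsv"))
  invisible(out_dir)
}
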