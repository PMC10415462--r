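# Cross-modal spatial concordance of EEG and fMRI group-difference maps,
# tested against a sensor-shuffling surrogate null: shuffling the channel
# series against the channel labels breaks the leadfield correspondence, so
# source maps from shuffled data carry no true anatomy-locked topography.

#' Spatial Pearson correlation of two vertex maps
#'
#' Correlation across vertices of two unthresholded maps, with the
#' parametric p-value (n = vertex count) retained for condition-similarity
#' use; cross-modal claims should use the surrogate test instead.
#'
#' @param map_a,map_b `vertex_map`s or numeric vectors over the same space.
#' @return List with `r`, `p` and `n`.
#' @export
spatial_correlation <- function(map_a, map_b) {
  a <- map_values(map_a); b <- map_values(map_b)
  rc_assert(length(a) == length(b), "maps must cover the same vertices")
  if (sd(a) == 0 || sd(b) == 0)
    rc_abort("correlation undefined for a constant map", "degenerate")
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Shuffle EEG channel series against their labels
#'
#' Permutes the channel time series relative to the channel labels (events
#' untouched); the identity permutation is rejected and redrawn. Used to
#' build surrogate datasets whose leadfield correspondence is broken.
#'
#' @param rec a `sensor_recording` with at least 2 channels.
#' @param seed integer seed.
#' @return The shuffled recording; the permutation used is stored under
#'   `meta$sensor_permutation`.
#' @export
shuffle_sensors <- function(rec, seed = 1) {
  S <- nrow(rec$data)
  if (S < 2) rc_abort("cannot shuffle a single channel", "validation")
  perm <- with_rc_seed(seed, {
    p <- sample.int(S)
    while (all(p == seq_len(S))) p <- sample.int(S)
    p
  })
  meta <- rec$meta
  meta$sensor_permutation <- perm
  out <- sensor_recording(rec$data[perm, , drop = FALSE], rec$rate,
                          rec$channel_labels, rec$events, rec$condition, meta)
  out
}

# Draw n distinct non-identity channel permutations.
.sensor_perms <- function(n_channels, n_surrogates, seed) {
  with_rc_seed(seed, {
    seen <- character(0)
    out <- matrix(0L, n_surrogates, n_channels)
    i <- 1
    while (i <= n_surrogates) {
      p <- sample.int(n_channels)
      key <- paste(p, collapse = ",")
      if (all(p == seq_len(n_channels)) || key %in% seen) next
      seen <- c(seen, key)
      out[i, ] <- p
      i <- i + 1
    }
    out
  })
}

# Apply a channel permutation to a sensor CSD. Identical (exactly) to
# re-estimating the CSD from the channel-shuffled recording, since the CSD
# is a per-channel-pair average; the equivalence is asserted by tests.
.permute_csd <- function(csd, perm) {
  cross_spectrum(csd$matrix[perm, perm, drop = FALSE], csd$band,
                 csd$n_trials_used, csd$space_tag, csd$meta)
}

# Seed-FC map from DICS filters without materializing the full source CSD:
# only the seed rows of W C W^H plus the per-vertex powers are needed.
.seed_fc_from_filters <- function(filters, csd, space, seed_region) {
  sv <- region_vertices(space, seed_region)
  W <- filters$weights
  WC <- W %*% csd$matrix                        # V x sensors
  pow <- Re(rowSums(WC * Conj(W)))
  if (any(pow <= 0))
    rc_abort("zero source power under the beamformer", "degenerate_power")
  Srow <- WC[sv, , drop = FALSE] %*% Conj(t(W)) # seeds x V
  ic <- abs(Im(Srow / (sqrt(pow[sv]) %o% sqrt(pow))))
  ic[cbind(seq_along(sv), sv)] <- 0
  val <- colSums(ic) / length(sv)
  if (length(sv) > 1) val[sv] <- colSums(ic)[sv] / (length(sv) - 1)
  vertex_map(pmin(val, 1), "seed_fc", band = csd$band$name,
             space_id = space$space_id,
             meta = list(seed_region = seed_region, seed_vertices = sv,
                         provenance = "dics_imcoh_seed_fc"))
}

#' Surrogate null distribution for cross-modal correlation
#'
#' For every subject, a fixed set of distinct channel permutations defines
#' surrogate datasets; each surrogate passes through the identical
#' beamformer + seed-connectivity code path as the real data. For each of
#' `n_draws` draws, one surrogate map per subject is chosen at random, the
#' group comparison is recomputed (at a reduced permutation count), and the
#' unthresholded -log10 p map is correlated with the fMRI target map,
#' yielding the null distribution of the cross-modal spatial correlation.
#' The observed correlation from the unshuffled data is computed by the
#' same path.
#'
#' @param subject_csds list of per-subject *sensor-space* `cross_spectrum`
#'   objects for the analysis band (one per subject, cleaned + selected
#'   trials), or a list of `trial_set`s (CSDs are then estimated here).
#' @param leadfield,space the shared forward model and source space.
#' @param fmri_target_map `vertex_map` (or vector) to correlate against.
#' @param seed_region seed region label.
#' @param band analysis band.
#' @param covariates covariate data frame for [make_design()].
#' @param n_surrogates_per_subject surrogate datasets per subject
#'   (default 50).
#' @param n_draws null draws (default 500).
#' @param n_perm permutations per group comparison in the surrogate branch
#'   (reduced; default 500).
#' @param lambda_fraction DICS regularization.
#' @param use_tfce enhance group maps with TFCE over the space adjacency.
#' @param use_fwe correlate the FWE-corrected (-log10) map; otherwise the
#'   uncorrected map. Both observed variants are stored.
#' @param seed integer seed.
#' @return A `surrogate_ensemble` with `null_r`, `observed_r`,
#'   per-subject permutations and the configuration.
#' @export
surrogate_null_distribution <- function(subject_csds, leadfield, space,
                                        fmri_target_map, seed_region, band,
                                        covariates,
                                        n_surrogates_per_subject = 50,
                                        n_draws = 500, n_perm = 500,
                                        lambda_fraction = 0.05,
                                        use_tfce = TRUE, use_fwe = TRUE,
                                        seed = 1) {
  band <- as_band(band)
  if (all(vapply(subject_csds, inherits, TRUE, "trial_set")))
    subject_csds <- lapply(subject_csds, estimate_csd, band = band)
  rc_assert(all(vapply(subject_csds, inherits, TRUE, "cross_spectrum")),
            "subject_csds must be cross_spectrum or trial_set objects")
  n_sub <- length(subject_csds)
  rc_assert(n_sub == nrow(covariates), "one CSD per covariate row required")
  S <- nrow(subject_csds[[1]]$matrix)
  fmri_vals <- map_values(fmri_target_map)

  design <- make_design(covariates)
  enh <- if (use_tfce) list(adjacency = space) else NULL
  target <- map_values(fmri_target_map)

  group_map_r <- function(maps, pseed) {
    res <- permutation_test(maps, design, "group", n_perm = n_perm,
                            seed = pseed, enhance = enh)
    # a draw with no positive statistic anywhere yields a constant p map;
    # spatially it carries no structure, so its correlation is 0
    safe_r <- function(m) tryCatch(spatial_correlation(m, target)$r,
                                   rc_error_degenerate = function(e) 0)
    c(fwe = safe_r(res$neglog10_p_fwe), unc = safe_r(res$neglog10_p))
  }

  # real branch
  real_maps <- lapply(subject_csds, function(cs) {
    f <- dics_filters(cs, leadfield, lambda_fraction)
    .seed_fc_from_filters(f, cs, space, seed_region)
  })
  obs <- group_map_r(real_maps, derive_seed(seed, "observed"))

  # surrogate maps per subject
  perms <- vector("list", n_sub)
  surr_maps <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    perms[[i]] <- .sensor_perms(S, n_surrogates_per_subject,
                                derive_seed(seed, "sensorperm", i))
    surr_maps[[i]] <- lapply(seq_len(n_surrogates_per_subject), function(k) {
      cs <- .permute_csd(subject_csds[[i]], perms[[i]][k, ])
      f <- dics_filters(cs, leadfield, lambda_fraction)
      map_values(.seed_fc_from_filters(f, cs, space, seed_region))
    })
  }

  choice <- with_rc_seed(derive_seed(seed, "draws"),
                         matrix(sample.int(n_surrogates_per_subject,
                                           n_draws * n_sub, replace = TRUE),
                                n_draws, n_sub))
  null_r <- numeric(n_draws)
  null_r_unc <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    maps <- do.call(rbind, lapply(seq_len(n_sub), function(i)
      surr_maps[[i]][[choice[d, i]]]))
    rr <- group_map_r(maps, derive_seed(seed, "drawperm", d))
    null_r[d] <- rr[if (use_fwe) "fwe" else "unc"]
    null_r_unc[d] <- rr["unc"]
  }
  structure(list(
    null_r = null_r, null_r_uncorrected = null_r_unc,
    observed_r = unname(obs[if (use_fwe) "fwe" else "unc"]),
    observed_r_uncorrected = unname(obs["unc"]),
    sensor_permutations = perms, draw_choice = choice,
    seed_region = seed_region, band = band$name,
    n_draws = n_draws,
    n_surrogates_per_subject = n_surrogates_per_subject,
    percentile_cutoff = 95, use_fwe = use_fwe, seed = seed
  ), class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> seed %s / band %s: observed r = %.3f, null median = %.3f (%d draws)\n",
    x$seed_region, x$band, x$observed_r, median(x$null_r), x$n_draws))
  invisible(x)
}

#' Surrogate-percentile significance with FDR
#'
#' For each tested (seed region x band) ensemble, the empirical p-value is
#' (1 + count(null >= observed)) / (1 + n_draws); a test is significant when
#' the observed correlation surpasses the 95th percentile of its null AND
#' its BH-FDR-adjusted p across the tested set is <= alpha.
#'
#' @param ensembles a `surrogate_ensemble` or list of them (the tested
#'   seed x band set).
#' @param alpha significance level (default 0.05).
#' @return Data frame: seed_region, band, observed_r, null 95th percentile,
#'   p, p_fdr, significant.
#' @export
percentile_significance <- function(ensembles, alpha = 0.05) {
  if (inherits(ensembles, "surrogate_ensemble")) ensembles <- list(ensembles)
  rows <- lapply(ensembles, function(e) {
    rc_assert(length(e$null_r) > 0, "empty surrogate null")
    p <- (1 + sum(e$null_r >= e$observed_r)) / (1 + length(e$null_r))
    data.frame(seed_region = e$seed_region, band = e$band,
               observed_r = e$observed_r,
               null_q95 = unname(quantile(e$null_r, e$percentile_cutoff / 100)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  out$significant <- out$observed_r > out$null_q95 & out$p_fdr <= alpha
  out
}
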