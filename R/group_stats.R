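# Group inference: GLM t-contrasts with covariates, Freedman-Lane
# permutation tests with optional TFCE and max-statistic FWE correction,
# Benjamini-Hochberg FDR, Cohen's d, and the paired condition x group test.

#' Build a group design matrix
#'
#' Columns: intercept, group indicator (1 = patient-like, 0 = control-like),
#' and the requested covariates (age as-is, sex coded female = 1).
#'
#' @param covariates data frame with columns `group`, `age`, `sex` (as in a
#'   [cohort_design()]'s `covariates`).
#' @param include covariate columns to include.
#' @param extra optional named list of additional numeric covariates (e.g.
#'   scan volume counts for fMRI maps).
#' @return Numeric design matrix with named columns.
#' @export
make_design <- function(covariates, include = c("age", "sex"), extra = NULL) {
  X <- cbind(intercept = 1,
             group = as.numeric(covariates$group %in% c("patient", 1, "1")))
  if ("age" %in% include) X <- cbind(X, age = as.numeric(covariates$age))
  if ("sex" %in% include)
    X <- cbind(X, sex = as.numeric(covariates$sex %in% c("f", "F", 1)))
  if (!is.null(extra))
    for (nm in names(extra)) {
      X <- cbind(X, as.numeric(extra[[nm]]))
      colnames(X)[ncol(X)] <- nm
    }
  # constant covariates (e.g. a single-sex mini-cohort) carry no information
  # and would break the fit; drop them rather than fail
  keep <- colnames(X) %in% c("intercept", "group") |
    apply(X, 2, function(x) sd(x) > 0)
  X <- X[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X))
    rc_abort("design matrix is rank deficient", "design")
  X
}

.obs_matrix <- function(observations) {
  if (inherits(observations, "vertex_map"))
    return(matrix(observations$values, nrow = 1))
  if (is.list(observations) && all(vapply(observations, inherits, TRUE,
                                          "vertex_map")))
    return(do.call(rbind, lapply(observations, map_values)))
  if (is.vector(observations) && is.numeric(observations))
    return(matrix(observations, ncol = 1))
  rc_assert(is.matrix(observations), "observations must be a matrix, vector, or list of vertex_maps")
  observations
}

.contrast_col <- function(design, contrast) {
  if (is.character(contrast)) {
    rc_assert(contrast %in% colnames(design),
              paste0("no design column '", contrast, "'"), "design")
    which(colnames(design) == contrast)[1]
  } else as.integer(contrast)
}

#' GLM t-statistics for a contrast
#'
#' Ordinary least squares per vertex; returns the t value of the contrast
#' (one value per vertex). For a plain two-group design without covariates
#' this equals the classic pooled two-sample t.
#'
#' @param observations subjects x vertices matrix (or vector / list of
#'   `vertex_map`s, one per subject).
#' @param design design matrix from [make_design()].
#' @param contrast design column name/index, or a numeric contrast vector.
#' @return Numeric vector of t values.
#' @export
glm_t_contrast <- function(observations, design, contrast = "group") {
  Y <- .obs_matrix(observations)
  X <- design
  rc_assert(nrow(Y) == nrow(X), "observation count must equal design rows",
            "design")
  if (qr(X)$rank < ncol(X)) rc_abort("design matrix is rank deficient", "design")
  cvec <- if (is.numeric(contrast) && length(contrast) == ncol(X)) contrast
  else {
    cc <- rep(0, ncol(X)); cc[.contrast_col(X, contrast)] <- 1; cc
  }
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  # relative guard: a numerically-zero residual variance means the contrast
  # explains nothing beyond rounding noise -> t = 0
  degenerate <- sigma2 <= 1e-20 * (colMeans(Y^2) + 1e-300)
  se <- sqrt(sigma2 * as.numeric(t(cvec) %*% XtXi %*% cvec))
  tt <- as.numeric(t(cvec) %*% B)
  ifelse(se > 0 & !degenerate, tt / se, 0)
}

.enumerate_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .enumerate_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

.perm_matrix <- function(n, n_perm, seed) {
  if (n <= 7 && factorial(n) <= n_perm) {
    warning(sprintf(
      "only %d distinct permutations available; enumerating exhaustively",
      factorial(n)), call. = FALSE)
    return(.enumerate_perms(n))
  }
  with_rc_seed(seed, t(replicate(n_perm, sample.int(n))))
}

.csr_from_adjacency <- function(adjacency, V) {
  if (inherits(adjacency, "source_space")) {
    V <- n_vertices(adjacency)
    nbr <- adjacency_list(adjacency$adjacency, V)
  } else if (is.matrix(adjacency)) {
    nbr <- adjacency_list(adjacency, V)
  } else nbr <- adjacency
  if (sum(lengths(nbr)) == 0 && V > 1)
    rc_abort("adjacency graph is empty", "graph")
  ptr <- c(0L, cumsum(lengths(nbr)))
  list(ptr = as.integer(ptr), idx = as.integer(unlist(nbr) - 1L), V = V)
}

#' Permutation test result
#' @param x list of result fields (see [permutation_test()]).
#' @return A `stat_result` object.
#' @keywords internal
#' @export
stat_result <- function(x) structure(x, class = "stat_result")

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf(
    "<stat_result> %d vertices, %d permutations, min p_fwe = %.4g (-log10 = %.3g)\n",
    length(x$t_map), x$n_permutations, min(x$p_fwe), max(-log10(x$p_fwe))))
  invisible(x)
}

#' Permutation GLM test with optional TFCE
#'
#' One-tailed test of a single design column (default: patients > controls)
#' using the Freedman-Lane scheme: the nuisance-only model residuals are
#' permuted, the full model is refit for each permutation, and p-values are
#' the empirical exceedance probabilities (1 + count) / (1 + n_perm). When
#' `enhance` is supplied the compared statistic is the TFCE-enhanced t map
#' and max-statistic familywise-error p-values are computed in the same
#' pass. For tiny designs where fewer distinct permutations than `n_perm`
#' exist, all permutations are enumerated (with a warning).
#'
#' @param observations subjects x vertices matrix (or vector / list of
#'   `vertex_map`s).
#' @param design design matrix from [make_design()].
#' @param contrast design column name or index (a single column).
#' @param n_perm number of permutations (>= 100 recommended; 20000 at study
#'   scale).
#' @param seed integer seed; the test is reproducible given (data, design,
#'   seed).
#' @param enhance optional TFCE settings: a list with `adjacency` (a
#'   `source_space`, edge matrix or neighbour list) and optional
#'   `height_power` (default 2), `extent_power` (default 1).
#' @return A `stat_result` with `t_map`, `stat_map` (enhanced statistic),
#'   `p_uncorrected`, `p_fwe`, their `-log10` versions, `max_null`,
#'   `n_permutations` and `seed`.
#' @export
permutation_test <- function(observations, design, contrast = "group",
                             n_perm = 2000, seed = 1, enhance = NULL) {
  Y <- .obs_matrix(observations)
  X <- design
  rc_assert(nrow(Y) == nrow(X), "observation count must equal design rows",
            "design")
  if (qr(X)$rank < ncol(X)) rc_abort("design matrix is rank deficient", "design")
  con <- .contrast_col(X, contrast)
  perms <- .perm_matrix(nrow(Y), n_perm, seed)
  use_tfce <- !is.null(enhance)
  if (use_tfce) {
    csr <- .csr_from_adjacency(enhance$adjacency, ncol(Y))
    rc_assert(csr$V == ncol(Y), "adjacency does not cover all vertices",
              "graph")
    H <- enhance$height_power %||% 2
    E <- enhance$extent_power %||% 1
  } else {
    csr <- list(ptr = c(0L, integer(ncol(Y))), idx = integer(0))
    H <- 2; E <- 1
  }
  res <- .perm_core_cpp(Y, X, con - 1L, perms - 1L, use_tfce,
                        csr$ptr, csr$idx, H, E)
  stat_result(list(
    t_map = res$t_obs, stat_map = res$stat_obs,
    p_uncorrected = res$p_unc, p_fwe = res$p_fwe,
    neglog10_p = -log10(res$p_unc), neglog10_p_fwe = -log10(res$p_fwe),
    max_null = res$max_null, tfce = use_tfce,
    n_permutations = nrow(perms), seed = seed, contrast = colnames(X)[con]))
}

#' Threshold-free cluster enhancement
#'
#' TFCE(v) = sum over thresholds h (step dh, up to stat(v)) of
#' e(h, v)^E * h^H * dh, where e(h, v) is the size of the connected
#' suprathreshold component containing v. Negative values map to 0
#' (one-tailed). Defaults follow the surface convention height H = 2,
#' extent E = 1.
#'
#' @param stat_map `vertex_map` or numeric vector of statistics.
#' @param adjacency a `source_space`, 2-column edge matrix, or neighbour
#'   list covering all vertices.
#' @param height_power,extent_power TFCE exponents H and E.
#' @param dh integration step; default `max(stat) / 100`.
#' @return Numeric vector of enhanced values.
#' @export
tfce_enhance <- function(stat_map, adjacency, height_power = 2,
                         extent_power = 1, dh = NULL) {
  v <- map_values(stat_map)
  csr <- .csr_from_adjacency(adjacency, length(v))
  rc_assert(csr$V == length(v), "adjacency does not cover all vertices",
            "graph")
  .tfce_cpp(pmax(v, 0), csr$ptr, csr$idx, height_power, extent_power,
            dh %||% 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Adjusted p-values (empty input gives empty output).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  rc_assert(all(p_values > 0 & p_values <= 1), "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Cohen's d effect size
#'
#' (mean_a - mean_b) / pooled SD with (n - 1)-weighted pooling. Matrix
#' inputs (subjects x vertices) give a per-vertex d.
#'
#' @param group_a,group_b numeric vectors, or matrices with subjects in rows.
#' @return Scalar or per-vertex numeric vector.
#' @export
cohens_d <- function(group_a, group_b) {
  A <- .obs_matrix(group_a); B <- .obs_matrix(group_b)
  na <- nrow(A); nb <- nrow(B)
  rc_assert(na >= 2 && nb >= 2, "each group needs at least 2 observations")
  va <- apply(A, 2, var); vb <- apply(B, 2, var)
  pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  if (all(pooled == 0))
    rc_abort("pooled standard deviation is zero", "degenerate")
  d <- (colMeans(A) - colMeans(B)) / ifelse(pooled > 0, pooled, Inf)
  if (length(d) == 1) as.numeric(d) else d
}

# scalar permutation t-test (Freedman-Lane), used by the paired tests
.perm_t_scalar <- function(y, X, con, perms, two_sided = TRUE) {
  tt <- function(d) glm_t_contrast(d, X, con)
  t_obs <- tt(y)
  Z <- X[, -.contrast_col(X, con), drop = FALSE]
  yz <- if (ncol(Z) > 0) stats::resid(stats::lm.fit(Z, y)) else y
  t_null <- apply(perms, 1, function(pp) tt(yz[pp]))
  cmp <- if (two_sided) abs(t_null) >= abs(t_obs) - 1e-12 else
    t_null >= t_obs - 1e-12
  list(t = t_obs, p = (1 + sum(cmp)) / (1 + length(t_null)))
}

#' Paired condition and condition-by-group permutation test
#'
#' Two-level-per-subject design: for each column (band) of the paired
#' observations, the condition main effect is tested by sign-flipping the
#' within-subject inside-minus-outside differences (one-sample t), and the
#' condition x group interaction by permuting group labels over the
#' differences with age and sex as nuisance covariates (Freedman-Lane).
#' Both p-values are two-sided and FDR-corrected across columns.
#'
#' @param inside,outside subjects x bands matrices (or vectors) of paired
#'   observations, rows aligned subject-for-subject.
#' @param design covariate data frame (columns `group`, `age`, `sex`) or a
#'   design matrix from [make_design()].
#' @param n_perm number of permutations / sign flips.
#' @param seed integer seed.
#' @return Data frame per band: t, p, FDR-adjusted p and Cohen's d for the
#'   condition effect and the interaction.
#' @export
condition_interaction_test <- function(inside, outside, design, n_perm = 2000,
                                       seed = 1) {
  Yi <- .obs_matrix(inside); Yo <- .obs_matrix(outside)
  if (!all(dim(Yi) == dim(Yo)))
    rc_abort("inside and outside observations are not paired", "pairing")
  D <- Yi - Yo
  n <- nrow(D)
  X <- if (is.data.frame(design)) make_design(design) else design
  rc_assert(nrow(X) == n, "design rows must match subject count", "pairing")
  grp <- X[, "group"]

  flips <- if (2^n <= n_perm) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else with_rc_seed(derive_seed(seed, "flips"),
                      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                             n_perm, n))
  perms <- .perm_matrix(n, n_perm, derive_seed(seed, "perms"))

  one_band <- function(d) {
    # condition main effect: sign-flip one-sample t on the differences
    se <- sd(d) / sqrt(n)
    t_c <- if (se > 0) mean(d) / se else 0
    t_null <- apply(flips, 1, function(s) {
      ds <- s * d
      se_s <- sd(ds) / sqrt(n)
      if (se_s > 0) mean(ds) / se_s else 0
    })
    p_c <- (1 + sum(abs(t_null) >= abs(t_c) - 1e-12)) / (1 + length(t_null))
    d_c <- if (sd(d) > 0) mean(d) / sd(d) else 0
    # interaction: group effect on the differences
    int <- .perm_t_scalar(d, X, "group", perms, two_sided = TRUE)
    d_i <- tryCatch(cohens_d(d[grp == 1], d[grp == 0]), rc_error = function(e) 0)
    c(condition_t = t_c, condition_p = p_c, condition_d = d_c,
      interaction_t = int$t, interaction_p = int$p, interaction_d = d_i)
  }
  res <- as.data.frame(t(apply(D, 2, one_band)))
  res$condition_p_fdr <- bh_fdr(res$condition_p)
  res$interaction_p_fdr <- bh_fdr(res$interaction_p)
  res$band <- colnames(D) %||% paste0("col", seq_len(ncol(D)))
  rownames(res) <- res$band
  res[, c("band", "condition_t", "condition_p", "condition_p_fdr",
          "condition_d", "interaction_t", "interaction_p",
          "interaction_p_fdr", "interaction_d")]
}
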