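mk_cov <- function(n_a, n_b, seed = 1) {
  withr::with_seed(seed, data.frame(
    group = rep(c("patient", "control"), c(n_a, n_b)),
    age = round(runif(n_a + n_b, 19, 57)),
    sex = sample(c("f", "m"), n_a + n_b, replace = TRUE)))
}

test_that("GLM t for a plain two-group design equals the pooled t-test", {
  cov <- mk_cov(6, 6)
  X <- cbind(intercept = 1,
             group = as.numeric(cov$group == "patient"))
  withr::with_seed(131, { y <- rnorm(12) + 0.5 * X[, "group"] })
  t_pkg <- glm_t_contrast(y, X, "group")
  t_oracle <- t.test(y[1:6], y[7:12], var.equal = TRUE)$statistic
  expect_equal(t_pkg, unname(t_oracle), tolerance = 1e-10)
})

test_that("GLM t is invariant to constant shifts and zero for flat contrasts", {
  cov <- mk_cov(5, 5)
  X <- make_design(cov)
  withr::with_seed(132, { Y <- matrix(rnorm(10 * 7), 10, 7) })
  t1 <- glm_t_contrast(Y, X, "group")
  t2 <- glm_t_contrast(Y + 100, X, "group")
  expect_equal(t1, t2, tolerance = 1e-8)
  # observations identical in both groups: contrast orthogonal to variation
  Yc <- matrix(rep(rnorm(7), each = 10), 10, 7)
  expect_equal(glm_t_contrast(Yc, X, "group"), rep(0, 7))
})

test_that("permutation p is 1 when groups are identical and is seeded", {
  cov <- mk_cov(4, 4)
  X <- cbind(intercept = 1, group = as.numeric(cov$group == "patient"))
  y <- rep(2.5, 8)
  res <- suppressWarnings(permutation_test(y, X, n_perm = 500, seed = 3))
  expect_equal(res$p_uncorrected, 1)
  withr::with_seed(133, { y2 <- rnorm(8) })
  r1 <- suppressWarnings(permutation_test(y2, X, n_perm = 200, seed = 9))
  r2 <- suppressWarnings(permutation_test(y2, X, n_perm = 200, seed = 9))
  expect_identical(r1$p_uncorrected, r2$p_uncorrected)
  expect_true(all(r1$p_uncorrected > 0))
  expect_true(all(r1$p_fwe >= r1$p_uncorrected - 1e-12))
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration within 0.02", {
  withr::with_seed(134, { y <- c(rnorm(4) + 1.2, rnorm(4)) })
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = 4))
  # exhaustive-permutation oracle over all choose(8,4) group reassignments
  t_of <- function(g) {
    a <- y[g == 1]; b <- y[g == 0]
    sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
    (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  }
  t_obs <- t_of(X[, "group"])
  combs <- combn(8, 4)
  t_null <- apply(combs, 2, function(idx) {
    g <- rep(0, 8); g[idx] <- 1; t_of(g)
  })
  p_exh <- mean(t_null >= t_obs - 1e-12)
  res <- permutation_test(y, X, n_perm = 10000, seed = 5)
  expect_lt(abs(res$p_uncorrected - p_exh), 0.02)
})

test_that("tiny designs fall back to exhaustive enumeration with a warning", {
  y <- c(1, 2, 3, 9, 10, 11)
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = 3))
  expect_warning(res <- permutation_test(y, X, n_perm = 5000, seed = 1),
                 "enumerat")
  expect_equal(res$n_permutations, factorial(6))
})

test_that("TFCE matches closed-form and brute-force oracles", {
  path_edges <- cbind(1:4, 2:5)
  # isolated suprathreshold vertex: integral of h^2 dh from 0 to 3 = 9
  v <- c(0, 0, 3, 0, 0)
  enh <- tfce_enhance(v, path_edges, dh = 0.005)
  expect_equal(enh[3], 9, tolerance = 0.02 * 9)
  expect_equal(enh[c(1, 2, 4, 5)], rep(0, 4))
  # all-zero map stays zero
  expect_equal(tfce_enhance(rep(0, 5), path_edges), rep(0, 5))
  # plateau on a path: brute-force threshold-sweep oracle
  v2 <- c(0.5, 2, 2, 2, 0.3)
  dh <- max(v2) / 400
  oracle <- numeric(5)
  nbr <- adjacency_list(path_edges, 5)
  for (k in seq_len(400)) {
    h <- k * dh
    above <- which(v2 >= h - 1e-12)
    # connected components by direct scan
    comp <- rep(NA_integer_, 5)
    cid <- 0
    for (s in above) {
      if (!is.na(comp[s])) next
      cid <- cid + 1
      q <- s; comp[s] <- cid
      while (length(q) > 0) {
        u <- q[1]; q <- q[-1]
        for (w in intersect(nbr[[u]], above)) {
          if (is.na(comp[w])) { comp[w] <- cid; q <- c(q, w) }
        }
      }
    }
    for (s in above) {
      e <- sum(comp == comp[s], na.rm = TRUE)
      oracle[s] <- oracle[s] + e^1 * h^2 * dh
    }
  }
  enh2 <- tfce_enhance(v2, path_edges, dh = dh)
  expect_equal(enh2, oracle, tolerance = 0.01 * max(oracle))
})

test_that("TFCE is monotone in the input map", {
  sp <- tiny_space()
  withr::with_seed(135, {
    v <- pmax(rnorm(n_vertices(sp)), 0)
  })
  lo <- tfce_enhance(v, sp)
  hi <- tfce_enhance(v + 0.5, sp)
  expect_true(all(hi >= lo - 1e-9))
  expect_error(tfce_enhance(v, list()), class = "rc_error_graph")
})

test_that("BH-FDR equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.007), 0.007)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # step-up oracle on a random vector
  withr::with_seed(136, { p <- runif(20) })
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  expect_equal(bh_fdr(p), adj, tolerance = 1e-12)
  expect_error(bh_fdr(c(0.1, 0)), class = "rc_error")
})

test_that("Cohen's d follows the pooled-SD formula", {
  expect_equal(cohens_d(c(0, 1, 2), c(-1, 0, 1)), 1)  # means 1/0, pooled SD 1
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  withr::with_seed(137, { a <- rnorm(9, 1); b <- rnorm(7) })
  d_oracle <- (mean(a) - mean(b)) /
    sqrt((8 * var(a) + 6 * var(b)) / 14)
  expect_equal(cohens_d(a, b), d_oracle, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "rc_error_degenerate")
})

test_that("paired condition test: identical conditions give p = 1", {
  cov <- mk_cov(4, 4)
  withr::with_seed(138, { M <- matrix(rnorm(8 * 3), 8, 3) })
  colnames(M) <- c("delta", "theta", "alpha")
  res <- suppressWarnings(
    condition_interaction_test(M, M, cov, n_perm = 200, seed = 1))
  expect_true(all(res$condition_p == 1))
  expect_true(all(res$interaction_p == 1))
  expect_error(suppressWarnings(
    condition_interaction_test(M, M[1:7, ], cov, n_perm = 100)),
    class = "rc_error_pairing")
})

test_that("a common condition offset is detected without a spurious interaction", {
  cov <- mk_cov(8, 8, seed = 2)
  n_rep <- 10
  cond_p <- int_p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    withr::with_seed(140 + r, {
      outside <- matrix(rnorm(16), 16, 1)
      inside <- outside + 1.5 + matrix(rnorm(16, sd = 0.5), 16, 1)
    })
    res <- suppressWarnings(
      condition_interaction_test(inside, outside, cov, n_perm = 300,
                                 seed = r))
    cond_p[r] <- res$condition_p
    int_p[r] <- res$interaction_p
  }
  expect_gte(mean(cond_p < 0.05), 0.9)       # main effect found
  expect_lte(mean(int_p < 0.05), 0.3)        # no planted interaction
})

test_that("a group-dependent condition offset shows up as an interaction", {
  cov <- mk_cov(8, 8, seed = 3)
  grp <- as.numeric(cov$group == "patient")
  hits <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    withr::with_seed(150 + r, {
      outside <- matrix(rnorm(16), 16, 1)
      inside <- outside + 2 * grp + matrix(rnorm(16, sd = 0.5), 16, 1)
    })
    res <- suppressWarnings(
      condition_interaction_test(inside, outside, cov, n_perm = 300,
                                 seed = r))
    hits <- hits + (res$interaction_p < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})
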