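# Forward model: sensors x vertices gain matrix. The spherical option solves
# the concentric three-shell conductor (scalp/skull/brain) analytically by
# expanding the radial-dipole potential in Legendre polynomials and matching
# potential and radial current at each shell boundary; the per-harmonic
# boundary conditions form a small linear system solved exactly.

# Solve the shell-matching system for harmonic n with unit dipole factor
# (radii normalised to the scalp radius). Returns the scalp-surface potential
# coefficient c_n such that phi(scalp) = sum_n c_n b^(n-1) P_n(cos gamma).
.shell_coef <- function(n, r, sig) {
  # unknowns: A1, A2, B2, A3, B3 (phi_j = A_j r^n + B_j r^-(n+1); shell 1 adds
  # the primary dipole term K n b^(n-1) r^-(n+1) with K folded out)
  r1 <- r[1]; r2 <- r[2]; r3 <- r[3]
  A <- matrix(0, 5, 5)
  rhs <- numeric(5)
  # potential continuity at r1
  A[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
  rhs[1] <- -n * r1^(-(n + 1))
  # radial current continuity at r1
  A[2, ] <- c(sig[1] * n * r1^(n - 1), -sig[2] * n * r1^(n - 1),
              sig[2] * (n + 1) * r1^(-(n + 2)), 0, 0)
  rhs[2] <- sig[1] * n * (n + 1) * r1^(-(n + 2))
  # potential continuity at r2
  A[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
  # radial current continuity at r2
  A[4, ] <- c(0, sig[2] * n * r2^(n - 1), -sig[2] * (n + 1) * r2^(-(n + 2)),
              -sig[3] * n * r2^(n - 1), sig[3] * (n + 1) * r2^(-(n + 2)))
  # no current through the scalp surface
  A[5, ] <- c(0, 0, 0, n * r3^(n - 1), -(n + 1) * r3^(-(n + 2)))
  x <- solve(A, rhs)
  x[4] * r3^n + x[5] * r3^(-(n + 1))
}

# EEG-cap-like sensor layout: Fibonacci spiral over the upper scalp cap.
.sensor_positions <- function(n_sensors, scalp_radius) {
  i <- seq_len(n_sensors)
  z <- seq(0.95, -0.25, length.out = n_sensors)
  phi <- (i - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  scalp_radius * cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Build a leadfield for a source space
#'
#' `model = "spherical3shell"` computes an analytic concentric three-shell
#' (brain/skull/scalp) forward solution with conductivities 0.33, 0.004 and
#' 0.33 S/m, radial source orientation and one gain column per vertex.
#' `model = "random"` draws an i.i.d. Gaussian gain (useful for algebraic
#' tests). Units are microvolts at the scalp per unit source amplitude
#' (a 20 nA m dipole moment defines the unit).
#'
#' @param space a [build_source_space()] result.
#' @param n_sensors number of scalp electrodes (>= 4); default 64.
#' @param model `"spherical3shell"` or `"random"`.
#' @param seed integer seed (used by the random model; kept in metadata).
#' @param shell_radii_mm brain/skull/scalp shell radii in mm.
#' @param conductivities shell conductivities in S/m (brain, skull, scalp).
#' @param n_terms number of Legendre terms in the series expansion.
#' @return A `leadfield` object with fields `gain` (sensors x vertices),
#'   `sensor_labels`, `sensor_coords`, `model_meta`.
#' @export
build_leadfield <- function(space, n_sensors = 64,
                            model = c("spherical3shell", "random"), seed = 1,
                            shell_radii_mm = c(80, 86, 92),
                            conductivities = c(0.33, 0.004, 0.33),
                            n_terms = 60) {
  model <- match.arg(model)
  rc_assert(n_sensors >= 4, "need at least 4 sensors", "invalid_design")
  V <- n_vertices(space)
  labels <- sprintf("E%03d", seq_len(n_sensors))
  if (model == "random") {
    gain <- with_rc_seed(seed, matrix(rnorm(n_sensors * V), n_sensors, V))
    dimnames(gain) <- list(labels, NULL)
    return(structure(list(
      gain = gain, sensor_labels = labels,
      sensor_coords = .sensor_positions(n_sensors, max(shell_radii_mm)),
      model_meta = list(model = "random", seed = as.integer(seed))
    ), class = "leadfield"))
  }
  rc_assert(length(shell_radii_mm) == 3 && all(diff(shell_radii_mm) > 0),
            "shell radii must be three increasing values", "geometry")
  r_scalp <- shell_radii_mm[3]
  rad <- sqrt(rowSums(space$coords^2))
  if (any(rad >= shell_radii_mm[1])) {
    rc_abort(sprintf(
      "%d vertex/vertices lie outside the innermost (brain) shell of the spherical model",
      sum(rad >= shell_radii_mm[1])), "geometry")
  }
  r_norm <- shell_radii_mm / r_scalp
  b <- rad / r_scalp
  vunit <- space$coords / rad
  sens <- .sensor_positions(n_sensors, r_scalp)
  sunit <- sens / sqrt(rowSums(sens^2))
  cosg <- sunit %*% t(vunit)                       # sensors x vertices

  # overall physical scale: 20 nA*m dipole, potentials in microvolts
  K <- 2e-8 / (4 * pi * conductivities[1] * (r_scalp / 1000)^2) * 1e6

  gain <- matrix(0, n_sensors, V)
  P_prev <- matrix(1, n_sensors, V)   # P_0
  P_cur <- cosg                       # P_1
  b_pow <- rep(1, V)                  # b^(n-1)
  for (n in seq_len(n_terms)) {
    cn <- .shell_coef(n, r_norm, conductivities)
    gain <- gain + (P_cur * rep(cn * b_pow, each = n_sensors))
    b_pow <- b_pow * b
    P_next <- ((2 * n + 1) * cosg * P_cur - n * P_prev) / (n + 1)
    P_prev <- P_cur
    P_cur <- P_next
  }
  gain <- K * gain
  dimnames(gain) <- list(labels, NULL)
  structure(list(
    gain = gain, sensor_labels = labels, sensor_coords = sens,
    model_meta = list(model = "spherical3shell",
                      shell_radii_mm = shell_radii_mm,
                      conductivities = conductivities,
                      n_terms = n_terms, seed = as.integer(seed))
  ), class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d vertices (%s model)\n",
              nrow(x$gain), ncol(x$gain), x$model_meta$model))
  invisible(x)
}
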