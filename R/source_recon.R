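# Band-wise cross-spectral density estimation and DICS beamformer source
# reconstruction.

#' Complex cross-spectral density matrix
#'
#' @param matrix complex Hermitian matrix (sensor or vertex space).
#' @param band a [band_spec()] or band name.
#' @param n_trials_used number of trials averaged.
#' @param space_tag `"sensor"` or `"source"`.
#' @param meta metadata list.
#' @return A `cross_spectrum` object.
#' @export
cross_spectrum <- function(matrix, band, n_trials_used = NA_integer_,
                           space_tag = c("sensor", "source"), meta = list()) {
  space_tag <- match.arg(space_tag)
  band <- as_band(band)
  rc_assert(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
            "CSD must be a square matrix")
  herm <- max(abs(matrix - Conj(t(matrix)))) /
    max(max(abs(matrix)), .Machine$double.eps)
  rc_assert(herm < 1e-10, "CSD must be Hermitian within 1e-10 relative")
  d <- Re(diag(matrix))
  rc_assert(all(d >= -1e-12 * max(d, 0) - 1e-300),
            "CSD diagonal must be real and non-negative")
  structure(list(matrix = matrix, band = band,
                 n_trials_used = as.integer(n_trials_used),
                 space_tag = space_tag, meta = meta),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d x %d (%s space), band %s, %d trials\n",
              nrow(x$matrix), ncol(x$matrix), x$space_tag, x$band$name,
              x$n_trials_used))
  invisible(x)
}

#' Estimate a band cross-spectral density from trials
#'
#' Each accepted trial is Hann-tapered and Fourier transformed; the CSD is
#' the average of the coefficient outer products over all trials and all
#' frequency bins inside the band (band-level CSD). The scaling is one-sided
#' spectral density (per Hz), so the band-integrated diagonal approximates
#' the band-filtered time-domain variance.
#'
#' @param ts a `trial_set` with at least 2 accepted trials.
#' @param band a [band_spec()] or default band name.
#' @return A sensor-space `cross_spectrum`.
#' @export
estimate_csd <- function(ts, band) {
  band <- as_band(band)
  acc <- accepted_trials(ts)
  rc_assert(length(acc) >= 2, "need at least 2 accepted trials")
  rate <- ts$rate
  len <- dim(ts$trials)[3]
  rc_assert(band$f_hi <= rate / 2, "band edge above Nyquist")
  freq <- (seq_len(len) - 1) * rate / len
  bins <- which(freq > 0 & freq >= band$f_lo & freq <= band$f_hi &
                  freq <= rate / 2)
  if (length(bins) == 0)
    rc_abort(sprintf(
      "band %s holds no frequency bins at %g s trials (resolution %g Hz)",
      band$name, len / rate, rate / len), "resolution")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / len)   # Hann
  scale <- 2 / (rate * sum(w^2))                            # one-sided PSD
  S <- dim(ts$trials)[2]
  acc_sum <- matrix(0 + 0i, S, S)
  for (j in acc) {
    tr <- matrix(ts$trials[j, , ], nrow = S)                # robust to S = 1
    X <- stats::mvfft(t(tr) * w)                            # len x channels
    Xb <- X[bins, , drop = FALSE]
    acc_sum <- acc_sum + t(Xb) %*% Conj(Xb)
  }
  csd <- acc_sum * scale / (length(acc) * length(bins))
  csd <- (csd + Conj(t(csd))) / 2
  cross_spectrum(csd, band, n_trials_used = length(acc), space_tag = "sensor",
                 meta = list(n_bins = length(bins), rate = rate,
                             channel_labels = ts$channel_labels))
}

#' Spatial filter set of a DICS beamformer
#'
#' @param weights vertices x sensors matrix.
#' @param band band of the CSD the filters were computed from.
#' @param lambda_fraction regularization fraction used.
#' @param meta metadata list.
#' @return A `spatial_filter_set` object.
#' @export
spatial_filter_set <- function(weights, band, lambda_fraction, meta = list()) {
  structure(list(weights = weights, band = as_band(band),
                 lambda_fraction = lambda_fraction, meta = meta),
            class = "spatial_filter_set")
}

#' Compute DICS beamformer spatial filters
#'
#' For each vertex v with leadfield column l_v, the unit-gain filter is
#' w_v = (C_r^-1 l_v) / (l_v' C_r^-1 l_v), where C_r is the real part of the
#' sensor CSD regularized by lambda times the mean sensor power:
#' C_r = Re(C) + lambda * (trace(Re(C)) / n_sensors) * I. The default
#' lambda of 5% follows the common DICS convention.
#'
#' @param csd sensor-space `cross_spectrum`.
#' @param lf a `leadfield` with matching sensor count.
#' @param lambda_fraction regularization fraction (default 0.05).
#' @return A `spatial_filter_set` (vertices x sensors weights).
#' @export
dics_filters <- function(csd, lf, lambda_fraction = 0.05) {
  rc_assert(inherits(csd, "cross_spectrum") && csd$space_tag == "sensor",
            "csd must be a sensor-space cross_spectrum")
  S <- nrow(csd$matrix)
  rc_assert(S == nrow(lf$gain), "sensor counts of CSD and leadfield differ")
  Cr <- Re(csd$matrix)
  Cr <- Cr + lambda_fraction * (sum(diag(Cr)) / S) * diag(S)
  Ci <- tryCatch(solve(Cr), error = function(e)
    rc_abort("regularized sensor CSD is numerically singular", "conditioning"))
  if (!all(is.finite(Ci)))
    rc_abort("regularized sensor CSD is numerically singular", "conditioning")
  Wt <- Ci %*% lf$gain                       # sensors x vertices
  denom <- colSums(lf$gain * Wt)             # l_v' C^-1 l_v per vertex
  if (any(abs(denom) < .Machine$double.eps))
    rc_abort("beamformer denominator vanished at some vertex", "conditioning")
  W <- t(Wt) / denom                         # vertices x sensors
  spatial_filter_set(W, csd$band, lambda_fraction,
                     meta = list(n_sensors = S))
}

#' Source power map
#'
#' power(v) = Re(w_v C w_v^H) for each vertex filter.
#'
#' @param filters a `spatial_filter_set`.
#' @param csd the sensor-space `cross_spectrum` (same band).
#' @return A `vertex_map` of kind `"power"`.
#' @export
source_power_map <- function(filters, csd) {
  rc_assert(identical(filters$band$name, csd$band$name),
            "band tags of filters and CSD differ", "pipeline")
  rc_assert(ncol(filters$weights) == nrow(csd$matrix),
            "sensor dimensions differ", "pipeline")
  WC <- filters$weights %*% csd$matrix
  p <- Re(rowSums(WC * Conj(filters$weights)))
  p[abs(p) < .Machine$double.eps * max(abs(p), 1)] <- 0
  vertex_map(pmax(p, 0), "power", band = csd$band$name)
}

#' Source-level cross-spectral density
#'
#' Projects the sensor CSD through the beamformer filters:
#' S_src = W C W^H, a vertices x vertices complex Hermitian matrix whose
#' diagonal equals the source power map.
#'
#' @param filters a `spatial_filter_set`.
#' @param csd the sensor-space `cross_spectrum` (same band).
#' @param max_vertices guard against accidental huge dense outputs.
#' @return A source-space `cross_spectrum`.
#' @export
source_cross_spectrum <- function(filters, csd, max_vertices = 3000) {
  rc_assert(identical(filters$band$name, csd$band$name),
            "band tags of filters and CSD differ", "pipeline")
  V <- nrow(filters$weights)
  if (V > max_vertices)
    rc_abort(sprintf(
      "source CSD would be %d x %d; downsample the source space or raise max_vertices",
      V, V), "memory")
  W <- filters$weights
  Ssrc <- (W %*% csd$matrix) %*% Conj(t(W))
  Ssrc <- (Ssrc + Conj(t(Ssrc))) / 2
  d <- Re(diag(Ssrc))
  diag(Ssrc) <- pmax(d, 0)
  cross_spectrum(Ssrc, csd$band, csd$n_trials_used, space_tag = "source",
                 meta = list(lambda_fraction = filters$lambda_fraction))
}
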