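# Functional connectivity from source cross-spectra: absolute imaginary
# coherency, node strength, global averages, condition differences and
# seed-based maps.

#' Vertex connectivity matrix (|ImCoh|)
#'
#' @param values symmetric vertices x vertices matrix in `[0, 1]` with zero
#'   diagonal.
#' @param band band name.
#' @param condition optional condition tag.
#' @param subject_id optional subject identifier.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, band = NULL, condition = NULL,
                                subject_id = NULL) {
  rc_assert(is.matrix(values) && nrow(values) == ncol(values),
            "connectivity must be a square matrix")
  rc_assert(max(abs(values - t(values))) < 1e-10, "connectivity must be symmetric")
  rc_assert(all(diag(values) == 0), "connectivity diagonal must be zero")
  rc_assert(all(values >= 0 & values <= 1 + 1e-12),
            "connectivity entries must lie in [0, 1]")
  structure(list(values = values, band = band, condition = condition,
                 subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<connectivity_matrix> %d vertices, band %s, mean |ImCoh| %.4f\n",
              nrow(x$values), x$band %||% "-", mean(off)))
  invisible(x)
}

#' Absolute imaginary coherency from a source CSD
#'
#' Coherency is the normalized cross-spectrum S_xy / sqrt(S_xx S_yy); the
#' connectivity value is |Im(coherency)|, which is zero for any zero-lag
#' (volume-conduction-like) mixing and reaches 1 for a pure quarter-cycle
#' phase lag. The diagonal is forced to zero.
#'
#' @param s a source-space `cross_spectrum` with strictly positive diagonal.
#' @return A `connectivity_matrix`.
#' @export
imcoh_from_csd <- function(s) {
  rc_assert(inherits(s, "cross_spectrum") && s$space_tag == "source",
            "s must be a source-space cross_spectrum")
  d <- Re(diag(s$matrix))
  bad <- which(d <= 0)
  if (length(bad) > 0)
    rc_abort(paste0("zero power at vertex/vertices ",
                    paste(head(bad, 5), collapse = ", "),
                    if (length(bad) > 5) ", ..."), "degenerate_power")
  denom <- sqrt(d) %o% sqrt(d)
  ic <- abs(Im(s$matrix / denom))
  ic <- pmin(ic, 1)
  ic <- (ic + t(ic)) / 2
  diag(ic) <- 0
  connectivity_matrix(ic, band = s$band$name)
}

#' Node strength map
#'
#' value(v) = mean connectivity of vertex v to all other vertices.
#'
#' @param c a `connectivity_matrix`.
#' @return A `vertex_map` of kind `"node_strength"`.
#' @export
node_strength_map <- function(c) {
  rc_assert(inherits(c, "connectivity_matrix"),
            "input must be a connectivity_matrix")
  V <- nrow(c$values)
  vertex_map(rowSums(c$values) / (V - 1), "node_strength", band = c$band,
             condition = c$condition)
}

#' Global average of a vertex map
#'
#' @param m a `vertex_map` (or bare numeric vector).
#' @return Arithmetic mean over all vertices.
#' @export
global_average <- function(m) {
  v <- map_values(m)
  rc_assert(all(is.finite(v)), "map must be finite")
  mean(v)
}

#' Relative difference between conditions (percent)
#'
#' 100 * (inside - outside) / outside, the Delta-percent convention for
#' comparing a group-mean metric between measurement conditions.
#'
#' @param inside_mean inside-condition group mean.
#' @param outside_mean outside-condition group mean (non-zero).
#' @return Percent difference (signed).
#' @export
relative_difference <- function(inside_mean, outside_mean) {
  if (abs(outside_mean) < .Machine$double.eps)
    rc_abort("outside-condition baseline is zero", "undefined_baseline")
  100 * (inside_mean - outside_mean) / outside_mean
}

#' Seed-based EEG connectivity map
#'
#' value(v) = mean |ImCoh| between vertex v and the seed-region vertices
#' (links, not a seed-averaged time course). For vertices inside the seed
#' region only links to *other* seed vertices are averaged; these vertices
#' are flagged in the metadata.
#'
#' @param c a `connectivity_matrix`.
#' @param space the aligned `source_space`.
#' @param seed_region region label of the seed.
#' @return A `vertex_map` of kind `"seed_fc"`.
#' @export
seed_fc_eeg <- function(c, space, seed_region) {
  sv <- region_vertices(space, seed_region)
  V <- nrow(c$values)
  rc_assert(V == n_vertices(space), "matrix and space sizes differ")
  sub <- c$values[sv, , drop = FALSE]              # seeds x V
  val <- colSums(sub) / length(sv)
  if (length(sv) > 1) {
    # inside the seed: exclude the (zero) self link from the average
    val[sv] <- (colSums(sub)[sv]) / (length(sv) - 1)
  }
  vertex_map(val, "seed_fc", band = c$band, condition = c$condition,
             space_id = space$space_id,
             meta = list(seed_region = seed_region, seed_vertices = sv))
}
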