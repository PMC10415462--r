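# Synthetic source space: a triangulated sphere-like cortical sheet plus
# interior subcortical vertex clusters, with contiguous atlas-style regions.

CORTICAL_RADIUS_MM <- 70

# Canonical anchor directions for the named cortical regions used as seeds
# downstream (medial prefrontal, lateral-parietal DMN, precuneus/PCC,
# intracalcarine). Remaining regions are placed by farthest-point sampling.
.canonical_cortical_anchors <- function() {
  rbind(
    mpfc             = c( 0.00,  0.92,  0.40),
    dmn_lp_l         = c(-0.85, -0.35,  0.40),
    dmn_lp_r         = c( 0.85, -0.35,  0.40),
    precuneus_pcc    = c( 0.00, -0.75,  0.66),
    intracalcarine_l = c(-0.18, -0.97, -0.15),
    intracalcarine_r = c( 0.18, -0.97, -0.15)
  )
}

.subcortical_nuclei <- function() {
  base <- c("thalamus", "hippocampus", "amygdala", "caudate", "putamen",
            "pallidum")
  centers <- list(
    thalamus    = c(0.15, -0.10,  0.12),
    hippocampus = c(0.35, -0.25, -0.15),
    amygdala    = c(0.30,  0.05, -0.18),
    caudate     = c(0.17,  0.10,  0.15),
    putamen     = c(0.33,  0.05,  0.02),
    pallidum    = c(0.25,  0.00,  0.00)
  )
  list(names = base, centers = centers)
}

# Distribute `total` items over weights deterministically (largest remainder).
.apportion <- function(weights, total) {
  w <- weights / sum(weights)
  base <- floor(w * total)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- w * total - base
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  # every bin gets at least one item, stolen from the largest bins
  while (any(base == 0) && any(base > 1)) {
    base[which.max(base)] <- max(base) - 1
    base[which(base == 0)[1]] <- 1
  }
  base
}

# Stitch two latitude rings (vertex index vectors, ordered by longitude) into
# a triangle strip; works for arbitrary ring sizes.
.zipper <- function(idx_a, idx_b) {
  p <- length(idx_a); q <- length(idx_b)
  tri <- matrix(0L, nrow = p + q, ncol = 3)
  i <- 0L; j <- 0L; k <- 1L
  while (i < p || j < q) {
    adv_a <- if (i >= p) FALSE else if (j >= q) TRUE else
      (i + 1) * q <= (j + 1) * p
    a0 <- idx_a[(i %% p) + 1L]; b0 <- idx_b[(j %% q) + 1L]
    if (adv_a) {
      a1 <- idx_a[((i + 1L) %% p) + 1L]
      tri[k, ] <- c(a0, b0, a1); i <- i + 1L
    } else {
      b1 <- idx_b[((j + 1L) %% q) + 1L]
      tri[k, ] <- c(a0, b0, b1); j <- j + 1L
    }
    k <- k + 1L
  }
  tri[seq_len(k - 1L), , drop = FALSE]
}

.edges_from_triangles <- function(tri) {
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e[e[, 1] != e[, 2], , drop = FALSE])
}

# Multi-source breadth-first region growing over an adjacency list; returns an
# integer label per vertex. Deterministic: frontier processed in sorted order.
.grow_regions <- function(nbr, seeds, n_vertices) {
  lab <- rep(NA_integer_, n_vertices)
  lab[seeds] <- seq_along(seeds)
  frontier <- seeds
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in sort(frontier)) {
      for (u in nbr[[v]]) {
        if (is.na(lab[u])) {
          lab[u] <- lab[v]
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  # orphans (disconnected) inherit the label of the nearest labelled vertex
  if (anyNA(lab)) lab[is.na(lab)] <- 1L
  lab
}

#' Build a synthetic source space
#'
#' Constructs a triangulated sphere-like cortical mesh (two poles plus
#' latitude rings stitched into triangle strips) and, optionally, interior
#' subcortical vertex clusters emulating bilateral nuclei (thalamus,
#' hippocampus, amygdala, caudate, putamen, pallidum). Cortical vertices are
#' partitioned into contiguous regions grown from anchor points; the first
#' regions carry the canonical seed labels (`mpfc`, `dmn_lp_l/r`,
#' `precuneus_pcc`, `intracalcarine_l/r`), each subcortical cluster is its own
#' region (`thalamus_l`, ...). At study scale this gives 2004 + 334 = 2338
#' vertices; the package's fixture default is 260 + 42 = 302.
#'
#' @param n_cortical number of cortical vertices (>= 4).
#' @param n_subcortical number of subcortical vertices (>= 0).
#' @param n_regions number of cortical regions (>= 2, <= n_cortical).
#' @param seed integer seed; the structure is a pure function of the
#'   arguments and this seed.
#' @return A `source_space` object with fields `coords` (vertices x 3, mm),
#'   `triangles` (cortical triangle index triples), `adjacency` (2-column
#'   edge matrix over all vertices), `region_label`, `is_subcortical`,
#'   `hemisphere`.
#' @export
build_source_space <- function(n_cortical = 260, n_subcortical = 42,
                               n_regions = 10, seed = 1) {
  rc_assert(n_cortical >= 4, "n_cortical must be >= 4", "invalid_design")
  rc_assert(n_regions >= 2 && n_cortical >= n_regions,
            "need n_cortical >= n_regions >= 2", "invalid_design")
  rc_assert(n_subcortical >= 0, "n_subcortical must be >= 0", "invalid_design")
  with_rc_seed(seed, {
    R <- CORTICAL_RADIUS_MM
    interior <- n_cortical - 2L
    nring <- max(1L, round(sqrt(interior)))
    theta <- pi * seq_len(nring) / (nring + 1)
    counts <- .apportion(sin(theta), interior)
    coords <- matrix(0, nrow = n_cortical, ncol = 3)
    coords[1, ] <- c(0, 0, R)
    ring_idx <- vector("list", nring)
    v <- 1L
    for (i in seq_len(nring)) {
      ci <- counts[i]
      phi <- 2 * pi * (seq_len(ci) - 1) / ci + 0.618 * i  # per-ring twist
      idx <- v + seq_len(ci)
      jit <- 1 + runif(ci, -0.02, 0.02)   # mild radial irregularity
      coords[idx, ] <- cbind(R * jit * sin(theta[i]) * cos(phi),
                             R * jit * sin(theta[i]) * sin(phi),
                             R * jit * cos(theta[i]))
      ring_idx[[i]] <- idx
      v <- v + ci
    }
    coords[n_cortical, ] <- c(0, 0, -R)

    tris <- list()
    r1 <- ring_idx[[1]]
    tris[[1]] <- cbind(1L, r1, c(r1[-1], r1[1]))
    if (nring > 1) {
      for (i in seq_len(nring - 1))
        tris[[length(tris) + 1]] <- .zipper(ring_idx[[i]], ring_idx[[i + 1]])
    }
    rl <- ring_idx[[nring]]
    tris[[length(tris) + 1]] <- cbind(n_cortical, rl, c(rl[-1], rl[1]))
    triangles <- do.call(rbind, tris)
    storage.mode(triangles) <- "integer"
    edges <- .edges_from_triangles(triangles)

    # subcortical clusters
    sub_label <- character(0)
    if (n_subcortical > 0) {
      k_clust <- min(12L, max(2L, 2L * (n_subcortical %/% 6L)))
      nuc <- .subcortical_nuclei()
      k_nuc <- k_clust %/% 2L
      cl_names <- as.vector(t(outer(nuc$names[seq_len(k_nuc)], c("l", "r"),
                                    paste, sep = "_")))
      sizes <- .apportion(rep(1, k_clust), n_subcortical)
      sub_coords <- matrix(0, n_subcortical, 3)
      sub_label <- character(n_subcortical)
      at <- 0L
      for (ci in seq_len(k_clust)) {
        nm <- cl_names[ci]
        nucleus <- sub("_(l|r)$", "", nm)
        side <- if (grepl("_l$", nm)) -1 else 1
        ctr <- nuc$centers[[nucleus]] * R
        ctr[1] <- side * ctr[1]
        sz <- sizes[ci]
        pts <- matrix(rnorm(3 * sz, sd = 3), ncol = 3)
        pts <- sweep(pts, 2, ctr, `+`)
        sub_coords[at + seq_len(sz), ] <- pts
        sub_label[at + seq_len(sz)] <- nm
        at <- at + sz
      }
      coords <- rbind(coords, sub_coords)
      # within-cluster k-nearest-neighbour adjacency (k = 6 capped by size)
      sub_edges <- list()
      for (nm in unique(sub_label)) {
        vi <- n_cortical + which(sub_label == nm)
        if (length(vi) == 1) {
          # degenerate cluster: connect to the nearest other vertex
          d <- rowSums((coords - matrix(coords[vi, ], nrow(coords), 3,
                                        byrow = TRUE))^2)
          d[vi] <- Inf
          sub_edges[[length(sub_edges) + 1]] <- cbind(vi, which.min(d))
          next
        }
        d <- as.matrix(stats::dist(coords[vi, , drop = FALSE]))
        k <- min(6L, length(vi) - 1L)
        for (a in seq_along(vi)) {
          ord <- order(d[a, ])[2:(k + 1)]
          sub_edges[[length(sub_edges) + 1]] <- cbind(vi[a], vi[ord])
        }
      }
      se <- do.call(rbind, sub_edges)
      se <- cbind(pmin(se[, 1], se[, 2]), pmax(se[, 1], se[, 2]))
      edges <- unique(rbind(edges, se))
    }

    n_total <- n_cortical + n_subcortical
    nbr <- adjacency_list(edges, n_cortical)

    # contiguous cortical regions grown from anchors
    canon <- .canonical_cortical_anchors()
    n_named <- min(nrow(canon), n_regions)
    unit <- coords[seq_len(n_cortical), ] /
      sqrt(rowSums(coords[seq_len(n_cortical), ]^2))
    anchors <- integer(n_regions)
    for (i in seq_len(n_named))
      anchors[i] <- which.max(unit %*% canon[i, ])
    if (n_regions > n_named) {
      for (i in (n_named + 1):n_regions) {
        d <- rep(Inf, n_cortical)
        for (a in anchors[seq_len(i - 1)])
          d <- pmin(d, rowSums((unit - matrix(unit[a, ], n_cortical, 3,
                                              byrow = TRUE))^2))
        anchors[i] <- which.max(d)
      }
    }
    reg_names <- c(rownames(canon)[seq_len(n_named)],
                   if (n_regions > n_named)
                     sprintf("cortex_%02d", seq_len(n_regions - n_named)))
    lab_int <- .grow_regions(nbr, anchors, n_cortical)
    region_label <- c(reg_names[lab_int], sub_label)

    structure(list(
      coords = coords,
      triangles = triangles,
      adjacency = edges,
      region_label = region_label,
      is_subcortical = c(rep(FALSE, n_cortical), rep(TRUE, n_subcortical)),
      hemisphere = ifelse(coords[, 1] < 0, "l", "r"),
      n_cortical = as.integer(n_cortical),
      n_subcortical = as.integer(n_subcortical),
      space_id = sprintf("space_c%d_s%d_r%d_seed%d", n_cortical,
                         n_subcortical, n_regions, as.integer(seed)),
      seed = as.integer(seed)
    ), class = "source_space")
  })
}

#' Number of vertices of a source space
#' @param space a `source_space`.
#' @return integer vertex count.
#' @export
n_vertices <- function(space) nrow(space$coords)

#' Neighbour list from an edge matrix
#'
#' @param edges 2-column integer edge matrix (symmetric, no self-edges).
#' @param n number of vertices.
#' @return list of integer neighbour vectors, one per vertex.
#' @export
adjacency_list <- function(edges, n) {
  if (inherits(edges, "source_space")) {
    n <- n_vertices(edges); edges <- edges$adjacency
  }
  nbr <- vector("list", n)
  both <- rbind(edges, edges[, 2:1, drop = FALSE])
  sp <- split(both[, 2], both[, 1])
  for (nm in names(sp))
    nbr[[as.integer(nm)]] <- sort(unique(as.integer(sp[[nm]])))
  for (i in seq_len(n)) if (is.null(nbr[[i]])) nbr[[i]] <- integer(0)
  nbr
}

#' Vertex indices of a region
#' @param space a `source_space`.
#' @param region region label (string) or vector of labels.
#' @return integer vertex indices.
#' @export
region_vertices <- function(space, region) {
  rc_assert(all(region %in% space$region_label),
            paste0("unknown region label(s): ",
                   paste(setdiff(region, space$region_label), collapse = ", ")),
            "label")
  which(space$region_label %in% region)
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf(
    "<source_space> %d vertices (%d cortical + %d subcortical), %d triangles, %d regions\n",
    n_vertices(x), x$n_cortical, x$n_subcortical, nrow(x$triangles),
    length(unique(x$region_label))))
  invisible(x)
}
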