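# Independent oracles used across test files. These deliberately use naive
# algorithms (union-find, O(N^2) scans, quadrature) so they share no code
# with the implementation they check.

# Union-find connected components over an edge list (data frame i, j).
# Returns a list of sorted integer vectors, ordered by size desc then
# smallest member.
uf_components <- function(edges) {
  nodes <- sort(unique(c(edges$i, edges$j)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) {
      parent[[as.character(x)]] <<- parent[[as.character(parent[[as.character(x)]])]]
      x <- parent[[as.character(x)]]
    }
    x
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri != rj) parent[[as.character(ri)]] <- rj
  }
  roots <- vapply(nodes, find, numeric(1))
  comps <- unname(split(nodes, roots))
  comps <- lapply(comps, sort)
  comps[order(-vapply(comps, length, integer(1)),
              vapply(comps, min, numeric(1)))]
}

# Kolmogorov-Smirnov distance between samples and a tabulated density
# (trapezoid CDF on the table's grid).
ks_distance_to_density <- function(samples, density_table) {
  x <- density_table$x; p <- density_table$density
  cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * diff(x)))
  cdf <- cdf / cdf[length(cdf)]
  ecdf_fun <- stats::ecdf(samples)
  max(abs(ecdf_fun(x) - cdf))
}

# Small trajectory ensemble from an explicit list of frame matrices.
ensemble_from_frames <- function(frames, ...) {
  n <- nrow(frames[[1]]); d <- ncol(frames[[1]])
  arr <- array(NA_real_, c(length(frames), n, d))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  trajectory_ensemble(list(arr), ...)
}

# Random rigid transform (rotation + translation) applied to an n x 3 matrix.
apply_random_rigid <- function(X, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_ <- rnorm(3)
  sweep(X %*% R, 2, t_, "+")
}

# Shared mid-size planted-pathway fixture (built once per test run; used by
# force-network unit tests). Kept smaller than the pipeline defaults.
planted_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- make_helix_chain(16, bond_k = 2000, network_k = 1000)
      cache <<- make_condition_pair(sys, c(4, 9, 14), delta_k = 150,
                                    n_steps = 8000, dt = 2e-4,
                                    n_replicates = 2, seed = 42,
                                    stride = 10, rest_scale = 0.5)
    }
    cache
  }
})
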