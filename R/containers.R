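#' Multi-replicate coordinate trajectory ensemble
#'
#' The substrate of all dynamics metrics: a list of frame-major coordinate
#' arrays (one per replicate), each `n_frames x n_particles x dim` in nm,
#' with 1-based residue labels per particle and a condition label.
#'
#' @param replicates List of numeric arrays `frames x particles x dim`.
#' @param frame_interval Time between stored frames (ps, > 0).
#' @param condition_label Free-text condition name (e.g. `"whole+Myr"`).
#' @param residue_index Integer residue label per particle.
#' @return An object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(replicates, frame_interval = 1,
                                condition_label = "", residue_index = NULL) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  replicates <- lapply(replicates, function(r) {
    if (length(dim(r)) != 3) stop("each replicate must be a 3-D array")
    r
  })
  n <- dim(replicates[[1]])[2]
  d <- dim(replicates[[1]])[3]
  for (r in replicates) {
    if (dim(r)[2] != n || dim(r)[3] != d)
      stop("all replicates must share particle count and dimensionality")
    if (!all(is.finite(r))) stop("coordinates must be finite")
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (is.null(residue_index)) residue_index <- seq_len(n)
  stopifnot(length(residue_index) == n)
  structure(list(replicates = replicates, frame_interval = frame_interval,
                 condition_label = condition_label,
                 residue_index = as.integer(residue_index),
                 n_particles = n, dim = d),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  nf <- vapply(x$replicates, function(r) dim(r)[1], integer(1))
  cat(sprintf(
    "TrajectoryEnsemble '%s': %d replicate(s), %s frames, %d particles (%d-D)\n",
    x$condition_label, length(x$replicates),
    paste(nf, collapse = "+"), x$n_particles, x$dim))
  invisible(x)
}

#' Number of frames per replicate
#' @param ensemble A `TrajectoryEnsemble`.
#' @return Integer vector of frame counts.
#' @export
n_frames <- function(ensemble) {
  vapply(ensemble$replicates, function(r) dim(r)[1], integer(1))
}

#' Per-frame signed scalar pair-force series
#'
#' One signed scalar per unordered particle pair per frame (pN; positive =
#' repulsive along the inter-particle axis), with replicate boundaries
#' recorded so averages can be formed over concatenated replicates.
#'
#' @param forces_pN Numeric matrix, frames x pairs, pN.
#' @param pairs Data frame with columns `i`, `j` (1-based particle indices,
#'   `i < j`), one row per column of `forces_pN`.
#' @param replicate Integer replicate id per frame.
#' @param condition_label Condition name.
#' @param residue_index Residue label per particle (maps particle pairs to
#'   residue pairs when aggregating).
#' @return An object of class `PairForceSeries`.
#' @export
pair_force_series <- function(forces_pN, pairs, replicate = NULL,
                              condition_label = "", residue_index = NULL) {
  forces_pN <- as.matrix(forces_pN)
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(forces_pN) == nrow(pairs), all(pairs$i < pairs$j))
  if (!all(is.finite(forces_pN))) stop("forces must be finite")
  if (is.null(replicate)) replicate <- rep(1L, nrow(forces_pN))
  stopifnot(length(replicate) == nrow(forces_pN))
  if (is.null(residue_index))
    residue_index <- seq_len(max(pairs$j, 1))
  structure(list(forces_pN = forces_pN,
                 pairs = pairs[, c("i", "j"), drop = FALSE],
                 replicate = as.integer(replicate),
                 condition_label = condition_label,
                 residue_index = as.integer(residue_index)),
            class = "PairForceSeries")
}

#' @export
print.PairForceSeries <- function(x, ...) {
  cat(sprintf("PairForceSeries '%s': %d frames (%d replicate(s)), %d pairs\n",
              x$condition_label, nrow(x$forces_pN),
              length(unique(x$replicate)), nrow(x$pairs)))
  invisible(x)
}

#' Concatenate force series from replicates of the same system
#'
#' @param series_list List of `PairForceSeries` over identical pair sets.
#' @return A single `PairForceSeries` with renumbered replicate ids.
#' @export
concat_force_series <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  ref <- series_list[[1]]
  for (s in series_list) {
    if (!identical(s$pairs, ref$pairs))
      stop("force series must share the same pair set")
  }
  forces <- do.call(rbind, lapply(series_list, `[[`, "forces_pN"))
  reps <- unlist(lapply(seq_along(series_list), function(k) {
    rep(k, nrow(series_list[[k]]$forces_pN))
  }))
  pair_force_series(forces, ref$pairs, replicate = reps,
                    condition_label = ref$condition_label,
                    residue_index = ref$residue_index)
}
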