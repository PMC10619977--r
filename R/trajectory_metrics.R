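#' Kabsch least-squares superposition and per-frame RMSD
#'
#' Each frame is rigid-body fitted (rotation + translation, no scaling) onto
#' the reference frame by the Kabsch algorithm over the particles in
#' `fit_selection`; the per-frame RMSD is then computed over
#' `analysis_selection`, which may differ from the fit selection (e.g. fit on
#' the kinase core, measure the deviation of the kinase excluding a helix).
#'
#' @param ensemble A [trajectory_ensemble()] (3-D coordinates).
#' @param reference Reference coordinates: an `n_particles x 3` matrix, or
#'   `NULL` to use the first frame of the first replicate.
#' @param fit_selection Integer vector of residue indices used for the fit
#'   (default: all). At least 3 non-collinear particles are required for a
#'   unique rotation; a collinear selection triggers an error naming the
#'   degeneracy.
#' @param analysis_selection Residues over which RMSD is computed (default:
#'   the fit selection).
#' @return List with `aligned` (a `TrajectoryEnsemble` of fitted coordinates)
#'   and `rmsd` (list of per-replicate RMSD series, nm).
#' @export
superpose <- function(ensemble, reference = NULL, fit_selection = NULL,
                      analysis_selection = NULL) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"), ensemble$dim == 3)
  if (is.null(fit_selection)) fit_selection <- unique(ensemble$residue_index)
  if (is.null(analysis_selection)) analysis_selection <- fit_selection
  fit_idx <- which(ensemble$residue_index %in% fit_selection)
  ana_idx <- which(ensemble$residue_index %in% analysis_selection)
  if (length(fit_idx) < 3) stop("fit selection must contain >= 3 particles")
  if (length(ana_idx) < 1) stop("analysis selection is empty")
  if (is.null(reference)) {
    reference <- ensemble$replicates[[1]][1, , ]
    if (is.null(dim(reference)))
      reference <- matrix(reference, ensemble$n_particles, 3)
  }
  ref_fit <- reference[fit_idx, , drop = FALSE]
  ref_cen <- colMeans(ref_fit)
  ref_fit_c <- sweep(ref_fit, 2, ref_cen)
  sv_ref <- svd(crossprod(ref_fit_c))
  if (sv_ref$d[2] / max(sv_ref$d[1], 1e-300) < 1e-10)
    stop("fit selection is (near-)collinear: rotation is ill-conditioned")

  aligned <- lapply(ensemble$replicates, function(arr) {
    out <- arr
    for (f in seq_len(dim(arr)[1])) {
      X <- arr[f, , ]
      if (is.null(dim(X))) X <- matrix(X, ensemble$n_particles, 3)
      fit <- kabsch_fit(X[fit_idx, , drop = FALSE], ref_fit)
      out[f, , ] <- sweep(sweep(X, 2, fit$x_center) %*% fit$rotation,
                          2, fit$ref_center, "+")
    }
    out
  })
  ref_ana <- reference[ana_idx, , drop = FALSE]
  rmsd <- lapply(aligned, function(arr) {
    vapply(seq_len(dim(arr)[1]), function(f) {
      X <- arr[f, ana_idx, , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, length(ana_idx), 3)
      sqrt(mean(rowSums((X - ref_ana)^2)))
    }, numeric(1))
  })
  list(
    aligned = trajectory_ensemble(aligned, ensemble$frame_interval,
                                  ensemble$condition_label,
                                  ensemble$residue_index),
    rmsd = rmsd
  )
}

# Kabsch rotation fitting x onto ref (both m x 3, matched rows).
# Returns rotation (3x3, det +1) applied to centered x, plus centers.
kabsch_fit <- function(x, ref) {
  xc <- colMeans(x); rc <- colMeans(ref)
  H <- crossprod(sweep(x, 2, xc), sweep(ref, 2, rc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(rotation = R, x_center = xc, ref_center = rc)
}

#' Per-residue root mean squared fluctuation
#'
#' RMSF of residue r is the root of the time-averaged squared 3-D
#' displacement of its particles from their time-mean positions, computed on
#' an already superposed ensemble (replicates concatenated). For isotropic
#' Gaussian jitter of standard deviation sigma per axis the RMSF converges
#' to sigma * sqrt(3).
#'
#' @param aligned A superposed [trajectory_ensemble()].
#' @param analysis_selection Residues to report (default all).
#' @return Data frame with `residue` and `rmsf` (nm).
#' @export
rmsf <- function(aligned, analysis_selection = NULL) {
  stopifnot(inherits(aligned, "TrajectoryEnsemble"))
  if (sum(n_frames(aligned)) < 2)
    stop("RMSF is undefined for a single frame")
  if (is.null(analysis_selection))
    analysis_selection <- sort(unique(aligned$residue_index))
  coords <- do.call(abind1, aligned$replicates)
  vals <- vapply(analysis_selection, function(r) {
    idx <- which(aligned$residue_index == r)
    per_particle <- vapply(idx, function(p) {
      X <- coords[, p, ]
      mu <- colMeans(X)
      mean(rowSums(sweep(X, 2, mu)^2))
    }, numeric(1))
    sqrt(mean(per_particle))
  }, numeric(1))
  data.frame(residue = analysis_selection, rmsf = vals)
}

# rbind 3-D arrays along the frame axis
abind1 <- function(...) {
  arrs <- list(...)
  n <- dim(arrs[[1]])[2]; d <- dim(arrs[[1]])[3]
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(total, n, d))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Average RMSF over residue ranges
#'
#' Reduction used for half-helix summaries: the mean RMSF within each named
#' residue range.
#'
#' @param rmsf_table Output of [rmsf()].
#' @param ranges Named list of integer vectors of residues.
#' @return Named numeric vector of range-averaged RMSF.
#' @export
rmsf_region_average <- function(rmsf_table, ranges) {
  vapply(ranges, function(rr) {
    mean(rmsf_table$rmsf[rmsf_table$residue %in% rr])
  }, numeric(1))
}

#' Principal component analysis of ensemble fluctuations
#'
#' Frames of all replicates are superposed onto the reference over
#' `fit_selection`, then the covariance of the mean-centered coordinates of
#' `analysis_selection` is eigendecomposed. Each eigenvector is oriented so
#' that its largest-magnitude component is positive, making projections
#' reproducible across platforms. A second ensemble (e.g. an active-state
#' reference) can be projected into the same model with
#' [pca_project()].
#'
#' Warns when the total frame count is below 3x the coordinate dimension
#' (rank-deficient covariance) and flags degenerate leading eigenvalues
#' (PC1/PC2 within 5%), where the PC1 direction is unstable.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param fit_selection,analysis_selection Residue masks (see [superpose()]).
#'   For non-3-D toy data, set `fit_selection = NULL` and `align = FALSE`.
#' @param reference Optional reference frame for the fit.
#' @param align Superpose before PCA (default `TRUE` for 3-D data).
#' @return List of class `PCAModel`: `mean` (coordinate mean vector),
#'   `eigenvectors` (columns, descending eigenvalue), `eigenvalues` (nm^2),
#'   `projections` (list of per-replicate PC1 series), `degenerate` flag,
#'   `analysis_idx` (particle indices used).
#' @export
pca_fit_project <- function(ensemble, fit_selection = NULL,
                            analysis_selection = NULL, reference = NULL,
                            align = ensemble$dim == 3) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"))
  if (align) {
    ensemble <- superpose(ensemble, reference, fit_selection,
                          analysis_selection)$aligned
  }
  if (is.null(analysis_selection))
    analysis_selection <- sort(unique(ensemble$residue_index))
  ana_idx <- which(ensemble$residue_index %in% analysis_selection)
  flat <- lapply(ensemble$replicates, function(arr) {
    nf <- dim(arr)[1]
    matrix(arr[, ana_idx, , drop = FALSE], nrow = nf)
  })
  X <- do.call(rbind, flat)
  p <- ncol(X)
  if (nrow(X) < 3 * p)
    warning(sprintf("only %d frames for %d coordinates: covariance may be rank deficient",
                    nrow(X), p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (k in seq_len(ncol(vecs))) {     # sign convention
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  degenerate <- length(vals) >= 2 && vals[1] > 0 &&
    (vals[1] - vals[2]) / vals[1] < 0.05
  if (degenerate)
    warning("leading eigenvalues are near-degenerate: PC1 direction is unstable")
  proj <- lapply(flat, function(Fm) as.numeric(sweep(Fm, 2, mu) %*% vecs[, 1]))
  structure(list(mean = mu, eigenvectors = vecs, eigenvalues = vals,
                 projections = proj, degenerate = degenerate,
                 analysis_idx = ana_idx, dim = ensemble$dim,
                 frame_interval = ensemble$frame_interval),
            class = "PCAModel")
}

#' Project another ensemble into an existing PCA model
#'
#' @param model A `PCAModel` from [pca_fit_project()].
#' @param ensemble A [trajectory_ensemble()] with the same particle count and
#'   dimensionality as the model's source.
#' @param component Which principal component to project onto (default 1).
#' @return List of per-replicate projection series.
#' @export
pca_project <- function(model, ensemble, component = 1) {
  stopifnot(inherits(model, "PCAModel"),
            inherits(ensemble, "TrajectoryEnsemble"))
  if (ensemble$dim != model$dim)
    stop("ensemble dimensionality does not match the PCA model")
  lapply(ensemble$replicates, function(arr) {
    nf <- dim(arr)[1]
    Fm <- matrix(arr[, model$analysis_idx, , drop = FALSE], nrow = nf)
    if (ncol(Fm) != length(model$mean))
      stop("particle count does not match the PCA model")
    as.numeric(sweep(Fm, 2, model$mean) %*% model$eigenvectors[, component])
  })
}

#' Non-overlapping block averages with gaps
#'
#' Greedy tiling from the start of the series: a block of `block_length`
#' frames, then `gap_length` frames skipped, repeated; a trailing partial
#' block is discarded. Leaving gaps between blocks de-correlates the block
#' means; independence is checked by the lag-1 autocorrelation of the block
#' means (flagged `independent` when |r1| < 2/sqrt(n_blocks), `correlated`
#' otherwise, `undefined` for constant series or fewer than 3 blocks).
#'
#' @param series Numeric vector.
#' @param block_length Frames per block (> 0).
#' @param gap_length Frames skipped between blocks (>= 0).
#' @return List of class `BlockSeries`: `means`, `starts` (1-based first
#'   frame of each block), `block_length`, `gap_length`, `independence`.
#' @export
block_averages <- function(series, block_length, gap_length = 0) {
  if (block_length <= 0) stop("block_length must be > 0")
  stopifnot(gap_length >= 0)
  n <- length(series)
  if (n < block_length) stop("series shorter than one block")
  starts <- seq(1, n, by = block_length + gap_length)
  starts <- starts[starts + block_length - 1 <= n]
  means <- vapply(starts, function(s) mean(series[s:(s + block_length - 1)]),
                  numeric(1))
  independence <- "undefined"
  if (length(means) >= 3 && stats::sd(means) > 0) {
    r1 <- stats::cor(means[-length(means)], means[-1])
    independence <- if (abs(r1) < 2 / sqrt(length(means)))
      "independent" else "correlated"
  }
  structure(list(means = means, starts = starts,
                 block_length = block_length, gap_length = gap_length,
                 independence = independence),
            class = "BlockSeries")
}

#' Compare two conditions on block means
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test on the block means, the
#' default significance test for ensemble metric comparisons; a permutation
#' test on the difference of means is available as an option. Also returns
#' the boxplot summary convention used in the figures: centerline = mean,
#' box edges = lower/upper quartile, whiskers = 1.5x the interquartile range
#' (clamped to the data range).
#'
#' @param a,b Numeric vectors of block means (>= 3 each), or `BlockSeries`.
#' @param method `"wilcoxon"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param seed Seed for the permutation test.
#' @return List with `statistic`, `p_value`, `method` and `boxplot`
#'   (data frame, one row per condition).
#' @export
compare_conditions <- function(a, b, method = c("wilcoxon", "permutation"),
                               n_perm = 1e5, seed = 1) {
  if (inherits(a, "BlockSeries")) a <- a$means
  if (inherits(b, "BlockSeries")) b <- b$means
  method <- match.arg(method)
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (stats::sd(c(a, b)) == 0) {
    stat <- NA_real_; p <- 1
  } else if (method == "wilcoxon") {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    stat <- unname(wt$statistic); p <- wt$p.value
  } else {
    set.seed(seed)
    obs <- mean(a) - mean(b)
    pool <- c(a, b)
    na <- length(a)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs) - 1e-12)
        hits <- hits + 1L
    }
    stat <- obs; p <- (hits + 1) / (n_perm + 1)
  }
  list(statistic = stat, p_value = p, method = method,
       boxplot = rbind(boxplot_summary(a, "A"), boxplot_summary(b, "B")))
}

#' Boxplot summary (mean centerline, quartile box, 1.5 IQR whiskers)
#'
#' @param x Numeric vector.
#' @param label Row label.
#' @return One-row data frame: `label`, `center` (mean), `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`.
#' @export
boxplot_summary <- function(x, label = "") {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  data.frame(label = label, center = mean(x), q1 = q[1], q3 = q[2],
             whisker_lo = max(min(x), q[1] - 1.5 * iqr),
             whisker_hi = min(max(x), q[2] + 1.5 * iqr))
}
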