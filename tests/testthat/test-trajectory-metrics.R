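test_that("superpose undoes arbitrary rigid-body motion exactly", {
  set.seed(1)
  ref <- matrix(rnorm(8 * 3), 8, 3)
  frames <- lapply(1:5, function(f) apply_random_rigid(ref, seed = 100 + f))
  ens <- ensemble_from_frames(frames)
  sup <- superpose(ens, reference = ref)
  expect_equal(max(abs(sup$rmsd[[1]])), 0, tolerance = 1e-8)
  for (f in 1:5)
    expect_equal(sup$aligned$replicates[[1]][f, , ], ref, tolerance = 1e-8)
})

test_that("superpose separates fit and analysis selections", {
  set.seed(2)
  ref <- matrix(rnorm(10 * 3), 10, 3)
  # residues 1..6 rigid, 7..10 displaced by a known offset
  moved <- ref
  moved[7:10, ] <- moved[7:10, ] + matrix(rep(c(0.3, 0, 0), each = 4), 4, 3)
  ens <- ensemble_from_frames(list(apply_random_rigid(moved, seed = 11)))
  sup <- superpose(ens, reference = ref, fit_selection = 1:6,
                   analysis_selection = 7:10)
  # after fitting on the rigid part, the analysis RMSD is exactly the offset
  expect_equal(sup$rmsd[[1]], 0.3, tolerance = 1e-8)
  expect_error(superpose(ens, fit_selection = 1:2), ">= 3")
  # collinear fit selections are rejected by name
  line <- cbind(seq_len(5), 0, 0)
  ens_line <- ensemble_from_frames(list(line, line))
  expect_error(superpose(ens_line), "collinear")
})

test_that("rmsf matches the closed form for isotropic Gaussian jitter", {
  sigma <- 0.05
  set.seed(3)
  base <- matrix(rnorm(6 * 3), 6, 3)
  frames <- lapply(1:4000, function(f) base + matrix(rnorm(18, 0, sigma), 6, 3))
  ens <- ensemble_from_frames(frames)
  tab <- rmsf(ens)              # already "aligned": no rigid motion added
  expect_equal(tab$rmsf, rep(sigma * sqrt(3), 6), tolerance = 0.03)
  expect_error(rmsf(ensemble_from_frames(frames[1])), "single frame")
  # direct-oracle check on a tiny deterministic ensemble
  f1 <- matrix(0, 3, 3); f2 <- f1; f2[2, 1] <- 0.2
  ens2 <- ensemble_from_frames(list(f1, f2))
  tab2 <- rmsf(ens2)
  expect_equal(tab2$rmsf, c(0, 0.1, 0))   # mean-centered deviation 0.1 each frame
})

test_that("rmsf_region_average reduces ranges correctly", {
  tab <- data.frame(residue = 1:6, rmsf = c(1, 2, 3, 4, 5, 6))
  out <- rmsf_region_average(tab, list(front = 1:3, back = 4:6))
  expect_equal(out, c(front = 2, back = 5))
})

test_that("PCA agrees exactly with a dense-solver oracle", {
  set.seed(4)
  # planted anisotropic fluctuations along a known direction
  n <- 5
  dir <- rnorm(n * 3); dir <- dir / sqrt(sum(dir^2))
  base <- as.numeric(matrix(rnorm(n * 3), n, 3))
  X <- t(vapply(1:400, function(f) {
    base + rnorm(1, 0, 0.3) * dir + rnorm(n * 3, 0, 0.01)
  }, numeric(n * 3)))
  frames <- lapply(seq_len(nrow(X)), function(f) matrix(X[f, ], n, 3))
  ens <- ensemble_from_frames(frames)
  model <- pca_fit_project(ens, align = FALSE)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)   # dense oracle
  expect_equal(model$eigenvalues, unname(pr$sdev^2), tolerance = 1e-8)
  v1 <- pr$rotation[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1               # same sign convention
  expect_equal(model$eigenvectors[, 1], unname(v1), tolerance = 1e-8)
  # PC1 recovers the planted direction
  expect_gt(abs(sum(model$eigenvectors[, 1] * dir)), 0.999)
  # sign convention: largest-magnitude component positive, so projections
  # are reproducible
  m <- apply(abs(model$eigenvectors), 2, which.max)
  expect_true(all(model$eigenvectors[cbind(m, seq_along(m))] > 0))
  # projecting the source ensemble reproduces the stored projections
  expect_equal(pca_project(model, ens), model$projections)
})

test_that("PCA flags rank deficiency and degenerate leading eigenvalues", {
  set.seed(5)
  frames <- lapply(1:10, function(f) matrix(rnorm(12), 4, 3))
  expect_warning(pca_fit_project(ensemble_from_frames(frames), align = FALSE),
                 "rank deficient")
  # exactly isotropic 2-D toy (uniform points on a circle): equal
  # eigenvalues -> degenerate flag
  theta <- 2 * pi * (0:359) / 360
  arr <- array(c(cos(theta), sin(theta)), c(360, 1, 2))
  ens <- trajectory_ensemble(list(arr))
  expect_warning(model <- pca_fit_project(ens, align = FALSE), "degenerate")
  expect_true(model$degenerate)
})

test_that("block tiling reproduces the section/gap arithmetic", {
  # 2000-frame series, 400-frame blocks, 100-frame gaps -> 4 blocks
  b <- block_averages(rnorm(2000), 400, 100)
  expect_equal(length(b$means), 4)
  expect_equal(b$starts, c(1, 501, 1001, 1501))
  # 1000-frame series -> 2 blocks
  expect_equal(length(block_averages(rnorm(1000), 400, 100)$means), 2)
  # exact means, no gap
  b2 <- block_averages(c(1, 1, 3, 3, 7), 2, 0)
  expect_equal(b2$means, c(1, 3))                 # trailing partial discarded
  expect_equal(b2$starts, c(1, 3))
  # gap frames are really skipped
  b3 <- block_averages(c(1, 2, 100, 3, 4), 2, 1)
  expect_equal(b3$means, c(1.5, 3.5))
  expect_error(block_averages(rnorm(10), 0))
  expect_error(block_averages(rnorm(3), 10), "shorter")
})

test_that("block independence flag follows the lag-1 autocorrelation", {
  expect_equal(block_averages(rep(1, 100), 10)$independence, "undefined")
  expect_equal(block_averages(rnorm(25), 10)$independence, "undefined") # < 3
  set.seed(6)
  expect_equal(block_averages(rnorm(5000), 10)$independence, "independent")
  trend <- seq(0, 10, length.out = 5000) + rnorm(5000, 0, 0.01)
  expect_equal(block_averages(trend, 10)$independence, "correlated")
  # white noise: block-mean variance ~ sigma^2 / L (within 20%, 200 blocks)
  set.seed(7)
  bw <- block_averages(rnorm(200 * 50, sd = 2), 50)
  expect_equal(stats::var(bw$means), 4 / 50, tolerance = 0.2)
})

test_that("compare_conditions tests block means and summarises boxplots", {
  set.seed(8)
  a <- rnorm(20, 0); b <- rnorm(20, 2)
  cmp <- compare_conditions(a, b)
  expect_lt(cmp$p_value, 1e-4)
  expect_equal(cmp$method, "wilcoxon")
  same <- compare_conditions(rep(1, 5), rep(1, 5))
  expect_equal(same$p_value, 1)                   # identical data: no signal
  # permutation option agrees in direction with wilcoxon
  cmp_p <- compare_conditions(a, b, method = "permutation", n_perm = 2000,
                              seed = 3)
  expect_lt(cmp_p$p_value, 0.01)
  # null case is not significant
  set.seed(9)
  expect_gt(compare_conditions(rnorm(15), rnorm(15))$p_value, 0.05)
  expect_error(compare_conditions(1:2, 1:5))
  # boxplot convention: mean centerline, quartile box, 1.5 IQR whiskers
  x <- c(1, 2, 3, 4, 100)
  bs <- boxplot_summary(x, "t")
  expect_equal(bs$center, mean(x))
  expect_equal(bs$q1, stats::quantile(x, 0.25, names = FALSE))
  expect_equal(bs$q3, stats::quantile(x, 0.75, names = FALSE))
  expect_equal(bs$whisker_hi, min(max(x), bs$q3 + 1.5 * (bs$q3 - bs$q1)))
  expect_equal(bs$whisker_lo, max(min(x), bs$q1 - 1.5 * (bs$q3 - bs$q1)))
})
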