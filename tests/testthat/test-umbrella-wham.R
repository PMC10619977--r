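test_that("sample_umbrella_windows draws from the biased Boltzmann density", {
  pmf <- pmf_harmonic(k = 0, center = 0, halfwidth = 1)   # flat potential
  win <- sample_umbrella_windows(pmf, centers = c(-0.3, 0.3), k = 100,
                                 n_per_window = 20000, seed = 3)
  # flat PMF + harmonic bias -> Gaussian with sd = sqrt(kBT / k)
  sd_th <- sqrt(kBT(300) / 100)
  for (w in 1:2) {
    s <- win$windows[[w]]$samples
    expect_equal(mean(s), win$windows[[w]]$center, tolerance = 0.005)
    expect_equal(stats::sd(s), sd_th, tolerance = 0.02)
    dens <- boltzmann_density(function(x) {
      50 * (x - win$windows[[w]]$center)^2
    }, -1, 1)
    expect_lt(ks_distance_to_density(s, dens), 0.01)
  }
  # reproducible per window through the derived seeds
  win2 <- sample_umbrella_windows(pmf, centers = c(-0.3, 0.3), k = 100,
                                  n_per_window = 20000, seed = 3)
  expect_identical(win$windows[[1]]$samples, win2$windows[[1]]$samples)
  expect_error(sample_umbrella_windows(pmf, centers = 5, k = 100,
                                       n_per_window = 200), "domain")
  # disconnected windows warn
  pmf2 <- pmf_flat(0, 10)
  expect_warning(sample_umbrella_windows(pmf2, centers = c(1, 9), k = 5000,
                                         n_per_window = 200, seed = 1),
                 "do not overlap")
})

test_that("build_histograms applies burn-in and conserves counts", {
  win <- umbrella_window_set(list(
    list(center = 0.2, k = 100, samples = c(rep(9, 4), seq(0.1, 0.3, 0.05))),
    list(center = 0.3, k = 100, samples = c(rep(9, 4), seq(0.2, 0.4, 0.05)))))
  # burn-in 4/9 rounded down: floor(0.45 * 9) = 4, the planted 9s drop out
  hist <- build_histograms(win, n_bins = 20, burn_in_frac = 0.45)
  expect_equal(rowSums(hist$counts), c(5, 5))
  expect_equal(range(hist$bin_edges), c(0.1, 0.4), tolerance = 1e-3)
  # every retained sample lands in exactly one bin, extremes included
  expect_equal(sum(hist$counts), 10)
  expect_error(build_histograms(win, n_bins = 10), "n_bins")
  expect_error(build_histograms(win, n_bins = 20, burn_in_frac = 1))
  # floor() burn-in can never empty a window: a single sample survives
  win1 <- suppressWarnings(umbrella_window_set(list(
    list(center = 0.2, k = 100, samples = 0.2),
    list(center = 0.3, k = 100, samples = 0.3))))
  h1 <- build_histograms(win1, n_bins = 20, burn_in_frac = 0.5)
  expect_equal(rowSums(h1$counts), c(1, 1))
})

test_that("WHAM recovers a flat potential and a harmonic potential", {
  # flat: any structure in the answer is pure estimator error
  flat <- pmf_flat(-1, 1)
  win <- sample_umbrella_windows(flat, centers = seq(-0.8, 0.8, by = 0.2),
                                 k = 200, n_per_window = 8000, seed = 5)
  prof <- solve_wham(build_histograms(win, n_bins = 100, burn_in_frac = 0.4))
  expect_true(prof$converged)
  occ <- prof$occupied
  err <- prof$F_kJmol[occ]
  expect_lt(sqrt(mean((err - mean(err))^2)), 0.3)
  # harmonic: recover curvature over the sampled range
  har <- pmf_harmonic(k = 50, center = 0, halfwidth = 1)
  win2 <- sample_umbrella_windows(har, centers = seq(-0.8, 0.8, by = 0.2),
                                  k = 300, n_per_window = 8000, seed = 6)
  prof2 <- solve_wham(build_histograms(win2, n_bins = 100,
                                       burn_in_frac = 0.4))
  # compare over the well-sampled interior: the bias tilts the outer windows
  # inward (effective centers k_bias c/(k_bias + k_U)), so the extreme bins
  # hold only a handful of counts and carry pure shot noise
  occ2 <- prof2$occupied & abs(prof2$xi) <= 0.7
  e2 <- prof2$F_kJmol[occ2] - 0.5 * 50 * prof2$xi[occ2]^2
  expect_lt(sqrt(mean((e2 - mean(e2))^2)), 0.3)
  # profile is defined up to a constant with min zero
  expect_equal(min(prof2$F_kJmol, na.rm = TRUE), 0)
})

test_that("solve_wham honours weights, tolerance and iteration cap", {
  flat <- pmf_flat(-1, 1)
  win <- sample_umbrella_windows(flat, centers = seq(-0.6, 0.6, by = 0.3),
                                 k = 200, n_per_window = 1000, seed = 7)
  hist <- build_histograms(win, n_bins = 60, burn_in_frac = 0)
  ref <- solve_wham(hist)
  # unit weights are the default
  same <- solve_wham(hist, weights = rep(1, 5))
  expect_equal(same$F_kJmol, ref$F_kJmol, tolerance = 1e-10)
  # iteration cap: non-convergence warns and flags
  expect_warning(capped <- solve_wham(hist, max_iter = 2), "did not converge")
  expect_false(capped$converged)
  expect_error(solve_wham(hist, weights = rep(0, 5)), "positive total weight")
  # far-apart stiff windows: overlap warning
  pmf2 <- pmf_flat(0, 10)
  win2 <- suppressWarnings(
    sample_umbrella_windows(pmf2, centers = c(1, 9), k = 5000,
                            n_per_window = 500, seed = 8))
  expect_warning(solve_wham(build_histograms(win2, n_bins = 50,
                                             burn_in_frac = 0)),
                 "share no occupied bins")
})

test_that("bootstrap_pmf yields a reproducible, sane error band", {
  flat <- pmf_flat(-1, 1)
  win <- sample_umbrella_windows(flat, centers = seq(-0.8, 0.8, by = 0.2),
                                 k = 200, n_per_window = 1000, seed = 9)
  hist <- build_histograms(win, n_bins = 80, burn_in_frac = 0.4)
  prof <- bootstrap_pmf(hist, n_boot = 30, seed = 10)
  expect_equal(prof$n_boot_ok, 30)
  occ <- prof$occupied
  expect_true(all(prof$stderr[occ] >= 0))
  expect_true(all(is.finite(prof$stderr[occ])))
  # errors grow toward the poorly sampled edges of the range
  mid <- which(abs(prof$xi) < 0.2 & occ)
  edge <- which(abs(prof$xi) > 0.75 & occ)
  expect_lt(mean(prof$stderr[mid]), mean(prof$stderr[edge]))
  prof2 <- bootstrap_pmf(hist, n_boot = 30, seed = 10)
  expect_identical(prof$stderr, prof2$stderr)
  expect_error(bootstrap_pmf(hist, n_boot = 5), "n_boot")
})

test_that("extract_deltaG measures plateau minus bound minimum", {
  xi <- seq(0, 3, length.out = 121)
  Fv <- ifelse(xi < 1, 10 * (xi - 0.5)^2, 2.5 + 7.5 * pmin(1, (xi - 1) / 0.5))
  prof <- structure(list(xi = xi, F_kJmol = Fv - min(Fv),
                         stderr = rep(0.2, 121), occupied = rep(TRUE, 121),
                         temperature = 300, converged = TRUE),
                    class = "PMFProfile")
  out <- extract_deltaG(prof, bound_region = c(0, 1),
                        plateau_region = c(2, 3))
  expect_equal(out$deltaG_kJmol, 10)
  expect_equal(out$bound_min_xi, 0.5, tolerance = 0.02)
  expect_equal(out$sigma_kJmol, sqrt(0.2^2 + 0.2^2))
  # tilted plateau warns
  prof$F_kJmol <- xi * 3
  expect_warning(extract_deltaG(prof, c(0, 1), c(1.5, 3)), "not flat")
  expect_error(extract_deltaG(prof, c(10, 11), c(1.5, 3)), "no occupied")
})
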