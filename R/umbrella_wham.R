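#' Histogram umbrella windows onto a shared grid
#'
#' Discards the leading `burn_in_frac` of each window's time series (the
#' equilibration span; with 200 ns windows and 80 ns discarded the fraction
#' is 0.4, the default), then bins the retained samples of every window into
#' half-open bins `[lo, hi)` on one shared grid spanning all retained
#' samples with a small margin.
#'
#' @param windows An [umbrella_window_set()].
#' @param n_bins Number of bins (>= 20).
#' @param burn_in_frac Fraction of each window discarded from the start,
#'   in `[0, 1)`. Default 0.4.
#' @param margin Fractional widening of the sample range (default 1e-6,
#'   just enough that the maximum falls inside the last bin).
#' @return An object of class `WhamInput`: list with `counts` (windows x
#'   bins matrix), `bin_centers`, `bin_edges`, `centers` (window restraint
#'   centers), `k` (spring constants), `temperature`, `burn_in_frac`.
#' @export
build_histograms <- function(windows, n_bins = 200, burn_in_frac = 0.4,
                             margin = 1e-6) {
  stopifnot(inherits(windows, "UmbrellaWindowSet"))
  if (n_bins < 20) stop("n_bins must be >= 20")
  if (burn_in_frac < 0 || burn_in_frac >= 1)
    stop("burn_in_frac must lie in [0, 1)")
  retained <- lapply(seq_along(windows$windows), function(w) {
    s <- windows$windows[[w]]$samples
    drop <- floor(burn_in_frac * length(s))
    out <- s[(drop + 1):length(s)]
    if (length(out) == 0)
      stop(sprintf("window %d is empty after burn-in", w))
    out
  })
  rng <- range(unlist(retained))
  span <- max(rng[2] - rng[1], 1e-9)
  edges <- seq(rng[1] - margin * span, rng[2] + margin * span,
               length.out = n_bins + 1)
  counts <- t(vapply(retained, function(s) {
    idx <- findInterval(s, edges, rightmost.closed = FALSE)
    idx[idx < 1] <- 1; idx[idx > n_bins] <- n_bins
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins)))
  structure(list(
    counts = counts,
    bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
    bin_edges = edges,
    centers = vapply(windows$windows, `[[`, numeric(1), "center"),
    k = vapply(windows$windows, `[[`, numeric(1), "k"),
    temperature = windows$temperature,
    burn_in_frac = burn_in_frac), class = "WhamInput")
}

#' @export
print.WhamInput <- function(x, ...) {
  cat(sprintf("WhamInput: %d windows x %d bins, T = %g K, burn-in %g\n",
              nrow(x$counts), ncol(x$counts), x$temperature, x$burn_in_frac))
  invisible(x)
}

#' Solve the WHAM self-consistent equations
#'
#' Standard weighted-histogram iteration: with bias potentials
#' `w_i(xi) = k_i/2 (xi - xi_i)^2` evaluated at bin centers, the unbiased
#' probabilities and window free energies
#' \deqn{p_b \propto \frac{\sum_i n_{ib}}{\sum_i N_i e^{(f_i - w_i(\xi_b))/k_BT}},
#'       \quad f_i = -k_BT \ln \sum_b p_b e^{-w_i(\xi_b)/k_BT}}
#' are iterated until the largest change in any `f_i` drops below `tol`
#' (log-sum-exp arithmetic throughout, so stiff springs cannot underflow).
#' The free-energy profile is `F(xi_b) = -kBT ln p_b`, shifted so its
#' minimum is zero. No Jacobian/pulling-geometry correction is applied.
#'
#' @param input A [build_histograms()] result.
#' @param tol Convergence tolerance on window free energies, kJ/mol
#'   (default `1e-6 * kBT`).
#' @param max_iter Iteration cap (default 1e5). On non-convergence the best
#'   estimate is returned with `converged = FALSE` and a warning reporting
#'   the residual.
#' @param weights Optional positive per-window weights (used by the
#'   bootstrap); default all 1.
#' @return An object of class `PMFProfile`: list with `xi`, `F_kJmol`,
#'   `stderr` (NA until [bootstrap_pmf()] fills it), `f_windows`,
#'   `converged`, `iterations`, `temperature`, plus the occupied-bin mask
#'   `occupied`.
#' @export
solve_wham <- function(input, tol = NULL, max_iter = 1e5, weights = NULL) {
  stopifnot(inherits(input, "WhamInput"))
  kT <- kBT(input$temperature)
  if (is.null(tol)) tol <- 1e-6 * kT
  W <- nrow(input$counts); B <- ncol(input$counts)
  if (is.null(weights)) weights <- rep(1, W)
  stopifnot(length(weights) == W, all(weights >= 0))
  counts <- input$counts * weights
  Ni <- rowSums(counts)
  if (any(Ni <= 0)) stop("every window needs positive total weight")
  nb <- colSums(counts)
  occupied <- nb > 0
  # check window overlap: adjacent (by center) windows sharing occupied bins
  ord <- order(input$centers)
  occ_rows <- input$counts > 0
  for (a in seq_len(W - 1)) {
    if (!any(occ_rows[ord[a], ] & occ_rows[ord[a + 1], ]))
      warning(sprintf("windows %d and %d share no occupied bins", ord[a],
                      ord[a + 1]))
  }
  # bias matrix: W x B; Boltzmann factors of the biases. Factors for bins far
  # from a window underflow to 0, which drops harmlessly out of the sums.
  wib <- 0.5 * outer(input$k, rep(1, B)) *
    (outer(input$centers, rep(1, B)) -
       outer(rep(1, W), input$bin_centers))^2
  E <- exp(-wib / kT)                     # W x B
  tE <- t(E)
  g <- rep(1, W)                          # exp(f_i / kBT)
  iter <- 0L; converged <- FALSE
  p <- numeric(B)
  repeat {
    iter <- iter + 1L
    den <- as.numeric(tE %*% (Ni * g))    # per-bin denominator
    p[] <- 0
    p[occupied] <- nb[occupied] / den[occupied]
    p <- p / sum(p)
    z <- as.numeric(E %*% p)              # sum_b p_b exp(-w_ib/kT)
    g_new <- 1 / z
    g_new <- g_new / g_new[1]
    delta <- kT * max(abs(log(g_new) - log(g)))
    g <- g_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("WHAM did not converge in %d iterations (residual %g kJ/mol)",
                    iter, delta))
  f <- kT * log(g)
  Fv <- rep(NA_real_, B)
  Fv[occupied] <- -kT * log(p[occupied])
  Fv <- Fv - min(Fv, na.rm = TRUE)
  structure(list(xi = input$bin_centers, F_kJmol = Fv,
                 stderr = rep(NA_real_, B), f_windows = f,
                 converged = converged, iterations = iter,
                 temperature = input$temperature, occupied = occupied),
            class = "PMFProfile")
}

#' @export
print.PMFProfile <- function(x, ...) {
  cat(sprintf("PMFProfile: %d bins (%d occupied), xi %g..%g nm, max F = %.2f kJ/mol%s\n",
              length(x$xi), sum(x$occupied), min(x$xi), max(x$xi),
              max(x$F_kJmol, na.rm = TRUE),
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Bootstrap error band for a WHAM profile
#'
#' Complete-histogram bootstrap: each iteration draws
#' Dirichlet(1, ..., 1) weights over the windows (the continuous analogue of
#' resampling whole window histograms with replacement), re-solves WHAM with
#' the weighted counts, aligns each bootstrap profile to the reference
#' profile by its mean over shared occupied bins, and reports the per-bin
#' standard deviation. Iterations whose solve fails are dropped and logged;
#' at least 90% must succeed.
#'
#' @param input A [build_histograms()] result.
#' @param n_boot Bootstrap iterations (>= 10; default 100).
#' @param seed Integer seed (bit-reproducible band given the seed).
#' @param tol,max_iter Passed to [solve_wham()].
#' @return The reference `PMFProfile` with `stderr` filled in and an extra
#'   element `n_boot_ok`.
#' @export
bootstrap_pmf <- function(input, n_boot = 100, seed = 1, tol = NULL,
                          max_iter = 1e5) {
  stopifnot(inherits(input, "WhamInput"))
  if (n_boot < 10) stop("n_boot must be >= 10")
  ref <- solve_wham(input, tol = tol, max_iter = max_iter)
  W <- nrow(input$counts)
  if (W < 2) {
    warning("single window: bootstrap error over windows is undefined")
    return(ref)
  }
  set.seed(seed)
  occ <- ref$occupied
  profiles <- matrix(NA_real_, n_boot, length(ref$xi))
  ok <- 0L
  for (b in seq_len(n_boot)) {
    wts <- stats::rgamma(W, shape = 1)
    wts <- wts / sum(wts) * W
    prof <- tryCatch(
      suppressWarnings(solve_wham(input, tol = tol, max_iter = max_iter,
                                  weights = wts)),
      error = function(e) NULL)
    if (is.null(prof)) next
    shared <- occ & prof$occupied
    shift <- mean(prof$F_kJmol[shared] - ref$F_kJmol[shared])
    profiles[b, ] <- prof$F_kJmol - shift
    ok <- ok + 1L
  }
  if (ok < 0.9 * n_boot)
    stop(sprintf("only %d of %d bootstrap solves succeeded", ok, n_boot))
  ref$stderr <- apply(profiles, 2, stats::sd, na.rm = TRUE)
  ref$n_boot_ok <- ok
  ref
}

#' Extract the binding free energy from a PMF profile
#'
#' `Delta G = mean F over the plateau (unbound) region - min F over the
#' bound region`. The plateau is checked for flatness (max - min within
#' `flat_tol`, default 2 kJ/mol; a tilted plateau triggers a warning). The
#' error combines the bootstrap errors of the two regions in quadrature:
#' the mean standard error over the plateau bins and the standard error at
#' the bound minimum.
#'
#' @param pmf A `PMFProfile`.
#' @param bound_region,plateau_region Length-2 numeric ranges of xi (nm).
#' @param flat_tol Plateau flatness tolerance, kJ/mol.
#' @return List with `deltaG_kJmol`, `sigma_kJmol`, `bound_min_xi`,
#'   `plateau_mean`.
#' @export
extract_deltaG <- function(pmf, bound_region, plateau_region, flat_tol = 2) {
  stopifnot(inherits(pmf, "PMFProfile"))
  in_range <- function(rg) which(pmf$xi >= rg[1] & pmf$xi <= rg[2] &
                                 pmf$occupied)
  bi <- in_range(bound_region)
  pi <- in_range(plateau_region)
  if (length(bi) == 0 || length(pi) == 0)
    stop("bound or plateau region contains no occupied bins")
  plateau_F <- pmf$F_kJmol[pi]
  if (max(plateau_F) - min(plateau_F) > flat_tol)
    warning(sprintf("plateau is not flat (spread %.2f kJ/mol > %g)",
                    max(plateau_F) - min(plateau_F), flat_tol))
  bmin <- bi[which.min(pmf$F_kJmol[bi])]
  dG <- mean(plateau_F) - pmf$F_kJmol[bmin]
  sig <- if (all(is.na(pmf$stderr))) NA_real_ else
    sqrt(mean(pmf$stderr[pi], na.rm = TRUE)^2 + pmf$stderr[bmin]^2)
  list(deltaG_kJmol = dG, sigma_kJmol = sig,
       bound_min_xi = pmf$xi[bmin], plateau_mean = mean(plateau_F))
}
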