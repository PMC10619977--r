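#' Analytic potential of mean force
#'
#' Wraps a closed-form free-energy profile U(xi) on a finite domain. Used as
#' the ground truth that umbrella windows are sampled from and that WHAM /
#' metadynamics estimates are validated against.
#'
#' @param fun Function of a numeric vector xi returning U in kJ/mol.
#' @param xi_min,xi_max Domain bounds, nm.
#' @param label Free-text description.
#' @return An object of class `AnalyticPMF`.
#' @export
analytic_pmf <- function(fun, xi_min, xi_max, label = "") {
  stopifnot(is.function(fun), xi_max > xi_min)
  test <- fun(seq(xi_min, xi_max, length.out = 11))
  if (!all(is.finite(test))) stop("U must be finite on the domain")
  structure(list(fun = fun, xi_min = xi_min, xi_max = xi_max, label = label),
            class = "AnalyticPMF")
}

#' Double-well analytic PMF
#'
#' U(xi) = h * (((xi - center)^2 / w^2) - 1)^2: minima at center +/- w,
#' barrier h at the center. Domain extends `pad` half-separations beyond the
#' minima.
#'
#' @param h Barrier height, kJ/mol.
#' @param center Barrier position, nm.
#' @param w Half-separation of the minima, nm.
#' @param pad Domain padding in units of w.
#' @return An `AnalyticPMF`.
#' @export
pmf_double_well <- function(h = 10, center = 1.2, w = 0.5, pad = 2.8) {
  analytic_pmf(function(xi) h * (((xi - center)^2 / w^2) - 1)^2,
               xi_min = center - pad * w, xi_max = center + pad * w,
               label = sprintf("double well h=%g center=%g w=%g", h, center, w))
}

#' Harmonic analytic PMF
#' @param k Curvature, kJ/mol/nm^2.
#' @param center Minimum position, nm.
#' @param halfwidth Domain half-width, nm.
#' @return An `AnalyticPMF`.
#' @export
pmf_harmonic <- function(k = 100, center = 0, halfwidth = 1) {
  analytic_pmf(function(xi) 0.5 * k * (xi - center)^2,
               center - halfwidth, center + halfwidth,
               label = sprintf("harmonic k=%g center=%g", k, center))
}

#' Flat analytic PMF
#' @param xi_min,xi_max Domain, nm.
#' @return An `AnalyticPMF`.
#' @export
pmf_flat <- function(xi_min = 0, xi_max = 1) {
  analytic_pmf(function(xi) rep(0, length(xi)), xi_min, xi_max, label = "flat")
}

#' Umbrella window set
#'
#' Per-window restraint center, spring constant and reaction-coordinate
#' samples -- the input to histogramming and WHAM. A warning is issued when
#' any pair of adjacent windows (ordered by center) shares no overlap in
#' sampled range, since WHAM cannot stitch disconnected windows.
#'
#' @param windows List of lists with elements `center` (nm), `k`
#'   (kJ/mol/nm^2, > 0) and `samples` (numeric vector of xi values, nm).
#' @param temperature Temperature in K.
#' @return An object of class `UmbrellaWindowSet`.
#' @export
umbrella_window_set <- function(windows, temperature = 300) {
  stopifnot(length(windows) >= 2)
  for (w in windows) {
    stopifnot(is.numeric(w$center), w$k > 0, length(w$samples) >= 1)
  }
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  windows <- windows[ord]
  for (a in seq_len(length(windows) - 1)) {
    ra <- range(windows[[a]]$samples)
    rb <- range(windows[[a + 1]]$samples)
    if (ra[2] < rb[1] || rb[2] < ra[1]) {
      warning(sprintf(
        "adjacent umbrella windows %d and %d (centers %g, %g nm) do not overlap",
        a, a + 1, windows[[a]]$center, windows[[a + 1]]$center))
    }
  }
  structure(list(windows = windows, temperature = temperature),
            class = "UmbrellaWindowSet")
}

#' @export
print.UmbrellaWindowSet <- function(x, ...) {
  centers <- vapply(x$windows, `[[`, numeric(1), "center")
  cat(sprintf("UmbrellaWindowSet: %d windows, centers %g..%g nm, T = %g K\n",
              length(x$windows), min(centers), max(centers), x$temperature))
  invisible(x)
}

#' Draw umbrella-window samples from an analytic PMF
#'
#' Each window's samples are independent draws from the biased Boltzmann
#' density p(xi) proportional to exp(-(U(xi) + k/2 (xi - center)^2) / kBT),
#' obtained by inverse transform sampling on a fine grid with linear
#' interpolation of the cumulative distribution (so draws are continuous,
#' not grid-locked). Samples are independent by construction: what is under
#' test downstream is WHAM correctness, not kinetics, so window time series
#' carry no autocorrelation.
#'
#' @param pmf An [analytic_pmf()].
#' @param centers Window centers, nm, inside the PMF domain.
#' @param k Restraint spring constant, kJ/mol/nm^2.
#' @param n_per_window Samples per window (>= 100).
#' @param temperature Temperature, K.
#' @param seed Integer seed; window w uses [derive_seed()] counter w.
#' @param n_grid Grid resolution for the inverse CDF.
#' @return An [umbrella_window_set()].
#' @export
sample_umbrella_windows <- function(pmf, centers, k, n_per_window,
                                    temperature = 300, seed = 1,
                                    n_grid = 4001) {
  stopifnot(inherits(pmf, "AnalyticPMF"), k > 0, n_per_window >= 100)
  if (any(centers < pmf$xi_min | centers > pmf$xi_max))
    stop("window centers must lie inside the PMF domain")
  grid <- seq(pmf$xi_min, pmf$xi_max, length.out = n_grid)
  U <- pmf$fun(grid)
  beta <- 1 / kBT(temperature)
  windows <- lapply(seq_along(centers), function(w) {
    Ub <- U + 0.5 * k * (grid - centers[w])^2
    logp <- -beta * (Ub - min(Ub))
    p <- exp(logp)
    # trapezoid cumulative: the interpolated sampling density is the cell
    # average, symmetric within each cell (no half-cell location bias)
    cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2))
    Z <- cdf[length(cdf)]
    if (!is.finite(Z) || Z <= 0)
      stop("biased density is not normalizable on the PMF domain")
    cdf <- cdf / Z
    set.seed(derive_seed(seed, w))
    u <- stats::runif(n_per_window)
    samples <- stats::approx(cdf, grid, xout = u,
                             ties = "ordered", rule = 2)$y
    list(center = centers[w], k = k, samples = samples)
  })
  umbrella_window_set(windows, temperature = temperature)
}

#' Boltzmann marginal density of a biased or unbiased 1-D potential
#'
#' Quadrature helper used as an oracle in validation: the normalised density
#' exp(-U(x)/kBT) on a grid, trapezoid-normalised.
#'
#' @param fun Potential function (kJ/mol).
#' @param lo,hi Integration limits.
#' @param temperature Temperature, K.
#' @param n_grid Grid points.
#' @return Data frame with `x` and `density`.
#' @export
boltzmann_density <- function(fun, lo, hi, temperature = 300, n_grid = 2001) {
  x <- seq(lo, hi, length.out = n_grid)
  U <- fun(x)
  p <- exp(-(U - min(U)) / kBT(temperature))
  dx <- x[2] - x[1]
  Z <- sum((p[-1] + p[-length(p)]) / 2) * dx
  data.frame(x = x, density = p / Z)
}

#' Bernoulli contact series with planted occupancies
#'
#' Generates a per-frame boolean contact indicator for each residue pair with
#' the requested marginal occupancy, independently across frames and pairs.
#' The empirical occupancy converges to the planted one as frames grow.
#'
#' @param occupancies Named or unnamed numeric vector in `[0, 1]`, one per
#'   pair; optionally a data frame with columns `i`, `j`, `occupancy`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param frame_interval Time per frame (ps).
#' @param condition_label Condition name.
#' @return A [contact_series()].
#' @export
generate_contact_series <- function(occupancies, n_frames, seed = 1,
                                    frame_interval = 1,
                                    condition_label = "synthetic") {
  if (is.data.frame(occupancies)) {
    pairs <- occupancies[, c("i", "j"), drop = FALSE]
    occ <- occupancies$occupancy
  } else {
    occ <- as.numeric(occupancies)
    pairs <- data.frame(i = rep(1L, length(occ)), j = seq_along(occ) + 1L)
  }
  if (any(occ < 0 | occ > 1)) stop("occupancies must lie in [0, 1]")
  stopifnot(n_frames >= 1)
  set.seed(seed)
  m <- matrix(stats::runif(n_frames * length(occ)), n_frames, length(occ)) <
    matrix(occ, n_frames, length(occ), byrow = TRUE)
  contact_series(m, pairs, frame_interval = frame_interval,
                 condition_label = condition_label)
}
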