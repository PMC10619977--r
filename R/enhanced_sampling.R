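#' Collective variable interface
#'
#' A collective variable (CV) maps the coordinate matrix of a system to a
#' scalar and provides the analytic gradient needed for biasing forces.
#'
#' @param value Function `X -> scalar`.
#' @param grad Function `X -> n x dim matrix` (ds/dx).
#' @param label Description.
#' @return An object of class `CollectiveVariable`.
#' @export
collective_variable <- function(value, grad, label = "cv") {
  structure(list(value = value, grad = grad, label = label),
            class = "CollectiveVariable")
}

#' Single-coordinate collective variable
#'
#' The position of one particle along one axis -- the natural CV for 1-D toy
#' systems.
#'
#' @param particle Particle index.
#' @param axis Axis index.
#' @return A [collective_variable()].
#' @export
cv_coordinate <- function(particle = 1, axis = 1) {
  collective_variable(
    value = function(X) X[particle, axis],
    grad = function(X) {
      G <- matrix(0, nrow(X), ncol(X))
      G[particle, axis] <- 1
      G
    },
    label = sprintf("x[%d,%d]", particle, axis))
}

#' Reference geometry for the helicity collective variable
#'
#' Describes what a "helical" window looks like on a bead chain: a window of
#' `window` consecutive residues, a set of intra-window index pairs and the
#' distances those pairs have in the ideal (helix-like) conformation, plus
#' the switching radius. This is a configurable analogue of helix-content
#' CVs that compare backbone distances to ideal helix distances; toy beads
#' are not peptides, so the reference distances are supplied rather than
#' hard-coded from peptide geometry.
#'
#' @param window Window length in residues (>= 2).
#' @param pairs Data frame of 1-based positions `a`, `b` within the window
#'   (default: the `(m, m+3)` pairs, the helix-defining span).
#' @param d_ref Reference distance for each pair, nm.
#' @param r0 Switching radius, nm: deviations well below `r0` count as
#'   helical, well above as non-helical.
#' @return An object of class `HelicityReference`.
#' @export
helicity_reference <- function(window = 6, pairs = NULL, d_ref = 0.5,
                               r0 = 0.08) {
  stopifnot(window >= 2, r0 > 0)
  if (is.null(pairs)) {
    if (window < 4) stop("default (m, m+3) pairs need window >= 4")
    pairs <- data.frame(a = seq_len(window - 3), b = seq_len(window - 3) + 3)
  }
  stopifnot(all(pairs$a >= 1), all(pairs$b <= window), all(pairs$a < pairs$b))
  d_ref <- rep_len(d_ref, nrow(pairs))
  if (any(d_ref <= 0)) stop("reference distances must be positive")
  structure(list(window = window, pairs = pairs, d_ref = d_ref, r0 = r0),
            class = "HelicityReference")
}

#' Helicity collective variable over a residue segment
#'
#' For each window position along `segment`, the RMS difference `d` between
#' the observed intra-window distances and the reference distances is passed
#' through the rational switching function
#' `f(d) = (1 - (d/r0)^6) / (1 - (d/r0)^12)`, algebraically identical to
#' `1 / (1 + (d/r0)^6)` -- the form used here, which also supplies the
#' analytic value 1/2 at the `d = r0` singularity of the quotient form. The
#' CV is the sum of the window contributions, so it runs from 0 (no window
#' helical) to the number of windows (all helical).
#'
#' @param segment Integer vector of particle indices (consecutive residues);
#'   must be at least as long as the reference window.
#' @param reference A [helicity_reference()].
#' @return A [collective_variable()] with analytic gradient.
#' @export
helicity_cv <- function(segment, reference) {
  stopifnot(inherits(reference, "HelicityReference"))
  segment <- as.integer(segment)
  L <- reference$window
  if (length(segment) < L) stop("segment shorter than the reference window")
  n_win <- length(segment) - L + 1
  pr <- reference$pairs
  m <- nrow(pr)
  r0 <- reference$r0
  d_ref <- reference$d_ref

  window_terms <- function(X) {
    lapply(seq_len(n_win), function(w) {
      ia <- segment[w + pr$a - 1]
      ib <- segment[w + pr$b - 1]
      dx <- X[ib, , drop = FALSE] - X[ia, , drop = FALSE]
      dist <- sqrt(rowSums(dx^2))
      d <- sqrt(mean((dist - d_ref)^2))
      list(ia = ia, ib = ib, dx = dx, dist = dist, d = d)
    })
  }
  fswitch <- function(d) 1 / (1 + (d / r0)^6)

  value <- function(X) {
    sum(vapply(window_terms(X), function(t) fswitch(t$d), numeric(1)))
  }
  grad <- function(X) {
    G <- matrix(0, nrow(X), ncol(X))
    for (t in window_terms(X)) {
      d <- max(t$d, 1e-12)
      u <- (d / r0)^6
      dfdd <- -6 * u / (d * (1 + u)^2)
      # d(d)/d(dist_k) = (dist_k - d_ref_k) / (m * d)
      ddddist <- (t$dist - d_ref) / (m * d)
      for (k in seq_len(m)) {
        unit <- t$dx[k, ] / max(t$dist[k], 1e-12)
        gk <- dfdd * ddddist[k] * unit
        G[t$ib[k], ] <- G[t$ib[k], ] + gk
        G[t$ia[k], ] <- G[t$ia[k], ] - gk
      }
    }
    G
  }
  collective_variable(value, grad,
                      label = sprintf("helicity[%d windows]", n_win))
}

#' Well-tempered metadynamics on a toy system
#'
#' Overdamped Langevin dynamics augmented with a history-dependent bias on a
#' collective variable: every `pace` steps a Gaussian of width `sigma` and
#' height `w0 * exp(-V_bias(s)/(kB * dT))`, `dT = (gamma - 1) * T`, is
#' deposited at the current CV value, so heights decay where bias has
#' accumulated (well-tempering) and approach the plain-metadynamics constant
#' `w0` as `gamma` grows. The bias force on the coordinates is
#' `-dV_bias/ds * ds/dx` with the bias and its derivative kept on a dense CV
#' grid (each deposit updates the grid; per-step lookup is linear
#' interpolation).
#'
#' @param system A [toy_system()].
#' @param cv A [collective_variable()].
#' @param n_steps Integration steps.
#' @param dt Time step, ps.
#' @param seed Integer seed.
#' @param w0 Initial Gaussian height, kJ/mol (default 1.2).
#' @param sigma Gaussian width in CV units (default 0.02).
#' @param gamma Bias factor (> 1; default 20; 20-30 is the useful range for
#'   barrier heights of a few kBT).
#' @param pace Steps between deposits (default 500).
#' @param record_stride Record CV and bias every this many steps (default
#'   100).
#' @param grid_range CV grid limits `c(lo, hi)`; deposits outside are
#'   clamped to the edge. Defaults to the initial CV value +/- 50 sigma.
#' @param grid_n Grid points (default 1200).
#' @return List with `trajectory` (recorded coordinates as a
#'   [trajectory_ensemble()]), `bias` (class `BiasState`: deposited
#'   Gaussians, grid bias, gamma, temperature, pace, w0), and `cv_series`
#'   (data frame `step`, `time`, `s`, `bias_kJmol`).
#' @export
run_metadynamics <- function(system, cv, n_steps, dt, seed,
                             w0 = 1.2, sigma = 0.02, gamma = 20, pace = 500,
                             record_stride = 100, grid_range = NULL,
                             grid_n = 1200) {
  stopifnot(inherits(system, "ToySystem"),
            inherits(cv, "CollectiveVariable"))
  if (gamma <= 1) stop("bias factor gamma must be > 1")
  if (sigma <= 0) stop("sigma must be > 0")
  stopifnot(pace >= 1, dt > 0, n_steps >= 1)
  set.seed(seed)
  X <- system$positions
  n <- system$n_particles; d <- system$dim
  Tk <- system$temperature
  kbdT <- ak_constants$kB * (gamma - 1) * Tk
  mob <- dt / system$friction
  noise_sd <- sqrt(2 * kBT(Tk) * dt / system$friction)

  s0 <- cv$value(X)
  if (is.null(grid_range)) grid_range <- c(s0 - 50 * sigma, s0 + 50 * sigma)
  grid <- seq(grid_range[1], grid_range[2], length.out = grid_n)
  dxg <- grid[2] - grid[1]
  Vg <- numeric(grid_n)    # bias potential on grid
  dVg <- numeric(grid_n)   # its derivative
  interp <- function(vals, s) {
    s <- min(max(s, grid[1]), grid[grid_n])
    k <- min(max(1L, floor((s - grid[1]) / dxg) + 1L), grid_n - 1L)
    w <- (s - grid[k]) / dxg
    (1 - w) * vals[k] + w * vals[k + 1]
  }

  n_dep <- n_steps %/% pace
  g_step <- integer(n_dep); g_center <- numeric(n_dep)
  g_height <- numeric(n_dep)
  n_rec <- n_steps %/% record_stride
  rec_step <- integer(n_rec); rec_s <- numeric(n_rec); rec_V <- numeric(n_rec)
  coords <- array(NA_real_, c(n_rec, n, d))
  dep <- 0L; rec <- 0L

  for (step in seq_len(n_steps)) {
    ff <- system_forces(system, X)
    s <- cv$value(X)
    dVds <- interp(dVg, s)
    Fb <- if (dVds != 0) -dVds * cv$grad(X) else 0
    X <- X + mob * (ff$forces + Fb) + noise_sd * matrix(stats::rnorm(n * d), n, d)
    if (!all(is.finite(X)))
      stop(sprintf("non-finite coordinates at step %d (bias force blow-up?)", step))
    if (step %% pace == 0L && dep < n_dep) {
      s <- cv$value(X)
      sc <- min(max(s, grid[1]), grid[grid_n])
      h <- w0 * exp(-interp(Vg, sc) / kbdT)
      z <- (grid - sc) / sigma
      gauss <- h * exp(-0.5 * z^2)
      Vg <- Vg + gauss
      dVg <- dVg - gauss * z / sigma
      dep <- dep + 1L
      g_step[dep] <- step; g_center[dep] <- sc; g_height[dep] <- h
    }
    if (step %% record_stride == 0L && rec < n_rec) {
      rec <- rec + 1L
      rec_step[rec] <- step
      rec_s[rec] <- cv$value(X)
      rec_V[rec] <- interp(Vg, rec_s[rec])
      coords[rec, , ] <- X
    }
  }
  bias <- structure(list(
    gaussians = data.frame(step = g_step, center = g_center,
                           sigma = sigma, height = g_height),
    gamma = gamma, temperature = Tk, pace = pace, w0 = w0,
    grid = grid, bias_on_grid = Vg), class = "BiasState")
  list(
    trajectory = trajectory_ensemble(list(coords),
                                     frame_interval = dt * record_stride,
                                     condition_label = "metadynamics",
                                     residue_index = system$residue_index),
    bias = bias,
    cv_series = data.frame(step = rec_step, time = rec_step * dt,
                           s = rec_s, bias_kJmol = rec_V))
}

#' @export
print.BiasState <- function(x, ...) {
  cat(sprintf("BiasState: %d Gaussians (w0 = %g kJ/mol, gamma = %g, pace = %d)\n",
              nrow(x$gaussians), x$w0, x$gamma, x$pace))
  invisible(x)
}

#' Evaluate the deposited bias potential
#'
#' @param bias A `BiasState`.
#' @param s CV values to evaluate at.
#' @return Bias potential, kJ/mol.
#' @export
evaluate_bias <- function(bias, s) {
  g <- bias$gaussians
  out <- numeric(length(s))
  for (k in seq_len(nrow(g))) {
    out <- out + g$height[k] * exp(-0.5 * ((s - g$center[k]) / g$sigma[k])^2)
  }
  out
}

#' Free-energy estimate from a well-tempered bias
#'
#' The standard well-tempered estimator
#' `F(s) = -(gamma / (gamma - 1)) * V_bias(s)`, shifted so the minimum over
#' the grid is zero.
#'
#' @param bias A `BiasState` with at least one deposited Gaussian.
#' @param grid CV values to evaluate on.
#' @return Data frame with `s` and `F_kJmol`.
#' @export
fes_from_bias <- function(bias, grid) {
  stopifnot(inherits(bias, "BiasState"))
  if (bias$gamma <= 1) stop("bias factor gamma must be > 1")
  if (nrow(bias$gaussians) < 1) stop("no Gaussians deposited")
  Fv <- -(bias$gamma / (bias$gamma - 1)) * evaluate_bias(bias, grid)
  data.frame(s = grid, F_kJmol = Fv - min(Fv))
}

#' Count threshold crossings of a CV series
#'
#' Reports transient events as upward crossings of a CV threshold (the series
#' moving from below to at-or-above the threshold).
#'
#' @param cv_series Data frame from [run_metadynamics()] (or any with column
#'   `s`), or a numeric vector.
#' @param threshold CV threshold.
#' @return Number of upward crossings.
#' @export
count_cv_crossings <- function(cv_series, threshold) {
  s <- if (is.data.frame(cv_series)) cv_series$s else as.numeric(cv_series)
  above <- s >= threshold
  sum(!above[-length(above)] & above[-1])
}

#' Write a bias state's Gaussians as TSV
#' @param bias A `BiasState`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias_tsv <- function(bias, path) {
  utils::write.table(bias$gaussians, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
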