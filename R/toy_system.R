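#' Construct a toy bead-chain system
#'
#' A `ToySystem` is the substrate for the overdamped Langevin generator: a set
#' of point particles ("beads", one per residue by default) interacting through
#' analytic pair potentials, optionally subject to an external potential.
#' It stands in for an all-atom protein system so that every downstream
#' analysis stage can be exercised against known physics.
#'
#' @param positions Numeric matrix, `n_particles x dim`, initial coordinates
#'   in nm. `dim` is usually 3 but 1-D systems are allowed for collective
#'   variable toys.
#' @param pairs Data frame of pair potentials with columns `i`, `j`
#'   (1-based particle indices, `i != j`), `form` (one of `"harmonic"`,
#'   `"double_well"`, `"none"`), `k` (spring constant, kJ/mol/nm^2; for
#'   `double_well` the barrier height h in kJ/mol), `r0` (equilibrium /
#'   center distance, nm) and optionally `w` (double-well half-separation,
#'   nm). Each unordered pair may appear once.
#' @param temperature Temperature in K (> 0).
#' @param friction Friction coefficient gamma in kJ/mol*ps/nm^2 (> 0). The
#'   overdamped mobility is 1/gamma and the diffusion constant kBT/gamma.
#' @param residue_index Integer vector of 1-based residue labels per particle;
#'   defaults to `1:n_particles` (one bead per residue).
#' @param external Optional external potential: a list with functions
#'   `energy(X)` returning a scalar (kJ/mol) and `grad(X)` returning the
#'   `n x dim` gradient dU/dx (kJ/mol/nm), both taking the coordinate matrix.
#' @return An object of class `ToySystem`.
#' @seealso [simulate_langevin()], [make_bead_chain()], [make_condition_pair()]
#' @export
toy_system <- function(positions, pairs = NULL, temperature = 300,
                       friction = 1, residue_index = NULL, external = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(n >= 1, all(is.finite(positions)))
  if (temperature <= 0) stop("temperature must be > 0")
  if (friction <= 0) stop("friction must be > 0")
  if (is.null(residue_index)) residue_index <- seq_len(n)
  stopifnot(length(residue_index) == n)
  if (is.null(pairs)) {
    pairs <- data.frame(i = integer(), j = integer(), form = character(),
                        k = numeric(), r0 = numeric(), w = numeric())
  }
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0) {
    stopifnot(all(c("i", "j", "form", "k", "r0") %in% names(pairs)))
    if (is.null(pairs$w)) pairs$w <- NA_real_
    if (any(pairs$i == pairs$j)) stop("self pairs are not allowed")
    if (any(pairs$i < 1 | pairs$j < 1 | pairs$i > n | pairs$j > n))
      stop("pair indices out of range")
    if (any(pairs$k < 0)) stop("spring constants must be >= 0")
    # canonical unordered storage: i < j, no duplicates
    swap <- pairs$i > pairs$j
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
    if (anyDuplicated(pairs[, c("i", "j")]))
      stop("duplicate pair potentials for the same unordered pair")
    stopifnot(all(pairs$form %in% c("harmonic", "double_well", "none")))
  }
  structure(list(
    n_particles = n,
    dim = ncol(positions),
    positions = positions,
    pairs = pairs,
    temperature = temperature,
    friction = friction,
    residue_index = as.integer(residue_index),
    external = external
  ), class = "ToySystem")
}

#' @export
print.ToySystem <- function(x, ...) {
  cat(sprintf("ToySystem: %d particles (%d-D), %d pair potentials, T = %g K\n",
              x$n_particles, x$dim, nrow(x$pairs), x$temperature))
  invisible(x)
}

#' Linear bead chain with harmonic backbone bonds
#'
#' Convenience constructor: `n_particles` beads on a line, consecutive beads
#' bonded harmonically. Next-nearest-neighbour springs (at twice the bond
#' length, with stiffness `k_nn`) can be added to give the chain some
#' persistence, mimicking a loosely structured polypeptide backbone.
#'
#' @param n_particles Number of beads.
#' @param bond_k Bond spring constant, kJ/mol/nm^2.
#' @param bond_r0 Bond length, nm (0.38 nm, the CA-CA distance scale).
#' @param k_nn Next-nearest-neighbour spring constant (0 disables).
#' @param temperature,friction Passed to [toy_system()].
#' @return A `ToySystem`.
#' @export
make_bead_chain <- function(n_particles, bond_k = 1000, bond_r0 = 0.38,
                            k_nn = 100, temperature = 300, friction = 1) {
  stopifnot(n_particles >= 2)
  pos <- cbind(bond_r0 * (seq_len(n_particles) - 1), 0, 0)
  pairs <- data.frame(i = seq_len(n_particles - 1), j = 2:n_particles,
                      form = "harmonic", k = bond_k, r0 = bond_r0,
                      w = NA_real_)
  if (k_nn > 0 && n_particles >= 3) {
    pairs <- rbind(pairs, data.frame(
      i = seq_len(n_particles - 2), j = 3:n_particles,
      form = "harmonic", k = k_nn, r0 = 2 * bond_r0, w = NA_real_))
  }
  toy_system(pos, pairs, temperature = temperature, friction = friction)
}

#' Helix-like bead chain with a distance-cutoff spring network
#'
#' Beads are placed on an ideal helix (radius, rise and twist per residue
#' default to alpha-helical CA geometry) and every bead pair within `cutoff`
#' is connected by a harmonic spring resting at its initial distance --
#' an elastic-network model of a folded segment. Because the springs point
#' in many directions, a planted extra coupling redistributes its load over
#' many network springs instead of a single series path, which is what makes
#' planted allosteric pairs stand out in force-difference networks.
#'
#' @param n_particles Number of beads.
#' @param radius Helix radius, nm.
#' @param rise Rise per residue, nm.
#' @param twist Twist per residue, degrees.
#' @param bond_k Spring constant for consecutive beads, kJ/mol/nm^2.
#' @param network_k Spring constant for other in-cutoff pairs.
#' @param cutoff Network distance cutoff, nm.
#' @param temperature,friction Passed to [toy_system()].
#' @return A `ToySystem`.
#' @export
make_helix_chain <- function(n_particles, radius = 0.23, rise = 0.15,
                             twist = 100, bond_k = 1000, network_k = 300,
                             cutoff = 0.65, temperature = 300, friction = 1) {
  stopifnot(n_particles >= 4)
  ang <- (seq_len(n_particles) - 1) * twist * pi / 180
  pos <- cbind(radius * cos(ang), radius * sin(ang),
               rise * (seq_len(n_particles) - 1))
  pr <- t(utils::combn(n_particles, 2))
  d0 <- sqrt(rowSums((pos[pr[, 2], ] - pos[pr[, 1], ])^2))
  keep <- d0 <= cutoff
  pairs <- data.frame(i = pr[keep, 1], j = pr[keep, 2], form = "harmonic",
                      k = ifelse(pr[keep, 2] - pr[keep, 1] == 1,
                                 bond_k, network_k),
                      r0 = d0[keep], w = NA_real_)
  toy_system(pos, pairs, temperature = temperature, friction = friction)
}

#' One particle in a 1-D double-well external potential
#'
#' U(x) = h * ((x^2 / w^2) - 1)^2: minima at x = -w and x = +w, barrier of
#' height h at x = 0. The standard test bed for enhanced sampling.
#'
#' @param h Barrier height, kJ/mol.
#' @param w Half-separation of the minima, nm.
#' @param x0 Starting coordinate (defaults to the left minimum).
#' @param temperature,friction Passed to [toy_system()].
#' @return A 1-D `ToySystem` with one particle.
#' @export
make_double_well_1d <- function(h, w, x0 = -w, temperature = 300,
                                friction = 10) {
  stopifnot(h > 0, w > 0)
  ext <- list(
    energy = function(X) h * ((X[1, 1]^2 / w^2) - 1)^2,
    grad = function(X) {
      x <- X[1, 1]
      matrix(4 * h * x * (x^2 / w^2 - 1) / w^2, 1, 1)
    },
    params = list(h = h, w = w)
  )
  toy_system(matrix(x0, 1, 1), temperature = temperature,
             friction = friction, external = ext)
}

# Vectorised pair energy derivative dU/dr for all pairs at distances r.
pairs_dUdr <- function(pairs, r) {
  dUdr <- numeric(nrow(pairs))
  h <- pairs$form == "harmonic"
  if (any(h)) dUdr[h] <- pairs$k[h] * (r[h] - pairs$r0[h])
  dw <- pairs$form == "double_well"
  if (any(dw)) {
    u <- (r[dw] - pairs$r0[dw]) / pairs$w[dw]
    dUdr[dw] <- 4 * pairs$k[dw] * u * (u^2 - 1) / pairs$w[dw]
  }
  dUdr
}

# Cartesian forces (n x dim, kJ/mol/nm) and per-pair signed scalar forces
# (+ = repulsive, kJ/mol/nm) at coordinates X for a ToySystem.
system_forces <- function(system, X) {
  n <- system$n_particles
  d <- system$dim
  F <- matrix(0, n, d)
  pairs <- system$pairs
  np <- nrow(pairs)
  scalar <- numeric(np)
  if (np > 0) {
    pi_ <- pairs$i; pj_ <- pairs$j
    dx <- X[pj_, , drop = FALSE] - X[pi_, , drop = FALSE]
    r <- pmax(sqrt(rowSums(dx^2)), 1e-12)
    dUdr <- pairs_dUdr(pairs, r)
    scalar <- -dUdr                         # + = repulsive
    fij <- (-dUdr / r) * dx                 # force on j along i->j
    for (p in seq_len(np)) {
      F[pj_[p], ] <- F[pj_[p], ] + fij[p, ]
      F[pi_[p], ] <- F[pi_[p], ] - fij[p, ]
    }
  }
  if (!is.null(system$external)) {
    F <- F - system$external$grad(X)
  }
  list(forces = F, pair_scalar = scalar)
}

#' Overdamped Langevin (Brownian) dynamics with analytic pair forces
#'
#' Integrates the Euler-Maruyama discretisation of overdamped Langevin
#' dynamics, `dx = (F/gamma) dt + sqrt(2 kBT dt / gamma) xi`, whose stationary
#' distribution is exactly the Boltzmann distribution of the system's
#' potential. Alongside the coordinates, the signed scalar force on every
#' interacting pair (projection of the pair force onto the inter-particle
#' unit vector, positive = repulsive) is recorded at each stored frame, in pN.
#'
#' Stability requires `dt < friction / k_max` where `k_max` is the stiffest
#' effective spring constant in the system; the integrator warns when this
#' bound is violated and aborts (naming the step) if coordinates become
#' non-finite.
#'
#' @param system A [toy_system()].
#' @param n_steps Number of integration steps.
#' @param dt Time step, ps (> 0).
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param stride Store every `stride`-th step (frame 1 is the state after the
#'   first `stride` steps).
#' @param condition_label Label carried into the outputs.
#' @return A list with `trajectory` (a [trajectory_ensemble()] with one
#'   replicate) and `forces` (a [pair_force_series()] over the system's
#'   interacting pairs, pN).
#' @export
simulate_langevin <- function(system, n_steps, dt, seed, stride = 1,
                              condition_label = "toy") {
  stopifnot(inherits(system, "ToySystem"))
  if (dt <= 0) stop("dt must be > 0")
  stopifnot(n_steps >= 1, stride >= 1)
  kmax <- if (nrow(system$pairs) > 0) max(system$pairs$k, 0) else 0
  if (kmax > 0 && dt >= system$friction / kmax) {
    warning(sprintf(
      "dt = %g exceeds the stability bound friction/k_max = %g; expect divergence",
      dt, system$friction / kmax))
  }
  set.seed(seed)
  n <- system$n_particles
  d <- system$dim
  X <- system$positions
  mob <- dt / system$friction
  noise_sd <- sqrt(2 * kBT(system$temperature) * dt / system$friction)
  n_frames <- n_steps %/% stride
  coords <- array(NA_real_, c(n_frames, n, d))
  np <- nrow(system$pairs)
  fmat <- matrix(NA_real_, n_frames, np)
  frame <- 0L
  for (step in seq_len(n_steps)) {
    ff <- system_forces(system, X)
    if (step > 1L && (step - 1L) %% stride == 0L) {
      # X (and ff) is the state after step-1 updates: record it here so the
      # force evaluation is shared with the propagation below
      frame <- frame + 1L
      coords[frame, , ] <- X
      if (np > 0) fmat[frame, ] <- ff$pair_scalar
    }
    X <- X + mob * ff$forces +
      noise_sd * matrix(stats::rnorm(n * d), n, d)
    if (!all(is.finite(X))) {
      stop(sprintf("coordinates diverged (non-finite) at step %d", step))
    }
  }
  if (n_steps %% stride == 0L) {
    frame <- frame + 1L
    coords[frame, , ] <- X
    if (np > 0) fmat[frame, ] <- system_forces(system, X)$pair_scalar
  }
  traj <- trajectory_ensemble(list(coords), frame_interval = dt * stride,
                              condition_label = condition_label,
                              residue_index = system$residue_index)
  forces <- pair_force_series(
    forces_pN = fmat * ak_constants$pN_per_kJmolnm,
    pairs = system$pairs[, c("i", "j"), drop = FALSE],
    replicate = rep(1L, n_frames),
    condition_label = condition_label,
    residue_index = system$residue_index)
  list(trajectory = traj, forces = forces)
}

#' Generate a matched pair of conditions with a planted allosteric pathway
#'
#' Builds the synthetic analogue of a ligand-bound vs ligand-free comparison:
#' condition B equals condition A plus extra harmonic couplings of stiffness
#' `delta_k` along consecutive residues of `planted_path`. The extra springs
#' rest at `rest_scale` times the residues' initial separation, so in
#' condition B they carry a nonzero mean tension at equilibrium while in
#' condition A the same pairs carry no direct force -- the planted pairs are
#' exactly where the time-averaged pair-force difference is largest.
#' Both conditions are simulated as independent replicates with seeds derived
#' from `seed` via [derive_seed()] (counters: replicate r of condition A uses
#' 2r-1, of condition B uses 2r).
#'
#' @param system Base `ToySystem` (condition A).
#' @param planted_path Ordered integer vector of at least 2 residue indices.
#' @param delta_k Extra coupling stiffness, kJ/mol/nm^2 (>= 0; 0 makes the
#'   two conditions statistically exchangeable).
#' @param n_steps,dt,stride Passed to [simulate_langevin()] per replicate.
#' @param n_replicates Replicates per condition.
#' @param seed Master seed.
#' @param rest_scale Rest length of planted springs as a fraction of the
#'   initial inter-residue distance.
#' @return A list with `ensemble_a`, `ensemble_b` (TrajectoryEnsemble),
#'   `forces_a`, `forces_b` (PairForceSeries, replicates concatenated) and
#'   `planted_pairs` (data frame of the planted residue pairs).
#' @export
make_condition_pair <- function(system, planted_path, delta_k, n_steps, dt,
                                n_replicates = 3, seed = 1, stride = 1,
                                rest_scale = 0.8) {
  stopifnot(inherits(system, "ToySystem"))
  planted_path <- as.integer(planted_path)
  if (length(planted_path) < 2) stop("planted_path must list >= 2 residues")
  if (!all(planted_path %in% system$residue_index))
    stop("planted_path residues not present in system")
  if (delta_k < 0) stop("delta_k must be >= 0")

  path_pairs <- data.frame(i = planted_path[-length(planted_path)],
                           j = planted_path[-1])
  swap <- path_pairs$i > path_pairs$j
  tmp <- path_pairs$i[swap]
  path_pairs$i[swap] <- path_pairs$j[swap]; path_pairs$j[swap] <- tmp

  # Condition B: base system plus planted springs (merged into existing pairs
  # if the pair already interacts -- here added as new rows; toy systems keep
  # planted pairs distinct from the backbone).
  sys_b <- system
  if (delta_k > 0) {
    d0 <- sqrt(rowSums((system$positions[path_pairs$j, , drop = FALSE] -
                        system$positions[path_pairs$i, , drop = FALSE])^2))
    extra <- data.frame(i = path_pairs$i, j = path_pairs$j,
                        form = "harmonic", k = delta_k,
                        r0 = rest_scale * d0, w = NA_real_)
    existing <- paste(system$pairs$i, system$pairs$j)
    clash <- paste(extra$i, extra$j) %in% existing
    if (any(clash)) {
      # stiffen existing springs and shift their rest length instead
      for (r in which(clash)) {
        idx <- which(system$pairs$i == extra$i[r] & system$pairs$j == extra$j[r])
        sys_b$pairs$k[idx] <- sys_b$pairs$k[idx] + delta_k
        sys_b$pairs$r0[idx] <- extra$r0[r]
      }
      extra <- extra[!clash, , drop = FALSE]
    }
    pairs_b <- rbind(sys_b$pairs, extra)
    sys_b <- toy_system(system$positions, pairs_b,
                        temperature = system$temperature,
                        friction = system$friction,
                        residue_index = system$residue_index,
                        external = system$external)
  } else {
    # ensure the planted pairs are tracked in both force series even at 0
    sys_b <- system
  }
  # track planted pairs in condition A as zero-force ("none") entries so both
  # series cover the same pair universe
  track <- data.frame(i = path_pairs$i, j = path_pairs$j, form = "none",
                      k = 0, r0 = 0, w = NA_real_)
  add_tracking <- function(sys) {
    existing <- paste(sys$pairs$i, sys$pairs$j)
    new <- track[!(paste(track$i, track$j) %in% existing), , drop = FALSE]
    if (nrow(new) == 0) return(sys)
    toy_system(sys$positions, rbind(sys$pairs, new),
               temperature = sys$temperature, friction = sys$friction,
               residue_index = sys$residue_index, external = sys$external)
  }
  sys_a <- add_tracking(system)
  sys_b <- add_tracking(sys_b)

  run_condition <- function(sys, label, counter_offset) {
    runs <- lapply(seq_len(n_replicates), function(r) {
      simulate_langevin(sys, n_steps, dt,
                        seed = derive_seed(seed, 2L * r + counter_offset),
                        stride = stride, condition_label = label)
    })
    list(
      ensemble = trajectory_ensemble(
        lapply(runs, function(x) x$trajectory$replicates[[1]]),
        frame_interval = dt * stride, condition_label = label,
        residue_index = sys$residue_index),
      forces = concat_force_series(lapply(runs, function(x) x$forces))
    )
  }
  a <- run_condition(sys_a, "condition_A", -1L)
  b <- run_condition(sys_b, "condition_B", 0L)
  list(ensemble_a = a$ensemble, ensemble_b = b$ensemble,
       forces_a = a$forces, forces_b = b$forces,
       planted_pairs = path_pairs)
}
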