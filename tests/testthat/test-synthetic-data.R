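test_that("toy_system validates and canonicalises pair potentials", {
  pos <- cbind(c(0, 0.4, 0.8), 0, 0)
  pairs <- data.frame(i = c(2, 1), j = c(1, 3), form = "harmonic",
                      k = 100, r0 = 0.4)
  sys <- toy_system(pos, pairs)
  expect_true(all(sys$pairs$i < sys$pairs$j))           # canonical order
  expect_error(toy_system(pos, transform(pairs, i = c(1, 1), j = c(1, 3))),
               "self pairs")
  expect_error(toy_system(pos, transform(pairs, j = c(9, 3))), "out of range")
  expect_error(toy_system(pos, pairs[c(1, 1), ]), "duplicate")
  expect_error(toy_system(pos, transform(pairs, k = -1)))
  expect_error(toy_system(pos, temperature = 0))
  expect_error(toy_system(pos, friction = -1))
})

test_that("system forces match analytic derivatives and Newton's third law", {
  pos <- cbind(c(0, 0.5, 0.9), c(0, 0.1, -0.2), c(0, 0, 0.3))
  pairs <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                      form = c("harmonic", "harmonic", "double_well"),
                      k = c(100, 50, 5), r0 = c(0.4, 0.4, 0.8), w = c(NA, NA, 0.2))
  sys <- toy_system(pos, pairs)
  ff <- allokit:::system_forces(sys, pos)
  # total force vanishes for pure pair interactions
  expect_equal(colSums(ff$forces), rep(0, 3), tolerance = 1e-12)
  # numerical gradient of the total pair energy
  energy <- function(X) {
    s <- 0
    for (p in seq_len(nrow(pairs))) {
      r <- sqrt(sum((X[pairs$j[p], ] - X[pairs$i[p], ])^2))
      s <- s + if (pairs$form[p] == "harmonic") {
        0.5 * pairs$k[p] * (r - pairs$r0[p])^2
      } else {
        pairs$k[p] * (((r - pairs$r0[p])^2 / pairs$w[p]^2) - 1)^2
      }
    }
    s
  }
  h <- 1e-6
  num <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    Xp <- pos; Xp[a, b] <- Xp[a, b] + h
    Xm <- pos; Xm[a, b] <- Xm[a, b] - h
    num[a, b] <- -(energy(Xp) - energy(Xm)) / (2 * h)
  }
  expect_equal(ff$forces, num, tolerance = 1e-6)
  # signed scalar: stretched harmonic bond is attractive (negative)
  stretched <- pos; stretched[2, 1] <- 0.6
  sc <- allokit:::system_forces(sys, stretched)$pair_scalar
  expect_lt(sc[1], 0)
  compressed <- pos; compressed[2, 1] <- 0.2
  expect_gt(allokit:::system_forces(sys, compressed)$pair_scalar[1], 0)
})

test_that("simulate_langevin is seeded, strided and guards stability", {
  sys <- make_bead_chain(4)
  r1 <- simulate_langevin(sys, 500, 1e-4, seed = 5, stride = 10)
  r2 <- simulate_langevin(sys, 500, 1e-4, seed = 5, stride = 10)
  expect_identical(r1$trajectory$replicates, r2$trajectory$replicates)
  expect_identical(r1$forces$forces_pN, r2$forces$forces_pN)
  r3 <- simulate_langevin(sys, 500, 1e-4, seed = 6, stride = 10)
  expect_false(identical(r1$trajectory$replicates, r3$trajectory$replicates))
  # frame count and interval
  expect_equal(n_frames(r1$trajectory), 50L)
  expect_equal(r1$trajectory$frame_interval, 1e-3)
  expect_equal(nrow(r1$forces$forces_pN), 50L)
  # stability warning at dt >= friction / k_max (k_max = 1000, friction = 1)
  expect_warning(simulate_langevin(sys, 10, 2e-3, seed = 1), "stability")
  expect_error(simulate_langevin(sys, 10, -1, seed = 1))
})

test_that("Langevin sampling reproduces the Boltzmann distribution (1-D)", {
  # double well, barrier 2 kBT: frequent crossings, known marginal
  sys <- make_double_well_1d(h = 5, w = 0.1, friction = 10)
  run <- simulate_langevin(sys, 2e5, 2.5e-4, seed = 21, stride = 10)
  x <- run$trajectory$replicates[[1]][, 1, 1]
  dens <- boltzmann_density(function(z) 5 * ((z^2 / 0.01) - 1)^2,
                            -0.3, 0.3)
  expect_lt(ks_distance_to_density(x[-(1:1000)], dens), 0.05)
})

test_that("bond-length distribution matches the r^2-Jacobian marginal (3-D)", {
  # two beads, harmonic bond: p(r) ~ r^2 exp(-k (r - r0)^2 / 2 kBT)
  k <- 100; r0 <- 0.38
  sys <- toy_system(rbind(c(0, 0, 0), c(r0, 0, 0)),
                    data.frame(i = 1, j = 2, form = "harmonic", k = k, r0 = r0))
  run <- simulate_langevin(sys, 1e5, 5e-4, seed = 31, stride = 5)
  arr <- run$trajectory$replicates[[1]]
  r <- sqrt(rowSums((arr[, 2, ] - arr[, 1, ])^2))
  beta <- 1 / kBT(300)
  dens <- local({
    x <- seq(0.05, 0.9, length.out = 2001)
    p <- x^2 * exp(-beta * 0.5 * k * (x - r0)^2)
    dx <- x[2] - x[1]
    data.frame(x = x, density = p / (sum((p[-1] + p[-length(p)]) / 2) * dx))
  })
  expect_lt(ks_distance_to_density(r[-(1:500)], dens), 0.05)
})

test_that("make_helix_chain builds a cutoff elastic network at rest", {
  sys <- make_helix_chain(12)
  # every spring rests at its initial distance: zero force at the start
  ff <- allokit:::system_forces(sys, sys$positions)
  expect_equal(max(abs(ff$forces)), 0, tolerance = 1e-10)
  d <- sqrt(rowSums((sys$positions[sys$pairs$j, ] -
                     sys$positions[sys$pairs$i, ])^2))
  expect_true(all(d <= 0.65 + 1e-12))
  expect_true(all(sys$pairs$k[sys$pairs$j - sys$pairs$i == 1] == 1000))
  expect_error(make_helix_chain(3))
})

test_that("make_condition_pair plants pre-tensioned springs in B only", {
  fx <- planted_fixture()
  expect_equal(fx$planted_pairs, data.frame(i = c(4, 9), j = c(9, 14)))
  expect_equal(length(fx$ensemble_a$replicates), 2)
  expect_equal(length(fx$ensemble_b$replicates), 2)
  # both force series track the same pair universe, planted pairs included
  expect_identical(fx$forces_a$pairs, fx$forces_b$pairs)
  key <- paste(fx$forces_a$pairs$i, fx$forces_a$pairs$j)
  idx <- match(paste(fx$planted_pairs$i, fx$planted_pairs$j), key)
  expect_false(anyNA(idx))
  # planted pairs carry no direct force in A, nonzero mean force in B
  expect_equal(max(abs(fx$forces_a$forces_pN[, idx])), 0)
  expect_true(all(abs(colMeans(fx$forces_b$forces_pN[, idx])) > 10))
  # replicates are decorrelated across and within conditions
  expect_false(identical(fx$ensemble_a$replicates[[1]],
                         fx$ensemble_a$replicates[[2]]))
  expect_false(identical(fx$ensemble_a$replicates[[1]],
                         fx$ensemble_b$replicates[[1]]))
  expect_error(make_condition_pair(make_bead_chain(5), c(1, 99), 10,
                                   n_steps = 10, dt = 1e-4), "not present")
  expect_error(make_condition_pair(make_bead_chain(5), 2, 10,
                                   n_steps = 10, dt = 1e-4), ">= 2 residues")
})

test_that("delta_k = 0 makes the two conditions statistically exchangeable", {
  sys <- make_bead_chain(5)
  pair <- make_condition_pair(sys, c(1, 3, 5), delta_k = 0, n_steps = 2000,
                              dt = 5e-5, n_replicates = 2, seed = 9, stride = 5)
  avg_a <- average_pair_forces(pair$forces_a)
  avg_b <- average_pair_forces(pair$forces_b)
  # same physics, different seeds: mean forces close, no planted signal
  g <- difference_network(avg_a, avg_b, threshold = 20)
  expect_equal(nrow(g$edges), 0)
})
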