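ff <- load_default_forcefield()

test_that("soft repulsion matches direct substitution and the cutoff", {
  pos <- matrix(c(1, 1, 1, 1.5, 1, 1), 2, 3, byrow = TRUE)
  res <- conservative_forces(pos, c("W", "W"), ff, 10)
  # |F| = 25 (1 - 0.5/1.0) = 12.5, pushing the beads apart
  expect_equal(res$forces[1, ], c(-12.5, 0, 0))
  expect_equal(res$forces[2, ], c(12.5, 0, 0))
  # beyond the cutoff the force vanishes
  pos2 <- matrix(c(1, 1, 1, 2.2, 1, 1), 2, 3, byrow = TRUE)
  expect_equal(conservative_forces(pos2, c("W", "W"), ff, 10)$forces,
               matrix(0, 2, 3))
  # coincident beads: zero force with a warning, finite energy
  pos3 <- matrix(c(1, 1, 1, 1, 1, 1), 2, 3, byrow = TRUE)
  expect_warning(r3 <- conservative_forces(pos3, c("W", "W"), ff, 10),
                 "coincident")
  expect_equal(r3$forces, matrix(0, 2, 3))
})

test_that("cell-list forces equal the all-pairs and R oracles", {
  set.seed(42)
  for (N in c(60, 200, 500)) {
    L <- if (N <= 200) 6 else 8
    pos <- matrix(runif(3 * N, 0, L), ncol = 3)
    nm <- sample(c("W", "T", "C2", "OH", "AM3"), N, replace = TRUE)
    cell <- conservative_forces(pos, nm, ff, L, method = "cell")
    allp <- conservative_forces(pos, nm, ff, L, method = "allpairs")
    expect_lt(max(abs(cell$forces - allp$forces)), 1e-10)
    expect_lt(abs(cell$virial - allp$virial), 1e-8)
    if (N == 200) {
      o <- brute_conservative(pos, nm, ff, L)
      expect_lt(max(abs(cell$forces - o$forces)), 1e-10)
      expect_lt(abs(cell$virial - o$virial), 1e-7)
    }
    # Newton's third law: forces sum to zero
    expect_lt(max(abs(colSums(cell$forces))), 1e-10)
  }
})

test_that("bonded terms vanish at equilibrium and match finite differences", {
  # bond at r0 and angle at theta0 give zero force
  p <- matrix(c(0, 0, 0, 0.5, 0, 0, 1.0, 0.1, 0), 3, 3, byrow = TRUE)
  bonds <- cbind(1, 2, 0.5)
  expect_equal(bonded_forces(p, bonds, NULL, 10)$forces, matrix(0, 3, 3))
  th <- acos(sum((p[1, ] - p[2, ]) * (p[3, ] - p[2, ])) /
               (sqrt(sum((p[1, ] - p[2, ])^2)) *
                  sqrt(sum((p[3, ] - p[2, ])^2))))
  angs <- matrix(c(1, 2, 3, th), 1, 4)
  expect_equal(max(abs(bonded_forces(p, NULL, angs, 10)$forces)), 0,
               tolerance = 1e-12)

  # analytic forces match central differences on random configurations
  set.seed(7)
  bonds <- cbind(c(1, 2, 3), c(2, 3, 4), c(0.5, 0.6, 0.4))
  angs <- matrix(c(1, 2, 3, 2.0, 2, 3, 4, 2.8), 2, 4, byrow = TRUE)
  worst <- 0
  for (rep in 1:50) {
    p <- matrix(runif(12, 0, 3), 4, 3)
    f <- bonded_forces(p, bonds, angs, 10)$forces
    en <- function(pp) bonded_forces(pp, bonds, angs, 10)$energy
    h <- 1e-6
    for (i in 1:4) for (k in 1:3) {
      pp <- p; pp[i, k] <- p[i, k] + h; e1 <- en(pp)
      pp[i, k] <- p[i, k] - h; e2 <- en(pp)
      worst <- max(worst, abs(f[i, k] + (e1 - e2) / (2 * h)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("collinear angles use the stable small-sine branch", {
  p <- matrix(c(0, 0, 0, 0.5, 0, 0, 1.0, 0, 0), 3, 3, byrow = TRUE)
  angs <- matrix(c(1, 2, 3, pi), 1, 4)
  f <- bonded_forces(p, NULL, angs, 10)$forces
  expect_true(all(is.finite(f)))
  # at theta = theta0 = pi the restoring force is zero
  expect_equal(max(abs(f)), 0, tolerance = 1e-9)
  angs2 <- matrix(c(1, 2, 3, 2.0), 1, 4)
  f2 <- bonded_forces(p, NULL, angs2, 10)$forces
  expect_true(all(is.finite(f2)))
})

test_that("velocity Verlet conserves energy without the thermostat", {
  pos <- matrix(c(1, 1, 1, 1.6, 1, 1), 2, 3, byrow = TRUE)
  vel <- matrix(c(0, 0.1, 0, 0, -0.1, 0), 2, 3, byrow = TRUE)
  res <- setsolv:::cpp_run_dpd(
    pos, vel, c(0L, 0L), c(0, 0), 10, matrix(25, 1, 1), matrix(1, 1, 1),
    0L, 1L, 0.5, 150, integer(0), integer(0), integer(0), numeric(0), 5,
    FALSE, 15.94, 0.929, 1, 3, 5, 8,
    0.01, 10000, 0, 1, 7, 50, FALSE, 23.7, 1, 0.5)
  E <- res$potential + res$kinetic
  # symplectic integrator: bounded O(dt^2) energy oscillation, no drift
  expect_lt(max(E) - min(E), 1e-3 * abs(mean(E)) + 1e-3)
})

test_that("trivial integrations behave: rest stays at rest, seeds reproduce", {
  # zero velocities, no forces: positions unchanged
  pos <- matrix(c(1, 1, 1, 4, 4, 4), 2, 3, byrow = TRUE)
  res <- setsolv:::cpp_run_dpd(
    pos, matrix(0, 2, 3), c(0L, 0L), c(0, 0), 10,
    matrix(0, 1, 1), matrix(1, 1, 1),
    integer(0), integer(0), numeric(0), 150,
    integer(0), integer(0), integer(0), numeric(0), 5,
    FALSE, 15.94, 0.929, 1, 3, 5, 8,
    0.01, 100, 0, 1, 3, 100, FALSE, 23.7, 1, 0.5)
  expect_equal(res$positions, pos)

  # same seed, same inputs: bitwise-identical trajectories
  t1 <- run_simulation(build_system(ff, L = 5, seed = 9),
                       simulation_settings(n_steps = 400,
                                           sample_every = 100, seed = 9))
  t2 <- run_simulation(build_system(ff, L = 5, seed = 9),
                       simulation_settings(n_steps = 400,
                                           sample_every = 100, seed = 9))
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$pressure, t2$pressure)
})

test_that("system construction enforces density, neutrality and momentum", {
  expect_error(build_system(ff, L = 5,
                            salt = list(cation = "Na+", anion = "Cl-",
                                        n_cation = 1, n_anion = 0)),
               "electroneutral")
  expect_error(build_system(ff, L = 5, water = 100), "reduced density")
  sys <- build_system(ff, L = 5, water = 100,
                      allow_density_mismatch = TRUE)
  expect_equal(nrow(sys$positions), 100)
  sys2 <- build_system(ff, L = 5, seed = 3)
  # net momentum zeroed at initialization
  expect_lt(max(abs(colSums(sys2$velocities))),
            1e-8 * nrow(sys2$velocities))
  expect_true(all(sys2$positions >= 0 & sys2$positions < 5))
})

test_that("instability guard aborts runaway integrations", {
  sys <- build_system(ff, L = 5, seed = 1)
  expect_error(run_simulation(sys, simulation_settings(n_steps = 50, dt = 1,
                                                       sample_every = 10,
                                                       seed = 1)),
               "unstable")
})

test_that("thermostat and barostat control their target observables", {
  # NVT: kinetic temperature within 2% of 1 at dt = 0.01
  sys <- build_system(ff, L = 5, seed = 3)
  tr <- run_simulation(sys, simulation_settings(n_steps = 5000,
                                                sample_every = 100,
                                                seed = 3))
  ob <- measure_observables(tr)
  expect_lt(abs(ob$temperature - 1), 0.02)
  # momentum conservation along the run
  vfin <- tr$final$velocities
  expect_lt(max(abs(colSums(vfin))), 1e-6)

  # ideal gas: virial pressure equals rho kT
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("bead1\tbead2\ta\tR", "W\tW\t0.0\t1.000"), tmp)
  ff0 <- load_default_forcefield(tmp)
  tr0 <- run_simulation(build_system(ff0, L = 7, seed = 2),
                        simulation_settings(n_steps = 4000,
                                            sample_every = 100, seed = 2))
  expect_lt(abs(measure_observables(tr0)$pressure - 3.0), 0.1)

  # NPT water at the reference pressure recovers density 3
  trn <- run_simulation(build_system(ff, L = 6, seed = 4),
                        simulation_settings(n_steps = 8000,
                                            sample_every = 100,
                                            ensemble = "NPT",
                                            target_pressure = 23.7,
                                            barostat_tau = 2, seed = 4))
  keep <- trn$steps > 1000
  rho <- nrow(trn$final$positions) / mean(trn$L[keep])^3
  expect_lt(abs(rho - 3), 0.03)
  expect_lt(abs(mean(trn$pressure[keep]) - 23.7), 0.24)
})

test_that("trajectories round-trip through extended XYZ with molecule maps", {
  topo <- load_topology("AMPH4")
  sys <- build_system(ff, L = 5,
                      molecules = list(list(topology = topo, count = 5)),
                      seed = 8)
  tr <- run_simulation(sys, simulation_settings(n_steps = 300,
                                                sample_every = 100,
                                                seed = 8))
  xyz <- tempfile(fileext = ".xyz"); mm <- tempfile(fileext = ".csv")
  write_trajectory_xyz(tr, xyz, mm)
  tr2 <- read_trajectory_xyz(xyz, mm)
  expect_equal(length(tr2$frames), length(tr$frames))
  expect_equal(tr2$frames[[1]], tr$frames[[1]], tolerance = 1e-7)
  expect_identical(tr2$bead_names, tr$bead_names)
  expect_identical(tr2$molecule_id, tr$molecule_id)
  expect_identical(tr2$steps, tr$steps)
})
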