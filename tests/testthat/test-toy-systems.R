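test_that("analytic potentials have the expected landmarks", {
  harm <- toy_system("harmonic", center = c(1, -2), stiffness = 3)
  at_center <- evaluate_potential(c(1, -2), harm)
  expect_identical(at_center$energy, 0)
  expect_true(all(at_center$gradient == 0))

  dw <- toy_system("double-well-1d", barrier = 4.2, half_width = 1)
  expect_equal(evaluate_potential(matrix(0), dw)$energy -
                 evaluate_potential(matrix(1), dw)$energy, 4.2)
  expect_equal(evaluate_potential(matrix(-1), dw)$energy, 0)

  # deepest Mueller-Brown minimum, located by the Newton oracle
  st <- mb_stationary()
  expect_lt(st$min_a$grad_norm, 1e-6)
  expect_equal(st$min_a$point, c(-0.5582, 1.4417), tolerance = 1e-3)
  expect_identical(st$min_a$kind, "minimum")
  expect_identical(st$saddle_1$kind, "saddle")

  expect_error(evaluate_potential(c(1, 2, 3), harm), "dimensionality")
})

test_that("gradients are exact derivatives of every potential kind", {
  set.seed(4)
  specs <- list(
    toy_system("harmonic", center = c(0.5, -1), stiffness = 2.5),
    toy_system("double-well-1d", barrier = 3, tilt = 0.7),
    toy_system("double-well-2d", barrier = 2, k_y = 1.5, tilt = 0.3),
    toy_system("mueller-brown"),
    toy_system("bead-chain", n_beads = 5, k_bond = 8,
               anchors = list(coords = matrix(rnorm(15), 5, 3),
                              k = c(1, 2, 0.5, 1, 3)),
               double_well_bond = list(pair = c(2, 4), barrier = 2,
                                       minima = c(3, 6)),
               contact_wells = list(list(pair = c(1, 5), depth = 3,
                                         width = 1.5, r_eq = 4))))
  for (spec in specs) {
    for (rep in 1:3) {
      x <- matrix(rnorm(spec$n_particles * spec$ndim, sd = 2),
                  spec$n_particles, spec$ndim)
      if (spec$kind == "bead-chain")
        x <- x + row(x) * 3  # keep beads apart
      pe <- evaluate_potential(x, spec)
      fd <- fd_gradient(function(v) evaluate_potential(v, spec)$energy, x)
      expect_equal(as.numeric(pe$gradient), as.numeric(fd),
                   tolerance = 1e-5)
    }
  }
})

test_that("restraint energies follow the harmonic and flat-bottom forms", {
  d <- cv_distance(1, 2)
  fb_up <- restraint("upper-flat-bottom", d, value = 6, k = 5)
  expect_identical(restraint_energy(fb_up, 5)$energy, 0)
  expect_equal(restraint_energy(fb_up, 7)$energy, 2.5)
  fb_lo <- restraint("lower-flat-bottom", d, value = 10, k = 5)
  expect_identical(restraint_energy(fb_lo, 11)$energy, 0)
  expect_equal(restraint_energy(fb_lo, 9)$energy, 2.5)
  h <- restraint("harmonic", d, value = 4.5, k = 10)
  expect_equal(restraint_energy(h, 6)$energy, 0.5 * 10 * 1.5^2)

  ramped <- restraint("harmonic", d, value = 4.5, k = 0,
                      ramp = list(k_start = 0, k_end = 10, duration = 200))
  expect_equal(restraint_k(ramped, 100), 5)
  expect_equal(restraint_k(ramped, 500), 10)  # constant after the ramp
  expect_error(restraint("harmonic", d, value = 1, k = -1), "non-negative")
})

test_that("restraint forces are exact derivatives of restraint energies", {
  set.seed(11)
  rs <- list(
    restraint("harmonic", cv_distance(1, 3), value = 4, k = 2),
    restraint("upper-flat-bottom", cv_distance(1, 2), value = 3, k = 5),
    restraint("lower-flat-bottom", cv_com_distance(1:2, 3:4), value = 6,
              k = 1.5))
  for (rep in 1:5) {
    x <- matrix(rnorm(12, sd = 3), 4, 3)
    re <- pathdyn:::.restraints_energy_grad(rs, x)
    fd <- fd_gradient(function(v)
      pathdyn:::.restraints_energy_grad(rs, v)$energy, x)
    denom <- max(1, max(abs(fd)))
    expect_lt(max(abs(re$gradient - fd)) / denom, 1e-6)
  }
})

test_that("zero-temperature Langevin relaxes a harmonic well monotonically", {
  sys <- toy_system("harmonic", center = c(0, 0), stiffness = 2,
                    temperature = 0, friction = 5, timestep = 0.005)
  tr <- run_langevin(sys, 1000, x0 = matrix(c(2, -1), 1), seed = 1)
  total <- tr$potential_energy + tr$kinetic_energy
  expect_true(all(diff(total) <= 1e-10))
  expect_lt(tr$potential_energy[1000], 1e-6)
})

test_that("Langevin sampling satisfies equipartition in a harmonic well", {
  k <- 2
  sys <- toy_system("harmonic", center = c(0, 0), stiffness = k,
                    temperature = 300, friction = 10, timestep = 0.004)
  tr <- run_langevin(sys, 150000, x0 = matrix(c(0, 0), 1), seed = 2)
  expected <- sim_constants()$kB * 300 / k
  v <- apply(tr$coords[, 1, ], 2, var)
  expect_equal(mean(v), expected, tolerance = 0.05)
})

test_that("Langevin trajectories are bit-identical under a fixed seed", {
  sys <- toy_system("double-well-2d", barrier = 2, temperature = 300,
                    friction = 2, timestep = 0.01)
  t1 <- run_langevin(sys, 500, seed = 33)
  t2 <- run_langevin(sys, 500, seed = 33)
  expect_identical(t1$coords, t2$coords)
})

test_that("frictionless zero-temperature dynamics conserves energy", {
  sys <- toy_system("harmonic", center = c(0, 0), stiffness = 1,
                    temperature = 0, friction = 0, timestep = 0.001)
  tr <- run_langevin(sys, 10000, x0 = matrix(c(1, 0), 1), seed = 1)
  total <- tr$potential_energy + tr$kinetic_energy
  expect_lt(max(total) - min(total), 1e-4)
})

test_that("double-well basin occupancies are Boltzmann-distributed", {
  # modest barrier so spontaneous crossings are frequent
  sys <- toy_system("double-well-1d", barrier = 1, tilt = 0.6,
                    temperature = 300, friction = 2, timestep = 0.01)
  tr <- run_langevin(sys, 2e5, x0 = matrix(-1), seed = 5, stride = 5)
  x <- tr$coords[, 1, 1]
  kT <- sim_constants()$kB * 300
  U <- function(x) (x^2 - 1)^2 + 0.6 * x / 2
  xg <- seq(-3, 3, by = 1e-3)
  w <- exp(-U(xg) / kT)
  p_right <- sum(w[xg >= 0]) / sum(w)
  phat <- mean(x >= 0)
  # 3 standard errors with a conservative effective sample size
  n_eff <- length(x) / 50
  expect_lt(abs(phat - p_right), 3 * sqrt(p_right * (1 - p_right) / n_eff))
})

test_that("two-state loop generation respects basins, noise and planting", {
  spec <- make_two_state_loop(n_beads = 12, seed = 8)
  gen <- generate_two_state_loop(spec, n_frames = 400)
  # symmetric basins: occupancy 50/50 within binomial error (4 sigma)
  p <- mean(gen$labels == "active")
  expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / 400))
  # selection rule recovers exactly the planted set (brute-force check)
  sel <- select_contacts(spec$ref_inactive, spec$ref_active)
  expect_identical(cbind(sel$i, sel$j), unname(spec$planted_pairs))
  expect_gt(nrow(sel), 0)
  # zero noise: every frame equals its generating reference
  spec0 <- make_two_state_loop(n_beads = 12, noise = 0, seed = 8)
  gen0 <- generate_two_state_loop(spec0, n_frames = 20)
  for (f in seq_len(20)) {
    ref <- gen0$references[[gen0$labels[f]]]
    expect_equal(gen0$pool$coords[f, , ], unname(ref))
  }
  # basin depths steer occupancy
  spec_b <- make_two_state_loop(n_beads = 12,
                                basin_depths = c(0, 0.6), seed = 9)
  gen_b <- generate_two_state_loop(spec_b, n_frames = 600)
  kT <- sim_constants()$kB * 300
  p_expect <- 1 / (1 + exp(0.6 / kT))
  expect_lt(abs(mean(gen_b$labels == "active") - p_expect), 0.08)
  # invariant violation is rejected
  expect_error(
    two_state_loop_spec(spec$ref_inactive, spec$ref_active,
                        planted_pairs = rbind(c(1, 2))),
    "crossing invariant")
})
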