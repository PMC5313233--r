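test_that("mean-force estimator is the restrained window average", {
  z <- matrix(rep(c(1.5, -2), each = 10), 10, 2)
  mf <- estimate_mean_force(z, zstar = c(1.5, -2), k = 3)
  expect_equal(mf$force, c(0, 0))
  # k = 1, mean displacement 0.2 A in one component
  z2 <- matrix(c(rep(0.8, 5), rep(0.8, 5)), ncol = 1)
  mf2 <- estimate_mean_force(z2, zstar = 1, k = 1)
  expect_equal(mf2$force, 0.2)
  expect_error(estimate_mean_force(matrix(0, 0, 1), 0, 1), "at least one")
})

test_that("restrained sampling recovers the harmonic closed-form mean force", {
  # analytic well U = a/2 (z - z0)^2 restrained at z*:
  # k <z* - z> -> k a (z* - z0) / (a + k)  (Gaussian-average closed form)
  a <- 2; z0 <- 0; zstar <- 0.5; k <- 1.5
  sys <- toy_system("harmonic", center = z0, stiffness = a,
                    temperature = 300, friction = 5, timestep = 0.005)
  rs <- list(restraint("harmonic", cv_cartesian(1, 1), value = zstar, k = k))
  tr <- run_langevin(sys, 10000, x0 = matrix(z0), restraints = rs, seed = 14)
  samples <- matrix(tr$coords[, 1, 1], ncol = 1)
  mf <- estimate_mean_force(samples, zstar, k)
  expected <- k * a * (zstar - z0) / (a + k)
  expect_lt(abs(mf$force - expected), 2 * max(mf$se, 1e-3))
})

test_that("the target update follows the overdamped equation of motion", {
  st <- string_state(matrix(0, 3, 2), k = 1, friction = 125, mass = 12.011,
                     dt = 0.02)
  expect_equal(update_string(st, matrix(0, 3, 2))$targets, matrix(0, 3, 2))
  # positive force component moves that target down
  f <- matrix(0, 3, 2); f[2, 1] <- 1
  upd <- update_string(st, f)
  expect_lt(upd$targets[2, 1], 0)
  # displacement for a unit force: dt * 418.4 / (gamma * m)
  expect_equal(upd$targets[2, 1], -0.02 * 418.4 / (125 * 12.011))
  expect_error(update_string(st, matrix(0, 2, 2)), "dimensionality")
})

test_that("string reparametrization equalizes CV-space spacing", {
  st <- string_state(matrix(c(0, 1, 4, 0, 0, 0), 3, 2), dt = 1)
  r <- reparametrize_string(st)
  expect_equal(r$targets[, 1], c(0, 2, 4))
  # fixed point on an equidistant string
  st2 <- string_state(cbind(0:4, 0), dt = 1)
  expect_equal(reparametrize_string(st2)$targets, st2$targets,
               tolerance = 1e-12)
  # random strings: new targets sit on the old CV-space polyline, equally
  # spaced in the along-polyline metric (projection oracle)
  set.seed(41)
  mat <- matrix(cumsum(rnorm(16)), 8, 2)
  st3 <- string_state(mat, dt = 1)
  r3 <- reparametrize_string(st3)
  proj <- t(apply(r3$targets, 1, function(p) arc_position_on(mat, p)))
  expect_lt(max(proj[, 1]), 1e-9)
  spacing <- diff(proj[, 2])
  expect_lt(diff(range(spacing)) / mean(spacing), 1e-8)
})

test_that("convergence is declared from the trailing RMSD window", {
  expect_true(check_convergence(rep(2, 30), window = 10, tolerance = 0.01))
  growing <- seq(0, 3, length.out = 30)
  expect_false(check_convergence(growing, window = 10, tolerance = 0.01))
  plateau <- c(seq(0, 1, length.out = 20), rep(1, 15))
  expect_true(check_convergence(plateau, window = 10, tolerance = 1e-9))
  expect_false(check_convergence(plateau, window = 30, tolerance = 1e-9))
  expect_error(check_convergence(rep(0, 5), window = 1, tolerance = 1), ">= 2")
})

test_that("PMF integration is exact on constant-force straight strings", {
  targets <- cbind(seq(0, 3, length.out = 7), 0)  # length L = 3
  zero <- matrix(0, 7, 2)
  expect_true(all(integrate_pmf(targets, zero)$F == 0))
  g <- 1.7
  forces <- cbind(rep(g, 7), 0)   # constant tangential force
  pmf <- integrate_pmf(targets, forces)
  expect_equal(pmf$F[1], 0)
  expect_equal(pmf$F[7], g * 3, tolerance = 1e-10)
  expect_error(integrate_pmf(targets[1, , drop = FALSE],
                             zero[1, , drop = FALSE]), "at least 2")
})

test_that("a converged string with exact mean forces is a fixed point", {
  # straight string through an isotropic harmonic well along its axis:
  # the exact mean force is purely tangential, so one update +
  # reparametrization leaves the geometry unchanged
  a <- 2
  targets <- cbind(seq(-1, 1, length.out = 9), 0)
  forces <- cbind(a * targets[, 1], 0)   # exact gradient of a/2 x^2
  st <- string_state(targets, k = 1, dt = 0.05)
  upd <- reparametrize_string(update_string(st, forces))
  expect_lt(max(abs(upd$targets[, 2])), 1e-12)        # stays on the axis
  expect_lt(max(abs(upd$targets - targets)), 0.05)    # endpoints shrink only
})

test_that("string runs are deterministic under a fixed seed", {
  sys <- toy_system("double-well-2d", barrier = 1.5, temperature = 300,
                    friction = 5, timestep = 0.005)
  cvs <- list(cv_cartesian(1, 1), cv_cartesian(1, 2))
  targets <- cbind(seq(-1, 1, length.out = 6), 0)
  run <- function() run_string_method(sys, targets, cvs, k = 20, stride = 10,
                                      burnin = 10, max_iter = 8, window = 5,
                                      tolerance = 1e-6, final_steps = 50,
                                      seed = 77)
  r1 <- suppressWarnings(run())
  r2 <- suppressWarnings(run())
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$pmf, r2$pmf)
})

test_that("the symmetric double well yields a symmetric PMF", {
  sys <- toy_system("double-well-2d", barrier = 2, k_y = 4,
                    temperature = 300, friction = 5, timestep = 0.005)
  cvs <- list(cv_cartesian(1, 1), cv_cartesian(1, 2))
  targets <- cbind(seq(-1, 1, length.out = 16), 0)
  res <- suppressWarnings(
    run_string_method(sys, targets, cvs, k = 50, stride = 10, burnin = 30,
                      max_iter = 40, window = 10, tolerance = 0.01,
                      final_steps = 1500, seed = 3))
  pmf <- res$pmf$F
  # interior maximum near the midpoint, symmetric ends
  expect_gt(max(pmf), pmf[1] + 0.5)
  expect_lt(abs(which.max(pmf) - 8.5), 2.1)
  expect_lt(abs(pmf[16] - pmf[1]), 0.6)
})
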