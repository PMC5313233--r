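#' Sample a model system with Langevin dynamics
#'
#' Integrates underdamped Langevin dynamics with the BAOAB splitting
#' (velocity half-kick, position half-drift, exact Ornstein-Uhlenbeck
#' friction/noise step, half-drift, half-kick), which gives accurate
#' configurational averages even at large friction.  Forces are the sum of
#' the analytic potential gradient, any restraint forces, and an optional
#' external bias (used by the metadynamics driver).  At zero temperature the
#' noise term vanishes and the integrator reduces to damped dynamics.
#'
#' @param spec A [toy_system()]; supplies temperature, friction, time step
#'   and mass.
#' @param n_steps Number of integration steps (>= 1).
#' @param x0 Initial coordinates (matrix `n_particles x ndim`); defaults to
#'   the potential's natural origin (harmonic center, or zeros).
#' @param restraints List of [restraint()] objects (may be empty).
#' @param bias Optional function `bias(coords)` returning a list with
#'   `energy` and `gradient` (same shape as `coords`).
#' @param seed Integer seed; when `NULL` the current RNG stream is used
#'   (so callers can manage one deterministic stream across stages).
#' @param stride Record every `stride`-th frame. Default 1.
#' @param v0 Optional initial velocities (A/ps); default zero.
#' @return Object of class `md_trajectory`: list with `coords` (array
#'   `frames x n_particles x ndim`), `potential_energy`, `kinetic_energy`,
#'   `times` (ps), `final` (list with coordinates and velocities), `spec`.
#' @examples
#' sys <- toy_system("harmonic", center = 0, stiffness = 1,
#'                   temperature = 0, timestep = 0.01)
#' tr <- run_langevin(sys, 100, x0 = matrix(2), seed = 1)
#' @export
run_langevin <- function(spec, n_steps, x0 = NULL, restraints = list(),
                         bias = NULL, seed = NULL, stride = 1, v0 = NULL) {
  stopifnot(inherits(spec, "toy_system"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  n <- spec$n_particles; d <- spec$ndim
  x <- if (is.null(x0)) .default_x0(spec) else .as_state(x0, spec)
  v <- if (is.null(v0)) matrix(0, n, d) else .as_state(v0, spec)

  dt <- spec$timestep; m <- spec$mass; gam <- spec$friction
  kT <- .kB * spec$temperature
  c1 <- exp(-gam * dt)
  c2 <- sqrt((1 - c1^2) * kT / m * .KCAL)  # A/ps

  force <- function(x, t) {
    pe <- evaluate_potential(x, spec)
    g <- pe$gradient
    e <- pe$energy
    if (length(restraints)) {
      re <- .restraints_energy_grad(restraints, x, t)
      g <- g + re$gradient
      e <- e + re$energy
    }
    if (!is.null(bias)) {
      be <- bias(x)
      g <- g + be$gradient
      e <- e + be$energy
    }
    list(grad = g, energy = e)
  }

  nrec <- floor(n_steps / stride)
  coords <- array(NA_real_, c(nrec, n, d))
  pot <- kin <- times <- numeric(nrec)
  rec <- 0L

  f <- force(x, 0)
  acc_fac <- .KCAL / m
  for (s in seq_len(n_steps)) {
    t_now <- (s - 1) * dt
    v <- v - 0.5 * dt * acc_fac * f$grad
    x <- x + 0.5 * dt * v
    if (kT > 0) {
      v <- c1 * v + c2 * matrix(stats::rnorm(n * d), n, d)
    } else {
      v <- c1 * v
    }
    x <- x + 0.5 * dt * v
    f <- force(x, t_now + dt)
    v <- v - 0.5 * dt * acc_fac * f$grad
    if (!is.finite(f$energy))
      stop("non-finite energy during Langevin integration: step ", s)
    if (s %% stride == 0) {
      rec <- rec + 1L
      coords[rec, , ] <- x
      pot[rec] <- f$energy
      kin[rec] <- 0.5 * m * sum(v^2) / .KCAL
      times[rec] <- s * dt
    }
  }

  structure(list(coords = coords, potential_energy = pot,
                 kinetic_energy = kin, times = times,
                 final = list(coords = x, velocities = v), spec = spec),
            class = "md_trajectory")
}

.default_x0 <- function(spec) {
  n <- spec$n_particles; d <- spec$ndim
  if (spec$kind == "harmonic")
    return(matrix(spec$params$center, 1))
  if (spec$kind == "bead-chain") {
    # extended chain along x
    x <- matrix(0, n, 3)
    x[, 1] <- (seq_len(n) - 1) * spec$params$bond_length
    return(x)
  }
  matrix(0, n, d)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames of %d particle(s) in %dD (%.3g ps)\n",
              dim(x$coords)[1], dim(x$coords)[2], dim(x$coords)[3],
              max(x$times)))
  invisible(x)
}
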