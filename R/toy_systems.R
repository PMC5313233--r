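#' Define an analytic model system for sampling and path finding
#'
#' A toy system bundles an analytic potential energy surface with the
#' parameters of its Langevin dynamics (temperature, friction, time step,
#' particle mass) and a seed.  Five potential kinds are available:
#'
#' * `"harmonic"`: isotropic harmonic well `U = k/2 * |x - center|^2`.
#' * `"double-well-1d"`: quartic double well
#'   `U = barrier * ((x/half_width)^2 - 1)^2 + tilt * x / (2 * half_width)`,
#'   with minima near `x = -half_width` and `x = +half_width` and a barrier of
#'   `barrier` kcal/mol at `x = 0` (exact when `tilt = 0`).
#' * `"double-well-2d"`: the 1d double well in x plus a harmonic channel
#'   `k_y/2 * y^2` in y.
#' * `"mueller-brown"`: the standard three-minimum benchmark surface for
#'   minimum-energy-path methods, in its usual reduced-unit parameterization;
#'   `scale` maps reduced energy to kcal/mol (default 1, i.e. energies are
#'   read as kcal/mol directly).
#' * `"bead-chain"`: a chain of beads in 3D with harmonic bonds of stiffness
#'   `k_bond` (kcal/mol/A^2) at length `bond_length` (A), optional per-bead
#'   harmonic position anchors (`anchors`), an optional double-well bond on a
#'   designated pair (`double_well_bond`, which replaces that pair's plain
#'   bond), optional short-range attractive Gaussian contact wells between
#'   designated pairs (`contact_wells`), and an optional soft double-basin
#'   term attracting the chain to two reference conformations
#'   (`basin_refs`, `basin_coupling`, `basin_softness`).
#'
#' @param kind One of `"harmonic"`, `"double-well-1d"`, `"double-well-2d"`,
#'   `"mueller-brown"`, `"bead-chain"`.
#' @param ... Potential parameters, by kind (see Details above): `stiffness`,
#'   `center`; `barrier`, `half_width`, `tilt`, `k_y`; `scale`; `n_beads`,
#'   `bond_length`, `k_bond`, `anchors`, `double_well_bond`, `basin_refs`,
#'   `basin_coupling`, `basin_softness`.
#' @param temperature Temperature in K (>= 0). Default 300.
#' @param friction Langevin friction in ps^-1 (>= 0; zero gives Hamiltonian
#'   dynamics at zero temperature). Default 1.
#' @param timestep Integration time step in ps (> 0). Default 0.002.
#' @param mass Particle mass in amu (> 0). Default 12.011 (carbon).
#' @param seed Optional integer seed recorded with the system.
#'
#' @return Object of class `toy_system` with fields `kind`, `params`,
#'   `temperature`, `friction`, `timestep`, `mass`, `seed`, `n_particles`,
#'   `ndim`.
#' @seealso [evaluate_potential()], [run_langevin()]
#' @export
toy_system <- function(kind = c("harmonic", "double-well-1d", "double-well-2d",
                                "mueller-brown", "bead-chain"),
                       ...,
                       temperature = 300, friction = 1, timestep = 0.002,
                       mass = 12.011, seed = NULL) {
  kind <- match.arg(kind)
  p <- list(...)
  if (!is.numeric(temperature) || temperature < 0)
    stop("temperature must be >= 0")
  if (friction < 0) stop("friction must be non-negative")
  if (timestep <= 0) stop("timestep must be strictly positive")
  if (mass <= 0) stop("mass must be strictly positive")

  params <- switch(kind,
    "harmonic" = {
      center <- p$center %||% c(0, 0)
      stiffness <- p$stiffness %||% 1
      if (stiffness <= 0) stop("stiffness must be strictly positive")
      list(center = as.numeric(center), stiffness = stiffness)
    },
    "double-well-1d" = {
      list(barrier = p$barrier %||% 3, half_width = p$half_width %||% 1,
           tilt = p$tilt %||% 0)
    },
    "double-well-2d" = {
      ky <- p$k_y %||% 2
      if (ky <= 0) stop("k_y must be strictly positive")
      list(barrier = p$barrier %||% 3, half_width = p$half_width %||% 1,
           tilt = p$tilt %||% 0, k_y = ky)
    },
    "mueller-brown" = list(scale = p$scale %||% 1),
    "bead-chain" = {
      n_beads <- p$n_beads %||% 12
      if (n_beads < 3) stop("bead-chain requires at least 3 beads")
      kb <- p$k_bond %||% 10
      if (kb < 0) stop("k_bond must be non-negative")
      list(n_beads = as.integer(n_beads),
           bond_length = p$bond_length %||% 3.8,
           k_bond = kb,
           anchors = p$anchors,             # list(coords = n x 3, k = scalar)
           double_well_bond = p$double_well_bond, # list(pair, barrier, minima)
           contact_wells = p$contact_wells, # list of (pair, depth, width, r_eq)
           basin_refs = p$basin_refs,       # list of two n x 3 matrices
           basin_coupling = p$basin_coupling %||% 0,
           basin_softness = p$basin_softness %||% 2)
    })

  geom <- switch(kind,
    "harmonic" = c(1L, length(params$center)),
    "double-well-1d" = c(1L, 1L),
    "double-well-2d" = c(1L, 2L),
    "mueller-brown" = c(1L, 2L),
    "bead-chain" = c(params$n_beads, 3L))

  structure(list(kind = kind, params = params, temperature = temperature,
                 friction = friction, timestep = timestep, mass = mass,
                 seed = seed, n_particles = geom[1], ndim = geom[2]),
            class = "toy_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system '%s': %d particle(s) in %dD, T = %g K, gamma = %g ps^-1, dt = %g ps\n",
              x$kind, x$n_particles, x$ndim, x$temperature, x$friction,
              x$timestep))
  invisible(x)
}

# Coerce a state to the n_particles x ndim matrix the system expects.
.as_state <- function(state, spec) {
  if (!is.matrix(state) &&
      length(state) != spec$n_particles * spec$ndim)
    stop(sprintf("state dimensionality (%d values) does not match system (%d x %d)",
                 length(state), spec$n_particles, spec$ndim))
  m <- if (is.matrix(state)) state else
    matrix(state, nrow = spec$n_particles, ncol = spec$ndim, byrow = TRUE)
  if (nrow(m) != spec$n_particles || ncol(m) != spec$ndim)
    stop(sprintf("state dimensionality (%d x %d) does not match system (%d x %d)",
                 nrow(m), ncol(m), spec$n_particles, spec$ndim))
  m
}

# Standard Mueller-Brown parameters (reduced units).
.mb_par <- list(A = c(-200, -100, -170, 15),
                a = c(-1, -1, -6.5, 0.7),
                b = c(0, 0, 11, 0.6),
                cc = c(-10, -10, -6.5, 0.7),
                x0 = c(1, 0, -0.5, -1),
                y0 = c(0, 0.5, 1.5, 1))

.mb_energy_grad <- function(x, y, scale = 1) {
  p <- .mb_par
  dx <- x - p$x0; dy <- y - p$y0
  ex <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$cc * dy^2)
  e <- sum(ex)
  gx <- sum(ex * (2 * p$a * dx + p$b * dy))
  gy <- sum(ex * (p$b * dx + 2 * p$cc * dy))
  list(energy = scale * e, gradient = scale * c(gx, gy))
}

.dw1d_energy_grad <- function(x, barrier, half_width, tilt) {
  u <- x / half_width
  e <- barrier * (u^2 - 1)^2 + tilt * u / 2
  g <- (4 * barrier * u * (u^2 - 1) + tilt / 2) / half_width
  list(energy = e, gradient = g)
}

#' Evaluate a model potential and its analytic gradient
#'
#' @param state Coordinates, either a numeric vector or an
#'   `n_particles x ndim` matrix matching the system geometry.
#' @param spec A [toy_system()].
#' @return List with `energy` (kcal/mol) and `gradient`
#'   (kcal/mol/A, same shape as the state matrix).
#' @examples
#' sys <- toy_system("harmonic", center = c(0, 0), stiffness = 2)
#' evaluate_potential(c(1, 0), sys)$energy  # 1
#' @export
evaluate_potential <- function(state, spec) {
  stopifnot(inherits(spec, "toy_system"))
  m <- .as_state(state, spec)
  p <- spec$params
  out <- switch(spec$kind,
    "harmonic" = {
      d <- m[1, ] - p$center
      list(energy = 0.5 * p$stiffness * sum(d^2),
           gradient = matrix(p$stiffness * d, 1))
    },
    "double-well-1d" = {
      r <- .dw1d_energy_grad(m[1, 1], p$barrier, p$half_width, p$tilt)
      list(energy = r$energy, gradient = matrix(r$gradient, 1))
    },
    "double-well-2d" = {
      r <- .dw1d_energy_grad(m[1, 1], p$barrier, p$half_width, p$tilt)
      list(energy = r$energy + 0.5 * p$k_y * m[1, 2]^2,
           gradient = matrix(c(r$gradient, p$k_y * m[1, 2]), 1))
    },
    "mueller-brown" = {
      r <- .mb_energy_grad(m[1, 1], m[1, 2], p$scale)
      list(energy = r$energy, gradient = matrix(r$gradient, 1))
    },
    "bead-chain" = .bead_chain_energy_grad(m, p))
  out
}

.bead_chain_energy_grad <- function(m, p) {
  n <- nrow(m)
  g <- matrix(0, n, 3)
  e <- 0
  # harmonic bonds along the chain; a double-well bond replaces the plain
  # bond on its pair
  dw_pair <- if (!is.null(p$double_well_bond))
    sort(p$double_well_bond$pair) else c(0L, 0L)
  if (p$k_bond > 0)
    for (i in seq_len(n - 1)) {
      if (i == dw_pair[1] && i + 1 == dw_pair[2]) next
      dvec <- m[i + 1, ] - m[i, ]
      r <- sqrt(sum(dvec^2))
      e <- e + 0.5 * p$k_bond * (r - p$bond_length)^2
      if (r > 0) {
        f <- p$k_bond * (r - p$bond_length) * dvec / r
        g[i + 1, ] <- g[i + 1, ] + f
        g[i, ] <- g[i, ] - f
      }
    }
  if (!is.null(p$contact_wells)) {
    # short-range attractive Gaussian wells between designated pairs:
    # U = -depth * exp(-(r - r_eq)^2 / (2 width^2))
    for (cw in p$contact_wells) {
      i <- cw$pair[1]; j <- cw$pair[2]
      dvec <- m[j, ] - m[i, ]
      r <- sqrt(sum(dvec^2))
      ew <- -cw$depth * exp(-(r - cw$r_eq)^2 / (2 * cw$width^2))
      e <- e + ew
      if (r > 0) {
        dEdr <- -ew * (r - cw$r_eq) / cw$width^2
        f <- dEdr * dvec / r
        g[j, ] <- g[j, ] + f
        g[i, ] <- g[i, ] - f
      }
    }
  }
  if (!is.null(p$anchors)) {
    ka <- rep(p$anchors$k, length.out = n)  # scalar or per-bead stiffness
    ref <- p$anchors$coords
    d <- m - ref
    e <- e + 0.5 * sum(ka * rowSums(d^2))
    g <- g + ka * d
  }
  if (!is.null(p$double_well_bond)) {
    dw <- p$double_well_bond
    i <- dw$pair[1]; j <- dw$pair[2]
    dvec <- m[j, ] - m[i, ]
    r <- sqrt(sum(dvec^2))
    rm <- mean(dw$minima); w <- diff(range(dw$minima)) / 2
    u <- (r - rm) / w
    e <- e + dw$barrier * (u^2 - 1)^2
    dEdr <- 4 * dw$barrier * u * (u^2 - 1) / w
    if (r > 0) {
      f <- dEdr * dvec / r
      g[j, ] <- g[j, ] + f
      g[i, ] <- g[i, ] - f
    }
  }
  if (!is.null(p$basin_refs) && p$basin_coupling > 0) {
    # soft-min of per-basin quadratic attractions:
    # U = -s * log(sum_b exp(-c * msd_b / s)), msd_b mean squared deviation
    s <- p$basin_softness; cc <- p$basin_coupling
    n3 <- length(m)
    msd <- vapply(p$basin_refs, function(rf) sum((m - rf)^2) / n3, 0)
    w <- exp(-cc * msd / s + cc * min(msd) / s)  # stabilized
    e <- e - s * log(sum(w)) + cc * min(msd)
    wn <- w / sum(w)
    for (b in seq_along(p$basin_refs))
      g <- g + wn[b] * (2 * cc / n3) * (m - p$basin_refs[[b]])
  }
  list(energy = e, gradient = g)
}
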