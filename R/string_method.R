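#' State of the finite-temperature string in collective variables
#'
#' Holds the per-image CV target vectors `z*`, the CV restraint constant,
#' and the parameters of the overdamped target evolution: targets move as
#' `z*(t + dt) = z*(t) - dF/dz * dt / (gamma * m)` with the package unit
#' conversion, where the mean force `dF/dz` is estimated from restrained
#' sampling.
#'
#' @param targets Matrix `n_images x n_cv` of CV target values.
#' @param k CV restraint constant, kcal/mol/A^2 (> 0). Default 1.
#' @param friction Evolution friction gamma, ps^-1 (> 0). Default 125.
#' @param mass Effective mass m, amu (> 0). Default 12.011 (carbon).
#' @param dt Evolution time step, ps.
#' @param stride MD steps between target updates. Default 10.
#' @param fixed_endpoints Keep the first and last targets fixed during
#'   evolution. Default `FALSE` (all images evolve).
#' @return Object of class `string_state`.
#' @export
string_state <- function(targets, k = 1, friction = 125, mass = 12.011,
                         dt = NULL, stride = 10, fixed_endpoints = FALSE) {
  targets <- as.matrix(targets)
  if (k <= 0) stop("restraint constant k must be > 0")
  if (friction <= 0) stop("friction must be > 0")
  if (mass <= 0) stop("mass must be > 0")
  structure(list(targets = targets, k = k, friction = friction, mass = mass,
                 dt = dt, stride = as.integer(stride),
                 fixed_endpoints = fixed_endpoints),
            class = "string_state")
}

#' Estimate the mean force on the CV targets from restrained samples
#'
#' With a harmonic CV restraint of constant `k`, the derivative of the free
#' energy with respect to target component `i` is approximated by the
#' window average `k * <z_i* - z_i>` over the instantaneous CV values
#' sampled under the restraint.  Standard errors come from block averaging.
#'
#' @param samples Matrix of sampled CV values (`n_samples x n_cv`), or a
#'   numeric vector for a single CV.
#' @param zstar Target vector (length `n_cv`).
#' @param k Restraint constant, kcal/mol/A^2.
#' @param blocks Number of blocks for the block-averaged standard error.
#'   Default 5.
#' @return Object of class `mean_force`: list with `force`
#'   (kcal/mol/A per component), `se`, `n_samples`.
#' @export
estimate_mean_force <- function(samples, zstar, k, blocks = 5) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 1) stop("mean-force estimation needs at least one sample")
  if (ncol(samples) != length(zstar))
    stop("sample dimensionality does not match the target vector")
  disp <- sweep(-samples, 2, zstar, `+`)   # zstar - z
  force <- k * colMeans(disp)
  if (n >= blocks * 2) {
    idx <- cut(seq_len(n), blocks, labels = FALSE)
    bm <- apply(disp, 2, function(col) tapply(col, idx, mean))
    se <- k * apply(as.matrix(bm), 2, stats::sd) / sqrt(blocks)
  } else {
    se <- k * apply(disp, 2, stats::sd) / sqrt(n)
  }
  structure(list(force = force, se = se, n_samples = n),
            class = "mean_force")
}

#' Evolve the string targets down the mean force
#'
#' Each target vector moves by `-(1 / (gamma * m)) * force * dt`, with
#' forces in kcal/mol/A converted through 1 kcal/mol = 418.4 amu A^2/ps^2
#' so the displacement is in A.  Endpoint targets are held when the string
#' state flags them fixed.
#'
#' @param state A [string_state()].
#' @param forces Matrix `n_images x n_cv` of mean-force components
#'   (kcal/mol/A), or a list of [estimate_mean_force()] results.
#' @return The updated `string_state`.
#' @export
update_string <- function(state, forces) {
  stopifnot(inherits(state, "string_state"))
  if (is.list(forces) && !is.matrix(forces))
    forces <- do.call(rbind, lapply(forces, `[[`, "force"))
  forces <- as.matrix(forces)
  if (!all(dim(forces) == dim(state$targets)))
    stop("force dimensionality does not match the string")
  if (is.null(state$dt)) stop("string state has no evolution time step dt")
  disp <- -forces * state$dt * .KCAL / (state$friction * state$mass)
  new_targets <- state$targets + disp
  if (state$fixed_endpoints) {
    new_targets[1, ] <- state$targets[1, ]
    new_targets[nrow(new_targets), ] <- state$targets[nrow(new_targets), ]
  }
  state$targets <- new_targets
  state
}

#' Reparametrize the string targets to equal spacing in CV space
#'
#' @param state A [string_state()] with >= 3 images.
#' @return The state with targets redistributed at equal arc length along
#'   the piecewise-linear CV-space polyline; endpoints unchanged.
#' @export
reparametrize_string <- function(state) {
  stopifnot(inherits(state, "string_state"))
  mat <- state$targets
  if (nrow(mat) < 3) stop("reparametrization needs at least 3 images")
  out <- .interp_polyline(mat, seq(0, 1, length.out = nrow(mat)))
  out[1, ] <- mat[1, ]
  out[nrow(out), ] <- mat[nrow(mat), ]
  state$targets <- out
  state
}

#' RMSD of a string from a reference string in CV space
#' @param targets,reference Matrices `n_images x n_cv`.
#' @return Scalar RMSD over all target components.
#' @export
string_rmsd <- function(targets, reference) {
  sqrt(mean((as.matrix(targets) - as.matrix(reference))^2))
}

#' Declare string convergence from the RMSD trace
#'
#' The string is converged when the RMSD-from-initial trace has gone
#' asymptotic: the range (max minus min) of the trailing `window` entries
#' is at or below `tolerance`.
#'
#' @param trace Numeric vector of per-update RMSD values (first entry 0).
#' @param window Trailing window length (>= 2).
#' @param tolerance Maximum allowed RMSD range within the window.
#' @return Logical.
#' @export
check_convergence <- function(trace, window, tolerance) {
  if (window < 2) stop("window must be >= 2")
  if (length(trace) < window) stop("trace shorter than the window")
  tail_vals <- utils::tail(trace, window)
  (max(tail_vals) - min(tail_vals)) <= tolerance
}

#' Integrate the potential of mean force along the string
#'
#' The free energy along the normalized arc parameter `alpha` is
#' `F(alpha) = integral of sum_i (dF/dz_i)(dz_i/dalpha) dalpha`, with the
#' path derivatives `dz_i/dalpha` computed by centered differences (forward
#' and backward at the ends) and the integral accumulated by the
#' trapezoidal rule; `F(0) = 0` exactly.
#'
#' @param state A [string_state()] (or plain target matrix).
#' @param forces Matrix `n_images x n_cv` of mean forces (kcal/mol/A).
#' @return Object of class `pmf_profile`: data.frame with columns `alpha`
#'   and `F` (kcal/mol).
#' @export
integrate_pmf <- function(state, forces) {
  targets <- if (inherits(state, "string_state")) state$targets
             else as.matrix(state)
  forces <- as.matrix(forces)
  n <- nrow(targets)
  if (n < 2) stop("PMF integration needs at least 2 images")
  if (!all(dim(forces) == dim(targets)))
    stop("forces must match the string dimensions")
  alpha <- seq(0, 1, length.out = n)
  dzda <- matrix(0, n, ncol(targets))
  dzda[1, ] <- (targets[2, ] - targets[1, ]) / (alpha[2] - alpha[1])
  dzda[n, ] <- (targets[n, ] - targets[n - 1, ]) / (alpha[n] - alpha[n - 1])
  if (n > 2)
    for (i in seq(2, n - 1))
      dzda[i, ] <- (targets[i + 1, ] - targets[i - 1, ]) /
        (alpha[i + 1] - alpha[i - 1])
  integrand <- rowSums(forces * dzda)
  F <- numeric(n)
  for (i in seq(2, n))
    F[i] <- F[i - 1] +
      0.5 * (integrand[i] + integrand[i - 1]) * (alpha[i] - alpha[i - 1])
  structure(data.frame(alpha = alpha, F = F),
            class = c("pmf_profile", "data.frame"))
}

#' Run the finite-temperature string method in collective variables
#'
#' Alternates, for each image of the string: restrained Langevin sampling
#' (`stride` steps after a burn-in), mean-force estimation from the sampled
#' CV values, the overdamped target update, and reparametrization of the
#' string; the RMSD of the targets from their initial values is recorded
#' each update and convergence is declared when that trace goes asymptotic
#' ([check_convergence()]).  A final longer sampling pass at the fixed
#' converged targets provides the mean forces for the PMF integration.
#'
#' @param spec A [toy_system()].
#' @param initial_targets Matrix `n_images x n_cv` of initial CV targets
#'   (typically CV values evaluated along a [zts_minimize()] path).
#' @param cv_specs List of [cv_specs] defining the collective variables.
#' @param k CV restraint constant, kcal/mol/A^2. Default 1.
#' @param friction,mass Eq-of-motion parameters for the target evolution
#'   (ps^-1, amu). Defaults 125 and 12.011.
#' @param stride MD steps per sampling window. Default 10.
#' @param dt Evolution time step; default `stride * spec$timestep`.
#' @param burnin Discarded MD steps after each reparametrization; default
#'   `10 * stride`.
#' @param max_iter Update-iteration cap. Default 200.
#' @param window,tolerance Convergence test parameters
#'   (see [check_convergence()]). Defaults 20 and 0.02.
#' @param reparam_every Reparametrize every this many updates. Default 1.
#' @param final_steps Sampling length of the final PMF pass. Default 2000.
#' @param fixed_endpoints Pin the endpoint targets. Default `FALSE`.
#' @param x0 Optional list of per-image initial coordinates; default: each
#'   image starts at coordinates matching its targets where the CVs are
#'   Cartesian, otherwise at the system origin.
#' @param seed Integer seed driving the single RNG stream of the run.
#' @return List of class `string_result`: `state` (final
#'   [string_state()]), `pmf` ([integrate_pmf()] profile), `trace`
#'   (data.frame update/rmsd), `converged`, `forces` (final mean-force
#'   matrix), `force_se`.
#' @export
run_string_method <- function(spec, initial_targets, cv_specs, k = 1,
                              friction = 125, mass = 12.011, stride = 10,
                              dt = NULL, burnin = NULL, max_iter = 200,
                              window = 20, tolerance = 0.02,
                              reparam_every = 1, final_steps = 2000,
                              fixed_endpoints = FALSE, x0 = NULL,
                              seed = NULL) {
  stopifnot(inherits(spec, "toy_system"))
  initial_targets <- as.matrix(initial_targets)
  n_img <- nrow(initial_targets)
  n_cv <- ncol(initial_targets)
  if (length(cv_specs) != n_cv)
    stop("number of CV specs must match the target dimensionality")
  if (is.null(dt)) dt <- stride * spec$timestep
  if (is.null(burnin)) burnin <- 10L * stride
  if (!is.null(seed)) set.seed(seed)

  state <- string_state(initial_targets, k = k, friction = friction,
                        mass = mass, dt = dt, stride = stride,
                        fixed_endpoints = fixed_endpoints)

  # persistent walker per image
  walkers <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    xi <- if (!is.null(x0)) .as_state(x0[[i]], spec)
          else .init_from_targets(spec, cv_specs, initial_targets[i, ])
    walkers[[i]] <- list(coords = xi, velocities = NULL)
  }

  sample_image <- function(i, targets, n_steps, collect) {
    rs <- lapply(seq_len(n_cv), function(cvi)
      restraint("harmonic", cv_specs[[cvi]], value = targets[i, cvi], k = k))
    tr <- run_langevin(spec, n_steps, x0 = walkers[[i]]$coords,
                       restraints = rs, stride = 1,
                       v0 = walkers[[i]]$velocities)
    walkers[[i]] <<- list(coords = tr$final$coords,
                          velocities = tr$final$velocities)
    if (!collect) return(NULL)
    t(apply(tr$coords, 1, function(fr)
      evaluate_cvs(matrix(fr, nrow = spec$n_particles,
                          ncol = spec$ndim), cv_specs)$values))
  }

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    forces <- matrix(0, n_img, n_cv)
    for (i in seq_len(n_img)) {
      if (burnin > 0) sample_image(i, state$targets, burnin, collect = FALSE)
      z <- sample_image(i, state$targets, stride, collect = TRUE)
      if (n_cv == 1) z <- matrix(z, ncol = 1)
      forces[i, ] <- estimate_mean_force(z, state$targets[i, ], k)$force
    }
    state <- update_string(state, forces)
    if (it %% reparam_every == 0) state <- reparametrize_string(state)
    trace <- c(trace, string_rmsd(state$targets, initial_targets))
    if (length(trace) >= window &&
        check_convergence(c(0, trace), window, tolerance)) {
      converged <- TRUE
      break
    }
  }

  # final PMF pass at fixed targets
  forces <- matrix(0, n_img, n_cv)
  force_se <- matrix(0, n_img, n_cv)
  for (i in seq_len(n_img)) {
    if (burnin > 0) sample_image(i, state$targets, burnin, collect = FALSE)
    z <- sample_image(i, state$targets, final_steps, collect = TRUE)
    if (n_cv == 1) z <- matrix(z, ncol = 1)
    mf <- estimate_mean_force(z, state$targets[i, ], k)
    forces[i, ] <- mf$force
    force_se[i, ] <- mf$se
  }
  pmf <- integrate_pmf(state, forces)

  if (!converged)
    warning("string method hit the iteration cap without convergence")
  structure(list(state = state, pmf = pmf,
                 trace = data.frame(update = seq_along(c(0, trace)) - 1L,
                                    rmsd = c(0, trace)),
                 converged = converged, forces = forces,
                 force_se = force_se),
            class = "string_result")
}

# Best-effort initial coordinates for an image from its CV targets: exact for
# Cartesian CVs, origin otherwise.
.init_from_targets <- function(spec, cv_specs, targets) {
  x <- .default_x0(spec)
  for (ci in seq_along(cv_specs)) {
    cv <- cv_specs[[ci]]
    if (cv$kind == "cartesian-coordinate")
      x[cv$particle, cv$dim] <- targets[ci]
  }
  x
}

#' @export
print.string_result <- function(x, ...) {
  cat(sprintf("string_result: %d images x %d CVs, %s after %d updates\n",
              nrow(x$state$targets), ncol(x$state$targets),
              if (x$converged) "converged" else "NOT converged",
              max(x$trace$update)))
  invisible(x)
}
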