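#' Well-tempered metadynamics parameters
#'
#' @param height Initial hill height h0, kcal/mol (> 0). Default 0.7.
#' @param width Hill width sigma per CV (recycled; > 0). Default 0.1.
#' @param stride Deposition stride in MD steps (>= 1). Default 500.
#' @param bias_temperature Bias temperature in K (> 0). Default 4200.
#' @param temperature System temperature in K. Default 300.
#' @param interpretation How to read `bias_temperature`: `"delta"` treats it
#'   as Delta-T (bias factor `(T + DT)/T`), `"total"` as `T + Delta-T`.
#'   Default `"delta"`.
#' @return Object of class `wt_params` with derived fields `delta_T` and
#'   `bias_factor`.
#' @export
wt_params <- function(height = 0.7, width = 0.1, stride = 500,
                      bias_temperature = 4200, temperature = 300,
                      interpretation = c("delta", "total")) {
  interpretation <- match.arg(interpretation)
  if (height <= 0) stop("hill height must be > 0")
  if (any(width <= 0)) stop("hill width must be > 0")
  if (stride < 1) stop("deposition stride must be >= 1")
  if (bias_temperature <= 0) stop("bias temperature must be > 0")
  delta_T <- if (interpretation == "delta") bias_temperature
             else bias_temperature - temperature
  if (delta_T <= 0) stop("effective Delta-T must be > 0")
  structure(list(height = height, width = width, stride = as.integer(stride),
                 bias_temperature = bias_temperature,
                 temperature = temperature, interpretation = interpretation,
                 delta_T = delta_T,
                 bias_factor = (temperature + delta_T) / temperature),
            class = "wt_params")
}

#' Create an empty hills log
#'
#' The shared record of deposited Gaussian biases: one row per hill with
#' deposition time, walker id, center and width per CV, and the deposited
#' (well-tempered) height.
#'
#' @param n_cv Number of collective variables.
#' @return Zero-row data.frame of class `hills_log` with columns `time`,
#'   `walker`, `center.1..n`, `sigma.1..n`, `height`.
#' @export
hills_log <- function(n_cv = 1) {
  cols <- c(list(time = numeric(), walker = integer()),
            stats::setNames(rep(list(numeric()), n_cv),
                            paste0("center.", seq_len(n_cv))),
            stats::setNames(rep(list(numeric()), n_cv),
                            paste0("sigma.", seq_len(n_cv))),
            list(height = numeric()))
  structure(do.call(data.frame, cols), n_cv = n_cv,
            class = c("hills_log", "data.frame"))
}

.hills_centers <- function(hills) {
  n_cv <- attr(hills, "n_cv")
  as.matrix(hills[, paste0("center.", seq_len(n_cv)), drop = FALSE])
}

.hills_sigmas <- function(hills) {
  n_cv <- attr(hills, "n_cv")
  as.matrix(hills[, paste0("sigma.", seq_len(n_cv)), drop = FALSE])
}

#' Regular grid for accumulated bias energy
#'
#' @param ranges List (one element per CV) of numeric `c(min, max)` ranges.
#' @param spacing Grid spacing in CV units (> 0). Default 0.002.
#' @return Object of class `bias_grid` with per-CV axes and an accumulated
#'   bias array (kcal/mol), initialized to zero.
#' @export
bias_grid <- function(ranges, spacing = 0.002) {
  if (spacing <= 0) stop("grid spacing must be > 0")
  if (!is.list(ranges)) ranges <- list(ranges)
  axes <- lapply(ranges, function(r) seq(r[1], r[2], by = spacing))
  dims <- vapply(axes, length, 0L)
  structure(list(axes = axes, spacing = spacing,
                 values = array(0, dims), clamped = 0L),
            class = "bias_grid")
}

# nearest-node index with clamping; returns list(idx, clamped)
.grid_locate <- function(grid, x) {
  idx <- integer(length(x)); clamped <- FALSE
  for (k in seq_along(x)) {
    ax <- grid$axes[[k]]
    i <- round((x[k] - ax[1]) / grid$spacing) + 1
    if (i < 1 || i > length(ax)) clamped <- TRUE
    idx[k] <- min(max(i, 1), length(ax))
  }
  list(idx = idx, clamped = clamped)
}

#' Deposit a well-tempered Gaussian hill
#'
#' The deposited height follows the well-tempered rule
#' `h = h0 * exp(-V_bias(center) / (kB * Delta-T))`, where `V_bias` is the
#' bias accumulated from all previously deposited hills, evaluated at the
#' new center by exact summation over the log (so the rule is reproducible
#' from the log alone).  The hill is appended to the log and added to the
#' grid.
#'
#' @param cv_values Current CV values (hill center).
#' @param hills A [hills_log()].
#' @param grid A [bias_grid()] or `NULL`.
#' @param params A [wt_params()].
#' @param time Deposition time, ps.
#' @param walker Walker id (integer).
#' @return List with updated `hills`, `grid`, and the deposited `height`.
#' @export
deposit_hill <- function(cv_values, hills, grid, params, time = 0,
                         walker = 1L) {
  stopifnot(inherits(hills, "hills_log"), inherits(params, "wt_params"))
  if (!all(is.finite(cv_values))) stop("CV values must be finite")
  n_cv <- attr(hills, "n_cv")
  if (length(cv_values) != n_cv) stop("CV dimensionality mismatch")
  v_prior <- bias_energy(cv_values, hills = hills)$energy
  h <- params$height * exp(-v_prior / (.kB * params$delta_T))
  sig <- rep(params$width, length.out = n_cv)
  row <- as.data.frame(as.list(c(time = time, walker = walker,
                                 stats::setNames(cv_values,
                                                 paste0("center.", seq_len(n_cv))),
                                 stats::setNames(sig,
                                                 paste0("sigma.", seq_len(n_cv))),
                                 height = h)))
  hills2 <- structure(rbind(as.data.frame(hills), row), n_cv = n_cv,
                      class = c("hills_log", "data.frame"))
  if (!is.null(grid)) grid <- .grid_add_hill(grid, cv_values, sig, h)
  list(hills = hills2, grid = grid, height = h)
}

# Add one Gaussian to the grid (within a 6-sigma cutoff box).
.grid_add_hill <- function(grid, center, sigma, height, cutoff = 6) {
  dims <- dim(grid$values)
  if (is.null(dims)) dims <- length(grid$values)
  nd <- length(grid$axes)
  sel <- vector("list", nd)
  gauss <- vector("list", nd)
  for (k in seq_len(nd)) {
    ax <- grid$axes[[k]]
    keep <- which(abs(ax - center[k]) <= cutoff * sigma[k])
    if (length(keep) == 0) { grid$clamped <- grid$clamped + 1L; return(grid) }
    sel[[k]] <- keep
    gauss[[k]] <- exp(-(ax[keep] - center[k])^2 / (2 * sigma[k]^2))
  }
  if (nd == 1) {
    grid$values[sel[[1]]] <- grid$values[sel[[1]]] + height * gauss[[1]]
  } else if (nd == 2) {
    grid$values[sel[[1]], sel[[2]]] <- grid$values[sel[[1]], sel[[2]]] +
      height * outer(gauss[[1]], gauss[[2]])
  } else {
    stop("bias grids support 1 or 2 CVs")
  }
  grid
}

#' Evaluate the accumulated bias energy (and gradient) at a point
#'
#' Direct mode sums the logged Gaussians exactly and differentiates them
#' analytically; grid mode interpolates the accumulated grid linearly and
#' uses the interpolation slope as the gradient.  The two agree within an
#' interpolation error bounded by the grid spacing.
#'
#' @param cv_values Query point in CV space.
#' @param hills A [hills_log()] (direct mode) or `NULL`.
#' @param grid A [bias_grid()] (grid mode) or `NULL`.  Exactly one of
#'   `hills`/`grid` is used; `hills` wins if both are given.
#' @return List with `energy` (kcal/mol) and `gradient` (per CV).
#' @export
bias_energy <- function(cv_values, hills = NULL, grid = NULL) {
  x <- as.numeric(cv_values)
  if (!is.null(hills)) {
    n_cv <- attr(hills, "n_cv")
    if (length(x) != n_cv) stop("CV dimensionality mismatch")
    if (nrow(hills) == 0)
      return(list(energy = 0, gradient = numeric(n_cv)))
    C <- .hills_centers(hills); S <- .hills_sigmas(hills)
    D <- sweep(C, 2, x, `-`)           # center - x
    ex <- exp(-rowSums((D / S)^2) / 2)
    e <- sum(hills$height * ex)
    grad <- vapply(seq_len(n_cv), function(k)
      sum(hills$height * ex * D[, k] / S[, k]^2), 0)
    return(list(energy = e, gradient = grad))
  }
  if (is.null(grid)) stop("either hills or grid must be supplied")
  .grid_interp(grid, x)
}

# multilinear interpolation with slope gradient
.grid_interp <- function(grid, x) {
  nd <- length(grid$axes)
  i0 <- integer(nd); f <- numeric(nd)
  for (k in seq_len(nd)) {
    ax <- grid$axes[[k]]
    u <- (x[k] - ax[1]) / grid$spacing
    i <- floor(u) + 1
    i <- min(max(i, 1), length(ax) - 1)
    i0[k] <- i
    f[k] <- min(max(u - (i - 1), 0), 1)
  }
  if (nd == 1) {
    v0 <- grid$values[i0[1]]; v1 <- grid$values[i0[1] + 1]
    e <- v0 + f[1] * (v1 - v0)
    g <- (v1 - v0) / grid$spacing
    return(list(energy = e, gradient = g))
  }
  v00 <- grid$values[i0[1], i0[2]]
  v10 <- grid$values[i0[1] + 1, i0[2]]
  v01 <- grid$values[i0[1], i0[2] + 1]
  v11 <- grid$values[i0[1] + 1, i0[2] + 1]
  e <- (1 - f[1]) * (1 - f[2]) * v00 + f[1] * (1 - f[2]) * v10 +
    (1 - f[1]) * f[2] * v01 + f[1] * f[2] * v11
  gx <- ((1 - f[2]) * (v10 - v00) + f[2] * (v11 - v01)) / grid$spacing
  gy <- ((1 - f[1]) * (v01 - v00) + f[1] * (v11 - v10)) / grid$spacing
  list(energy = e, gradient = c(gx, gy))
}

#' Run well-tempered multiple-walker metadynamics
#'
#' Several walkers sample the same system and share one hills log: the run
#' proceeds in rounds of `stride` MD steps; within each round the walkers
#' advance in walker-id order, then deposit their hills in walker-id order,
#' each deposition seeing every hill laid down at earlier times and by
#' lower-id walkers at the same time (a deterministic, synchronous version
#' of shared-bias multiple walkers).  Per-step bias forces on the dynamics
#' are taken from the shared grid.
#'
#' @param spec A [toy_system()].
#' @param cv_specs List of [cv_specs] biased by the metadynamics.
#' @param params A [wt_params()].
#' @param n_walkers Number of walkers. Default 10.
#' @param steps Steps per walker (>= `params$stride`).
#' @param seed Integer seed (one stream drives all walkers).
#' @param grid_ranges Optional list of per-CV `c(min, max)` grid ranges;
#'   default spans the initial walker CV values +/- 3 in CV units.
#' @param grid_spacing Grid spacing. Default 0.002.
#' @param x0 Optional list of per-walker starting coordinates (recycled).
#' @param restraints Optional restraint list applied to every walker.
#' @return List of class `metad_result`: `hills` (shared [hills_log()]),
#'   `grid`, `cv_traj` (list of per-walker CV trajectories, one row per
#'   round), `params`.
#' @export
run_wt_metadynamics <- function(spec, cv_specs, params = wt_params(),
                                n_walkers = 10, steps = 10000, seed = NULL,
                                grid_ranges = NULL, grid_spacing = 0.002,
                                x0 = NULL, restraints = list()) {
  stopifnot(inherits(spec, "toy_system"), inherits(params, "wt_params"))
  if (steps < params$stride) stop("steps must be at least the stride")
  if (!is.null(seed)) set.seed(seed)
  n_cv <- length(cv_specs)

  walkers <- vector("list", n_walkers)
  for (w in seq_len(n_walkers)) {
    xw <- if (!is.null(x0)) .as_state(x0[[((w - 1) %% length(x0)) + 1]], spec)
          else .default_x0(spec)
    walkers[[w]] <- list(coords = xw, velocities = NULL)
  }
  if (is.null(grid_ranges)) {
    z0 <- vapply(walkers, function(wk)
      evaluate_cvs(wk$coords, cv_specs)$values, numeric(n_cv))
    z0 <- matrix(z0, nrow = n_cv)
    grid_ranges <- lapply(seq_len(n_cv), function(k)
      c(min(z0[k, ]) - 3, max(z0[k, ]) + 3))
  }
  grid <- bias_grid(grid_ranges, grid_spacing)
  hills <- hills_log(n_cv)

  bias_fun <- function(coords) {
    cvv <- evaluate_cvs(coords, cv_specs, gradients = TRUE)
    be <- .grid_interp(grid, cvv$values)
    g <- matrix(0, nrow(coords), ncol(coords))
    for (k in seq_len(n_cv)) g <- g + be$gradient[k] * cvv$gradients[[k]]
    list(energy = be$energy, gradient = g)
  }

  n_rounds <- floor(steps / params$stride)
  cv_traj <- lapply(seq_len(n_walkers), function(w)
    matrix(NA_real_, n_rounds, n_cv))

  for (round in seq_len(n_rounds)) {
    for (w in seq_len(n_walkers)) {
      tr <- run_langevin(spec, params$stride, x0 = walkers[[w]]$coords,
                         restraints = restraints, bias = bias_fun,
                         stride = params$stride,
                         v0 = walkers[[w]]$velocities)
      walkers[[w]] <- list(coords = tr$final$coords,
                           velocities = tr$final$velocities)
    }
    t_now <- round * params$stride * spec$timestep
    for (w in seq_len(n_walkers)) {
      z <- evaluate_cvs(walkers[[w]]$coords, cv_specs)$values
      cv_traj[[w]][round, ] <- z
      dep <- deposit_hill(z, hills, grid, params, time = t_now, walker = w)
      hills <- dep$hills
      grid <- dep$grid
    }
  }

  structure(list(hills = hills, grid = grid, cv_traj = cv_traj,
                 params = params, n_walkers = n_walkers),
            class = "metad_result")
}

#' Reconstruct the free energy surface from a hills log
#'
#' In the well-tempered limit the accumulated bias converges to
#' `-Delta-T / (T + Delta-T) * F`, so the surface is recovered as
#' `F = -(T + Delta-T) / Delta-T * V_bias`, shifted so its minimum is 0.
#'
#' @param hills A [hills_log()].
#' @param params The [wt_params()] of the run.
#' @param grid_ranges List of per-CV `c(min, max)` ranges.
#' @param grid_spacing Grid spacing. Default 0.002.
#' @return Object of class `fe_surface`: list with `axes`, `F` (array,
#'   kcal/mol, minimum exactly 0), `params`.
#' @export
reconstruct_fes <- function(hills, params, grid_ranges,
                            grid_spacing = 0.002) {
  stopifnot(inherits(hills, "hills_log"), inherits(params, "wt_params"))
  if (!is.list(grid_ranges)) grid_ranges <- list(grid_ranges)
  axes <- lapply(grid_ranges, function(r) seq(r[1], r[2], by = grid_spacing))
  nd <- length(axes)
  scale <- -(params$temperature + params$delta_T) / params$delta_T
  if (nrow(hills) == 0) {
    F <- array(0, vapply(axes, length, 0L))
    return(structure(list(axes = axes, F = F, params = params),
                     class = "fe_surface"))
  }
  C <- .hills_centers(hills); S <- .hills_sigmas(hills)
  h <- hills$height
  if (nd == 1) {
    x <- axes[[1]]
    V <- vapply(x, function(xi)
      sum(h * exp(-(xi - C[, 1])^2 / (2 * S[, 1]^2))), 0)
    F <- scale * V
  } else if (nd == 2) {
    gx <- vapply(axes[[1]], function(xi)
      exp(-(xi - C[, 1])^2 / (2 * S[, 1]^2)), numeric(nrow(C)))
    gy <- vapply(axes[[2]], function(yi)
      exp(-(yi - C[, 2])^2 / (2 * S[, 2]^2)), numeric(nrow(C)))
    # V[i, j] = sum_k h_k gx[k, i] gy[k, j]
    F <- scale * (t(gx * h) %*% gy)
  } else stop("FES reconstruction supports 1 or 2 CVs")
  F <- F - min(F)
  structure(list(axes = axes, F = F, params = params), class = "fe_surface")
}

#' Free energy difference between two regions of a 1D FES
#'
#' Boltzmann-integrates `exp(-F/kBT)` over two half-lines split at `divide`
#' and returns `-kBT log(Z_right / Z_left)` — the free energy of the right
#' basin relative to the left.
#'
#' @param fes A 1D `fe_surface` from [reconstruct_fes()].
#' @param divide Dividing point on the CV axis.
#' @param temperature Temperature in K; default the FES params temperature.
#' @return Scalar free energy difference, kcal/mol.
#' @export
fes_basin_delta_f <- function(fes, divide = 0,
                              temperature = fes$params$temperature) {
  x <- fes$axes[[1]]
  kT <- .kB * temperature
  w <- exp(-(fes$F - min(fes$F)) / kT)
  zl <- sum(w[x < divide]); zr <- sum(w[x >= divide])
  -kT * log(zr / zl)
}
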