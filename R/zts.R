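#' Schedule for the zero-temperature string method
#'
#' The classic protocol starts from a short string (endpoints plus linear
#' interpolants), runs a fixed number of iterations — each iteration being a
#' fixed number of steepest-descent steps per image followed by
#' reparametrization — then doubles the image count and repeats until the
#' final count is reached, finally extracting a smaller set of equally
#' spaced images.
#'
#' @param start_images Image count of the first stage (>= 2). Default 4.
#' @param final_images Image count of the last stage; must equal
#'   `start_images * 2^k` for integer `k >= 0`. Default 256.
#' @param iterations Iterations per stage. Default 100.
#' @param descent_steps Steepest-descent steps per image per iteration.
#'   Default 20.
#' @param extract Number of equally spaced images extracted at the end
#'   (`NULL` to keep all). Default 32.
#' @param middle_double Insert two images in the central interval at each
#'   doubling (see [double_images()]). Default `FALSE`.
#' @param step_size Steepest-descent step (distance units per unit
#'   gradient). Default 1e-4, suited to steep benchmark surfaces.
#' @return Object of class `zts_schedule`.
#' @export
zts_schedule <- function(start_images = 4, final_images = 256,
                         iterations = 100, descent_steps = 20,
                         extract = 32, middle_double = FALSE,
                         step_size = 1e-4) {
  ratio <- final_images / start_images
  k <- log2(ratio)
  if (start_images < 2 || abs(k - round(k)) > 1e-9 || k < 0)
    stop("final_images must be start_images times a power of two")
  if (!is.null(extract) && extract > final_images)
    stop("extraction count cannot exceed the final image count")
  structure(list(start_images = as.integer(start_images),
                 final_images = as.integer(final_images),
                 iterations = as.integer(iterations),
                 descent_steps = as.integer(descent_steps),
                 extract = if (is.null(extract)) NULL else as.integer(extract),
                 middle_double = middle_double, step_size = step_size),
            class = "zts_schedule")
}

#' Zero-temperature string method: minimum energy path
#'
#' Evolves a string of images toward the minimum energy path of an analytic
#' potential.  Each iteration applies `descent_steps` steps of steepest
#' descent to every movable image and then reparametrizes the string to
#' equal spacing; after `iterations` iterations the image count is doubled
#' and the procedure repeats up to `final_images`, after which `extract`
#' equally spaced images are returned.  Endpoints flagged fixed never move.
#'
#' @param path Initial path ([make_path()]); endpoints should be at or near
#'   local minima.  If it has fewer images than `schedule$start_images` it
#'   is resampled up.
#' @param spec A [toy_system()] supplying the potential.
#' @param schedule A [zts_schedule()].
#' @return List of class `zts_result`: `path` (the extracted MEP),
#'   `full_path` (before extraction), `energies` (per extracted image),
#'   `max_energy_trace` (max image energy after each stage).
#' @export
zts_minimize <- function(path, spec, schedule = zts_schedule()) {
  stopifnot(inherits(path, "tpath"), inherits(spec, "toy_system"),
            inherits(schedule, "zts_schedule"))
  if (nrow(path) != schedule$start_images)
    path <- resample_images(path, schedule$start_images)
  fixed <- attr(path, "fixed_endpoints")
  step <- schedule$step_size
  max_energy_trace <- numeric(0)

  image_energy <- function(mat, i)
    evaluate_potential(path_image(.repath(mat, path), i), spec)$energy

  current <- path
  repeat {
    mat <- unclass(current)
    n <- nrow(mat)
    movable <- if (fixed) seq(2, n - 1) else seq_len(n)
    for (it in seq_len(schedule$iterations)) {
      for (i in movable) {
        x <- path_image(current, i)
        for (s in seq_len(schedule$descent_steps)) {
          pe <- evaluate_potential(x, spec)
          if (!is.finite(pe$energy))
            stop("divergent energy during ZTS descent (image ", i, ")")
          x <- x - step * pe$gradient
        }
        mat[i, ] <- as.numeric(t(x))
      }
      current <- reparametrize(.repath(mat, current))
      mat <- unclass(current)
    }
    e <- vapply(seq_len(n), function(i)
      evaluate_potential(path_image(current, i), spec)$energy, 0)
    max_energy_trace <- c(max_energy_trace, max(e))
    if (n >= schedule$final_images) break
    current <- double_images(current, schedule$middle_double)
    if (nrow(current) > schedule$final_images)
      current <- resample_images(current, schedule$final_images)
  }

  full <- current
  out <- if (!is.null(schedule$extract) && schedule$extract < nrow(full))
    resample_images(full, schedule$extract) else full
  energies <- vapply(seq_len(nrow(out)), function(i)
    evaluate_potential(path_image(out, i), spec)$energy, 0)
  structure(list(path = out, full_path = full, energies = energies,
                 max_energy_trace = max_energy_trace),
            class = "zts_result")
}

#' Locate stationary points of a 2D analytic potential by Newton iteration
#'
#' Newton's method on the analytic gradient with a finite-difference
#' Hessian; classifies the converged point by the Hessian eigenvalues
#' (minimum: both positive; saddle: one negative).  Used as an independent
#' oracle to verify paths produced by the string methods.
#'
#' @param spec A 2D [toy_system()].
#' @param start Numeric length-2 starting point.
#' @param tol Gradient-norm convergence tolerance. Default 1e-10.
#' @param max_iter Maximum Newton steps. Default 200.
#' @return List with `point`, `energy`, `grad_norm`, `kind`
#'   (`"minimum"`, `"saddle"` or `"maximum"`).
#' @export
find_stationary_point <- function(spec, start, tol = 1e-10, max_iter = 200) {
  x <- as.numeric(start)
  h <- 1e-6
  grad <- function(x) as.numeric(evaluate_potential(matrix(x, 1), spec)$gradient)
  for (i in seq_len(max_iter)) {
    g <- grad(x)
    if (sqrt(sum(g^2)) < tol) break
    H <- matrix(0, 2, 2)
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      H[, k] <- (grad(x + e) - grad(x - e)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    x <- x - solve(H, g)
  }
  g <- grad(x)
  H <- matrix(0, 2, 2)
  for (k in 1:2) {
    e <- c(0, 0); e[k] <- h
    H[, k] <- (grad(x + e) - grad(x - e)) / (2 * h)
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  kind <- if (all(ev > 0)) "minimum" else if (all(ev < 0)) "maximum" else "saddle"
  list(point = x, energy = evaluate_potential(matrix(x, 1), spec)$energy,
       grad_norm = sqrt(sum(g^2)), kind = kind)
}

#' Gradient component perpendicular to the path tangent
#'
#' Diagnostic for minimum-energy-path convergence: at every interior image,
#' the potential gradient minus its projection on the local path tangent.
#'
#' @param path A [make_path()] object.
#' @param spec A [toy_system()].
#' @return Numeric vector of perpendicular gradient norms (interior images).
#' @export
perpendicular_gradient_norms <- function(path, spec) {
  mat <- unclass(path)
  n <- nrow(mat)
  out <- numeric(n - 2)
  for (i in seq(2, n - 1)) {
    g <- as.numeric(t(evaluate_potential(path_image(path, i), spec)$gradient))
    tau <- mat[i + 1, ] - mat[i - 1, ]
    tau <- tau / sqrt(sum(tau^2))
    gp <- g - sum(g * tau) * tau
    out[i - 1] <- sqrt(sum(gp^2))
  }
  out
}
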