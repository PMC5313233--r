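#' Reaction coordinate as a signed combination of three distances
#'
#' `RC = d1 - d2 - d3`, the classic phosphotransfer-style coordinate: one
#' breaking distance minus two forming distances.  Signs are fixed by the
#' definition.
#'
#' @param pair1,pair2,pair3 Integer pairs of particle indices defining
#'   `d1`, `d2`, `d3`; the three pairs must be distinct.
#' @return Object of class `reaction_coordinate`.
#' @export
reaction_coordinate <- function(pair1, pair2, pair3) {
  pairs <- list(sort(as.integer(pair1)), sort(as.integer(pair2)),
                sort(as.integer(pair3)))
  key <- vapply(pairs, paste, "", collapse = "-")
  if (anyDuplicated(key)) stop("the three distance pairs must be distinct")
  structure(list(pair1 = as.integer(pair1), pair2 = as.integer(pair2),
                 pair3 = as.integer(pair3)), class = "reaction_coordinate")
}

#' Evaluate the reaction coordinate and its gradient
#'
#' @param coords Conformation matrix (`n x d`).
#' @param rc A [reaction_coordinate()].
#' @param gradient Also return the analytic gradient. Default `FALSE`.
#' @return Scalar RC value (A), or `list(value, gradient)`.
#' @export
rc_value <- function(coords, rc, gradient = FALSE) {
  stopifnot(inherits(rc, "reaction_coordinate"))
  coords <- as.matrix(coords)
  dist_grad <- function(pair, sign) {
    dvec <- coords[pair[1], ] - coords[pair[2], ]
    r <- sqrt(sum(dvec^2))
    if (gradient && r == 0)
      stop("coincident particles in a pair: RC gradient undefined")
    g <- NULL
    if (gradient) {
      g <- matrix(0, nrow(coords), ncol(coords))
      g[pair[1], ] <- sign * dvec / r
      g[pair[2], ] <- -sign * dvec / r
    }
    list(r = r, g = g)
  }
  t1 <- dist_grad(rc$pair1, 1)
  t2 <- dist_grad(rc$pair2, -1)
  t3 <- dist_grad(rc$pair3, -1)
  val <- t1$r - t2$r - t3$r
  if (!gradient) return(val)
  list(value = val, gradient = t1$g + t2$g + t3$g)
}

#' Schedule for reaction-coordinate driving
#'
#' @param targets Strictly monotone numeric vector of RC target values (A).
#' @param k Harmonic restraint constant on the RC, kcal/mol/A^2 (> 0).
#' @param max_iter Minimizer iteration cap per stage. Default 500.
#' @param tol Gradient-norm convergence tolerance. Default 1e-6.
#' @return Object of class `driving_schedule`.
#' @export
driving_schedule <- function(targets, k, max_iter = 500, tol = 1e-6) {
  targets <- as.numeric(targets)
  if (length(targets) > 1) {
    dd <- diff(targets)
    if (!(all(dd > 0) || all(dd < 0)))
      stop("RC targets must be strictly monotone")
  }
  if (k <= 0) stop("RC restraint constant must be > 0")
  structure(list(targets = targets, k = k, max_iter = as.integer(max_iter),
                 tol = tol), class = "driving_schedule")
}

#' Drive a system along a reaction coordinate by restrained minimization
#'
#' Starting from a minimized reactant structure, each schedule stage
#' minimizes `U(x) + k/2 * (RC(x) - target)^2` (BFGS with the analytic
#' gradient) from the previous stage's optimum, emitting the optimized
#' state, achieved RC and potential energy per stage.  A minimizer failure
#' returns the stages completed so far with the failing index.
#'
#' @param spec A [toy_system()].
#' @param rc A [reaction_coordinate()].
#' @param schedule A [driving_schedule()] (zero-length target list is
#'   allowed and returns only the optimized initial state).
#' @param x0 Initial coordinates; default the system origin.
#' @return Object of class `driving_result`: list with `profile`
#'   (data.frame `stage`, `target`, `rc`, `energy`), `states` (list of
#'   conformations; element 1 is the optimized initial state),
#'   `failure_index` (`NA` if all stages succeeded).
#' @export
drive_reaction <- function(spec, rc, schedule, x0 = NULL) {
  stopifnot(inherits(spec, "toy_system"),
            inherits(rc, "reaction_coordinate"),
            inherits(schedule, "driving_schedule"))
  x <- if (is.null(x0)) .default_x0(spec) else .as_state(x0, spec)
  shape <- dim(x)

  minimize <- function(x, target = NULL) {
    fn <- function(v) {
      m <- matrix(v, shape[1], shape[2])
      e <- evaluate_potential(m, spec)$energy
      if (!is.null(target))
        e <- e + 0.5 * schedule$k * (rc_value(m, rc) - target)^2
      e
    }
    gr <- function(v) {
      m <- matrix(v, shape[1], shape[2])
      g <- evaluate_potential(m, spec)$gradient
      if (!is.null(target)) {
        rcv <- rc_value(m, rc, gradient = TRUE)
        g <- g + schedule$k * (rcv$value - target) * rcv$gradient
      }
      as.numeric(g)
    }
    opt <- stats::optim(as.numeric(x), fn, gr, method = "BFGS",
                        control = list(maxit = schedule$max_iter,
                                       reltol = 1e-14))
    list(x = matrix(opt$par, shape[1], shape[2]),
         converged = opt$convergence == 0,
         grad_norm = sqrt(sum(gr(opt$par)^2)))
  }

  init <- minimize(x)
  states <- list(init$x)
  prof <- data.frame(stage = 0L, target = NA_real_,
                     rc = rc_value(init$x, rc),
                     energy = evaluate_potential(init$x, spec)$energy)
  failure <- NA_integer_
  xcur <- init$x
  for (s in seq_along(schedule$targets)) {
    res <- minimize(xcur, schedule$targets[s])
    if (!res$converged && res$grad_norm > schedule$tol * 100) {
      failure <- s
      break
    }
    xcur <- res$x
    states[[length(states) + 1]] <- xcur
    prof <- rbind(prof, data.frame(stage = s, target = schedule$targets[s],
                                   rc = rc_value(xcur, rc),
                                   energy = evaluate_potential(xcur,
                                                               spec)$energy))
  }
  structure(list(profile = prof, states = states, failure_index = failure),
            class = "driving_result")
}

#' @export
print.driving_result <- function(x, ...) {
  n <- nrow(x$profile) - 1
  cat(sprintf("driving_result: %d stage(s)%s; RC %.3f -> %.3f A\n", n,
              if (is.na(x$failure_index)) "" else
                sprintf(" (failed at stage %d)", x$failure_index),
              x$profile$rc[1], x$profile$rc[nrow(x$profile)]))
  invisible(x)
}
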