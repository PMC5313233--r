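#' Define a restraint on a collective variable
#'
#' Three kinds are supported. A harmonic restraint contributes
#' `k/2 * (v - value)^2` everywhere.  Flat-bottom (half-harmonic) restraints
#' contribute exactly zero inside their allowed region and `k/2 *
#' (v - value)^2` outside it: an upper flat bottom activates when the
#' quantity exceeds the threshold, a lower flat bottom when it drops below.
#' The force constant may follow a linear ramp in time (`k` interpolates
#' from `ramp$k_start` to `ramp$k_end` over `ramp$duration` ps and is
#' constant afterwards).
#'
#' @param kind `"harmonic"`, `"lower-flat-bottom"` or `"upper-flat-bottom"`.
#' @param target A [cv_specs] object naming the restrained quantity (e.g.
#'   [cv_distance()]).
#' @param value Equilibrium value (harmonic) or threshold (flat-bottom), A.
#' @param k Force constant, kcal/mol/A^2 (>= 0).
#' @param ramp Optional list `(k_start, k_end, duration)` describing a linear
#'   force-constant ramp; overrides `k` during evaluation.
#' @return Object of class `restraint`.
#' @export
restraint <- function(kind = c("harmonic", "lower-flat-bottom",
                               "upper-flat-bottom"),
                      target, value, k, ramp = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(target, "cv_spec"))
  if (k < 0) stop("force constant must be non-negative")
  if (!is.null(ramp)) {
    stopifnot(all(c("k_start", "k_end", "duration") %in% names(ramp)))
    if (ramp$k_start < 0 || ramp$k_end < 0)
      stop("force constant must be non-negative")
    if (ramp$duration <= 0) stop("ramp duration must be positive")
  }
  structure(list(kind = kind, target = target, value = value, k = k,
                 ramp = ramp), class = "restraint")
}

#' Effective force constant of a restraint at a given time
#'
#' @param r A [restraint()].
#' @param time Simulation time in ps.
#' @return Force constant in kcal/mol/A^2.
#' @export
restraint_k <- function(r, time = 0) {
  if (is.null(r$ramp)) return(r$k)
  f <- min(max(time / r$ramp$duration, 0), 1)
  r$ramp$k_start + f * (r$ramp$k_end - r$ramp$k_start)
}

#' Restraint energy and force on the restrained quantity
#'
#' @param r A [restraint()].
#' @param value Current value of the restrained quantity (A).
#' @param time Simulation time in ps (used for ramped force constants).
#' @return List with `energy` (kcal/mol) and `dEdv`, the derivative of the
#'   energy with respect to the restrained quantity (kcal/mol/A); the force
#'   on the quantity is `-dEdv`.
#' @examples
#' fb <- restraint("upper-flat-bottom", cv_distance(1, 2), value = 6, k = 5)
#' restraint_energy(fb, 7)$energy  # 2.5
#' @export
restraint_energy <- function(r, value, time = 0) {
  stopifnot(inherits(r, "restraint"))
  k <- restraint_k(r, time)
  d <- value - r$value
  active <- switch(r$kind,
    "harmonic" = TRUE,
    "upper-flat-bottom" = d > 0,
    "lower-flat-bottom" = d < 0)
  if (!active) return(list(energy = 0, dEdv = 0))
  list(energy = 0.5 * k * d^2, dEdv = k * d)
}

# Total restraint energy and coordinate-space gradient for a conformation.
.restraints_energy_grad <- function(restraints, coords, time = 0) {
  e <- 0
  g <- matrix(0, nrow(coords), ncol(coords))
  for (r in restraints) {
    v <- cv_value(r$target, coords)
    re <- restraint_energy(r, v, time)
    e <- e + re$energy
    if (re$dEdv != 0)
      g <- g + re$dEdv * cv_gradient(r$target, coords)
  }
  list(energy = e, gradient = g)
}
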