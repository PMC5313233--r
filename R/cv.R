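#' Collective variable definitions
#'
#' Constructors for the four CV kinds supported by the toolkit: a single
#' Cartesian coordinate component, an interatomic distance, a distance
#' between centers of mass of two particle groups, and a contact-map
#' distance to a named reference state.  All CVs evaluate to a finite scalar
#' for any finite conformation and carry analytic gradients.
#'
#' @param particle,dim For `cv_cartesian`: particle index and coordinate
#'   component (1 = x, ...).
#' @param i,j For `cv_distance`: the two particle indices.
#' @param group1,group2 For `cv_com_distance`: integer vectors of particle
#'   indices.
#' @param spec For `cv_contact_map`: a [contact_map_spec()].
#' @param reference Which reference state's `d0` column to use
#'   (`"inactive"` or `"active"`).
#' @param variant `"literal"` (square root of the summed switching terms;
#'   maximal at the reference) or `"squared-difference"` (root-sum-square of
#'   switching-term deviations from 1; zero at the reference).
#' @return An object of class `cv_spec`.
#' @seealso [cv_value()], [evaluate_cvs()], [contact_map_value()]
#' @name cv_specs
NULL

#' @rdname cv_specs
#' @export
cv_cartesian <- function(particle, dim = 1) {
  structure(list(kind = "cartesian-coordinate", particle = as.integer(particle),
                 dim = as.integer(dim)), class = "cv_spec")
}

#' @rdname cv_specs
#' @export
cv_distance <- function(i, j) {
  structure(list(kind = "interatomic-distance", i = as.integer(i),
                 j = as.integer(j)), class = "cv_spec")
}

#' @rdname cv_specs
#' @export
cv_com_distance <- function(group1, group2) {
  structure(list(kind = "com-distance", group1 = as.integer(group1),
                 group2 = as.integer(group2)), class = "cv_spec")
}

#' @rdname cv_specs
#' @export
cv_contact_map <- function(spec, reference = c("inactive", "active"),
                           variant = c("literal", "squared-difference")) {
  stopifnot(inherits(spec, "contact_map_spec"))
  structure(list(kind = "contact-map-distance", cmap = spec,
                 reference = match.arg(reference),
                 variant = match.arg(variant)), class = "cv_spec")
}

.check_indices <- function(idx, coords) {
  if (any(idx < 1) || any(idx > nrow(coords)))
    stop("particle index out of range for this conformation")
}

#' Evaluate one collective variable
#'
#' @param cv A `cv_spec`.
#' @param coords Conformation as an `n x d` coordinate matrix (A).
#' @return Scalar CV value (A, or unitless for contact-map CVs).
#' @export
cv_value <- function(cv, coords) {
  stopifnot(inherits(cv, "cv_spec"))
  coords <- as.matrix(coords)
  switch(cv$kind,
    "cartesian-coordinate" = {
      .check_indices(cv$particle, coords)
      coords[cv$particle, cv$dim]
    },
    "interatomic-distance" = {
      .check_indices(c(cv$i, cv$j), coords)
      sqrt(sum((coords[cv$i, ] - coords[cv$j, ])^2))
    },
    "com-distance" = {
      .check_indices(c(cv$group1, cv$group2), coords)
      c1 <- colMeans(coords[cv$group1, , drop = FALSE])
      c2 <- colMeans(coords[cv$group2, , drop = FALSE])
      sqrt(sum((c1 - c2)^2))
    },
    "contact-map-distance" =
      contact_map_value(coords, cv$cmap, cv$reference, cv$variant))
}

#' Analytic gradient of one collective variable
#'
#' @inheritParams cv_value
#' @return Matrix of the same shape as `coords` with d(CV)/d(coordinate).
#' @export
cv_gradient <- function(cv, coords) {
  stopifnot(inherits(cv, "cv_spec"))
  coords <- as.matrix(coords)
  g <- matrix(0, nrow(coords), ncol(coords))
  switch(cv$kind,
    "cartesian-coordinate" = {
      g[cv$particle, cv$dim] <- 1
      g
    },
    "interatomic-distance" = {
      dvec <- coords[cv$i, ] - coords[cv$j, ]
      r <- sqrt(sum(dvec^2))
      if (r == 0) stop("coincident particles: distance gradient undefined")
      g[cv$i, ] <- dvec / r
      g[cv$j, ] <- -dvec / r
      g
    },
    "com-distance" = {
      c1 <- colMeans(coords[cv$group1, , drop = FALSE])
      c2 <- colMeans(coords[cv$group2, , drop = FALSE])
      dvec <- c1 - c2
      r <- sqrt(sum(dvec^2))
      if (r == 0) stop("coincident centers of mass: gradient undefined")
      u <- dvec / r
      for (p in cv$group1) g[p, ] <- g[p, ] + u / length(cv$group1)
      for (p in cv$group2) g[p, ] <- g[p, ] - u / length(cv$group2)
      g
    },
    "contact-map-distance" =
      contact_map_value(coords, cv$cmap, cv$reference, cv$variant,
                        gradient = TRUE)$gradient)
}

#' Evaluate an ordered list of collective variables
#'
#' @param coords Conformation matrix (`n x d`).
#' @param specs List of `cv_spec` objects.
#' @param gradients If `TRUE`, also return the per-CV gradient matrices.
#' @return Object of class `cv_vector`: list with `values` (numeric, ordered
#'   as `specs`) and, when requested, `gradients` (list of matrices).
#' @export
evaluate_cvs <- function(coords, specs, gradients = FALSE) {
  stopifnot(all(vapply(specs, inherits, TRUE, "cv_spec")))
  coords <- as.matrix(coords)
  vals <- vapply(specs, cv_value, 0, coords = coords)
  out <- list(values = vals)
  if (gradients) out$gradients <- lapply(specs, cv_gradient, coords = coords)
  structure(out, class = "cv_vector")
}

#' Rational switching term of the contact-map metric
#'
#' Computes `(1 - x^6) / (1 - x^12)` with `x = (r - d0) / r0`, evaluated
#' through the singularity-free equivalent form `1 / (1 + x^6)`, which is
#' identical everywhere including the removable singularity at `x = 1`.
#' The value lies in (0, 1], equals 1 at `r = d0`, and decreases smoothly
#' away from the reference distance.
#'
#' @param r Distance(s) in A (vectorized).
#' @param d0 Reference distance in A.
#' @param r0 Switching radius in A (> 0). Default 8.
#' @return Switching value(s) in (0, 1].
#' @examples
#' switching_term(8, d0 = 8)            # 1
#' switching_term(16, d0 = 8, r0 = 8)   # 0.5 at x = 1
#' @export
switching_term <- function(r, d0, r0 = 8) {
  if (r0 <= 0) stop("r0 must be strictly positive")
  x6 <- ((r - d0) / r0)^6
  1 / (1 + x6)
}

# d/dr of switching_term
.switching_deriv <- function(r, d0, r0) {
  x <- (r - d0) / r0
  -6 * x^5 / (r0 * (1 + x^6)^2)
}

#' Specify a contact map
#'
#' A contact map is a set of particle pairs, each with a reference distance
#' `d0` per named reference state and a common switching radius `r0`.
#'
#' @param pairs Two-column integer matrix of particle pairs.
#' @param d0 Matrix (or data.frame) with one row per pair and columns named
#'   by reference state (default states `"inactive"`, `"active"`), in A.
#' @param r0 Switching radius in A (> 0). Default 8.
#' @return Object of class `contact_map_spec`.
#' @export
contact_map_spec <- function(pairs, d0, r0 = 8) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  d0 <- as.matrix(d0)
  if (r0 <= 0) stop("r0 must be strictly positive")
  if (nrow(d0) != nrow(pairs))
    stop("d0 must have exactly one row per pair")
  if (is.null(colnames(d0)))
    stop("d0 columns must be named by reference state")
  structure(list(pairs = pairs, d0 = d0, r0 = r0),
            class = "contact_map_spec")
}

#' Contact-map distance of a conformation to a reference state
#'
#' The literal variant returns the square root of the summed switching terms
#' over all pairs: it is maximal (sqrt of the pair count) when every pair sits
#' at its reference distance, i.e. it measures similarity to the reference.
#' The squared-difference variant returns the root-sum-square of
#' `switching(r) - 1` (the switching term evaluated at the reference distance
#' is identically 1), a true distance that is 0 at the reference.
#'
#' @param coords Conformation matrix (`n x 3`).
#' @param spec A [contact_map_spec()].
#' @param reference Name of the reference state (a column of `spec$d0`).
#' @param variant `"literal"` or `"squared-difference"`.
#' @param gradient If `TRUE`, return a list with `value` and `gradient`.
#' @return Scalar value, or list(value, gradient) when `gradient = TRUE`.
#' @export
contact_map_value <- function(coords, spec,
                              reference = c("inactive", "active"),
                              variant = c("literal", "squared-difference"),
                              gradient = FALSE) {
  stopifnot(inherits(spec, "contact_map_spec"))
  variant <- match.arg(variant)
  coords <- as.matrix(coords)
  if (length(reference) > 1) reference <- reference[1]
  if (!reference %in% colnames(spec$d0))
    stop(sprintf("unknown reference state '%s'", reference))
  d0 <- spec$d0[, reference]
  i <- spec$pairs[, 1]; j <- spec$pairs[, 2]
  dvec <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  s <- switching_term(r, d0, spec$r0)
  if (variant == "literal") {
    val <- sqrt(sum(s))
    if (!gradient) return(val)
    # dval/dr_p = s'(r_p) / (2 val)
    w <- .switching_deriv(r, d0, spec$r0) / (2 * val)
  } else {
    dev <- s - 1
    val <- sqrt(sum(dev^2))
    if (!gradient) return(val)
    if (val == 0) {
      return(list(value = 0, gradient = matrix(0, nrow(coords), ncol(coords))))
    }
    w <- dev * .switching_deriv(r, d0, spec$r0) / val
  }
  g <- matrix(0, nrow(coords), ncol(coords))
  unit <- dvec / r
  for (p in seq_along(r)) {
    g[i[p], ] <- g[i[p], ] + w[p] * unit[p, ]
    g[j[p], ] <- g[j[p], ] - w[p] * unit[p, ]
  }
  list(value = val, gradient = g)
}

#' Select contact pairs that distinguish two reference conformations
#'
#' A candidate pair is selected when its distances in the two conformations
#' straddle the switching radius (one side below `r0`, the other above) and
#' the larger of the two distances is at least `ratio` times the smaller.
#' By default candidate pairs exclude bonded chain neighbours
#' (`|i - j| <= exclude_bonded`).
#'
#' @param conf_a,conf_b Conformation matrices sharing the same particle set.
#' @param candidates Optional two-column matrix of candidate pairs; default
#'   is all unordered pairs subject to the bonded-neighbour exclusion.
#' @param r0 Crossing threshold in A. Default 8.
#' @param ratio Minimum larger/smaller distance ratio. Default 1.5.
#' @param exclude_bonded Exclude pairs with `|i - j|` at or below this value
#'   when building the default candidate set. Default 2.
#' @return Data frame with columns `i`, `j`, `dist_a`, `dist_b` (one row per
#'   selected pair; zero rows when nothing qualifies).
#' @export
select_contacts <- function(conf_a, conf_b, candidates = NULL, r0 = 8,
                            ratio = 1.5, exclude_bonded = 2) {
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  if (nrow(conf_a) != nrow(conf_b))
    stop("conformations must share the same particle set")
  n <- nrow(conf_a)
  if (is.null(candidates)) {
    candidates <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    candidates <- candidates[abs(candidates[, 1] - candidates[, 2]) >
                               exclude_bonded, , drop = FALSE]
  }
  candidates <- matrix(as.integer(as.matrix(candidates)), ncol = 2)
  empty <- data.frame(i = integer(), j = integer(),
                      dist_a = numeric(), dist_b = numeric())
  if (nrow(candidates) == 0) return(empty)
  i <- candidates[, 1]; j <- candidates[, 2]
  da <- sqrt(rowSums((conf_a[i, , drop = FALSE] -
                        conf_a[j, , drop = FALSE])^2))
  db <- sqrt(rowSums((conf_b[i, , drop = FALSE] -
                        conf_b[j, , drop = FALSE])^2))
  crosses <- (da < r0 & db > r0) | (da > r0 & db < r0)
  big_enough <- pmax(da, db) >= ratio * pmin(da, db)
  keep <- crosses & big_enough
  data.frame(i = i[keep], j = j[keep], dist_a = da[keep], dist_b = db[keep])
}

#' Build a contact map from two reference conformations
#'
#' Convenience wrapper: runs [select_contacts()] and packages the selected
#' pairs with their per-state reference distances into a
#' [contact_map_spec()].
#'
#' @inheritParams select_contacts
#' @param state_names Names for the two reference states.
#'   Default `c("inactive", "active")` with `conf_a` the inactive state.
#' @return A `contact_map_spec`.
#' @export
contact_map_from_states <- function(conf_a, conf_b, candidates = NULL,
                                    r0 = 8, ratio = 1.5, exclude_bonded = 2,
                                    state_names = c("inactive", "active")) {
  sel <- select_contacts(conf_a, conf_b, candidates, r0, ratio, exclude_bonded)
  if (nrow(sel) == 0) stop("no contacts selected between the two states")
  d0 <- cbind(sel$dist_a, sel$dist_b)
  colnames(d0) <- state_names
  contact_map_spec(cbind(sel$i, sel$j), d0, r0)
}
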