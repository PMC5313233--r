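#' Specify a synthetic two-state bead-chain loop
#'
#' The two-state loop emulates a flexible loop (such as a kinase activation
#' loop) with two reference conformers — an "inactive" and an "active" state
#' — and a planted set of bead pairs whose distances cross the 8 A contact
#' threshold between the states.  The spec is validated against the planted
#' invariant: every planted pair must be below the threshold in exactly one
#' reference and above it in the other, with the larger distance at least
#' 1.5 times the smaller, so that the contact-selection rule recovers the
#' planted set exactly.
#'
#' @param ref_inactive,ref_active Reference conformations (`n x 3` matrices,
#'   A) with identical bead counts.
#' @param planted_pairs Two-column matrix of the bead pairs planted to cross
#'   the contact threshold between the references.
#' @param basin_depths Free energies (kcal/mol) of the two basins,
#'   `c(inactive, active)`; relative values set the basin occupancies through
#'   the Boltzmann factor at `temperature`. Default `c(0, 0)` (symmetric).
#' @param noise Thermal noise amplitude (A): isotropic Gaussian standard
#'   deviation of bead displacements about the generating reference.
#'   Default 0.5.
#' @param temperature Temperature (K) used for basin occupancies. Default 300.
#' @param contact_threshold Contact threshold in A. Default 8.
#' @param ratio Minimum larger/smaller distance ratio for planted pairs.
#'   Default 1.5.
#' @param seed Integer seed for [generate_two_state_loop()].
#' @return Object of class `two_state_loop_spec`.
#' @export
two_state_loop_spec <- function(ref_inactive, ref_active, planted_pairs,
                                basin_depths = c(0, 0), noise = 0.5,
                                temperature = 300, contact_threshold = 8,
                                ratio = 1.5, seed = NULL) {
  ref_inactive <- as.matrix(ref_inactive); ref_active <- as.matrix(ref_active)
  if (nrow(ref_inactive) != nrow(ref_active))
    stop("reference conformations must have the same bead count")
  if (nrow(ref_inactive) < 3) stop("two-state loop requires at least 3 beads")
  planted_pairs <- matrix(as.integer(as.matrix(planted_pairs)), ncol = 2)
  if (noise < 0) stop("noise amplitude must be non-negative")

  pd <- function(ref, p) sqrt(sum((ref[p[1], ] - ref[p[2], ])^2))
  for (r in seq_len(nrow(planted_pairs))) {
    p <- planted_pairs[r, ]
    da <- pd(ref_inactive, p); db <- pd(ref_active, p)
    crossing <- (da < contact_threshold) != (db < contact_threshold)
    if (!crossing || max(da, db) < ratio * min(da, db))
      stop(sprintf(
        "planted pair (%d, %d) violates the crossing invariant: %.2f / %.2f A",
        p[1], p[2], da, db))
  }
  structure(list(n_beads = nrow(ref_inactive), ref_inactive = ref_inactive,
                 ref_active = ref_active, planted_pairs = planted_pairs,
                 basin_depths = basin_depths, noise = noise,
                 temperature = temperature,
                 contact_threshold = contact_threshold, ratio = ratio,
                 seed = seed),
            class = "two_state_loop_spec")
}

#' Build a standard synthetic two-state loop
#'
#' Constructs a deterministic pair of reference conformers for an `n_beads`
#' chain with bond length `bond_length`: the inactive reference is an
#' extended zig-zag, the active reference folds the second half of the chain
#' back into a hairpin so that several (first-half, second-half) bead pairs
#' move from far apart (> 8 A) to close contact (< 8 A).  The planted pair
#' set is derived from the two references by the selection rule itself
#' (crossing 8 A with a >= 1.5 distance ratio, bonded neighbours excluded),
#' so the spec invariant holds by construction.
#'
#' @param n_beads Number of beads (>= 8 recommended). Default 12.
#' @param bond_length Bond length in A. Default 3.8.
#' @param basin_depths,noise,temperature,seed Passed to
#'   [two_state_loop_spec()].
#' @return A `two_state_loop_spec`.
#' @export
make_two_state_loop <- function(n_beads = 12, bond_length = 3.8,
                                basin_depths = c(0, 0), noise = 0.5,
                                temperature = 300, seed = NULL) {
  if (n_beads < 6) stop("need at least 6 beads for a hairpin")
  b <- bond_length
  # inactive: extended zig-zag along x
  ref_in <- matrix(0, n_beads, 3)
  ref_in[, 1] <- (seq_len(n_beads) - 1) * b * 0.95
  ref_in[, 2] <- rep(c(0, b * 0.3), length.out = n_beads)
  # active: first half extended, then fold back antiparallel at ~5 A offset
  half <- ceiling(n_beads / 2)
  ref_act <- matrix(0, n_beads, 3)
  ref_act[seq_len(half), ] <- ref_in[seq_len(half), ]
  for (k in seq_len(n_beads - half)) {
    ref_act[half + k, 1] <- ref_in[half, 1] - (k - 1) * b * 0.95
    ref_act[half + k, 2] <- 5
    ref_act[half + k, 3] <- 1.5
  }
  sel <- select_contacts(ref_in, ref_act, r0 = 8, ratio = 1.5,
                         exclude_bonded = 2)
  two_state_loop_spec(ref_in, ref_act, cbind(sel$i, sel$j),
                      basin_depths = basin_depths, noise = noise,
                      temperature = temperature, seed = seed)
}

#' Sample an ensemble from a two-state loop
#'
#' Frames are drawn by first choosing a generating basin with Boltzmann
#' probabilities `exp(-G_b / kB T)` from the basin depths, then displacing
#' every bead of that basin's reference conformer by isotropic Gaussian
#' noise of standard deviation `spec$noise`.  Labels record the generating
#' basin.
#'
#' @param spec A [two_state_loop_spec()].
#' @param n_frames Number of frames to draw. Default 200.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return List with `references` (list of the two reference matrices),
#'   `pool` (a [conformation_pool()]), and `labels` (character vector,
#'   `"inactive"`/`"active"` per frame).
#' @export
generate_two_state_loop <- function(spec, n_frames = 200, seed = spec$seed) {
  stopifnot(inherits(spec, "two_state_loop_spec"))
  if (!is.null(seed)) set.seed(seed)
  kT <- .kB * spec$temperature
  w <- exp(-(spec$basin_depths - min(spec$basin_depths)) / kT)
  p_active <- w[2] / sum(w)
  lab <- ifelse(stats::runif(n_frames) < p_active, "active", "inactive")
  n <- spec$n_beads
  coords <- array(0, c(n_frames, n, 3))
  for (f in seq_len(n_frames)) {
    ref <- if (lab[f] == "active") spec$ref_active else spec$ref_inactive
    coords[f, , ] <- ref + spec$noise * matrix(stats::rnorm(n * 3), n, 3)
  }
  list(references = list(inactive = spec$ref_inactive,
                         active = spec$ref_active),
       pool = conformation_pool(coords, source = lab),
       labels = lab)
}
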