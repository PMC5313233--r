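#' Physical constants and unit conventions
#'
#' All quantities in pathdyn use a single unit system: lengths in Angstrom
#' (A), time in picoseconds (ps), energies in kcal/mol, masses in atomic mass
#' units (amu), temperatures in Kelvin.  Forces in kcal/mol/A acting on a mass
#' in amu are converted to accelerations in A/ps^2 through the factor
#' 1 kcal/mol = 418.4 amu A^2/ps^2.
#'
#' @return Named list with elements `kB` (Boltzmann constant,
#'   kcal/mol/K) and `kcal_to_acc` (conversion factor from kcal/mol/A per amu
#'   to A/ps^2).
#' @examples
#' sim_constants()$kB * 300  # thermal energy at 300 K, kcal/mol
#' @export
sim_constants <- function() {
  list(kB = 0.0019872041, kcal_to_acc = 418.4)
}

.kB <- 0.0019872041
.KCAL <- 418.4
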