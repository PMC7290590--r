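#' Membrane interaction energy of one protonation state
#'
#' Evaluates the effective one-dimensional potential `U_s(d)` (in kT) felt by
#' the titrable group at signed insertion depth `d` (A below the phosphate
#' plane; negative values are on the water side).  The state-specific part is
#' a logistic step from `water_plateau` down to `-well_depth`; on top of it
#' both states share an interface attraction (a Gaussian well emulating
#' headgroup interactions) and two soft exponential walls confining the ligand
#' to one monolayer: one at the bilayer midplane side and one in the water
#' phase.
#'
#' @param d numeric vector of insertion depths (A; positive = membrane
#'   interior below the phosphate plane).
#' @param state protonation state, 0 (neutral) or 1 (protonated); scalar.
#' @param config a [sim_config()] object.
#' @return numeric vector of energies in kT.
#' @seealso [true_pka()]
#' @export
potential_energy <- function(d, state, config) {
  state_energy(d, state, config) + potential_common(d, config)
}

# state-dependent part alone; differences between states are computed on
# these terms so the shared walls (which can be numerically huge far outside
# the sampled region) cancel exactly rather than by floating-point subtraction
state_energy <- function(d, state, config) {
  stopifnot(state %in% c(0, 1))
  p <- if (state == 1) config$potential_protonated else config$potential_neutral
  p$water_plateau +
    (-p$well_depth - p$water_plateau) * stats::plogis((d - p$well_center) / p$well_width)
}

# state-independent part: interface attraction + confinement walls.
# Cancels exactly in U_neutral - U_protonated, hence never enters true_pka().
potential_common <- function(d, config) {
  iw <- config$interface_well
  w <- config$walls
  -iw$depth * exp(-(d - iw$center)^2 / (2 * iw$width^2)) +
    exp((d - w$deep) / w$width) +
    exp(-(d - w$water) / w$width)
}

#' Ground-truth pKa at a given insertion depth
#'
#' The analytically known pKa of the simulated titrable group at depth `d`,
#' defined by the thermodynamic cycle linking the water-phase pKa to the
#' membrane-interaction energies of the two protonation states:
#' `pKa(d) = pKa_water + (U_neutral(d) - U_protonated(d)) / ln(10)`.
#' State-independent energy terms cancel.  With the default configuration the
#' profile is non-increasing in `d`, equals `pKa_water` in the water phase and
#' drops 3.5 units at full insertion.
#'
#' @inheritParams potential_energy
#' @return numeric vector of pKa values (pH units).
#' @examples
#' cfg <- sim_config()
#' true_pka(c(-8, 0, 6, 12), cfg)
#' @export
true_pka <- function(d, config) {
  config$pka_water +
    (state_energy(d, 0, config) - state_energy(d, 1, config)) / log(10)
}

#' Equilibrium protonation probability at fixed depth
#'
#' Henderson-Hasselbalch probability that the group is protonated at depth
#' `d` under an imposed `pH`: `1 / (1 + 10^(pH - pKa(d)))`.
#'
#' @inheritParams potential_energy
#' @param pH imposed pH value(s).
#' @return protonation probabilities in `[0, 1]`.
#' @export
equilibrium_protonation <- function(d, pH, config) {
  1 / (1 + 10^(pH - true_pka(d, config)))
}
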