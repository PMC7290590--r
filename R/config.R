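#' Simulation configuration for the constant-pH / pH-replica-exchange sampler
#'
#' Builds a validated configuration object for [run_replicate()] and
#' [run_simulation()].  All lengths are in Angstrom, all energies in units of
#' kT (reduced units, kT = 1), pH values in pH units.  One Monte-Carlo step
#' corresponds to one nominal picosecond, so the default exchange and
#' titration periods of 20 steps mirror exchange attempts every 20 ps.
#'
#' The per-state membrane interaction is a logistic insertion step: the energy
#' goes from `water_plateau` on the water side to `-well_depth` on the
#' membrane-interior side, switching at `well_center` over a lengthscale
#' `well_width`.  Both states additionally feel a shared (state-independent)
#' interface attraction and soft confinement walls; because these terms are
#' identical for the neutral and protonated species they cancel exactly in the
#' ground-truth pKa (see [true_pka()]).
#'
#' With the defaults the ground-truth pKa profile is
#' `pka_water - 3.5 * plogis((d - 6)/1.5)`: flat at `pka_water` in water and
#' shifted 3.5 units below it deep in the membrane, the protonated species
#' concentrates ~3 A below the phosphate plane and the neutral species
#' ~10 A below it.
#'
#' @param pka_water water-phase pKa of the titrable amine (pH units).
#' @param pH_ladder strictly increasing, uniformly spaced replica pH values;
#'   the default `7:10` is a 4-rung ladder with a 1.0 pH-unit step.
#' @param n_replicates independent replicate simulations (default 5).
#' @param n_steps Monte-Carlo steps per replica (default 2e5; one step is one
#'   nominal ps, so the default mirrors a 200 ns run).
#' @param exchange_period steps between pH-exchange attempt rounds.
#' @param titration_period steps between titration attempts.
#' @param burn_in_fraction fraction of initial frames discarded downstream.
#' @param potential_neutral,potential_protonated lists with entries
#'   `well_center` (A), `well_depth` (kT, energy at full insertion is
#'   `-well_depth`), `well_width` (A) and `water_plateau` (kT).
#' @param interface_well shared interface attraction, list with `center` (A),
#'   `depth` (kT) and `width` (A); applied identically to both states.
#' @param walls soft confinement, list with `deep` (A, onset of the
#'   bilayer-midplane wall that keeps the ligand in one monolayer), `water`
#'   (A, onset of the water-side wall) and `width` (A).
#' @param membrane list with `lipids_per_leaflet`, `box_xy` (length-2, A),
#'   `plane_offset` (A), `jitter_sd` (A), `deformation_amplitude` (A),
#'   `deformation_wavelength` (A) and `oxygens_per_phosphate`.
#' @param step_sizes list with `lateral` and `normal` Gaussian proposal
#'   standard deviations (A).
#' @param seed integer base seed; replicate streams are derived from it.
#'
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_steps = 1000, n_replicates = 1)
#' cfg$pH_ladder
#' @export
sim_config <- function(pka_water = 9.0,
                       pH_ladder = c(7, 8, 9, 10),
                       n_replicates = 5L,
                       n_steps = 200000L,
                       exchange_period = 20L,
                       titration_period = 20L,
                       burn_in_fraction = 0.5,
                       potential_neutral = list(well_center = 6, well_depth = 6.5,
                                                well_width = 1.5, water_plateau = 0),
                       potential_protonated = list(well_center = 6,
                                                   well_depth = 6.5 - 3.5 * log(10),
                                                   well_width = 1.5, water_plateau = 0),
                       interface_well = list(center = 3, depth = 2, width = 2),
                       walls = list(deep = 13, water = -7, width = 0.7),
                       membrane = list(lipids_per_leaflet = 64L,
                                       box_xy = c(62, 62),
                                       plane_offset = 18,
                                       jitter_sd = 0.4,
                                       deformation_amplitude = 1.5,
                                       deformation_wavelength = 31,
                                       oxygens_per_phosphate = 3L),
                       step_sizes = list(lateral = 1.5, normal = 2.0),
                       seed = 1L) {
  defaults <- formals(sim_config)
  cfg <- list(pka_water = pka_water,
              pH_ladder = as.numeric(pH_ladder),
              n_replicates = as.integer(n_replicates),
              n_steps = as.integer(n_steps),
              exchange_period = as.integer(exchange_period),
              titration_period = as.integer(titration_period),
              burn_in_fraction = burn_in_fraction,
              potential_neutral = utils::modifyList(eval(defaults$potential_neutral),
                                                    potential_neutral),
              potential_protonated = utils::modifyList(eval(defaults$potential_protonated),
                                                       potential_protonated),
              interface_well = utils::modifyList(eval(defaults$interface_well),
                                                 interface_well),
              walls = utils::modifyList(eval(defaults$walls), walls),
              membrane = utils::modifyList(eval(defaults$membrane), membrane),
              step_sizes = utils::modifyList(eval(defaults$step_sizes), step_sizes),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()] object: strictly
#' increasing uniformly spaced pH ladder, positive counts and periods,
#' positive well widths, burn-in fraction in `[0, 1)` and a positive box.
#'
#' @param cfg a `sim_config` object (or a plain list with the same fields).
#' @return `cfg`, invisibly, if valid; otherwise a configuration error is
#'   signalled (condition class `memtitrate_config_error`).
#' @export
validate_config <- function(cfg) {
  fail <- function(msg) stop_config(msg)
  lad <- cfg$pH_ladder
  if (length(lad) < 1 || anyNA(lad)) fail("pH_ladder must be non-empty and finite")
  if (length(lad) > 1) {
    d <- diff(lad)
    if (any(d <= 0)) fail("pH_ladder must be strictly increasing")
    if (max(d) - min(d) > 1e-9) fail("pH_ladder must have a constant step")
  }
  if (cfg$n_replicates < 1) fail("n_replicates must be >= 1")
  if (cfg$n_steps < 0) fail("n_steps must be >= 0")
  if (cfg$exchange_period < 1 || cfg$titration_period < 1)
    fail("exchange_period and titration_period must be >= 1")
  if (cfg$burn_in_fraction < 0 || cfg$burn_in_fraction >= 1)
    fail("burn_in_fraction must be in [0, 1)")
  for (nm in c("potential_neutral", "potential_protonated")) {
    p <- cfg[[nm]]
    need <- c("well_center", "well_depth", "well_width", "water_plateau")
    if (!all(need %in% names(p))) fail(paste0(nm, " is missing a field"))
    if (p$well_width <= 0) fail(paste0(nm, "$well_width must be > 0"))
  }
  if (cfg$interface_well$width <= 0) fail("interface_well$width must be > 0")
  if (cfg$walls$width <= 0) fail("walls$width must be > 0")
  m <- cfg$membrane
  if (m$lipids_per_leaflet < 1) fail("membrane$lipids_per_leaflet must be >= 1")
  if (any(m$box_xy <= 0)) fail("membrane$box_xy must be positive")
  if (m$oxygens_per_phosphate < 0) fail("membrane$oxygens_per_phosphate must be >= 0")
  if (cfg$step_sizes$lateral <= 0 || cfg$step_sizes$normal <= 0)
    fail("step sizes must be > 0")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds nested sections mirroring the arguments of [sim_config()];
#' missing sections fall back to the defaults.
#'
#' @param path path to a YAML configuration file.
#' @return a validated `sim_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_config(paste0("unknown configuration key(s): ",
                       paste(unknown, collapse = ", ")))
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  pKa(water):", x$pka_water,
      " ladder:", paste(x$pH_ladder, collapse = ", "), "\n")
  cat("  replicates:", x$n_replicates, " steps/replica:", x$n_steps,
      " burn-in:", x$burn_in_fraction, "\n")
  cat("  exchange every", x$exchange_period, "steps; titration every",
      x$titration_period, "steps\n")
  cat("  membrane:", x$membrane$lipids_per_leaflet, "lipids/leaflet, box",
      paste(x$membrane$box_xy, collapse = " x "), "A\n")
  invisible(x)
}

# classed error helpers: config (exit 2 semantics), data (exit 3), format
stop_config <- function(msg) {
  stop(structure(class = c("memtitrate_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("memtitrate_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_format <- function(msg) {
  stop(structure(class = c("memtitrate_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
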