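#' Single stochastic titration attempt
#'
#' Proposes flipping the protonation state of the titrable group held at
#' insertion depth `d` under an imposed `pH` and accepts with the Metropolis
#' probability `min(1, exp(-dU) * 10^(ds * (pKa_water - pH)))`, where
#' `dU = U_new(d) - U_old(d)` (kT) and `ds = s_new - s_old`.  Iterating this
#' rule at fixed `d` samples the Henderson-Hasselbalch stationary
#' distribution: `P(protonated) = 1 / (1 + 10^(pH - pKa_true(d)))`.
#'
#' @param d insertion depth (A).
#' @param pH imposed pH.
#' @param state current protonation state, 0 or 1.
#' @param config a [sim_config()] object.
#' @return the new protonation state (0 or 1).
#' @seealso [titration_acceptance()] for the acceptance probability itself.
#' @export
attempt_titration <- function(d, pH, state, config) {
  p <- titration_acceptance(d, pH, state, config)
  if (stats::runif(1) < p) 1L - as.integer(state) else as.integer(state)
}

#' @rdname attempt_titration
#' @return for `titration_acceptance()`: the acceptance probability of the
#'   proposed flip, in `[0, 1]`.
#' @export
titration_acceptance <- function(d, pH, state, config) {
  new_state <- 1 - state
  du <- state_energy(d, new_state, config) - state_energy(d, state, config)
  ds <- new_state - state
  pmin(1, exp(-du) * 10^(ds * (config$pka_water - pH)))
}

#' pH replica-exchange acceptance probability
#'
#' Probability of accepting a swap of pH values between two replicas in the
#' semi-grand-canonical pH replica-exchange scheme:
#' `min(1, 10^((pH_i - pH_j) * (N_i - N_j)))`, with `N` the number of protons
#' bound in each replica (equal to the protonation state for a single
#' titrable site).  Symmetric under a simultaneous swap of `(i, j)`.
#'
#' @param pH_i,pH_j pH values of the two replicas.
#' @param N_i,N_j protons bound in each replica.
#' @return acceptance probability in `[0, 1]`.
#' @examples
#' exchange_probability(7, 8, 1, 0)  # 0.1
#' @export
exchange_probability <- function(pH_i, pH_j, N_i, N_j) {
  pmin(1, 10^((pH_i - pH_j) * (N_i - N_j)))
}

#' Run one replicate of the constant-pH / pH-replica-exchange sampler
#'
#' Simulates all pH replicas of one replicate.  Each Monte-Carlo step applies
#' a joint lateral (periodically wrapped) and normal-coordinate Gaussian move
#' accepted by Metropolis against the state's membrane potential evaluated at
#' the true insertion depth (from the analytic deformed surface); titration
#' attempts occur every `titration_period` steps and ladder-adjacent pH
#' exchange attempts every `exchange_period` steps, alternating odd/even
#' pairs, swapping pH labels on acceptance.  Every step of every replica is
#' recorded; downstream analysis applies burn-in and may subsample.
#'
#' @param config a [sim_config()] object.
#' @param replicate_id integer replicate label; different replicates use
#'   different random streams derived from `config$seed`.
#' @param snapshot_id snapshot label stored with each frame.
#' @param exchange logical; attempt pH exchanges (requires a ladder of at
#'   least two pH values).
#' @return a `data.frame` of frames with columns `replicate_id`,
#'   `replica_id`, `step`, `time` (ps; equal to `step`), `pH`, `prot_state`,
#'   `group_x`, `group_y`, `group_z`, `snapshot_id`.
#' @export
run_replicate <- function(config, replicate_id = 1L, snapshot_id = "snap1",
                          exchange = TRUE) {
  validate_config(config)
  if (exchange && length(config$pH_ladder) < 2)
    stop_config("pH exchange requires a ladder of at least two pH values")
  m <- config$membrane
  mat <- cpp_run_replicate(
    n_steps = config$n_steps,
    ladder = config$pH_ladder,
    pka_water = config$pka_water,
    pot_neutral = unlist(config$potential_neutral),
    pot_protonated = unlist(config$potential_protonated),
    common_par = c(iw_center = config$interface_well$center,
                   iw_depth = config$interface_well$depth,
                   iw_width = config$interface_well$width,
                   wall_deep = config$walls$deep,
                   wall_water = config$walls$water,
                   wall_width = config$walls$width),
    surface_par = c(plane_offset = m$plane_offset,
                    amplitude = m$deformation_amplitude,
                    wavelength = m$deformation_wavelength),
    box = rep(as.numeric(m$box_xy), length.out = 2),
    sd_lateral = config$step_sizes$lateral,
    sd_normal = config$step_sizes$normal,
    titration_period = config$titration_period,
    exchange_period = config$exchange_period,
    exchange = exchange,
    seed = config$seed,
    replicate_id = as.integer(replicate_id))
  df <- as.data.frame(mat)
  if (!nrow(df)) {
    return(data.frame(replicate_id = integer(), replica_id = integer(),
                      step = integer(), time = numeric(), pH = numeric(),
                      prot_state = integer(), group_x = numeric(),
                      group_y = numeric(), group_z = numeric(),
                      snapshot_id = character(), stringsAsFactors = FALSE))
  }
  data.frame(replicate_id = as.integer(replicate_id),
             replica_id = as.integer(df$replica_id),
             step = as.integer(df$step),
             time = df$step,
             pH = df$pH,
             prot_state = as.integer(df$prot_state),
             group_x = df$group_x,
             group_y = df$group_y,
             group_z = df$group_z,
             snapshot_id = snapshot_id,
             stringsAsFactors = FALSE)
}

#' Run a full synthetic simulation (all replicates)
#'
#' Builds the membrane snapshot and runs [run_replicate()] for each of the
#' `config$n_replicates` replicates, returning everything as a trajectory
#' bundle ready for [write_frames()] or [compute_insertion()].
#'
#' @param config a [sim_config()] object.
#' @param exchange logical; attempt pH exchanges.
#' @return a `trajectory_bundle`: list with `frames` (all replicates'
#'   frames), `snapshots` (named list of [build_membrane()] snapshots) and
#'   `metadata` (config echo, format version, seed).
#' @examples
#' cfg <- sim_config(n_steps = 200, n_replicates = 1)
#' bundle <- run_simulation(cfg)
#' nrow(bundle$frames)
#' @export
run_simulation <- function(config, exchange = length(config$pH_ladder) >= 2) {
  validate_config(config)
  snap <- build_membrane(config, seed = config$seed)
  frames <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    run_replicate(config, replicate_id = r, snapshot_id = snap$snapshot_id,
                  exchange = exchange)
  }))
  trajectory_bundle(frames, list(snap), config = config)
}

#' Construct a trajectory bundle
#'
#' Container pairing a frame table with the membrane snapshot(s) it refers
#' to.  Frames are sorted by (replicate_id, replica_id, step) and every
#' `snapshot_id` must resolve to a supplied snapshot.
#'
#' @param frames data.frame of frames (see [run_replicate()] for columns).
#' @param snapshots list of `membrane_snapshot` objects.
#' @param config optional `sim_config` echoed into the metadata.
#' @param seed optional seed recorded in the metadata.
#' @return an object of class `trajectory_bundle`.
#' @export
trajectory_bundle <- function(frames, snapshots, config = NULL, seed = NULL) {
  need <- c("replicate_id", "replica_id", "step", "time", "pH", "prot_state",
            "group_x", "group_y", "group_z", "snapshot_id")
  miss <- setdiff(need, names(frames))
  if (length(miss))
    stop_format(paste0("frames missing column(s): ", paste(miss, collapse = ", ")))
  names(snapshots) <- vapply(snapshots, function(s) s$snapshot_id, "")
  if (nrow(frames)) {
    unknown <- setdiff(unique(frames$snapshot_id), names(snapshots))
    if (length(unknown))
      stop_format(paste0("frames reference unknown snapshot_id: ",
                         paste(unknown, collapse = ", ")))
    frames <- frames[order(frames$replicate_id, frames$replica_id, frames$step), ,
                     drop = FALSE]
    rownames(frames) <- NULL
    bad <- !is.finite(frames$group_x) | !is.finite(frames$group_y) |
      !is.finite(frames$group_z)
    if (any(bad))
      stop_format(paste0("non-finite group coordinates in frame row ",
                         which(bad)[1]))
    if (!all(frames$prot_state %in% c(0L, 1L)))
      stop_format(paste0("prot_state outside {0,1} in frame row ",
                         which(!(frames$prot_state %in% c(0L, 1L)))[1]))
  }
  structure(list(frames = frames,
                 snapshots = snapshots,
                 metadata = list(format_version = 1L,
                                 seed = if (!is.null(seed)) as.integer(seed)
                                        else if (!is.null(config)) config$seed,
                                 config = config)),
            class = "trajectory_bundle")
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat("<trajectory_bundle>", nrow(x$frames), "frames,",
      length(x$snapshots), "snapshot(s)\n")
  if (nrow(x$frames)) {
    cat("  replicates:", paste(unique(x$frames$replicate_id), collapse = ", "),
        "; pH values:", paste(sort(unique(x$frames$pH)), collapse = ", "), "\n")
  }
  invisible(x)
}
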