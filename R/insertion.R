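#' Assign a ligand to a leaflet
#'
#' Returns the leaflet whose phosphate atoms lie on the same side of the
#' bilayer midplane (the mean of the two leaflet mean z values) as the
#' ligand.  A ligand exactly at the midplane is assigned to the upper leaflet
#' and a crossing warning is emitted.
#'
#' @param group_z z coordinate(s) of the titrable group (A).
#' @param snapshot a `membrane_snapshot` with both leaflets.
#' @return character vector, `"upper"` or `"lower"`.
#' @export
assign_leaflet <- function(group_z, snapshot) {
  a <- snapshot$atoms
  mu_up <- mean(a$z[a$leaflet == "upper"])
  mu_lo <- mean(a$z[a$leaflet == "lower"])
  if (is.na(mu_up) || is.na(mu_lo))
    stop_data("snapshot must contain both leaflets")
  mid <- (mu_up + mu_lo) / 2
  at_mid <- group_z == mid
  if (any(at_mid))
    warning("ligand exactly at the bilayer midplane in ", sum(at_mid),
            " frame(s); assigned to the upper leaflet", call. = FALSE)
  ifelse(group_z >= mid, "upper", "lower")
}

#' Local phosphate reference plane
#'
#' Computes the reference z of the phosphate plane in the lateral
#' neighbourhood of the ligand: the mean z of all phosphate-group atoms
#' (phosphorus and oxygen) of the given leaflet within `radius` Angstrom of
#' the ligand in the x/y plane (minimum-image convention).  If fewer than
#' `min_atoms` atoms fall inside the radius, the `min_atoms` laterally
#' closest atoms are used instead and the fallback flag is set; distance ties
#' are broken by `atom_id`.  Using only nearby lipids makes the reference
#' robust to local membrane deformations.
#'
#' @param group_x,group_y lateral ligand coordinates (A); vectorised.
#' @param snapshot a `membrane_snapshot`.
#' @param leaflet `"upper"` or `"lower"`; which leaflet supplies the
#'   reference atoms.
#' @param radius lateral search radius (A); default 6.
#' @param min_atoms minimum number of reference atoms; default 10.
#' @return a data.frame with columns `ref_z` (A), `n_ref_atoms`,
#'   `fallback_used` (logical).
#' @export
local_phosphate_reference <- function(group_x, group_y, snapshot,
                                      leaflet = "upper", radius = 6,
                                      min_atoms = 10L) {
  a <- snapshot$atoms
  a <- a[a$leaflet == leaflet, , drop = FALSE]
  a <- a[order(a$atom_id), , drop = FALSE]
  if (nrow(a) < min_atoms)
    stop_data(paste0("leaflet '", leaflet, "' has ", nrow(a),
                     " phosphate-group atoms; at least ", min_atoms,
                     " are required"))
  m <- cpp_local_reference(as.numeric(group_x), as.numeric(group_y),
                           a$x, a$y, a$z, snapshot$box_x, snapshot$box_y,
                           radius, as.integer(min_atoms))
  data.frame(ref_z = m[, "ref_z"],
             n_ref_atoms = as.integer(m[, "n_ref_atoms"]),
             fallback_used = m[, "fallback_used"] > 0)
}

#' Compute signed insertion depths for a trajectory
#'
#' For every frame, computes the insertion depth of the titrable group
#' relative to the local phosphate reference of its own leaflet:
#' `d = ref_z - group_z` for the upper leaflet (mirrored for the lower), so
#' that positive `d` means the group sits below the phosphate plane, toward
#' the membrane interior, and negative `d` means the water side.  The
#' insertion coordinate tracks the titrable group only, not the whole
#' molecule.
#'
#' @param bundle a `trajectory_bundle`, or a frames data.frame (in which case
#'   `snapshot` must be supplied).
#' @param snapshot optional single `membrane_snapshot` overriding the
#'   bundle's snapshots.
#' @param radius lateral search radius (A).
#' @param min_atoms minimum reference atoms.
#' @return a data.frame of insertion records: `replicate_id`, `replica_id`,
#'   `step`, `pH`, `prot_state`, `d`, `leaflet`, `n_ref_atoms`,
#'   `fallback_used`, `ref_z`.
#' @examples
#' cfg <- sim_config(n_steps = 100, n_replicates = 1)
#' b <- run_simulation(cfg)
#' rec <- compute_insertion(b)
#' range(rec$d)
#' @export
compute_insertion <- function(bundle, snapshot = NULL, radius = 6,
                              min_atoms = 10L) {
  if (inherits(bundle, "trajectory_bundle")) {
    frames <- bundle$frames
    snapshots <- bundle$snapshots
  } else {
    frames <- bundle
    if (is.null(snapshot)) stop_data("a membrane snapshot is required")
    snapshots <- stats::setNames(list(snapshot), snapshot$snapshot_id)
    if (is.null(frames$snapshot_id)) frames$snapshot_id <- snapshot$snapshot_id
  }
  if (!nrow(frames)) stop_data("no frames to analyse")
  out <- vector("list", length(unique(frames$snapshot_id)))
  i <- 0L
  for (sid in unique(frames$snapshot_id)) {
    snap <- snapshots[[sid]]
    if (is.null(snap)) stop_data(paste0("unknown snapshot_id: ", sid))
    fr <- frames[frames$snapshot_id == sid, , drop = FALSE]
    leaf <- assign_leaflet(fr$group_z, snap)
    rec <- data.frame(replicate_id = fr$replicate_id,
                      replica_id = fr$replica_id,
                      step = fr$step, pH = fr$pH,
                      prot_state = fr$prot_state,
                      d = NA_real_, leaflet = leaf,
                      n_ref_atoms = NA_integer_, fallback_used = NA,
                      ref_z = NA_real_, stringsAsFactors = FALSE)
    for (lf in unique(leaf)) {
      sel <- leaf == lf
      ref <- local_phosphate_reference(fr$group_x[sel], fr$group_y[sel],
                                       snap, lf, radius, min_atoms)
      sgn <- if (lf == "upper") 1 else -1
      rec$ref_z[sel] <- ref$ref_z
      rec$d[sel] <- sgn * (ref$ref_z - fr$group_z[sel])
      rec$n_ref_atoms[sel] <- ref$n_ref_atoms
      rec$fallback_used[sel] <- ref$fallback_used
    }
    i <- i + 1L
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicate_id, res$replica_id, res$step), , drop = FALSE]
  rownames(res) <- NULL
  res
}
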