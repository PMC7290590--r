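# shared fixtures and independent oracles

hh <- function(pH, pka) 1 / (1 + 10^(pH - pka))

# small, fast configuration for unit tests
small_config <- function(...) {
  sim_config(n_steps = 2000L, n_replicates = 2L,
             membrane = list(lipids_per_leaflet = 64L),
             ...)
}

# a hand-built snapshot from an atom table (for exact-geometry tests)
manual_snapshot <- function(atoms, box_x = 60, box_y = 60, id = "manual",
                            metadata = list()) {
  structure(list(snapshot_id = id, box_x = box_x, box_y = box_y,
                 atoms = atoms, metadata = metadata),
            class = "membrane_snapshot")
}

# brute-force local-reference oracle: exhaustive minimum-image search with
# order()-based closest-10 fallback (ties by atom_id)
brute_reference <- function(gx, gy, atoms, box_x, box_y, radius = 6,
                            min_atoms = 10L) {
  atoms <- atoms[order(atoms$atom_id), ]
  dx <- abs(gx - atoms$x); dx <- pmin(dx, box_x - dx)
  dy <- abs(gy - atoms$y); dy <- pmin(dy, box_y - dy)
  d2 <- dx^2 + dy^2
  inr <- which(d2 <= radius^2)
  if (length(inr) >= min_atoms) {
    list(ref_z = mean(atoms$z[inr]), n = length(inr), fallback = FALSE)
  } else {
    o <- order(d2, atoms$atom_id)[seq_len(min_atoms)]
    list(ref_z = mean(atoms$z[o]), n = min_atoms, fallback = TRUE)
  }
}

# unwrapped 3x3 periodic-tiling oracle (no minimum-image shortcut)
tiled_reference <- function(gx, gy, atoms, box_x, box_y, radius = 6,
                            min_atoms = 10L) {
  atoms <- atoms[order(atoms$atom_id), ]
  shifts <- expand.grid(sx = -1:1, sy = -1:1)
  d2min <- rep(Inf, nrow(atoms))
  for (k in seq_len(nrow(shifts))) {
    dx <- gx - (atoms$x + shifts$sx[k] * box_x)
    dy <- gy - (atoms$y + shifts$sy[k] * box_y)
    d2min <- pmin(d2min, dx^2 + dy^2)
  }
  inr <- which(d2min <= radius^2)
  if (length(inr) >= min_atoms) {
    list(ref_z = mean(atoms$z[inr]), n = length(inr), fallback = FALSE)
  } else {
    o <- order(d2min, atoms$atom_id)[seq_len(min_atoms)]
    list(ref_z = mean(atoms$z[o]), n = min_atoms, fallback = TRUE)
  }
}

# exact-fraction titration records: protonation counts chosen so that every
# (pH, replicate) cell mean is exactly the Henderson-Hasselbalch value for
# pka 9 at pH 8, 9, 10 (20/22, 11/22, 2/22)
exact_hh_records <- function(d = 2.3, replicates = 1:3) {
  cells <- expand.grid(pH = c(8, 9, 10), replicate_id = replicates)
  counts <- c(`8` = 20L, `9` = 11L, `10` = 2L)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    k <- counts[[as.character(cells$pH[i])]]
    data.frame(replicate_id = cells$replicate_id[i], replica_id = 1L,
               step = seq_len(22L), pH = cells$pH[i],
               prot_state = rep(c(1L, 0L), c(k, 22L - k)), d = d)
  }))
}
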