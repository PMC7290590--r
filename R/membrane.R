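#' Analytic deformed phosphate surface
#'
#' Height of the idealised phosphate surface of the upper leaflet above the
#' bilayer midplane: `z_P(x, y) = plane_offset + A * sin(2*pi*x/lambda) *
#' sin(2*pi*y/lambda)`.  The lower leaflet is its mirror image at `-z_P`.
#' For consistency with the periodic lateral boundaries the wavelength should
#' divide the box edge.
#'
#' @param x,y lateral coordinates (A).
#' @param membrane the `membrane` section of a [sim_config()].
#' @return surface z (A), vectorised over `x`/`y`.
#' @export
membrane_surface_z <- function(x, y, membrane) {
  membrane$plane_offset +
    membrane$deformation_amplitude *
      sin(2 * pi * x / membrane$deformation_wavelength) *
      sin(2 * pi * y / membrane$deformation_wavelength)
}

#' Build a synthetic phosphate-group membrane snapshot
#'
#' Generates a geometric stand-in for a phospholipid bilayer's phosphate
#' region: `lipids_per_leaflet` lattice sites per leaflet, each contributing
#' one phosphorus atom plus `oxygens_per_phosphate` oxygen atoms clustered
#' within 1.5 A of it.  Site heights follow the analytic deformed surface
#' (see [membrane_surface_z()]) plus Gaussian jitter of sd `jitter_sd`;
#' the lower leaflet mirrors the upper.  The generation parameters are kept
#' as metadata so that analysis code can be checked against the analytic
#' surface (oracle use).
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; the same seed reproduces the snapshot exactly.
#' @param snapshot_id identifier stored with the snapshot.
#' @return an object of class `membrane_snapshot`: a list with `snapshot_id`,
#'   `box_x`, `box_y`, `atoms` (data.frame with `atom_id`, `element`,
#'   `leaflet`, `x`, `y`, `z`) and `metadata` (generation parameters).
#' @examples
#' snap <- build_membrane(sim_config(), seed = 1)
#' table(snap$atoms$element, snap$atoms$leaflet)
#' @export
build_membrane <- function(config, seed = config$seed, snapshot_id = "snap1") {
  validate_config(config)
  m <- config$membrane
  n <- as.integer(m$lipids_per_leaflet)
  box <- rep(as.numeric(m$box_xy), length.out = 2)

  withr::with_seed(as.integer(seed), {
    n_side <- ceiling(sqrt(n))
    gx <- (seq_len(n_side) - 0.5) * box[1] / n_side
    gy <- (seq_len(n_side) - 0.5) * box[2] / n_side
    grid <- expand.grid(x = gx, y = gy)[seq_len(n), ]

    one_leaflet <- function(leaflet) {
      sgn <- if (leaflet == "upper") 1 else -1
      surf <- membrane_surface_z(grid$x, grid$y, m)
      pz <- sgn * (surf + stats::rnorm(n, 0, m$jitter_sd))
      k <- as.integer(m$oxygens_per_phosphate)
      px <- grid$x; py <- grid$y
      if (k > 0) {
        # oxygens uniform in a 1.2 A-radius ball around their phosphorus
        u <- matrix(stats::rnorm(3 * n * k), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        r <- 1.2 * stats::runif(n * k)^(1 / 3)
        ox <- rep(px, each = k) + r * u[, 1]
        oy <- rep(py, each = k) + r * u[, 2]
        oz <- rep(pz, each = k) + r * u[, 3]
      } else {
        ox <- oy <- oz <- numeric(0)
      }
      data.frame(element = c(rep("P", n), rep("O", n * k)),
                 leaflet = leaflet,
                 x = c(px, ox) %% box[1],
                 y = c(py, oy) %% box[2],
                 z = c(pz, oz),
                 stringsAsFactors = FALSE)
    }

    atoms <- rbind(one_leaflet("upper"), one_leaflet("lower"))
    atoms <- data.frame(atom_id = seq_len(nrow(atoms)), atoms,
                        stringsAsFactors = FALSE)
  })

  structure(list(snapshot_id = snapshot_id,
                 box_x = box[1], box_y = box[2],
                 atoms = atoms,
                 metadata = list(plane_offset = m$plane_offset,
                                 deformation_amplitude = m$deformation_amplitude,
                                 deformation_wavelength = m$deformation_wavelength,
                                 jitter_sd = m$jitter_sd,
                                 lipids_per_leaflet = n,
                                 oxygens_per_phosphate = as.integer(m$oxygens_per_phosphate),
                                 seed = as.integer(seed))),
            class = "membrane_snapshot")
}

#' @export
print.membrane_snapshot <- function(x, ...) {
  cat("<membrane_snapshot>", x$snapshot_id, "\n")
  cat("  box:", x$box_x, "x", x$box_y, "A;", nrow(x$atoms), "atoms (",
      sum(x$atoms$element == "P"), "P )\n")
  invisible(x)
}
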