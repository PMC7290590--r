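test_that("leaflet assignment splits at the bilayer midplane with upper ties", {
  atoms <- data.frame(atom_id = 1:24, element = "P",
                      leaflet = rep(c("upper", "lower"), each = 12),
                      x = rep(seq(2, 57, 5), 2), y = 5,
                      z = rep(c(18, -14), each = 12))
  snap <- manual_snapshot(atoms)
  expect_equal(assign_leaflet(10, snap), "upper")   # midplane is z = 2
  expect_equal(assign_leaflet(-3, snap), "lower")
  expect_warning(lf <- assign_leaflet(2, snap), "midplane")
  expect_equal(lf, "upper")
})

test_that("in-radius averaging uses all atoms and the fallback the closest ten", {
  # 12 atoms on a constant plane within radius -> plain average
  atoms <- data.frame(atom_id = 1:12, element = "P", leaflet = "upper",
                      x = 30 + cos(1:12), y = 30 + sin(1:12), z = 18)
  snap <- manual_snapshot(atoms)
  ref <- local_phosphate_reference(30, 30, snap, "upper")
  expect_equal(ref$ref_z, 18)
  expect_equal(ref$n_ref_atoms, 12L)
  expect_false(ref$fallback_used)

  # 8 atoms in radius inside a 200-atom leaflet -> closest-10 fallback,
  # identical to the exhaustive sort oracle
  withr::with_seed(42, {
    far <- data.frame(atom_id = 9:208, element = "P", leaflet = "upper",
                      x = runif(200, 0, 60), y = runif(200, 0, 60),
                      z = rnorm(200, 18, 0.5))
    keepout <- sqrt((far$x - 30)^2 + (far$y - 30)^2) > 7
    far <- far[keepout, ]
    near <- data.frame(atom_id = 1:8, element = "P", leaflet = "upper",
                       x = 30 + runif(8, -3, 3), y = 30 + runif(8, -3, 3),
                       z = rnorm(8, 18, 0.5))
  })
  atoms <- rbind(near, far)
  snap <- manual_snapshot(atoms)
  got <- local_phosphate_reference(30, 30, snap, "upper")
  expect_true(got$fallback_used)
  expect_equal(got$n_ref_atoms, 10L)
  oracle <- brute_reference(30, 30, atoms, 60, 60)
  expect_equal(got$ref_z, oracle$ref_z, tolerance = 1e-12)
})

test_that("periodic boundaries match an unwrapped 3x3 tiling computation", {
  withr::with_seed(7, {
    atoms <- data.frame(atom_id = 1:150, element = "P", leaflet = "upper",
                        x = runif(150, 0, 60), y = runif(150, 0, 60),
                        z = rnorm(150, 18, 1))
  })
  snap <- manual_snapshot(atoms)
  corners <- expand.grid(x = c(0.1, 59.9, 30), y = c(0.2, 59.8, 30))
  for (i in seq_len(nrow(corners))) {
    got <- local_phosphate_reference(corners$x[i], corners$y[i], snap, "upper")
    oracle <- tiled_reference(corners$x[i], corners$y[i], atoms, 60, 60)
    expect_equal(got$ref_z, oracle$ref_z, tolerance = 1e-12)
    expect_equal(got$fallback_used, oracle$fallback)
  }
})

test_that("insertion depth follows the sign convention", {
  atoms <- data.frame(atom_id = 1:24, element = "P",
                      leaflet = rep(c("upper", "lower"), each = 12),
                      x = rep(30 + cos(1:12), 2), y = rep(30 + sin(1:12), 2),
                      z = rep(c(18, -18), each = 12))
  snap <- manual_snapshot(atoms)
  frames <- data.frame(replicate_id = 1L, replica_id = 1L, step = 1:3,
                       pH = 7, prot_state = 0L,
                       group_x = 30, group_y = 30,
                       group_z = c(15, 25, -15), snapshot_id = "manual")
  rec <- compute_insertion(frames, snap)
  expect_equal(rec$d[rec$step == 1], 3)                         # inserted
  expect_equal(rec$d[rec$step == 2], -7)                        # water side
  expect_equal(rec$leaflet[rec$step == 3], "lower")
  expect_equal(rec$d[rec$step == 3], 3)                         # mirrored
})

test_that("pipeline reference equals brute force on random frames", {
  withr::with_seed(11, {
    atoms <- data.frame(atom_id = 1:300, element = sample(c("P", "O"), 300,
                                                          replace = TRUE),
                        leaflet = "upper",
                        x = runif(300, 0, 62), y = runif(300, 0, 62),
                        z = rnorm(300, 18, 0.8))
    gx <- runif(1200, 0, 62)
    gy <- runif(1200, 0, 62)
  })
  snap <- manual_snapshot(atoms, box_x = 62, box_y = 62)
  got <- local_phosphate_reference(gx, gy, snap, "upper")
  for (i in seq_len(1200)) {
    oracle <- brute_reference(gx[i], gy[i], atoms, 62, 62)
    expect_equal(got$ref_z[i], oracle$ref_z, tolerance = 1e-12)
    expect_equal(got$n_ref_atoms[i], oracle$n)
  }
})

test_that("joint lateral translation (mod box) leaves d unchanged", {
  cfg <- sim_config(n_steps = 200L, n_replicates = 1L)
  b <- run_simulation(cfg)
  rec <- compute_insertion(b)
  shift <- c(17.3, -24.9)
  snap2 <- b$snapshots[[1]]
  snap2$atoms$x <- (snap2$atoms$x + shift[1]) %% snap2$box_x
  snap2$atoms$y <- (snap2$atoms$y + shift[2]) %% snap2$box_y
  fr2 <- b$frames
  fr2$group_x <- (fr2$group_x + shift[1]) %% snap2$box_x
  fr2$group_y <- (fr2$group_y + shift[2]) %% snap2$box_y
  rec2 <- compute_insertion(fr2, snap2)
  expect_equal(rec2$d, rec$d, tolerance = 1e-9)
})

test_that("with zero deformation and zero jitter d is exact", {
  cfg <- sim_config(n_steps = 300L, n_replicates = 1L,
                    membrane = list(jitter_sd = 0, deformation_amplitude = 0,
                                    oxygens_per_phosphate = 0L))
  b <- run_simulation(cfg)
  rec <- compute_insertion(b)
  expect_equal(rec$d, cfg$membrane$plane_offset - b$frames$group_z,
               tolerance = 1e-12)
})

test_that("deformed-surface depths track the analytic truth at high density", {
  cfg <- sim_config(n_steps = 2500L, n_replicates = 1L,
                    membrane = list(lipids_per_leaflet = 256L, jitter_sd = 0,
                                    deformation_wavelength = 62))
  b <- run_simulation(cfg)
  rec <- compute_insertion(b)
  fr <- b$frames
  d_true <- membrane_surface_z(fr$group_x, fr$group_y, cfg$membrane) -
    fr$group_z
  expect_lt(max(abs(rec$d - d_true)), 0.5)
})
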