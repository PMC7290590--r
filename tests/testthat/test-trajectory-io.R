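test_that("an empty bundle survives the round trip", {
  cfg <- sim_config(n_steps = 0L, n_replicates = 1L)
  b <- run_simulation(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frames(b, path)
  b2 <- read_frames(path)
  expect_equal(nrow(b2$frames), 0)
  expect_named(b2$snapshots, "snap1")
  expect_equal(b2$metadata$format_version, 1L)
})

test_that("random bundles round-trip losslessly at format precision", {
  for (seed in c(2, 3)) {
    cfg <- sim_config(n_steps = 125L, n_replicates = 2L, seed = seed)
    b <- run_simulation(cfg)
    expect_equal(nrow(b$frames), 125 * 4 * 2)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_frames(b, path)
    b2 <- read_frames(path)
    expect_equal(nrow(b2$frames), nrow(b$frames))  # no silent row drops
    for (cc in c("replicate_id", "replica_id", "step", "prot_state",
                 "snapshot_id"))
      expect_identical(b2$frames[[cc]], b$frames[[cc]])
    for (cc in c("time", "pH", "group_x", "group_y", "group_z"))
      expect_equal(b2$frames[[cc]], b$frames[[cc]], tolerance = 1e-6)
    s1 <- b$snapshots[[1]]; s2 <- b2$snapshots[[1]]
    expect_equal(s2$box_x, s1$box_x)
    expect_identical(s2$atoms$element, s1$atoms$element)
    expect_identical(s2$atoms$leaflet, s1$atoms$leaflet)
    expect_equal(s2$atoms$z, s1$atoms$z, tolerance = 1e-6)
    expect_equal(s2$metadata$plane_offset, s1$metadata$plane_offset)
  }
})

test_that("malformed frame files are rejected with row-addressed errors", {
  cfg <- sim_config(n_steps = 5L, n_replicates = 1L)
  b <- run_simulation(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_frames(b, path, membrane_path = mpath)

  lines <- readLines(path)
  body_at <- grep("^replicate_id", lines)
  set_field <- function(line, col, value) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    f[col] <- value
    paste(f, collapse = "\t")
  }
  corrupt <- lines
  corrupt[body_at + 2] <- set_field(corrupt[body_at + 2], 6, "2")
  bad_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(corrupt, bad_path)
  expect_error(read_frames(bad_path, mpath),
               "prot_state.*row 2", class = "memtitrate_format_error")

  # missing column
  corrupt2 <- lines
  corrupt2[body_at] <- set_field(corrupt2[body_at], 5, "acid")
  writeLines(corrupt2, bad_path)
  expect_error(read_frames(bad_path, mpath),
               "missing column", class = "memtitrate_format_error")

  # unknown snapshot id
  corrupt3 <- lines
  corrupt3[body_at + 1] <- set_field(corrupt3[body_at + 1], 10, "ghost")
  writeLines(corrupt3, bad_path)
  expect_error(read_frames(bad_path, mpath),
               "snapshot_id.*row 1", class = "memtitrate_format_error")
})

test_that("structure files convert units and select phosphate atoms", {
  gro <- c("two atoms", "    2",
           "    1MEM      P    1   1.000   2.000   2.000",
           "    1MEM     C1    2   1.000   1.000   1.000",
           "   6.00000   6.00000   6.00000")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  snap <- read_structure(path)
  expect_equal(nrow(snap$atoms), 1)
  expect_equal(snap$atoms$z, 20)   # 2 nm -> 20 A
  expect_equal(snap$atoms$x, 10)
  expect_equal(snap$box_x, 60)

  writeLines(c("none", "    1",
               "    1MEM     C1    1   1.000   1.000   1.000",
               "   6.00000   6.00000   6.00000"), path)
  expect_error(read_structure(path), "no phosphate-group atoms selected",
               class = "memtitrate_format_error")

  writeLines(c("short", "    5",
               "    1MEM      P    1   1.000   1.000   1.000",
               "   6.00000   6.00000   6.00000"), path)
  expect_error(read_structure(path), "atom-count mismatch",
               class = "memtitrate_format_error")
})

test_that("a flat synthetic membrane survives the structure-format round trip", {
  cfg <- sim_config(membrane = list(lipids_per_leaflet = 64L,
                                    deformation_amplitude = 0))
  snap <- build_membrane(cfg, seed = 2)
  path <- withr::local_tempfile(fileext = ".gro")
  write_structure(snap, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(snap$atoms))
  expect_identical(back$atoms$leaflet, snap$atoms$leaflet)
  expect_equal(back$atoms$z, snap$atoms$z, tolerance = 0.006)  # 0.001 nm grid
  expect_identical(back$atoms$element, snap$atoms$element)
})
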