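test_that("exchange probability follows the semi-grand-canonical criterion", {
  expect_equal(exchange_probability(7, 8, 1, 1), 1)   # equal proton counts
  expect_equal(exchange_probability(7, 7, 1, 0), 1)   # equal pH
  expect_equal(exchange_probability(7, 8, 1, 0), 0.1) # 10^((-1)(1))
  expect_equal(exchange_probability(7, 8, 0, 1), 1)   # favourable swap
  # symmetric under simultaneous swap of (i, j)
  expect_equal(exchange_probability(7.3, 9.1, 1, 0),
               exchange_probability(9.1, 7.3, 0, 1))
})

test_that("a zero-step run yields an empty frame table with valid structure", {
  cfg <- sim_config(n_steps = 0L, n_replicates = 1L)
  b <- run_simulation(cfg)
  expect_equal(nrow(b$frames), 0)
  expect_named(b$snapshots, "snap1")
  expect_identical(b$metadata$config$pH_ladder, cfg$pH_ladder)
})

test_that("trajectories are deterministic in the seed and differ by replicate", {
  cfg <- small_config()
  expect_identical(run_replicate(cfg, 1), run_replicate(cfg, 1))
  r1 <- run_replicate(cfg, 1)
  r2 <- run_replicate(cfg, 2)
  expect_false(identical(r1$group_z, r2$group_z))
  cfg2 <- small_config(seed = 99L)
  expect_false(identical(run_replicate(cfg2, 1)$group_z, r1$group_z))
})

test_that("exchange requires a ladder and conserves pH labels at every step", {
  cfg <- small_config(pH_ladder = 9)
  expect_error(run_replicate(cfg, 1, exchange = TRUE),
               class = "memtitrate_config_error")

  cfg <- small_config()
  fr <- run_replicate(cfg, 1)
  lab <- vapply(split(fr$pH, fr$step),
                function(p) identical(sort(p), cfg$pH_ladder), TRUE)
  expect_true(all(lab))
})

test_that("bulk limit with flat equal potentials titrates to one half", {
  cfg <- sim_config(n_steps = 20000L, n_replicates = 1L, pH_ladder = 9,
                    potential_neutral = list(well_depth = 0),
                    potential_protonated = list(well_depth = 0),
                    interface_well = list(depth = 0))
  stopifnot(cfg$pka_water == 9)
  fr <- run_replicate(cfg, 1, exchange = FALSE)
  f <- mean(fr$prot_state)
  n_eff <- cfg$n_steps / cfg$titration_period
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n_eff))
})

test_that("sampled (d, s) histograms match the integrated stationary law", {
  # reduced-size stationarity check (the full-scale one lives with the
  # acceptance suite): 2 replicates, subsampled far beyond the measured
  # autocorrelation time so multinomial errors apply
  cfg <- sim_config(n_steps = 60000L, n_replicates = 2L)
  b <- run_simulation(cfg)
  fr <- b$frames
  fr$d_true <- membrane_surface_z(fr$group_x, fr$group_y, cfg$membrane) -
    fr$group_z
  fr <- fr[fr$step > cfg$n_steps * 0.5 & fr$step %% 1000 == 0, ]
  breaks <- seq(-9, 16, by = 2)
  for (ph in cfg$pH_ladder) {
    sub <- fr[fr$pH == ph, ]
    N <- nrow(sub)
    ex <- stationary_bin_probabilities(cfg, ph, breaks)
    for (i in seq_len(nrow(ex))) {
      if (N * ex$prob[i] >= 20) {
        obs <- sum(sub$d_true >= ex$d_lo[i] & sub$d_true < ex$d_hi[i] &
                     sub$prot_state == ex$prot_state[i])
        z <- (obs - N * ex$prob[i]) / sqrt(N * ex$prob[i] * (1 - ex$prob[i]))
        expect_lt(abs(z), 3.5)
      }
    }
  }
})

test_that("replica pH occupancies are uniform under exchange", {
  cfg <- sim_config(n_steps = 100000L, n_replicates = 1L)
  fr <- run_replicate(cfg, 1)
  fr <- fr[fr$step > cfg$n_steps * 0.5 & fr$step %% 1000 == 0, ]
  for (r in seq_along(cfg$pH_ladder)) {
    counts <- table(factor(fr$pH[fr$replica_id == r], levels = cfg$pH_ladder))
    p <- stats::chisq.test(counts)$p.value
    expect_gt(p, 0.05)
  }
})
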