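test_that("burn-in removal drops the leading fraction per series", {
  rec <- data.frame(replicate_id = rep(1:2, each = 10),
                    replica_id = 1L, step = rep(1:10, 2),
                    pH = 7, prot_state = 0L, d = 1)
  expect_identical(discard_burn_in(rec, 0), rec)
  half <- discard_burn_in(rec, 0.5)
  expect_equal(nrow(half), 10)
  expect_true(all(half$step >= 6))
  expect_equal(as.vector(table(half$replicate_id)), c(5L, 5L))
  # odd lengths: ceiling(fraction * n) dropped
  odd <- discard_burn_in(rec[1:7, ], 0.5)
  expect_equal(odd$step, 5:7)
})

test_that("binning is half-open, conservative and matches a group-by oracle", {
  rec1 <- data.frame(replicate_id = 1L, replica_id = 1L, step = 1L,
                     pH = 7, prot_state = 1L, d = 2.3)
  cells <- bin_records(rec1, bin_width = 1)
  expect_equal(cells$d_lo, 2)
  expect_equal(cells$d_hi, 3)

  withr::with_seed(8, {
    rec <- data.frame(replicate_id = sample(1:5, 1e4, TRUE),
                      replica_id = 1L, step = 1:1e4,
                      pH = sample(c(7, 8, 9, 10), 1e4, TRUE),
                      prot_state = sample(0:1, 1e4, TRUE),
                      d = runif(1e4, -8, 14))
  })
  cells <- bin_records(rec, bin_width = 1)
  expect_equal(sum(cells$n_frames), nrow(rec))  # conservation
  # naive group-by oracle
  key <- paste(floor(rec$d), rec$pH, rec$replicate_id)
  oracle <- tapply(rec$prot_state, key, mean)
  got <- cells$mean_prot
  names(got) <- paste(cells$d_lo, cells$pH, cells$replicate_id)
  expect_equal(as.numeric(got[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-12)
  expect_true(all(cells$mean_prot >= 0 & cells$mean_prot <= 1))
})

test_that("quality gating assigns the documented statuses", {
  cell <- function(pH, rep, prot) data.frame(pH = pH, replicate_id = rep,
                                             mean_prot = prot, n_frames = 10L)
  one_ph <- rbind(cell(7, 1, 0.8), cell(7, 2, 0.7))
  expect_equal(bin_quality(one_ph), "insufficient_pH")
  one_rep <- rbind(cell(7, 1, 0.8), cell(8, 1, 0.3))
  expect_equal(bin_quality(one_rep), "insufficient_replicates")
  good <- rbind(cell(7, 1, 0.8), cell(7, 2, 0.8), cell(8, 1, 0.3),
                cell(8, 2, 0.3))
  expect_equal(bin_quality(good), "ok")
  rising <- rbind(cell(7, 1, 0.5), cell(7, 2, 0.5), cell(8, 1, 0.7),
                  cell(8, 2, 0.7))
  expect_equal(bin_quality(rising), "non_monotonic")
  # ties pass (non-strict monotonicity)
  flat <- rbind(cell(7, 1, 0.5), cell(7, 2, 0.5), cell(8, 1, 0.5),
                cell(8, 2, 0.5))
  expect_equal(bin_quality(flat), "ok")
  # tolerance admits small rises
  expect_equal(bin_quality(rising, monotonic_tolerance = 0.25), "ok")
})

test_that("the Henderson-Hasselbalch fit is exact on noiseless data", {
  for (pka in c(6.2, 9.0, 10.4)) {
    cur3 <- data.frame(pH = c(pka - 1, pka, pka + 1), prot = hh(c(pka - 1,
                       pka, pka + 1), pka))
    expect_equal(fit_hh(cur3)$pka, pka, tolerance = 1e-6)
    pts <- seq(pka - 1.5, pka + 1.5, by = 1)
    cur4 <- data.frame(pH = pts, prot = hh(pts, pka))
    expect_equal(fit_hh(cur4)$pka, pka, tolerance = 1e-6)
  }
  # single point: closed form pKa = pH + log10(x / (1 - x))
  expect_equal(fit_hh(data.frame(pH = 8, prot = 0.5))$pka, 8)
  expect_equal(fit_hh(data.frame(pH = 8, prot = 0.9))$pka,
               8 + log10(0.9 / 0.1))
  expect_equal(fit_hh(data.frame(pH = 8, prot = 1))$status, "fit_failed")
})

test_that("the fit matches a dense grid-search minimiser on noisy curves", {
  withr::with_seed(13, {
    for (k in 1:5) {
      pka <- runif(1, 7, 10)
      pH <- seq(floor(pka) - 1.5, floor(pka) + 1.5, by = 1)
      y <- pmin(1, pmax(0, hh(pH, pka) + rnorm(4, 0, 0.05)))
      got <- fit_hh(data.frame(pH = pH, prot = y))$pka
      grid <- seq(min(pH) - 5, max(pH) + 5, by = 1e-4)
      sse <- vapply(grid, function(kk) sum((y - hh(pH, kk))^2), 0)
      expect_equal(got, grid[which.min(sse)], tolerance = 1e-3)
    }
  })
})

test_that("SEM is zero for identical replicate means and non-negative otherwise", {
  cells <- data.frame(pH = rep(c(8, 9), each = 3), replicate_id = rep(1:3, 2),
                      mean_prot = rep(c(0.7, 0.3), each = 3), n_frames = 5L)
  cur <- titration_curve(cells)
  expect_equal(cur$sem, c(0, 0))
  expect_equal(cur$n_replicates, c(3L, 3L))
  cells$mean_prot <- cells$mean_prot + c(-0.01, 0, 0.01)
  cur2 <- titration_curve(cells)
  expect_true(all(cur2$sem > 0))
  expect_equal(cur2$sem[1], sd(c(0.69, 0.70, 0.71)) / sqrt(3))
})

test_that("the Bayesian bootstrap is degenerate-exact and seed-reproducible", {
  # cells exactly on one HH curve: every Dirichlet reweighting reproduces the
  # same per-pH means, so the SE collapses to zero
  cells <- data.frame(pH = rep(c(8, 9, 10), each = 3),
                      replicate_id = rep(1:3, 3),
                      mean_prot = rep(hh(c(8, 9, 10), 9), each = 3),
                      n_frames = 10L)
  bs <- bayesian_bootstrap_pka(cells, B = 200, seed = 5)
  expect_lt(bs$se, 1e-9)
  expect_equal(bs$n_retained, 200)

  noisy <- cells
  withr::with_seed(3, noisy$mean_prot <- pmin(1, pmax(0, noisy$mean_prot +
                                                        rnorm(9, 0, 0.03))))
  b1 <- bayesian_bootstrap_pka(noisy, B = 300, seed = 17)
  b2 <- bayesian_bootstrap_pka(noisy, B = 300, seed = 17)
  expect_identical(b1$se, b2$se)
  expect_gt(b1$se, 0)
  b3 <- bayesian_bootstrap_pka(noisy, B = 300, seed = 18)
  expect_false(identical(b1$se, b3$se))
  # gating is a precondition
  bad <- cells[cells$pH == 8, ]
  expect_error(bayesian_bootstrap_pka(bad), class = "memtitrate_data_error")
})

test_that("bootstrap SE tracks the true sampling spread of the pKa estimate", {
  # Monte-Carlo oracle: regenerate replicate-jittered bins many times; the
  # spread of their fitted pKa values is the ground-truth SE that the
  # Bayesian bootstrap should estimate
  pka0 <- 9; pHs <- c(8, 9, 10); n_rep <- 5; sigma <- 0.03
  make_cells <- function() {
    data.frame(pH = rep(pHs, each = n_rep), replicate_id = rep(1:n_rep, 3),
               mean_prot = pmin(1, pmax(0, rep(hh(pHs, pka0), each = n_rep) +
                                          rnorm(3 * n_rep, 0, sigma))),
               n_frames = 50L)
  }
  withr::with_seed(21, {
    pkas <- numeric(200)
    boot_se <- numeric(200)
    for (i in 1:200) {
      cells <- make_cells()
      pkas[i] <- fit_hh(titration_curve(cells))$pka
      boot_se[i] <- bayesian_bootstrap_pka(cells, B = 100, seed = i)$se
    }
  })
  truth <- sd(pkas)
  expect_lt(abs(mean(boot_se) - truth) / truth, 0.30)
})

test_that("profiles recover the generating pKa and normalise abundances", {
  rec <- exact_hh_records(d = 2.3)
  pr <- build_profiles(rec, burn_in = 0, bootstraps = 100, seed = 2)
  expect_equal(nrow(pr$pka_profile), 1)
  expect_equal(pr$pka_profile$status, "ok")
  expect_equal(pr$pka_profile$pka, 9, tolerance = 1e-6)
  expect_equal(pr$pka_profile$n_frames, nrow(rec))

  # abundance fractions sum to one per pH
  cfg <- sim_config(n_steps = 3000L, n_replicates = 2L)
  b <- run_simulation(cfg)
  pr2 <- build_profiles(compute_insertion(b), config = cfg, bootstraps = 50)
  sums <- tapply(pr2$abundance$fraction, pr2$abundance$pH, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)
  expect_true(all(pr2$charge$mean_charge >= 0 & pr2$charge$mean_charge <= 1))
  # gated bins never carry a pKa; statuses partition the bins
  p <- pr2$pka_profile
  expect_true(all(is.na(p$pka[p$status != "ok"])))
  expect_true(all(!is.na(p$pka[p$status == "ok"])))
})

test_that("monotone truth yields a near-monotone recovered profile", {
  cfg <- sim_config(n_steps = 30000L, n_replicates = 3L)
  b <- run_simulation(cfg)
  pr <- build_profiles(compute_insertion(b), config = cfg, bootstraps = 200)
  ok <- pr$pka_profile[pr$pka_profile$status == "ok" &
                         pr$pka_profile$n_frames >= 500, ]
  ok <- ok[order(ok$d_center), ]
  rise <- diff(ok$pka)
  allowance <- 2 * sqrt(ok$bootstrap_se[-1]^2 + ok$bootstrap_se[-nrow(ok)]^2)
  expect_true(all(rise <= pmax(allowance, 0.1)))
})
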