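test_that("toy lead fields have rank 3, decay with distance, reproduce", {
  pos <- rbind(c(0, 0, 0), c(0.8, 0, 0), c(0.1, -0.2, 0.3),
               c(-0.5, 0.4, 0.1), c(0, 0.6, -0.6))
  lf <- make_toy_leadfields(50, pos, seed = 1)
  expect_length(lf$leadfields, 5)
  for (L in lf$leadfields) {
    expect_equal(dim(L), c(50, 3))
    expect_equal(qr(L)$rank, 3)
  }
  lf2 <- make_toy_leadfields(50, pos, seed = 1)
  expect_identical(lf$leadfields, lf2$leadfields)

  # source near the sensor shell couples more strongly than a deep one
  norm_center <- sqrt(sum(lf$leadfields[[1]]^2))
  norm_surface <- sqrt(sum(lf$leadfields[[2]]^2))
  expect_gt(norm_surface, norm_center)

  expect_error(make_toy_leadfields(5, pos), "at least 10")
  expect_error(make_toy_leadfields(50, matrix(c(2, 0, 0), 1)),
               "unit sphere")
})

test_that("population dwPLI is monotone in coupling with exact endpoints", {
  expect_equal(expected_dwpli(0, pi / 2), 0)
  expect_equal(expected_dwpli(1, pi / 2), 1)
  expect_equal(expected_dwpli(0.7, 0), 0)

  grid <- seq(0, 1, by = 0.05)
  for (phi in c(pi / 6, pi / 4, pi / 2, 3 * pi / 4)) {
    vals <- vapply(grid, expected_dwpli, numeric(1), phase_lag = phi)
    expect_true(all(diff(vals) > -1e-12),
                info = sprintf("phi = %.2f", phi))
  }
  expect_error(expected_dwpli(1.2, pi / 2), "\\[0, 1\\]")
})

test_that("simulated sources hit the analytic dwPLI targets", {
  # full coupling at a quarter-cycle lag: dwPLI near 1 in the band
  cfg <- sim_config(2, list(coupling_spec(1, 2, "theta", 1, pi / 2)),
                    fs = 128, n_trials = 200, source_noise_sd = 0.2,
                    seed = 42)
  adj <- connectivity_matrices(simulate_sources(cfg), "theta")$theta
  expect_gte(adj[1, 2], 0.9)

  # uncoupled sources: mean dwPLI near 0
  cfg0 <- sim_config(4, list(), fs = 128, n_trials = 100,
                     source_noise_sd = 1, seed = 43)
  adj0 <- connectivity_matrices(simulate_sources(cfg0), "theta")$theta
  expect_lt(max(abs(adj0[upper.tri(adj0)])), 0.05 + 0.05)

  # zero-lag full coupling (volume-conduction surrogate): dwPLI ~ 0
  cfgz <- sim_config(2, list(coupling_spec(1, 2, "theta", 1, 0)),
                     fs = 128, n_trials = 200, source_noise_sd = 0,
                     seed = 44)
  adjz <- connectivity_matrices(simulate_sources(cfgz), "theta")$theta
  expect_lt(adjz[1, 2], 0.05)

  # moderate coupling converges to the numeric-integration target
  cfgm <- sim_config(2, list(coupling_spec(1, 2, "theta", 0.3, pi / 2)),
                     fs = 128, n_trials = 400, source_noise_sd = 0,
                     seed = 45)
  adjm <- connectivity_matrices(simulate_sources(cfgm), "theta")$theta
  expect_equal(adjm[1, 2], expected_dwpli(0.3, pi / 2), tolerance = 0.05)
})

test_that("sensor projection is linear, seeded, and rank-1 for one source", {
  pos <- matrix(c(0.3, 0, 0), 1)
  lf <- make_toy_leadfields(12, pos, seed = 3)
  cfg <- sim_config(1, list(), fs = 128, n_trials = 16,
                    source_noise_sd = 1, seed = 5)
  src <- simulate_sources(cfg)
  ori <- matrix(c(1, 0, 0), 1)
  sens <- project_to_sensors(src, lf$leadfields, ori,
                             sensor_snr_db = Inf)
  x <- sens$data[1, , ]
  expect_equal(qr(x)$rank, 1)

  sens_a <- project_to_sensors(src, lf$leadfields, ori, 10, seed = 9)
  sens_b <- project_to_sensors(src, lf$leadfields, ori, 10, seed = 9)
  expect_identical(sens_a$data, sens_b$data)

  src2 <- src
  src2$data <- 2 * src2$data
  sens2 <- project_to_sensors(src2, lf$leadfields, ori,
                              sensor_snr_db = Inf)
  expect_equal(sens2$data, 2 * sens$data)
})

test_that("adjacency cohorts are valid, seeded, and noise-free when asked", {
  spec <- cohort_spec(groups = c(LP = 3, RP = 3), bands = "theta",
                      seed = 7)
  coh <- generate_cohort(spec)
  for (s in coh$subjects) {
    m <- s$matrices$theta
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  coh2 <- generate_cohort(spec)
  expect_identical(coh$subjects[[1]]$matrices$theta,
                   coh2$subjects[[1]]$matrices$theta)

  spec0 <- cohort_spec(groups = c(LP = 3, RP = 3), bands = "theta",
                       between_subject_sd = 0, seed = 7)
  coh0 <- generate_cohort(spec0)
  lp <- cohort_matrices(coh0, "theta", "LP")
  expect_identical(lp[[1]], lp[[2]])
  rp <- cohort_matrices(coh0, "theta", "RP")
  # implanted RP effect shifts the expected matrices between groups
  expect_gt(max(abs(rp[[1]] - lp[[1]])), 0.05)

  expect_error(cohort_spec(groups = c(LP = 1, RP = 5)), ">= 2")
})

test_that("null cohorts give calibrated edgewise t statistics", {
  coh <- null_theta_cohort(15, seed = 31)
  tm <- edge_tstats(cohort_matrices(coh, "theta", "RP"),
                    cohort_matrices(coh, "theta", "LP"))
  tv <- tm[upper.tri(tm)]
  expect_lt(abs(mean(tv)), 0.03)
  # t with 28 df has variance 28/26
  expect_gt(var(tv), 0.9)
  expect_lt(var(tv), 1.25)
})

test_that("cohorts round-trip through the on-disk layout", {
  spec <- cohort_spec(groups = c(LP = 2, RP = 2), bands = c("theta",
                                                            "alpha"),
                      seed = 3)
  coh <- generate_cohort(spec)
  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$subjects[[1]]$id, coh$subjects[[1]]$id)
  expect_equal(back$subjects[[3]]$group, "RP")
  expect_equal(back$subjects[[2]]$matrices$alpha,
               coh$subjects[[2]]$matrices$alpha, tolerance = 1e-8)
})

test_that("sensor-mode cohorts run the full forward model", {
  spec <- cohort_spec(groups = c(LP = 2, RP = 2),
                      base_couplings = list(coupling_spec(1, 2, "theta",
                                                          0.8, pi / 2)),
                      effect_edges = list(LP = list(), RP = list()),
                      mode = "sensor", bands = "theta", n_rois = 4,
                      fs = 128, n_trials = 16, n_sensors = 20, seed = 11)
  coh <- generate_cohort(spec)
  expect_length(coh$subjects, 4)
  expect_s3_class(coh$subjects[[1]]$sensors, "hemilat_sensor_set")
  expect_equal(dim(coh$subjects[[1]]$sensors$data), c(16, 20, 384))
})
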