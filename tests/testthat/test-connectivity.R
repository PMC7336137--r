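make_ve <- function(n_rois = 2, n_trials = 8, n = 60, fs = 20,
                    seed = 1, trial_index = seq_len(n_trials)) {
  set.seed(seed)
  ve_set(array(rnorm(n_rois * n_trials * n),
               dim = c(n_rois, n_trials, n)),
         fs = fs, trial_length = n / fs, trial_index = trial_index)
}

test_that("12-s trials are formed only from consecutive 3-s survivors", {
  ve <- make_ve(2, 9, 30, fs = 10)  # nine 3-s trials
  out <- segment_trials(ve, 12)
  expect_equal(dim(out$data), c(2, 2, 120))
  # first group is the concatenation of trials 1..4
  expect_equal(out$data[1, 1, 1:30], ve$data[1, 1, ])
  expect_equal(out$data[1, 1, 91:120], ve$data[1, 4, ])

  # trial 4 rejected: only {5,6,7,8} forms a 12-s trial
  ve_gap <- make_ve(1, 8, 30, fs = 10,
                    trial_index = c(1, 2, 3, 5, 6, 7, 8, 9))
  out_gap <- segment_trials(ve_gap, 12)
  expect_equal(dim(out_gap$data)[2], 1)
  expect_equal(out_gap$data[1, 1, 1:30], ve_gap$data[1, 4, ])
  expect_equal(out_gap$data[1, 1, 91:120], ve_gap$data[1, 7, ])

  # identity on already-matching length; error when nothing fits
  expect_identical(segment_trials(ve, 3), ve)
  ve_short <- make_ve(1, 3, 30, fs = 10)
  expect_error(segment_trials(ve_short, 12), "consecutive")
})

test_that("cross-spectra have Hermitian structure and analytic phases", {
  ve <- make_ve(3, 4, 64, fs = 16)
  cs_auto <- trial_cross_spectra(ve, matrix(c(2, 2), 1))
  expect_lt(max(abs(Im(cs_auto$values))), 1e-10)

  cs_ij <- trial_cross_spectra(ve, matrix(c(1, 3), 1))
  cs_ji <- trial_cross_spectra(ve, matrix(c(3, 1), 1))
  expect_equal(cs_ij$values, Conj(cs_ji$values), tolerance = 1e-12)

  # y(t) = x(t - tau) for a sinusoid at a bin frequency: the cross-spectrum
  # phase at that bin is 2 pi f0 tau
  fs <- 32
  n <- 128
  f0 <- 4            # bin frequency (n / fs = 4 s window, bin 16)
  tau <- 1 / (8 * f0)  # 45 degrees
  t_grid <- (0:(n - 1)) / fs
  x <- sin(2 * pi * f0 * t_grid)
  y <- sin(2 * pi * f0 * (t_grid - tau))
  d <- array(0, dim = c(2, 1, n))
  d[1, 1, ] <- x
  d[2, 1, ] <- y
  cs <- trial_cross_spectra(ve_set(d, fs = fs), matrix(c(1, 2), 1))
  bin <- which.min(abs(cs$freqs - f0))
  expect_equal(Arg(cs$values[1, 1, bin]), 2 * pi * f0 * tau,
               tolerance = 1e-6)

  expect_error(trial_cross_spectra(ve, matrix(c(1, 9), 1)), "out of range")
})

test_that("PLI, wPLI and dwPLI match hand enumeration and conventions", {
  # constant +90 degree lag across trials: all indices 1
  n <- 64
  fs <- 16
  k <- 6
  d <- array(0, dim = c(2, k, n))
  t_grid <- (0:(n - 1)) / fs
  set.seed(2)
  for (tr in seq_len(k)) {
    ph <- runif(1, 0, 2 * pi)
    d[1, tr, ] <- cos(2 * pi * 4 * t_grid + ph)
    d[2, tr, ] <- cos(2 * pi * 4 * t_grid + ph - pi / 2)
  }
  cs <- trial_cross_spectra(ve_set(d, fs = fs), matrix(c(1, 2), 1))
  bin <- which.min(abs(cs$freqs - 4))
  expect_equal(phase_lag_indices(cs, "pli")[1, bin], 1)
  expect_equal(phase_lag_indices(cs, "wpli")[1, bin], 1)
  expect_equal(phase_lag_indices(cs, "dwpli")[1, bin], 1)

  # identical signals: Im s = 0 everywhere, all indices 0 by convention
  d2 <- d
  d2[2, , ] <- d2[1, , ]
  cs2 <- trial_cross_spectra(ve_set(d2, fs = fs), matrix(c(1, 2), 1))
  expect_true(all(phase_lag_indices(cs2, "pli") == 0))
  expect_true(all(phase_lag_indices(cs2, "wpli") == 0))
  expect_true(all(phase_lag_indices(cs2, "dwpli") == 0))

  # four trials with Im s = (+1, +1, -1, +1): PLI = 0.5 and dwPLI equals
  # the direct enumeration of the 12 ordered trial products
  im <- c(1, 1, -1, 1)
  fake <- structure(list(
    values = array(complex(real = 0, imaginary = im), dim = c(1, 4, 1)),
    freqs = 1, pairs = matrix(c(1, 2), 1), window = "hann", fs = 1,
    trial_length = 1), class = "hemilat_cross_spectra")
  expect_equal(phase_lag_indices(fake, "pli")[1, 1], 0.5)
  expect_equal(phase_lag_indices(fake, "dwpli")[1, 1], bf_dwpli(im))

  # random imaginary parts: estimator equals the enumeration oracle
  for (s in 1:20) {
    set.seed(s)
    imr <- rnorm(7)
    fk <- fake
    fk$values <- array(complex(real = 0, imaginary = imr),
                       dim = c(1, 7, 1))
    expect_equal(phase_lag_indices(fk, "dwpli")[1, 1], bf_dwpli(imr),
                 tolerance = 1e-12)
  }

  one_trial <- structure(list(
    values = array(complex(real = 1), dim = c(1, 1, 1)), freqs = 1,
    pairs = matrix(c(1, 2), 1), window = "hann", fs = 1,
    trial_length = 1), class = "hemilat_cross_spectra")
  expect_error(phase_lag_indices(one_trial, "dwpli"), "2 trials")
})

test_that("dwPLI ignores amplitude scaling and zero-lag mixtures", {
  cfg <- sim_config(2, list(coupling_spec(1, 2, "alpha", 0.6, pi / 3)),
                    fs = 128, n_trials = 60, source_noise_sd = 0.5,
                    seed = 3)
  src <- simulate_sources(cfg)
  a1 <- connectivity_matrices(src, "alpha")$alpha[1, 2]
  scaled <- src
  scaled$data[2, , ] <- 7.3 * scaled$data[2, , ]
  a2 <- connectivity_matrices(scaled, "alpha")$alpha[1, 2]
  expect_equal(a1, a2, tolerance = 1e-10)

  # two channels as zero-lag mixtures of one common source
  set.seed(4)
  common <- simulate_sources(sim_config(1, list(), fs = 128,
                                        n_trials = 60,
                                        source_noise_sd = 1, seed = 5))
  mix <- array(0, dim = c(2, 60, dim(common$data)[3]))
  mix[1, , ] <- 1.0 * common$data[1, , ]
  mix[2, , ] <- 0.6 * common$data[1, , ]
  mixed <- ve_set(mix, fs = 128, trial_length = 3)
  am <- connectivity_matrices(mixed, "alpha")$alpha[1, 2]
  expect_lt(am, 0.02)
})

test_that("band averaging uses the exact closed bin grid per band", {
  # 3-s trials: 1/3 Hz grid; theta bins are exactly 4, 4.33.., ..., 7
  ve <- make_ve(2, 4, 96, fs = 32)  # 3-s trials
  cs <- trial_cross_spectra(ve, matrix(c(1, 2), 1))
  b <- band_specs("theta")
  in_band <- cs$freqs >= b$f_low & cs$freqs <= b$f_high
  expect_equal(cs$freqs[in_band], seq(4, 7, by = 1 / 3),
               tolerance = 1e-12)

  # constant per-bin values average to the constant
  vals <- matrix(0.42, nrow = 1, ncol = length(cs$freqs))
  adj <- band_adjacency(vals, cs, "theta", 2)
  expect_equal(adj[1, 2], 0.42)
  expect_equal(adj, t(adj))
  expect_equal(diag(adj), c(0, 0))

  # negative debiased estimates are clipped after averaging
  vals_neg <- matrix(-0.1, nrow = 1, ncol = length(cs$freqs))
  expect_equal(band_adjacency(vals_neg, cs, "theta", 2)[1, 2], 0)

  # delta band demands 12-s trials
  expect_error(band_adjacency(vals, cs, "delta", 2), "12-s")
})

test_that("dwPLI debiasing removes the small-sample bias of wPLI^2", {
  set.seed(6)
  n_rep <- 500
  k <- 40
  n <- 64
  dw <- numeric(n_rep)
  w2 <- numeric(n_rep)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  for (r in seq_len(n_rep)) {
    s_k <- complex(length.out = k)
    for (tr in seq_len(k)) {
      s_k[tr] <- fft(rnorm(n) * taper)[5] * Conj(fft(rnorm(n) * taper)[5])
    }
    cs <- structure(list(values = array(s_k, dim = c(1, k, 1)), freqs = 1,
                         pairs = matrix(c(1, 2), 1), window = "hann",
                         fs = 1, trial_length = 1),
                    class = "hemilat_cross_spectra")
    dw[r] <- phase_lag_indices(cs, "dwpli")[1, 1]
    w2[r] <- phase_lag_indices(cs, "wpli")[1, 1]^2
  }
  expect_lt(abs(mean(dw)), 0.01)
  expect_gt(mean(w2), mean(dw))
})
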