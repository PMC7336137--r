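#' Coupling specification for the synthetic generator
#'
#' Describes one directed phase-lag coupling: the band-limited component of
#' node `j` is `sqrt(coupling)` times the carrier of node `i` rotated by a
#' constant phase lag, plus `sqrt(1 - coupling)` times an independent
#' carrier. With `phase_lag` strictly between 0 and pi the pair has a
#' consistent non-zero lag, which is what the phase-lag-index family
#' detects; `phase_lag = 0` produces a pure zero-lag (volume-conduction
#' like) dependence that dwPLI should ignore.
#'
#' @param i,j Node indices (i != j).
#' @param band Band name (see [band_specs()]).
#' @param coupling Fraction of shared carrier variance, in [0, 1].
#' @param phase_lag Phase lag in radians, in (-pi, pi].
#' @return A list of class `hemilat_coupling`.
#' @export
coupling_spec <- function(i, j, band = "theta", coupling = 0.5,
                          phase_lag = pi / 2) {
  if (i == j) stop("coupling requires i != j", call. = FALSE)
  if (coupling < 0 || coupling > 1) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  if (phase_lag <= -pi || phase_lag > pi) {
    stop("phase_lag must lie in (-pi, pi]", call. = FALSE)
  }
  band_specs(band)  # validates the name
  structure(list(i = as.integer(i), j = as.integer(j), band = band,
                 coupling = coupling, phase_lag = phase_lag),
            class = "hemilat_coupling")
}

# hermitian random spectrum restricted to [f_low, f_high]; unit variance
#' @keywords internal
rand_band_spectrum <- function(n, fs, f_low, f_high) {
  z <- complex(real = rep(0, n), imaginary = rep(0, n))
  half <- seq_len(floor((n - 1) / 2))
  freqs <- half * fs / n
  keep <- half[freqs >= f_low & freqs <= f_high]
  if (length(keep) == 0L) {
    stop("no frequency bins inside [", f_low, ", ", f_high, "] Hz",
         call. = FALSE)
  }
  z[keep + 1L] <- complex(real = stats::rnorm(length(keep)),
                          imaginary = stats::rnorm(length(keep)))
  z[n + 1L - keep] <- Conj(z[keep + 1L])
  # scale so the real time series has unit variance
  z * sqrt(n / (2 * length(keep)))
}

# all-pass rotation: positive-frequency bins multiplied by exp(-i*phi)
#' @keywords internal
rotate_spectrum <- function(z, phi) {
  n <- length(z)
  half <- seq_len(floor((n - 1) / 2))
  z[half + 1L] <- z[half + 1L] * exp(complex(imaginary = -phi))
  z[n + 1L - half] <- Conj(z[half + 1L])
  z
}

#' @keywords internal
spectrum_to_series <- function(z) {
  Re(stats::fft(z, inverse = TRUE)) / sqrt(length(z))
}

#' Simulation configuration for ROI-level sources
#'
#' @param n_rois Number of ROI sources.
#' @param couplings List of [coupling_spec()] objects. Each (node, band) may
#'   be the target (`j`) of at most one coupling.
#' @param fs Sampling rate in Hz (default 678.17, a common MEG acquisition
#'   rate).
#' @param n_trials Number of trials (>= 16).
#' @param trial_length Trial length in seconds (default 3).
#' @param source_noise_sd Standard deviation of broadband background noise
#'   added to every source.
#' @param seed Integer seed.
#' @return A list of class `hemilat_simconfig`.
#' @export
sim_config <- function(n_rois, couplings = list(), fs = 678.17,
                       n_trials = 40, trial_length = 3,
                       source_noise_sd = 1, seed = 1) {
  bands <- band_specs()
  if (fs < 2 * max(bands$f_high)) {
    stop("fs must be at least twice the highest band edge", call. = FALSE)
  }
  if (n_trials < 16) stop("n_trials must be >= 16", call. = FALSE)
  tgt <- character(0)
  for (cs in couplings) {
    stopifnot(inherits(cs, "hemilat_coupling"))
    if (cs$i > n_rois || cs$j > n_rois) {
      stop("coupling references a node beyond n_rois", call. = FALSE)
    }
    key <- paste(cs$j, cs$band)
    if (key %in% tgt) {
      stop("node ", cs$j, " is the target of more than one ", cs$band,
           "-band coupling", call. = FALSE)
    }
    tgt <- c(tgt, key)
  }
  structure(list(n_rois = as.integer(n_rois), couplings = couplings,
                 fs = fs, n_trials = as.integer(n_trials),
                 trial_length = trial_length,
                 source_noise_sd = source_noise_sd, seed = seed),
            class = "hemilat_simconfig")
}

#' Simulate coupled band-limited ROI sources
#'
#' Carriers are band-limited Gaussian processes, independent across trials.
#' For every coupling, the target node's band component is
#' `sqrt(coupling) * rotate(carrier_i, phase_lag) + sqrt(1 - coupling) *
#' independent carrier`; the phase rotation is applied in the frequency
#' domain (all-pass), so the lag is constant across the band.
#'
#' @param config A [sim_config()].
#' @return A virtual-electrode set (see [ve_set()]) with `n_rois` sources.
#' @export
simulate_sources <- function(config) {
  stopifnot(inherits(config, "hemilat_simconfig"))
  n <- round(config$fs * config$trial_length)
  out <- array(0, dim = c(config$n_rois, config$n_trials, n))
  bands <- band_specs()
  with_seed(config$seed, {
    for (tr in seq_len(config$n_trials)) {
      if (config$source_noise_sd > 0) {
        out[, tr, ] <- matrix(stats::rnorm(config$n_rois * n,
                                           sd = config$source_noise_sd),
                              config$n_rois, n)
      }
      for (bname in unique(vapply(config$couplings, `[[`, "", "band"))) {
        b <- bands[bands$name == bname, ]
        specs <- Filter(function(cs) cs$band == bname, config$couplings)
        src_nodes <- unique(vapply(specs, `[[`, 1L, "i"))
        carriers <- lapply(src_nodes, function(i) {
          rand_band_spectrum(n, config$fs, b$f_low, b$f_high)
        })
        names(carriers) <- as.character(src_nodes)
        for (i in src_nodes) {
          out[i, tr, ] <- out[i, tr, ] +
            spectrum_to_series(carriers[[as.character(i)]])
        }
        for (cs in specs) {
          zi <- rotate_spectrum(carriers[[as.character(cs$i)]], cs$phase_lag)
          own <- rand_band_spectrum(n, config$fs, b$f_low, b$f_high)
          out[cs$j, tr, ] <- out[cs$j, tr, ] +
            sqrt(cs$coupling) * spectrum_to_series(zi) +
            sqrt(1 - cs$coupling) * spectrum_to_series(own)
        }
      }
    }
  })
  ve_set(out, fs = config$fs, trial_length = config$trial_length,
         roi_ids = seq_len(config$n_rois))
}

#' Toy lead fields for a spherical sensor array
#'
#' Sensors are placed on a jittered spherical shell of radius 1.2 (arbitrary
#' units; sources live inside the unit sphere) using a Fibonacci lattice.
#' The lead field of a source is a smooth inverse-cube kernel of the
#' sensor-source displacement, one column per Cartesian orientation
#' component, so entries decay with distance and every matrix has full
#' column rank 3. This is deliberately a geometric toy: it preserves the
#' rank/decay structure a beamformer needs without modeling a volume
#' conductor.
#'
#' @param n_sensors Number of sensors (>= 10).
#' @param source_positions Matrix (sources x 3) of positions inside the unit
#'   sphere.
#' @param seed Integer seed (controls shell jitter and per-sensor gains).
#' @return A list with `leadfields` (list of n_sensors x 3 matrices) and
#'   `sensor_positions`.
#' @export
make_toy_leadfields <- function(n_sensors, source_positions, seed = 1) {
  if (n_sensors < 10) stop("need at least 10 sensors", call. = FALSE)
  source_positions <- as.matrix(source_positions)
  if (ncol(source_positions) != 3) {
    stop("source_positions must be an n x 3 matrix", call. = FALSE)
  }
  if (any(sqrt(rowSums(source_positions^2)) >= 1)) {
    stop("sources must lie strictly inside the unit sphere", call. = FALSE)
  }
  with_seed(seed, {
    k <- seq_len(n_sensors)
    golden <- pi * (3 - sqrt(5))
    zs <- 1 - 2 * (k - 0.5) / n_sensors
    r <- sqrt(pmax(0, 1 - zs^2))
    th <- golden * k
    pos <- cbind(r * cos(th), r * sin(th), zs) *
      (1.2 * stats::runif(n_sensors, 0.99, 1.01))
    gains <- exp(stats::rnorm(n_sensors, sd = 0.05))
    if (anyDuplicated(round(pos, 10))) {
      stop("duplicate sensor positions: degenerate geometry", call. = FALSE)
    }
    lfs <- lapply(seq_len(nrow(source_positions)), function(s) {
      d <- sweep(pos, 2, source_positions[s, ])
      dist <- sqrt(rowSums(d^2))
      L <- gains * d / dist^3
      if (qr(L)$rank < 3) {
        stop("rank-deficient lead field for source ", s, call. = FALSE)
      }
      L
    })
    list(leadfields = lfs, sensor_positions = pos)
  })
}

#' Project ROI sources to sensors
#'
#' Forms the sensor data as the superposition of every source's time series
#' through its lead field at a fixed unit orientation, plus white sensor
#' noise scaled to the requested SNR (signal power / noise power, in dB).
#'
#' @param sources A [ve_set()] of source time series.
#' @param leadfields List of M x 3 lead-field matrices, one per source.
#' @param orientations Matrix (sources x 3) of unit orientation vectors.
#' @param sensor_snr_db Sensor-level SNR in dB; `Inf` for noiseless data.
#' @param seed Integer seed for the noise realization.
#' @return A [sensor_trial_set()].
#' @export
project_to_sensors <- function(sources, leadfields, orientations,
                               sensor_snr_db = 20, seed = 1) {
  stopifnot(inherits(sources, "hemilat_ve_set"))
  n_src <- dim(sources$data)[1]
  if (length(leadfields) != n_src || nrow(orientations) != n_src) {
    stop("need one lead field and one orientation per source", call. = FALSE)
  }
  m <- nrow(leadfields[[1]])
  orientations <- orientations / sqrt(rowSums(orientations^2))
  gain <- vapply(seq_len(n_src),
                 function(s) drop(leadfields[[s]] %*% orientations[s, ]),
                 numeric(m))  # M x n_src
  n_trials <- dim(sources$data)[2]
  n <- dim(sources$data)[3]
  b <- array(0, dim = c(n_trials, m, n))
  for (tr in seq_len(n_trials)) {
    b[tr, , ] <- gain %*% sources$data[, tr, ]
  }
  if (is.finite(sensor_snr_db)) {
    p_sig <- mean(b^2)
    noise_sd <- sqrt(p_sig * 10^(-sensor_snr_db / 10))
    with_seed(seed, {
      b <- b + array(stats::rnorm(length(b), sd = noise_sd), dim = dim(b))
    })
  }
  sensor_trial_set(b, fs = sources$fs, trial_length = sources$trial_length)
}

#' Population dwPLI of the generator's coupling model
#'
#' For the coupled-oscillator model used by [simulate_sources()], the dwPLI
#' estimator converges (in the number of trials) to the squared population
#' wPLI, `(E Im s / E |Im s|)^2`, where at any bin inside the band
#' `Im s = sqrt(c) u sin(phi) + sqrt(1 - c) W`, with `u` a unit-mean
#' exponential carrier power and `W | u ~ N(0, u/2)`. The expectation of
#' `|Im s|` is evaluated by numerical integration over `u`; the result is
#' the deterministic target used by the adjacency-mode cohort generator.
#'
#' @param coupling Shared-variance fraction in [0, 1].
#' @param phase_lag Phase lag in radians.
#' @return The population dwPLI, in [0, 1].
#' @export
expected_dwpli <- function(coupling, phase_lag) {
  if (coupling < 0 || coupling > 1) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  a <- sqrt(coupling) * abs(sin(phase_lag))
  if (a == 0) return(0)
  if (coupling >= 1) return(1)
  b2 <- (1 - coupling) / 2
  e_abs <- stats::integrate(function(u) {
    mu <- a * u
    sg <- sqrt(b2 * u)
    (sg * sqrt(2 / pi) * exp(-mu^2 / (2 * sg^2)) +
       mu * (1 - 2 * stats::pnorm(-mu / sg))) * exp(-u)
  }, lower = 0, upper = Inf, rel.tol = 1e-10)$value
  (a / e_abs)^2
}

#' Designated right intra-hemispheric effect subnetwork
#'
#' Selects `n_nodes` nodes by cycling through right-hemisphere (mostly
#' temporal and subcortical) atlas areas, taking successive nodes from
#' each, and returns the first `n_edges` pairwise edges among them
#' (lexicographic order; `n_edges = NULL` keeps the full clique). A clique
#' concentrates triangles, so strengthening its couplings raises
#' segregation (transitivity) together with integration, matching the
#' pattern reported for right-lateralized temporal-lobe epilepsy.
#'
#' @param atlas Atlas table (default [default_atlas()]).
#' @param areas Right-hemisphere area groups to cycle through.
#' @param n_nodes Number of nodes to select.
#' @param n_edges Number of edges to keep, or `NULL` for all pairs.
#' @return Integer matrix (n_edges x 2) of node-id pairs.
#' @export
right_theta_subnetwork <- function(atlas = default_atlas(),
                                   areas = c("R_STG", "R_MTG", "R_ITG",
                                             "R_FuG", "R_IPL", "R_Hipp",
                                             "R_BG", "R_PhG", "R_PCun",
                                             "R_INS", "R_Tha"),
                                   n_nodes = 7, n_edges = 20) {
  pool <- lapply(areas, function(a) {
    ids <- sort(atlas$node_id[atlas$area_group == a])
    if (length(ids) == 0L) stop("area ", a, " not in atlas", call. = FALSE)
    ids
  })
  nodes <- integer(0)
  round_i <- 1L
  while (length(nodes) < n_nodes) {
    for (p in pool) {
      if (length(nodes) >= n_nodes) break
      if (round_i <= length(p)) nodes <- c(nodes, p[round_i])
    }
    round_i <- round_i + 1L
    if (round_i > max(lengths(pool))) break
  }
  if (length(nodes) < n_nodes) {
    stop("not enough nodes in the requested areas", call. = FALSE)
  }
  pairs <- t(utils::combn(sort(nodes), 2))
  if (is.null(n_edges)) n_edges <- nrow(pairs)
  if (n_edges > nrow(pairs)) {
    stop("n_edges exceeds the number of available pairs", call. = FALSE)
  }
  pairs[seq_len(n_edges), , drop = FALSE]
}

# population dwPLI at phase pi/2 on a coupling grid, linearly interpolated;
# exact at the endpoints (used for the dense background edges)
#' @keywords internal
expected_dwpli_interp <- function(coupling) {
  grid <- get_dwpli_grid()
  stats::approx(grid$c, grid$e, xout = coupling, rule = 2)$y
}

.dwpli_grid_env <- new.env(parent = emptyenv())
#' @keywords internal
get_dwpli_grid <- function() {
  if (is.null(.dwpli_grid_env$grid)) {
    cs <- seq(0, 1, by = 0.0025)
    es <- vapply(cs, expected_dwpli, numeric(1), phase_lag = pi / 2)
    .dwpli_grid_env$grid <- list(c = cs, e = es)
  }
  .dwpli_grid_env$grid
}

#' Cohort specification
#'
#' Defines a synthetic three-group cohort. Group sizes default to the
#' unbalanced 22/25/16 (HC/LP/RP) design of the study population the
#' generator emulates. Every subject shares a heterogeneous background
#' connectome: per-edge couplings drawn once per cohort (per band) from
#' `Uniform(0, background_coupling_max)` at a pi/2 phase lag, giving the
#' broad weight distribution real resting dwPLI connectomes show. The
#' default implanted effect raises theta-band coupling by `effect_delta`
#' on the full clique over 15 [right_theta_subnetwork()] nodes for the RP
#' group only, strengthening that subnetwork to the top of - not beyond -
#' the background weight range; `effect_delta = 0` yields a null cohort.
#'
#' @param groups Named integer vector of group sizes (each >= 2).
#' @param base_couplings List of [coupling_spec()] shared by all subjects
#'   (override the background on their edges).
#' @param effect_edges Named list (per group label) of [coupling_spec()]
#'   objects whose `coupling` is a *delta* added to the background/base
#'   coupling of that edge (clipped to [0, 1]).
#' @param effect_delta Convenience scalar used when `effect_edges` is NULL
#'   (see above).
#' @param background_coupling_max Upper end of the per-edge background
#'   coupling distribution (0 disables the background).
#' @param between_subject_sd SD of the subject-level Gaussian perturbation
#'   of adjacency entries.
#' @param mode `"adjacency"` (fast; subject matrices are population dwPLI
#'   plus subject noise) or `"sensor"` (full forward simulation; no
#'   background, `base_couplings`/`effect_edges` only).
#' @param bands Character vector of bands to generate.
#' @param n_rois Number of nodes (246 for atlas-shaped cohorts).
#' @param atlas Atlas used to place the default effect subnetwork.
#' @param fs,n_trials,n_sensors,sensor_snr_db Sensor-mode parameters.
#' @param seed Integer seed.
#' @return A list of class `hemilat_cohort_spec`.
#' @export
cohort_spec <- function(groups = c(HC = 22, LP = 25, RP = 16),
                        base_couplings = list(),
                        effect_edges = NULL,
                        effect_delta = 0.1,
                        background_coupling_max = 0.2,
                        between_subject_sd = 0.05,
                        mode = c("adjacency", "sensor"),
                        bands = band_names(),
                        n_rois = 246,
                        atlas = NULL,
                        fs = 678.17, n_trials = 40, n_sensors = 50,
                        sensor_snr_db = 20,
                        seed = 1) {
  mode <- match.arg(mode)
  if (any(groups < 2)) stop("each group needs >= 2 subjects", call. = FALSE)
  if (is.null(effect_edges)) {
    effect_edges <- stats::setNames(vector("list", length(groups)),
                                    names(groups))
    if (effect_delta != 0 && "RP" %in% names(groups)) {
      if (is.null(atlas) && n_rois == 246) atlas <- default_atlas()
      if (!is.null(atlas)) {
        ed <- right_theta_subnetwork(atlas, n_nodes = 15, n_edges = NULL)
        effect_edges$RP <- lapply(seq_len(nrow(ed)), function(r) {
          coupling_spec(ed[r, 1], ed[r, 2], band = "theta",
                        coupling = effect_delta, phase_lag = pi / 2)
        })
      }
    }
  }
  structure(list(groups = groups, base_couplings = base_couplings,
                 effect_edges = effect_edges,
                 background_coupling_max = background_coupling_max,
                 between_subject_sd = between_subject_sd, mode = mode,
                 bands = bands, n_rois = as.integer(n_rois),
                 fs = fs, n_trials = n_trials, n_sensors = n_sensors,
                 sensor_snr_db = sensor_snr_db, seed = seed),
            class = "hemilat_cohort_spec")
}

# per-band coupling configuration shared by the cohort: background draws
# plus explicit base couplings; returns coupling and phase matrices
#' @keywords internal
cohort_band_couplings <- function(spec, band) {
  n <- spec$n_rois
  base_c <- matrix(0, n, n)
  base_phi <- matrix(pi / 2, n, n)
  if (spec$background_coupling_max > 0) {
    ut <- upper.tri(base_c)
    base_c[ut] <- with_seed(
      derive_seed(spec$seed, 900L + match(band, band_names())),
      stats::runif(sum(ut), 0, spec$background_coupling_max))
    base_c[lower.tri(base_c)] <- t(base_c)[lower.tri(base_c)]
  }
  for (cs in spec$base_couplings) {
    if (cs$band != band) next
    base_c[cs$i, cs$j] <- base_c[cs$j, cs$i] <- cs$coupling
    base_phi[cs$i, cs$j] <- base_phi[cs$j, cs$i] <- cs$phase_lag
  }
  list(coupling = base_c, phase = base_phi)
}

# expected adjacency for one group in one band: interpolated population
# dwPLI for the (dense, pi/2-phase) background, exact integration for any
# edge with a non-default phase
#' @keywords internal
group_expected_adjacency <- function(spec, group, band, base = NULL) {
  if (is.null(base)) base <- cohort_band_couplings(spec, band)
  base_c <- base$coupling
  base_phi <- base$phase
  for (cs in spec$effect_edges[[group]]) {
    if (cs$band != band) next
    cc <- min(1, max(0, base_c[cs$i, cs$j] + cs$coupling))
    base_c[cs$i, cs$j] <- base_c[cs$j, cs$i] <- cc
    base_phi[cs$i, cs$j] <- base_phi[cs$j, cs$i] <- cs$phase_lag
  }
  n <- spec$n_rois
  e <- matrix(0, n, n)
  ut_idx <- which(upper.tri(base_c))
  cvals <- base_c[ut_idx]
  pvals <- base_phi[ut_idx]
  evals <- numeric(length(cvals))
  std <- abs(pvals - pi / 2) < 1e-12
  evals[std] <- expected_dwpli_interp(cvals[std])
  if (any(!std)) {
    evals[!std] <- mapply(expected_dwpli, cvals[!std], pvals[!std])
  }
  evals[cvals == 0] <- 0
  e[ut_idx] <- evals
  symmetrize_zero_diag(e)
}

#' Generate a synthetic cohort
#'
#' In adjacency mode each subject's per-band matrix is the deterministic
#' population dwPLI of the subject's coupling configuration plus a
#' subject-level symmetric Gaussian perturbation, clipped to [0, 1] with a
#' zero diagonal. In sensor mode each subject is simulated end to end
#' ([simulate_sources()] then [project_to_sensors()]).
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `hemilat_cohort` with elements `subjects` (each
#'   with `id`, `group`, and `matrices` or `sensors`), `groups`, `bands`,
#'   and (adjacency mode) `expected` per group. The implanted effect edges
#'   are attached as attribute `effect_edges`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "hemilat_cohort_spec"))
  subjects <- list()
  if (spec$mode == "adjacency") {
    expected <- lapply(stats::setNames(nm = names(spec$groups)), function(g) {
      lapply(stats::setNames(nm = spec$bands), function(b) {
        group_expected_adjacency(spec, g, b)
      })
    })
    sid <- 0L
    n <- spec$n_rois
    ut <- upper.tri(matrix(0, n, n))
    for (g in names(spec$groups)) {
      for (k in seq_len(spec$groups[[g]])) {
        sid <- sid + 1L
        mats <- lapply(stats::setNames(nm = spec$bands), function(b) {
          m <- expected[[g]][[b]]
          if (spec$between_subject_sd > 0) {
            noise <- matrix(0, n, n)
            noise[ut] <- with_seed(
              derive_seed(spec$seed, sid * 101L + match(b, band_names())),
              stats::rnorm(sum(ut), sd = spec$between_subject_sd))
            m <- m + symmetrize_zero_diag(noise)
          }
          m[m < 0] <- 0
          m[m > 1] <- 1
          diag(m) <- 0
          m
        })
        subjects[[sid]] <- list(id = sprintf("%s_%02d", g, k), group = g,
                                matrices = mats)
      }
    }
    out <- list(subjects = subjects, groups = spec$groups,
                bands = spec$bands, expected = expected, spec = spec)
  } else {
    src_pos <- with_seed(derive_seed(spec$seed, 7L), {
      p <- matrix(stats::runif(spec$n_rois * 3, -0.6, 0.6), ncol = 3)
      p
    })
    lf <- make_toy_leadfields(spec$n_sensors, src_pos,
                              seed = derive_seed(spec$seed, 11L))
    ori <- with_seed(derive_seed(spec$seed, 13L), {
      o <- matrix(stats::rnorm(spec$n_rois * 3), ncol = 3)
      o / sqrt(rowSums(o^2))
    })
    sid <- 0L
    for (g in names(spec$groups)) {
      for (k in seq_len(spec$groups[[g]])) {
        sid <- sid + 1L
        couplings <- spec$base_couplings
        for (cs in spec$effect_edges[[g]]) {
          cs$coupling <- min(1, max(0, cs$coupling))
          couplings <- c(couplings, list(cs))
        }
        cfg <- sim_config(spec$n_rois, couplings, fs = spec$fs,
                          n_trials = spec$n_trials,
                          seed = derive_seed(spec$seed, sid * 211L))
        src <- simulate_sources(cfg)
        sens <- project_to_sensors(src, lf$leadfields, ori,
                                   sensor_snr_db = spec$sensor_snr_db,
                                   seed = derive_seed(spec$seed,
                                                      sid * 211L + 1L))
        subjects[[sid]] <- list(id = sprintf("%s_%02d", g, k), group = g,
                                sensors = sens, sources = src)
      }
    }
    out <- list(subjects = subjects, groups = spec$groups,
                bands = spec$bands, leadfields = lf, orientations = ori,
                spec = spec)
  }
  attr(out, "effect_edges") <- spec$effect_edges
  class(out) <- "hemilat_cohort"
  out
}

#' Write an adjacency-mode cohort to disk
#'
#' One directory per subject holding `<subject>_<band>.tsv` adjacency files
#' (no header), plus a top-level `manifest.json` with group labels, bands
#' and the generating seed.
#'
#' @param cohort A `hemilat_cohort` in adjacency mode.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hemilat_cohort"))
  if (is.null(cohort$subjects[[1]]$matrices)) {
    stop("write_cohort supports adjacency-mode cohorts", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$id)
    dir.create(sdir, showWarnings = FALSE)
    for (b in names(s$matrices)) {
      write_connectivity(s$matrices[[b]],
                         file.path(sdir, paste0(s$id, "_", b, ".tsv")))
    }
  }
  manifest <- list(
    subjects = vapply(cohort$subjects, `[[`, "", "id"),
    groups = vapply(cohort$subjects, `[[`, "", "group"),
    bands = cohort$bands,
    seed = cohort$spec$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read an adjacency-mode cohort from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `hemilat_cohort`-like list with `subjects`, `groups`, `bands`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- lapply(seq_along(manifest$subjects), function(k) {
    id <- manifest$subjects[k]
    mats <- lapply(stats::setNames(nm = manifest$bands), function(b) {
      read_connectivity(file.path(dir, id, paste0(id, "_", b, ".tsv")))
    })
    list(id = id, group = manifest$groups[k], matrices = mats)
  })
  structure(list(subjects = subjects,
                 groups = table(manifest$groups),
                 bands = manifest$bands, seed = manifest$seed),
            class = "hemilat_cohort")
}

#' Extract one band's matrices for chosen groups
#'
#' @param cohort A `hemilat_cohort`.
#' @param band Band name.
#' @param group Optional group label filter.
#' @return A named list of adjacency matrices.
#' @export
cohort_matrices <- function(cohort, band, group = NULL) {
  subs <- cohort$subjects
  if (!is.null(group)) {
    subs <- Filter(function(s) s$group %in% group, subs)
  }
  stats::setNames(lapply(subs, function(s) s$matrices[[band]]),
                  vapply(subs, `[[`, "", "id"))
}
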