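#' Sensor-level trial container
#'
#' @param data Numeric array, trials x sensors x samples.
#' @param fs Sampling rate in Hz.
#' @param trial_length Trial length in seconds.
#' @param trial_index Original temporal indices of the trials (used when
#'   grouping 3-s trials into 12-s trials after artifact rejection).
#' @return A list of class `hemilat_sensor_set`.
#' @export
sensor_trial_set <- function(data, fs, trial_length = dim(data)[3] / fs,
                             trial_index = seq_len(dim(data)[1])) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] < 10) stop("need at least 10 sensors", call. = FALSE)
  if (anyNA(data)) stop("sensor data must have no missing samples",
                        call. = FALSE)
  structure(list(data = data, fs = fs, trial_length = trial_length,
                 trial_index = as.integer(trial_index)),
            class = "hemilat_sensor_set")
}

#' Virtual-electrode (source-space) trial container
#'
#' @param data Numeric array, ROI x trials x samples.
#' @param fs Sampling rate in Hz.
#' @param trial_length Trial length in seconds.
#' @param roi_ids ROI identifiers (one per first-dimension slice).
#' @param trial_index Original temporal indices of the trials.
#' @return A list of class `hemilat_ve_set`.
#' @export
ve_set <- function(data, fs, trial_length = dim(data)[3] / fs,
                   roi_ids = seq_len(dim(data)[1]),
                   trial_index = seq_len(dim(data)[2])) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  structure(list(data = data, fs = fs, trial_length = trial_length,
                 roi_ids = roi_ids, trial_index = as.integer(trial_index)),
            class = "hemilat_ve_set")
}

#' Broadband filtering of sensor trials
#'
#' Zero-phase 4th-order Butterworth band-pass (default 0.1-150 Hz) followed
#' by zero-phase 2nd-order band-stop notches at the power-line frequency and
#' its first harmonic (60 and 120 Hz).
#'
#' @param trials A [sensor_trial_set()].
#' @param band_pass Length-2 vector of band-pass edges in Hz.
#' @param notches Center frequencies of the band-stop filters (Hz);
#'   half-width 2 Hz. Use `numeric(0)` to skip.
#' @return The filtered [sensor_trial_set()].
#' @export
broadband_filter <- function(trials, band_pass = c(0.1, 150),
                             notches = c(60, 120)) {
  stopifnot(inherits(trials, "hemilat_sensor_set"))
  nyq <- trials$fs / 2
  bp <- signal::butter(4, band_pass / nyq, type = "pass")
  notch_filts <- lapply(notches[notches + 2 < nyq], function(f0) {
    signal::butter(2, c(f0 - 2, f0 + 2) / nyq, type = "stop")
  })
  d <- trials$data
  for (tr in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      x <- signal::filtfilt(bp, d[tr, ch, ])
      for (nf in notch_filts) x <- signal::filtfilt(nf, x)
      d[tr, ch, ] <- x
    }
  }
  trials$data <- d
  trials
}

#' Broadband data covariance from all trials
#'
#' Covariance of the per-sensor demeaned concatenation of every trial (one
#' time window covering all trials, global demeaning).
#'
#' @param trials A [sensor_trial_set()].
#' @return A list of class `hemilat_cov` with `matrix`, `regularized`
#'   (FALSE), and `noise_floor` (0).
#' @export
broadband_covariance <- function(trials) {
  stopifnot(inherits(trials, "hemilat_sensor_set"))
  d <- trials$data
  n_trials <- dim(d)[1]
  if (n_trials < 2) stop("need at least 2 trials", call. = FALSE)
  m <- dim(d)[2]
  # concatenate trials along time: sensors x (trials * samples)
  x <- matrix(aperm(d, c(2, 3, 1)), nrow = m)
  if (ncol(x) < 2) stop("need more than one sample", call. = FALSE)
  x <- x - rowMeans(x)
  cov <- tcrossprod(x) / (ncol(x) - 1)
  structure(list(matrix = cov, regularized = FALSE, noise_floor = 0),
            class = "hemilat_cov")
}

#' Tikhonov regularization of a covariance matrix
#'
#' Adds a diagonal noise floor equal to `fraction` times the mean eigenvalue
#' of the matrix: `C + fraction * mean(eig(C)) * I`.
#'
#' @param cov A `hemilat_cov` or plain symmetric matrix.
#' @param fraction Noise-floor fraction (default 0.05).
#' @return A regularized `hemilat_cov` (positive definite for any
#'   nonnegative-definite input with positive trace).
#' @export
regularize_covariance <- function(cov, fraction = 0.05) {
  m <- if (inherits(cov, "hemilat_cov")) cov$matrix else cov
  check_square_sym(m, "covariance")
  floor_val <- fraction * mean(diag(m))  # mean eigenvalue = trace / M
  reg <- m + diag(floor_val, nrow(m))
  structure(list(matrix = reg, regularized = TRUE, noise_floor = floor_val),
            class = "hemilat_cov")
}

#' Optimal source orientation from the beamformer source covariance
#'
#' Computes `P(r) = (L^T C^-1 L)^-1` and returns the eigenvector of `P(r)`
#' with the largest eigenvalue. This is the orientation maximizing the
#' unit-gain LCMV output power `1 / (l^T C^-1 l)`, `l = L %*% orientation`.
#' The sign is fixed so that the largest-magnitude component is positive.
#'
#' @param lf M x p lead-field matrix (full column rank).
#' @param cov_reg Regularized covariance (`hemilat_cov` or matrix).
#' @param criterion `"max_power"` (default) or `"min_power"` (smallest
#'   eigenvalue), kept selectable because the eigenvector convention of the
#'   original analyses is not uniquely determined by the power criterion's
#'   citation trail.
#' @return A list with unit `orientation` (length p) and `source_cov`
#'   (`P(r)`, p x p).
#' @export
optimal_orientation <- function(lf, cov_reg,
                                criterion = c("max_power", "min_power")) {
  criterion <- match.arg(criterion)
  c_mat <- if (inherits(cov_reg, "hemilat_cov")) cov_reg$matrix else cov_reg
  lf <- as.matrix(lf)
  gram <- crossprod(lf, solve(c_mat, lf))
  gram <- (gram + t(gram)) / 2
  if (rcond(gram) < 1e-14) {
    stop("singular L^T C^-1 L: lead field is rank deficient", call. = FALSE)
  }
  p_r <- solve(gram)
  p_r <- (p_r + t(p_r)) / 2
  eg <- eigen(p_r, symmetric = TRUE)
  k <- if (criterion == "max_power") 1L else ncol(p_r)
  v <- eg$vectors[, k]
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  list(orientation = v, source_cov = p_r)
}

#' LCMV beamformer weights
#'
#' `W = C^-1 l / (l^T C^-1 l)` with `l = L %*% orientation`; satisfies the
#' unit-gain constraint `W^T l = 1`.
#'
#' @param lf M x p lead-field matrix.
#' @param orientation Unit orientation vector (length p).
#' @param cov_reg Regularized covariance (`hemilat_cov` or matrix).
#' @return A list of class `hemilat_weights` with `weights` (length M),
#'   `orientation`, and `gain` (the constrained lead field `l`).
#' @export
compute_weights <- function(lf, orientation, cov_reg) {
  c_mat <- if (inherits(cov_reg, "hemilat_cov")) cov_reg$matrix else cov_reg
  orientation <- orientation / sqrt(sum(orientation^2))
  l <- drop(as.matrix(lf) %*% orientation)
  ci_l <- solve(c_mat, l)
  denom <- sum(l * ci_l)
  if (denom <= 0) {
    stop("l^T C^-1 l must be positive; covariance not positive definite?",
         call. = FALSE)
  }
  w <- ci_l / denom
  structure(list(weights = w, orientation = orientation, gain = l),
            class = "hemilat_weights")
}

#' Reconstruct virtual-electrode time series
#'
#' Projects each trial through each ROI's weight vector: `V = B %*% W` per
#' trial (samples x sensors times sensors).
#'
#' @param trials A [sensor_trial_set()].
#' @param weights A list of `hemilat_weights`, one per ROI.
#' @param roi_ids Optional ROI identifiers.
#' @return A [ve_set()], ROI x trials x samples, same trial structure as
#'   the input.
#' @export
reconstruct_ve <- function(trials, weights, roi_ids = seq_along(weights)) {
  stopifnot(inherits(trials, "hemilat_sensor_set"))
  m <- dim(trials$data)[2]
  w_mat <- vapply(weights, function(w) {
    if (length(w$weights) != m) {
      stop("weight length does not match sensor count", call. = FALSE)
    }
    w$weights
  }, numeric(m))  # M x R
  n_trials <- dim(trials$data)[1]
  n <- dim(trials$data)[3]
  out <- array(0, dim = c(length(weights), n_trials, n))
  for (tr in seq_len(n_trials)) {
    out[, tr, ] <- crossprod(w_mat, trials$data[tr, , ])
  }
  ve_set(out, fs = trials$fs, trial_length = trials$trial_length,
         roi_ids = roi_ids, trial_index = trials$trial_index)
}

#' Full LCMV virtual-electrode reconstruction
#'
#' Convenience wrapper: broadband covariance, Tikhonov regularization,
#' per-ROI optimal orientation and weights, then VE projection.
#'
#' @param trials A [sensor_trial_set()].
#' @param leadfields List of M x p lead-field matrices, one per ROI.
#' @param reg_fraction Tikhonov noise-floor fraction (default 0.05).
#' @param roi_ids Optional ROI identifiers.
#' @return A [ve_set()].
#' @export
beamform_rois <- function(trials, leadfields, reg_fraction = 0.05,
                          roi_ids = seq_along(leadfields)) {
  cov_reg <- regularize_covariance(broadband_covariance(trials),
                                   reg_fraction)
  weights <- lapply(leadfields, function(lf) {
    ori <- optimal_orientation(lf, cov_reg)
    compute_weights(lf, ori$orientation, cov_reg)
  })
  reconstruct_ve(trials, weights, roi_ids = roi_ids)
}
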