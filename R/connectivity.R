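#' Re-segment trials to a target length
#'
#' 3-s trials are the native unit; 12-s trials (needed so the delta band has
#' a fine enough bin grid) are formed only from 4 *consecutive* surviving
#' 3-s trials, as judged by the original temporal indices carried in
#' `trial_index` - trials separated by a rejected trial are never glued
#' together. Leftover trials that do not complete a group of 4 are dropped.
#'
#' @param ve A [ve_set()] (or [sensor_trial_set()]-shaped object) of 3-s
#'   trials.
#' @param target_length Target trial length in seconds: 3 (identity) or 12.
#' @return A re-segmented object of the same class.
#' @export
segment_trials <- function(ve, target_length) {
  if (!target_length %in% c(3, 12)) {
    stop("target_length must be 3 or 12 seconds", call. = FALSE)
  }
  if (abs(ve$trial_length - target_length) < 1e-9) return(ve)
  if (abs(ve$trial_length - 3) > 1e-9) {
    stop("12-s trials can only be formed from 3-s trials", call. = FALSE)
  }
  idx <- ve$trial_index
  # split surviving trials into runs of consecutive original indices
  runs <- split(seq_along(idx), cumsum(c(1, diff(idx) != 1)))
  groups <- list()
  for (r in runs) {
    n_full <- length(r) %/% 4L
    for (g in seq_len(n_full)) {
      groups[[length(groups) + 1L]] <- r[(4 * g - 3):(4 * g)]
    }
  }
  if (length(groups) == 0L) {
    stop("fewer than 4 consecutive trials: no 12-s trial can be formed",
         call. = FALSE)
  }
  d <- ve$data
  n <- dim(d)[3]
  out <- array(0, dim = c(dim(d)[1], length(groups), 4 * n))
  for (g in seq_along(groups)) {
    for (q in 1:4) {
      out[, g, ((q - 1) * n + 1):(q * n)] <- d[, groups[[g]][q], ]
    }
  }
  ve_set(out, fs = ve$fs, trial_length = 12, roi_ids = ve$roi_ids,
         trial_index = seq_along(groups))
}

#' @keywords internal
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Per-trial cross-spectra of virtual-electrode pairs
#'
#' Hann-tapered discrete Fourier transform of each trial (no zero padding),
#' then `s_k(f) = X_i(f) * Conj(X_j(f))` per requested pair. The bin grid is
#' `k / trial_length` Hz, k = 0..floor(n/2).
#'
#' @param ve A [ve_set()].
#' @param pairs Integer matrix (n_pairs x 2) of ROI indices (positions in
#'   the first dimension of `ve$data`).
#' @return A list of class `hemilat_cross_spectra` with complex `values`
#'   (pairs x trials x bins), `freqs`, `pairs`, `fs`, `trial_length`.
#' @export
trial_cross_spectra <- function(ve, pairs) {
  stopifnot(inherits(ve, "hemilat_ve_set"))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n_roi <- dim(ve$data)[1]
  if (any(pairs < 1 | pairs > n_roi)) {
    stop("pair index out of range", call. = FALSE)
  }
  n_trials <- dim(ve$data)[2]
  if (n_trials < 1) stop("need at least one trial", call. = FALSE)
  n <- dim(ve$data)[3]
  taper <- hann_window(n)
  n_bins <- floor(n / 2) + 1L
  freqs <- (seq_len(n_bins) - 1L) / ve$trial_length
  vals <- array(complex(real = 0), dim = c(nrow(pairs), n_trials, n_bins))
  rois <- sort(unique(as.vector(pairs)))
  for (tr in seq_len(n_trials)) {
    x <- ve$data[rois, tr, , drop = FALSE]
    spec <- t(apply(matrix(x, nrow = length(rois)), 1,
                    function(row) stats::fft(row * taper)[seq_len(n_bins)]))
    if (length(rois) == 1L) spec <- matrix(spec, nrow = 1)
    rownames(spec) <- as.character(rois)
    for (p in seq_len(nrow(pairs))) {
      vals[p, tr, ] <- spec[as.character(pairs[p, 1]), ] *
        Conj(spec[as.character(pairs[p, 2]), ])
    }
  }
  structure(list(values = vals, freqs = freqs, pairs = pairs,
                 window = "hann", fs = ve$fs,
                 trial_length = ve$trial_length),
            class = "hemilat_cross_spectra")
}

#' @keywords internal
dwpli_from_im <- function(im) {
  # im: trials vector of Im s_k at one bin; paper's debiased wPLI-square
  s1 <- sum(im)
  s2 <- sum(im^2)
  sa <- sum(abs(im))
  num <- s1^2 - s2
  den <- sa^2 - s2
  if (den == 0) 0 else num / den
}

#' Phase-lag index family from cross-spectra
#'
#' Computes, per pair and frequency bin across trials:
#' PLI `= |mean_k sgn(Im s_k)|`; wPLI `= |mean_k Im s_k| / mean_k |Im s_k|`;
#' dwPLI `= sum_{k != j} Im s_k Im s_j / sum_{k != j} |Im s_k Im s_j|`
#' (the debiased wPLI-square estimator; can be negative in small samples).
#' All three return 0 in 0/0 cases (identical signals carry no lagged
#' coupling).
#'
#' @param cs A `hemilat_cross_spectra`.
#' @param estimator One of `"pli"`, `"wpli"`, `"dwpli"`.
#' @return A numeric matrix, pairs x bins.
#' @export
phase_lag_indices <- function(cs, estimator = c("dwpli", "pli", "wpli")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(cs, "hemilat_cross_spectra"))
  k <- dim(cs$values)[2]
  if (estimator == "dwpli" && k < 2) {
    stop("dwPLI needs at least 2 trials", call. = FALSE)
  }
  im <- Im(cs$values)  # pairs x trials x bins
  n_pairs <- dim(im)[1]
  n_bins <- dim(im)[3]
  out <- matrix(0, n_pairs, n_bins)
  for (p in seq_len(n_pairs)) {
    for (b in seq_len(n_bins)) {
      v <- im[p, , b]
      out[p, b] <- switch(estimator,
        pli = abs(mean(sign(v))),
        wpli = {
          den <- mean(abs(v))
          if (den == 0) 0 else abs(mean(v)) / den
        },
        dwpli = dwpli_from_im(v)
      )
    }
  }
  out
}

#' Band-averaged adjacency matrix
#'
#' Averages per-bin connectivity values over the bins inside the band
#' (closed interval), checks that the trial length matches the band's
#' required segmentation (12 s for delta, 3 s otherwise), and assembles the
#' symmetric zero-diagonal adjacency. Negative dwPLI estimates are clipped
#' to 0 after averaging so the weights are valid for graph analysis.
#'
#' @param values Pairs x bins matrix from [phase_lag_indices()].
#' @param cs The `hemilat_cross_spectra` the values came from (provides the
#'   bin grid and pair list).
#' @param band Band name (see [band_specs()]).
#' @param n_nodes Number of nodes of the output adjacency.
#' @return An n_nodes x n_nodes symmetric matrix with zero diagonal and
#'   entries in [0, 1].
#' @export
band_adjacency <- function(values, cs, band, n_nodes) {
  b <- band_specs(band)
  if (abs(cs$trial_length - b$trial_length) > 1e-9) {
    stop("band ", band, " requires ", b$trial_length, "-s trials, got ",
         cs$trial_length, "-s", call. = FALSE)
  }
  in_band <- cs$freqs >= b$f_low & cs$freqs <= b$f_high
  if (!any(in_band)) stop("no frequency bins inside band", call. = FALSE)
  avg <- rowMeans(values[, in_band, drop = FALSE])
  avg[avg < 0] <- 0
  adj <- matrix(0, n_nodes, n_nodes)
  adj[cs$pairs] <- avg
  adj <- adj + t(adj)
  diag(adj) <- 0
  adj
}

#' Band-specific dwPLI connectomes from virtual electrodes
#'
#' High-level wrapper: for each requested band, re-segments the 3-s trials
#' as needed (12-s for delta), computes Hann cross-spectra over all node
#' pairs, per-bin dwPLI, and the band-averaged adjacency.
#'
#' @param ve A [ve_set()] of 3-s trials.
#' @param bands Character vector of band names.
#' @param estimator Connectivity estimator passed to [phase_lag_indices()].
#' @return Named list of adjacency matrices, one per band.
#' @export
connectivity_matrices <- function(ve, bands = band_names(),
                                  estimator = "dwpli") {
  n_roi <- dim(ve$data)[1]
  pairs <- upper_pairs(n_roi)
  out <- list()
  for (bname in bands) {
    b <- band_specs(bname)
    ve_b <- segment_trials(ve, b$trial_length)
    cs <- trial_cross_spectra(ve_b, pairs)
    vals <- phase_lag_indices(cs, estimator)
    out[[bname]] <- band_adjacency(vals, cs, bname, n_roi)
  }
  out
}

#' Write an adjacency matrix as headerless TSV
#'
#' @param adj Square numeric matrix in canonical atlas order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(adj, path) {
  utils::write.table(adj, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an adjacency matrix from headerless TSV
#'
#' @param path Path to a TSV written by [write_connectivity()].
#' @return A numeric matrix.
#' @export
read_connectivity <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}
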