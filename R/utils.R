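#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that every generator in the
#' package is a pure function of its `seed` argument without disturbing the
#' session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' @keywords internal
derive_seed <- function(seed, offset) {
  # deterministic substream seeds, kept within 32-bit integer range
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# upper-triangle (i < j) index pairs of an n x n matrix, in column order
#' @keywords internal
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

# flatten symmetric matrices to upper-triangle vectors (subjects x edges)
#' @keywords internal
stack_upper <- function(mats) {
  n <- nrow(mats[[1]])
  ut <- upper.tri(mats[[1]])
  t(vapply(mats, function(m) m[ut], numeric(sum(ut))))
}

#' @keywords internal
symmetrize_zero_diag <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

#' @keywords internal
check_square_sym <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}
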