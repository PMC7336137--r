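#' Canonical frequency band definitions
#'
#' Returns the six narrow bands used throughout the pipeline. Trials of 3 s
#' are used for all bands above 3 Hz; the delta band is estimated on 12-s
#' trials so that its 1/12 Hz bin grid resolves the 0.5-3 Hz range.
#'
#' @param name Optional band name; if given, the single matching row is
#'   returned (error if unknown).
#' @return A data.frame with columns `name`, `f_low`, `f_high` (Hz) and
#'   `trial_length` (seconds).
#' @export
band_specs <- function(name = NULL) {
  bands <- data.frame(
    name = c("delta", "theta", "alpha", "low_beta", "high_beta", "low_gamma"),
    f_low = c(0.5, 4, 8, 13, 20, 30),
    f_high = c(3, 7, 13, 20, 30, 50),
    trial_length = c(12, 3, 3, 3, 3, 3),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(bands)
  hit <- bands[bands$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("unknown band name: ", name, call. = FALSE)
  }
  hit
}

#' @keywords internal
band_names <- function() band_specs()$name
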