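#' Frequency band definition
#'
#' A named frequency band with lower and upper edges in Hz. Band edges are
#' treated as half-open intervals `[low, high)` when assigning spectral bins,
#' so that the five canonical bands tile 0.5--30 Hz exactly; the band-pass
#' filter uses `low` and `high` as its -6 dB points.
#'
#' @param name Band name (e.g. `"alpha2"`).
#' @param low Lower edge in Hz, `> 0`.
#' @param high Upper edge in Hz, `> low`.
#' @return An object of class `frequency_band`.
#' @examples
#' frequency_band("alpha2", 10, 13)
#' @export
frequency_band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low)
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  structure(list(name = name, low = low, high = high), class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Canonical frequency bands
#'
#' The five canonical resting-state bands used throughout the pipeline:
#' delta (0.5--4 Hz), theta (4--8 Hz), alpha1 (8--10 Hz), alpha2 (10--13 Hz)
#' and beta (13--30 Hz). The gamma band is deliberately excluded from the
#' analysis range, which ends at 30 Hz.
#'
#' @return A named list of [frequency_band()] objects.
#' @examples
#' names(canonical_bands())
#' @export
canonical_bands <- function() {
  list(
    delta  = frequency_band("delta", 0.5, 4),
    theta  = frequency_band("theta", 4, 8),
    alpha1 = frequency_band("alpha1", 8, 10),
    alpha2 = frequency_band("alpha2", 10, 13),
    beta   = frequency_band("beta", 13, 30)
  )
}

# analysis range shared by spectra and relative power
.analysis_range <- c(0.5, 30)
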