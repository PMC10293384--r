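#' Spectrum set container
#'
#' Per-region power spectra on the analysis grid. The frequency grid spacing
#' is `sample_rate / epoch_length` (0.076 Hz at the 312.5 Hz / 4096-sample
#' defaults) and the grid is restricted to 0.5--30 Hz. `normalization` is
#' `"raw"` (periodogram units) or `"unit-area"` (each region integrates to 1
#' over 0.5--30 Hz).
#'
#' @param frequencies Frequency grid in Hz.
#' @param power Region x frequency matrix of non-negative power values.
#' @param normalization `"raw"` or `"unit-area"`.
#' @param sample_rate,epoch_length,n_epochs Estimation metadata.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(frequencies, power, normalization = "raw",
                         sample_rate = NA_real_, epoch_length = NA_integer_,
                         n_epochs = NA_integer_) {
  power <- as.matrix(power)
  if (ncol(power) != length(frequencies))
    stop("power must have one column per frequency", call. = FALSE)
  if (any(power < 0)) stop("power must be non-negative", call. = FALSE)
  normalization <- match.arg(normalization, c("raw", "unit-area"))
  structure(list(frequencies = frequencies, power = power,
                 normalization = normalization, sample_rate = sample_rate,
                 epoch_length = epoch_length, n_epochs = n_epochs),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d regions x %d bins (%.3f-%.3f Hz, df = %.4f Hz, %s)\n",
              nrow(x$power), length(x$frequencies), min(x$frequencies),
              max(x$frequencies), x$frequencies[2L] - x$frequencies[1L],
              x$normalization))
  invisible(x)
}

#' Epoch-averaged power spectra
#'
#' Single-window Hann-tapered periodogram of each full epoch (no
#' sub-windowing, so the stated spectral resolution `fs / epoch_length` is
#' preserved), averaged over epochs per region, restricted to the 0.5--30 Hz
#' analysis range. The scaling is the standard one-sided power spectral
#' density, so the integral of the raw spectrum approximates the signal
#' variance contributed by 0.5--30 Hz.
#'
#' @param es A broadband (untagged) [epoch_set()]; band-tagged input is
#'   rejected.
#' @return A raw-normalization [spectrum_set()].
#' @export
epoch_spectra <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  if (!is.null(es$band))
    stop("spectra are estimated on broadband epochs; input is band-tagged (",
         es$band$name, ")", call. = FALSE)
  d <- dim(es$epochs)
  E <- d[1L]; R <- d[2L]; L <- d[3L]
  fs <- es$sample_rate
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / L)
  scale <- 2 / (fs * sum(w^2))
  mat <- matrix(aperm(es$epochs, c(3L, 1L, 2L)), nrow = L) # cols: epoch within region
  P <- Mod(stats::mvfft(mat * w))^2 * scale
  freq <- (0:(L - 1L)) * fs / L
  keep <- which(freq >= .analysis_range[1L] - 1e-9 &
                  freq <= .analysis_range[2L] + 1e-9)
  P <- P[keep, , drop = FALSE]
  power <- matrix(0, nrow = R, ncol = length(keep))
  for (r in seq_len(R)) {
    cols <- ((r - 1L) * E + 1L):(r * E)
    power[r, ] <- rowMeans(P[, cols, drop = FALSE])
  }
  rownames(power) <- rownames(es$epochs)
  spectrum_set(freq[keep], power, "raw", sample_rate = fs, epoch_length = L,
               n_epochs = E)
}

#' Area-normalize spectra
#'
#' Divides each region's spectrum by its integral over 0.5--30 Hz so that
#' every region's spectrum has unit area under the curve. Normalized spectra
#' depend only on spectral shape, not on overall signal amplitude.
#'
#' @param ss A raw [spectrum_set()].
#' @return A unit-area [spectrum_set()].
#' @export
normalize_spectrum <- function(ss) {
  stopifnot(inherits(ss, "spectrum_set"))
  if (ss$normalization != "raw")
    stop("spectra are already area-normalized", call. = FALSE)
  df <- ss$frequencies[2L] - ss$frequencies[1L]
  tot <- rowSums(ss$power) * df
  if (any(tot <= 0))
    stop("zero total power in region(s): ",
         paste(which(tot <= 0), collapse = ", "), call. = FALSE)
  spectrum_set(ss$frequencies, ss$power / tot, "unit-area",
               sample_rate = ss$sample_rate, epoch_length = ss$epoch_length,
               n_epochs = ss$n_epochs)
}

#' Relative band power
#'
#' For each region and band, the sum of power over bins with frequency in
#' `[low, high)` divided by the sum over `[0.5, 30)`. Because the five
#' canonical bands tile the analysis range under this half-open convention,
#' the per-region values sum to 1. The result is identical for raw and
#' unit-area input (the normalization cancels).
#'
#' @param ss A [spectrum_set()].
#' @param bands Named list of [frequency_band()]s; default [canonical_bands()].
#' @return Region x band matrix of relative powers in `[0, 1]`.
#' @export
relative_band_power <- function(ss, bands = canonical_bands()) {
  stopifnot(inherits(ss, "spectrum_set"))
  f <- ss$frequencies
  denom_mask <- f >= .analysis_range[1L] - 1e-9 & f < .analysis_range[2L] - 1e-9
  denom <- rowSums(ss$power[, denom_mask, drop = FALSE])
  masks <- lapply(bands, function(b) f >= b$low - 1e-9 & f < b$high - 1e-9)
  cover <- Reduce(`+`, masks)
  if (any(cover[denom_mask] != 1L))
    warning("bands do not tile 0.5-30 Hz exactly; relative powers will not sum to 1",
            call. = FALSE)
  rp <- vapply(masks, function(m)
    rowSums(ss$power[, m & denom_mask, drop = FALSE]) / denom,
    numeric(nrow(ss$power)))
  rp <- matrix(rp, nrow = nrow(ss$power),
               dimnames = list(rownames(ss$power), names(bands)))
  rp
}

#' Dominant peak frequency
#'
#' Per region, the frequency of the maximum-power bin within the closed
#' 4--13 Hz search range (on the native grid, so the answer has the
#' estimator's 0.076 Hz resolution at the defaults). Ties are broken toward
#' the lower frequency, so a flat spectrum yields the lowest in-range grid
#' point.
#'
#' @param ss A [spectrum_set()] covering the search range.
#' @param range Search range in Hz; default `c(4, 13)`.
#' @return Numeric vector of per-region peak frequencies in Hz.
#' @export
peak_frequency <- function(ss, range = c(4, 13)) {
  stopifnot(inherits(ss, "spectrum_set"), length(range) == 2L)
  m <- which(ss$frequencies >= range[1L] - 1e-9 &
               ss$frequencies <= range[2L] + 1e-9)
  if (!length(m))
    stop("spectra do not cover the peak search range", call. = FALSE)
  idx <- apply(ss$power[, m, drop = FALSE], 1L, which.max) # first max = lowest f
  ss$frequencies[m][idx]
}

#' Cortical / subcortical summary means
#'
#' Unweighted means of a per-region measure over the 78 cortical and the 12
#' subcortical regions of the atlas. Accepts a per-region vector (e.g. peak
#' frequency, connectivity profile) or a region x measure matrix (e.g. a
#' relative band-power table).
#'
#' @param x Numeric vector of length 90 or matrix with 90 rows.
#' @param atlas A [region_atlas()].
#' @return A data frame with columns `measure`, `cortical_mean`,
#'   `subcortical_mean`.
#' @export
summarize_regions <- function(x, atlas) {
  g <- region_groups(atlas)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                   dimnames = list(NULL, "value"))
  if (nrow(x) != length(atlas$labels))
    stop(sprintf("measure has %d regions but atlas has %d", nrow(x),
                 length(atlas$labels)), call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  data.frame(
    measure = colnames(x),
    cortical_mean = colMeans(x[g$cortical, , drop = FALSE], na.rm = TRUE),
    subcortical_mean = colMeans(x[g$subcortical, , drop = FALSE], na.rm = TRUE),
    row.names = NULL
  )
}
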