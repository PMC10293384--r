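#' Downsample a recording by an integer factor
#'
#' Anti-alias low-pass filtering (zero-phase frequency-domain mask with a
#' raised-cosine roll-off between 0.9 and 1.0 times the new Nyquist
#' frequency) followed by decimation. Used to bring recordings acquired at
#' higher rates (e.g. 1250 Hz) down to the common 312.5 Hz analysis rate.
#'
#' @param rec A [roi_recording()].
#' @param factor Integer decimation factor `>= 1`.
#' @return A [roi_recording()] with `sample_rate = old / factor`.
#' @examples
#' rec <- roi_recording(matrix(rnorm(2 * 5000), 2), 1250)
#' downsample(rec, 4)$sample_rate
#' @export
downsample <- function(rec, factor) {
  stopifnot(inherits(rec, "roi_recording"))
  if (!is.numeric(factor) || length(factor) != 1L || factor != round(factor) ||
      factor < 1)
    stop("factor must be a single integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  new_fs <- rec$sample_rate / factor
  if (new_fs <= 60)
    stop(sprintf(paste("downsampling to %g Hz violates the 0.5-30 Hz analysis",
                       "range (resulting rate must exceed 60 Hz)"), new_fs),
         call. = FALSE)
  n <- ncol(rec$data)
  nyq_new <- new_fs / 2
  f <- .onesided_freq(n, rec$sample_rate)
  mask <- .raised_cosine_mask(f, high = 0.95 * nyq_new, tw_high = 0.1 * nyq_new)
  idx <- seq.int(1L, n, by = factor)
  filt <- t(.apply_mask_columns(t(rec$data), mask))
  roi_recording(filt[, idx, drop = FALSE], new_fs, rec$subject, rec$visit)
}

#' Split a recording into fixed-length epochs
#'
#' Cuts consecutive, non-overlapping windows of `epoch_length` samples
#' (default 4096, i.e. 13.11 s at 312.5 Hz). If `n_epochs` is given, the
#' first `n_epochs` windows are returned (synthetic data carry no artefacts,
#' so "first n clean windows" is simply "first n windows"); the trailing
#' remainder is discarded.
#'
#' @param rec A [roi_recording()].
#' @param epoch_length Epoch length in samples; default 4096.
#' @param n_epochs Number of epochs to keep, or `NULL` for all available.
#' @return A broadband (untagged) [epoch_set()].
#' @export
epoch <- function(rec, epoch_length = 4096L, n_epochs = NULL) {
  stopifnot(inherits(rec, "roi_recording"))
  L <- as.integer(epoch_length)
  if (L < 2L) stop("epoch_length must be at least 2 samples", call. = FALSE)
  n <- ncol(rec$data)
  avail <- n %/% L
  if (avail < 1L)
    stop(sprintf("recording has %d samples, fewer than one epoch of %d", n, L),
         call. = FALSE)
  if (!is.null(n_epochs)) {
    n_epochs <- as.integer(n_epochs)
    if (avail < n_epochs)
      stop(sprintf("requested %d epochs but only %d available", n_epochs, avail),
           call. = FALSE)
    E <- n_epochs
  } else {
    E <- avail
  }
  R <- nrow(rec$data)
  arr <- array(0, dim = c(E, R, L))
  for (e in seq_len(E))
    arr[e, , ] <- rec$data[, ((e - 1L) * L + 1L):(e * L), drop = FALSE]
  epoch_set(arr, rec$sample_rate)
}

#' Band-pass filter an epoch set
#'
#' Applies a zero-phase band-pass to every epoch of every region and tags the
#' result with the band. The filter is a frequency-domain amplitude mask with
#' raised-cosine transitions whose -6 dB points sit exactly on the band
#' edges; the transition width is half the band's lower edge, capped at 2 Hz.
#' Epoch count and length are preserved. Filtering an already band-tagged
#' epoch set is rejected (no double filtering).
#'
#' @param es A broadband [epoch_set()].
#' @param band A [frequency_band()] within the Nyquist range.
#' @return A band-tagged [epoch_set()].
#' @export
bandpass <- function(es, band) {
  stopifnot(inherits(es, "epoch_set"), inherits(band, "frequency_band"))
  if (!is.null(es$band))
    stop(sprintf("epoch set is already band-filtered (%s); refusing to filter twice",
                 es$band$name), call. = FALSE)
  if (band$high > es$sample_rate / 2)
    stop(sprintf("band %s (%g-%g Hz) extends beyond the Nyquist frequency %g Hz",
                 band$name, band$low, band$high, es$sample_rate / 2),
         call. = FALSE)
  d <- dim(es$epochs)
  L <- d[3L]
  mask <- .band_mask(L, es$sample_rate, band)
  # flatten to samples x (epoch*region) so one mvfft covers everything
  mat <- matrix(aperm(es$epochs, c(3L, 1L, 2L)), nrow = L)
  out <- .apply_mask_columns(mat, mask)
  arr <- aperm(array(out, dim = c(L, d[1L], d[2L])), c(2L, 3L, 1L))
  epoch_set(arr, es$sample_rate, band = band)
}
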