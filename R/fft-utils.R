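# Internal frequency-domain primitives: analytic signal, raised-cosine
# spectral masks, and zero-phase filtering by FFT multiplication.

# analytic signal via half-spectrum doubling; input must be real
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

.signal_envelope <- function(x) Mod(.analytic_signal(x))

# |f_k| for the k-th DFT bin, k = 0..n-1
.onesided_freq <- function(n, fs) {
  k <- 0:(n - 1L)
  pmin(k, n - k) * fs / n
}

# Amplitude mask that is 1 in [low, high], 0 outside, with raised-cosine
# transitions of full width tw_low / tw_high centred on the edges, so the
# edges themselves sit at -6 dB (amplitude 0.5). NULL low/high disables the
# corresponding edge (low-pass / high-pass).
.raised_cosine_mask <- function(f, low = NULL, high = NULL,
                                tw_low = 0, tw_high = 0) {
  m <- rep(1, length(f))
  if (!is.null(low)) {
    if (tw_low <= 0) {
      m[f < low] <- 0
    } else {
      a <- low - tw_low / 2
      m[f <= a] <- 0
      r <- f > a & f < low + tw_low / 2
      m[r] <- m[r] * 0.5 * (1 - cos(pi * (f[r] - a) / tw_low))
    }
  }
  if (!is.null(high)) {
    if (tw_high <= 0) {
      m[f > high] <- 0
    } else {
      a <- high - tw_high / 2
      r <- f > a & f < high + tw_high / 2
      m[r] <- m[r] * 0.5 * (1 + cos(pi * (f[r] - a) / tw_high))
      m[f >= high + tw_high / 2] <- 0
    }
  }
  m
}

.fft_apply_mask <- function(x, mask) {
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / length(x)
}

# transition width rule: half the band's lower edge, capped at 2 Hz
.band_transition <- function(band) min(0.5 * band$low, 2)

.band_mask <- function(n, fs, band, tw = .band_transition(band)) {
  f <- .onesided_freq(n, fs)
  .raised_cosine_mask(f, low = band$low, high = band$high,
                      tw_low = tw, tw_high = tw)
}

.bandpass_vector <- function(x, fs, band) {
  .fft_apply_mask(x, .band_mask(length(x), fs, band))
}

# columns of `mat` filtered with a shared mask (mask recycles down columns)
.apply_mask_columns <- function(mat, mask) {
  n <- nrow(mat)
  Re(stats::mvfft(stats::mvfft(mat) * mask, inverse = TRUE)) / n
}
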