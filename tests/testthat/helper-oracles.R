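# Independent reference implementations and fixture builders shared by the
# tests. The oracle code deliberately avoids the package's internal helpers:
# orthogonalization through lm(), the analytic signal through explicit
# half-spectrum zeroing.

oracle_envelope <- function(v) {
  n <- length(v)
  X <- stats::fft(v)
  keep <- rep(0 + 0i, n)
  keep[1L] <- X[1L]
  half <- floor(n / 2)
  if (n %% 2 == 0) {
    keep[half + 1L] <- X[half + 1L]
    keep[2L:half] <- 2 * X[2L:half]
  } else {
    keep[2L:(half + 1L)] <- 2 * X[2L:(half + 1L)]
  }
  Mod(stats::fft(keep, inverse = TRUE) / n)
}

# brute-force AEC-c matrix: per-epoch regression residuals via lm(), envelope
# correlation, two-direction average, (r + 1) / 2, epoch average
oracle_aec_matrix <- function(es, trim_fraction = 0.05) {
  d <- dim(es$epochs)
  E <- d[1L]; R <- d[2L]; L <- d[3L]
  tr <- floor(trim_fraction * L)
  sel <- (tr + 1L):(L - tr)
  ref <- matrix(NA_real_, R, R)
  for (i in seq_len(R - 1L)) {
    for (j in (i + 1L):R) {
      vals <- numeric(E)
      for (e in seq_len(E)) {
        x <- es$epochs[e, i, ]
        y <- es$epochs[e, j, ]
        x <- x - mean(x)
        y <- y - mean(y)
        ry <- stats::residuals(stats::lm(y ~ 0 + x))
        rx <- stats::residuals(stats::lm(x ~ 0 + y))
        r1 <- stats::cor(oracle_envelope(x)[sel], oracle_envelope(ry)[sel])
        r2 <- stats::cor(oracle_envelope(y)[sel], oracle_envelope(rx)[sel])
        vals[e] <- ((r1 + r2) / 2 + 1) / 2
      }
      ref[i, j] <- ref[j, i] <- mean(vals)
    }
  }
  ref
}

white_noise_recording <- function(n_regions, n_samples, fs = 312.5) {
  roi_recording(matrix(stats::rnorm(n_regions * n_samples), n_regions), fs)
}

# mean AEC-c of a white-noise pair (optionally instantaneously mixed with
# coefficient alpha) over n_epochs epochs, band-filtered first
aecc_noise_pair <- function(alpha = 0, n_epochs = 10L, epoch_length = 4096L,
                            fs = 312.5, band = canonical_bands()$alpha2) {
  n <- n_epochs * epoch_length
  x <- stats::rnorm(n)
  y <- alpha * x + sqrt(1 - alpha^2) * stats::rnorm(n)
  es <- bandpass(epoch(roi_recording(rbind(x, y), fs), epoch_length), band)
  mean(vapply(seq_len(n_epochs), function(e)
    aec_pair(es$epochs[e, 1L, ], es$epochs[e, 2L, ]), numeric(1)),
    na.rm = TRUE)
}
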