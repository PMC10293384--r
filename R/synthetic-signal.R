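#' Spectral specification for a simulated region signal
#'
#' Describes the target power spectrum of one region's resting-state signal:
#' a 1/f-type background with exponent `one_over_f_exponent`, plus a Gaussian
#' oscillatory bump centred at `peak_frequency` whose integrated power is
#' `peak_power_ratio` times the 0.5--30 Hz background power, optionally
#' reshaped by per-band multiplicative tilts.
#'
#' @param one_over_f_exponent Slope of the log-log background; 0 gives a flat
#'   (white) background. Default 1.
#' @param peak_frequency Centre of the oscillatory bump in Hz, within
#'   `[4, 13]`. Default 10.
#' @param peak_power_ratio Bump power / background power over 0.5--30 Hz;
#'   `>= 0`. Default 1.
#' @param peak_width Gaussian SD of the bump in Hz. Default 0.75.
#' @param band_power_tilts Optional named non-negative multipliers applied to
#'   the spectrum within canonical bands (names must be band names).
#' @param sample_rate Sampling rate in Hz, `> 60` (i.e. above twice the 30 Hz
#'   analysis edge). Default 312.5.
#' @param duration Signal duration in seconds. Default `131.072` (ten
#'   4096-sample epochs at 312.5 Hz).
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(one_over_f_exponent = 1, peak_frequency = 10,
                        peak_power_ratio = 1, peak_width = 0.75,
                        band_power_tilts = NULL, sample_rate = 312.5,
                        duration = 131.072) {
  vals <- c(one_over_f_exponent, peak_frequency, peak_power_ratio, peak_width,
            sample_rate, duration)
  if (!all(is.finite(vals)))
    stop("signal spec values must be finite", call. = FALSE)
  if (sample_rate <= 60)
    stop("sample_rate must exceed 60 Hz (twice the 30 Hz analysis edge)",
         call. = FALSE)
  if (peak_frequency < 4 || peak_frequency > 13)
    stop("peak_frequency must lie within [4, 13] Hz", call. = FALSE)
  if (peak_power_ratio < 0 || peak_width <= 0 || duration <= 0)
    stop("power quantities must be >= 0 and peak_width/duration > 0",
         call. = FALSE)
  if (!is.null(band_power_tilts)) {
    bands <- canonical_bands()
    if (is.null(names(band_power_tilts)) ||
        !all(names(band_power_tilts) %in% names(bands)))
      stop("band_power_tilts must be named after canonical bands", call. = FALSE)
    if (!all(is.finite(band_power_tilts)) || any(band_power_tilts < 0))
      stop("band_power_tilts must be finite and >= 0", call. = FALSE)
  }
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 peak_frequency = peak_frequency,
                 peak_power_ratio = peak_power_ratio,
                 peak_width = peak_width,
                 band_power_tilts = band_power_tilts,
                 sample_rate = sample_rate, duration = duration),
            class = "signal_spec")
}

# target power spectrum of a spec on the length-n DFT grid
.target_spectrum <- function(spec, n) {
  fs <- spec$sample_rate
  f <- .onesided_freq(n, fs)
  B <- pmax(f, .analysis_range[1L])^(-spec$one_over_f_exponent)
  B[f == 0] <- 0
  an <- f >= .analysis_range[1L] - 1e-9 & f < .analysis_range[2L] - 1e-9
  G <- exp(-(f - spec$peak_frequency)^2 / (2 * spec$peak_width^2))
  cc <- if (sum(G[an]) > 0) spec$peak_power_ratio * sum(B[an]) / sum(G[an]) else 0
  S <- B + cc * G
  if (!is.null(spec$band_power_tilts)) {
    bands <- canonical_bands()
    for (nm in names(spec$band_power_tilts)) {
      b <- bands[[nm]]
      m <- f >= b$low - 1e-9 & f < b$high - 1e-9
      S[m] <- S[m] * spec$band_power_tilts[[nm]]
    }
  }
  S
}

#' Expected relative band powers of a signal spec
#'
#' The relative band powers implied by the spec's target spectrum (the
#' quantity the spectral estimator recovers on long realizations, up to
#' estimation noise).
#'
#' @param spec A [signal_spec()].
#' @param bands Named list of bands; default [canonical_bands()].
#' @param n Grid size used to evaluate the target spectrum. Default 8192.
#' @return Named numeric vector of relative band powers (summing to 1 for
#'   tiling bands).
#' @export
expected_band_powers <- function(spec, bands = canonical_bands(), n = 8192L) {
  S <- .target_spectrum(spec, n)
  f <- .onesided_freq(n, spec$sample_rate)
  an <- f >= .analysis_range[1L] - 1e-9 & f < .analysis_range[2L] - 1e-9
  denom <- sum(S[an])
  vapply(bands, function(b)
    sum(S[f >= b$low - 1e-9 & f < b$high - 1e-9 & an]) / denom, numeric(1))
}

#' Band tilts that realize target relative band powers
#'
#' Computes the multiplicative per-band adjustments that reshape a spec's
#' spectrum so its expected relative band powers equal `targets` exactly
#' (targets are renormalized to sum to 1).
#'
#' @param spec A [signal_spec()] (its existing tilts are ignored).
#' @param targets Named numeric vector of desired relative band powers, one
#'   per canonical band.
#' @return Named numeric tilt vector suitable for `band_power_tilts`.
#' @export
band_tilts_for_targets <- function(spec, targets) {
  bands <- canonical_bands()
  if (!setequal(names(targets), names(bands)))
    stop("targets must name every canonical band", call. = FALSE)
  targets <- targets[names(bands)] / sum(targets)
  base_spec <- spec
  base_spec$band_power_tilts <- NULL
  base <- expected_band_powers(base_spec)
  if (any(base <= 0))
    stop("base spectrum carries no power in some band", call. = FALSE)
  tilts <- targets / base
  tilts / max(tilts)
}

#' Simulate one region's resting-state signal
#'
#' Spectrally shaped Gaussian noise: white noise is transformed to the
#' frequency domain, its amplitudes are multiplied by the square root of the
#' spec's target spectrum (1/f background plus oscillatory bump, with any
#' band tilts), and the result is transformed back and scaled to unit
#' variance. The realization is deterministic given the seed.
#'
#' @param spec A [signal_spec()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `round(duration * sample_rate)` samples.
#' @examples
#' x <- simulate_roi_signal(signal_spec(duration = 13.2), seed = 1)
#' @export
simulate_roi_signal <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "signal_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$duration * spec$sample_rate)
  S <- .target_spectrum(spec, n)
  z <- stats::rnorm(n)
  x <- Re(stats::fft(stats::fft(z) * sqrt(S), inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) stop("degenerate spectrum produced a constant signal", call. = FALSE)
  x / s
}

#' Envelope-coupling specification
#'
#' Declares that a pair of regions share band-limited amplitude-envelope
#' coupling of a given target strength.
#'
#' @param region_pair Integer vector of two distinct 1-based region indices.
#' @param band The [frequency_band()] carrying the coupling.
#' @param strength Target leakage-free envelope correlation in `[0, 1)`.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(region_pair, band, strength) {
  region_pair <- as.integer(region_pair)
  if (length(region_pair) != 2L || region_pair[1L] == region_pair[2L] ||
      any(region_pair < 1L))
    stop("region_pair must be two distinct positive indices", call. = FALSE)
  stopifnot(inherits(band, "frequency_band"))
  if (!is.finite(strength) || strength < 0 || strength >= 1)
    stop("strength must lie in [0, 1)", call. = FALSE)
  structure(list(region_pair = region_pair, band = band, strength = strength),
            class = "coupling_spec")
}

# cache for the numeric strength -> modulator-mixing calibration curves
.megslow_cache <- new.env(parent = emptyenv())

# slow (< ~0.7 Hz) unit-variance modulator field used for envelope coupling
.slow_modulator_mask <- function(n, fs) {
  f <- .onesided_freq(n, fs)
  .raised_cosine_mask(f, high = 0.4, tw_high = 0.5)
}

.unit_sd <- function(x) {
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# one coupled band-limited pair at modulator mixing weight w; returns the two
# band components (not yet power-matched)
.coupled_band_pair <- function(n, fs, band, w) {
  bm <- .band_mask(n, fs, band)
  sm <- .slow_modulator_mask(n, fs)
  cx <- .fft_apply_mask(stats::rnorm(n), bm)
  cy <- .fft_apply_mask(stats::rnorm(n), bm)
  g1 <- .unit_sd(.fft_apply_mask(stats::rnorm(n), sm))
  g2 <- .unit_sd(.fft_apply_mask(stats::rnorm(n), sm))
  s0 <- .unit_sd(.fft_apply_mask(stats::rnorm(n), sm))
  m1 <- sqrt(1 - w) * g1 + sqrt(w) * s0
  m2 <- sqrt(1 - w) * g2 + sqrt(w) * s0
  list(x = exp(0.7 * m1) * cx, y = exp(0.7 * m2) * cy)
}

# seeded lookup: measured leakage-free envelope correlation as a function of
# the modulator mixing weight, inverted by interpolation to hit `strength`
.coupling_weight <- function(strength, band, fs,
                             n = 16384L, n_reps = 6L) {
  key <- sprintf("%s_%g_%g_%g", band$name, band$low, band$high, fs)
  curve <- .megslow_cache[[key]]
  if (is.null(curve)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(202391L)
    wgrid <- c(0, 0.15, 0.3, 0.45, 0.6, 0.75, 0.9, 0.99)
    rbar <- vapply(wgrid, function(w) {
      mean(vapply(seq_len(n_reps), function(i) {
        p <- .coupled_band_pair(n, fs, band, w)
        stats::cor(.signal_envelope(p$x), .signal_envelope(p$y))
      }, numeric(1)))
    }, numeric(1))
    rbar <- cummax(rbar) # enforce monotonicity against Monte-Carlo jitter
    curve <- list(w = wgrid, r = rbar)
    .megslow_cache[[key]] <- curve
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  stats::approx(curve$r, curve$w, xout = strength, rule = 2, ties = "ordered")$y
}

#' Plant amplitude-envelope coupling in a signal pair
#'
#' Replaces the band-limited components of `x` and `y` with amplitude-coupled
#' ones: two independent band-limited carriers are each multiplied by a slow
#' (< 1 Hz) positive amplitude modulator, and the two modulators share a
#' common component mixed at a level calibrated (numerically, once per band
#' and sampling rate, via a seeded lookup) so the leakage-free envelope
#' correlation of the pair approaches `spec$strength`. The new band
#' components are scaled to the original band power; content outside the
#' band is left unchanged. With `strength = 0` the pair is returned
#' unmodified.
#'
#' @param x,y Numeric vectors of equal length (broadband signals).
#' @param spec A [coupling_spec()]; only its band and strength are used here.
#' @param sample_rate Sampling rate of `x` and `y` in Hz.
#' @param seed Optional integer seed; the output is deterministic given
#'   (inputs, spec, seed).
#' @return List with coupled signals `x` and `y`.
#' @export
plant_envelope_coupling <- function(x, y, spec, sample_rate, seed = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (length(x) != length(y))
    stop("series must have equal length", call. = FALSE)
  if (spec$band$high > sample_rate / 2)
    stop("coupling band extends beyond the Nyquist frequency", call. = FALSE)
  if (spec$strength == 0) return(list(x = x, y = y))
  w <- .coupling_weight(spec$strength, spec$band, sample_rate)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  bm <- .band_mask(n, sample_rate, spec$band)
  xb <- .fft_apply_mask(x, bm)
  yb <- .fft_apply_mask(y, bm)
  px <- mean(xb^2)
  py <- mean(yb^2)
  p <- .coupled_band_pair(n, sample_rate, spec$band, w)
  nx <- p$x * sqrt(px / mean(p$x^2))
  ny <- p$y * sqrt(py / mean(p$y^2))
  list(x = (x - xb) + nx, y = (y - yb) + ny)
}

#' Measure the AEC-c realized by a planted coupling strength
#'
#' Monte-Carlo mapping from generator coupling strength to the AEC-c the
#' pipeline actually measures: white-noise pairs are coupled with
#' [plant_envelope_coupling()], epoched, band-filtered and scored with
#' [aec_pair()], and the grand mean over realizations is returned. Used to
#' anchor parametric connectivity simulations to the signal-level pipeline.
#'
#' @param strength Coupling strength in `[0, 1)`.
#' @param band The [frequency_band()] carrying the coupling.
#' @param sample_rate Sampling rate in Hz. Default 312.5.
#' @param n_epochs,epoch_length Epoching of each realization. Defaults 2 and
#'   4096.
#' @param n_reps Number of realizations. Default 20.
#' @param seed Optional integer seed.
#' @return Mean AEC-c across realizations.
#' @export
measure_coupling_aecc <- function(strength, band, sample_rate = 312.5,
                                  n_epochs = 2L, epoch_length = 4096L,
                                  n_reps = 20L, seed = NULL) {
  cs <- coupling_spec(c(1L, 2L), band, strength)
  w <- if (strength > 0) .coupling_weight(strength, band, sample_rate) else 0
  if (!is.null(seed)) set.seed(seed)
  n <- n_epochs * epoch_length
  mean(vapply(seq_len(n_reps), function(i) {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    p <- plant_envelope_coupling(x, y, cs, sample_rate)
    rec <- roi_recording(rbind(p$x, p$y), sample_rate)
    es <- bandpass(epoch(rec, epoch_length), band)
    vals <- vapply(seq_len(n_epochs), function(e)
      aec_pair(es$epochs[e, 1L, ], es$epochs[e, 2L, ]), numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1)))
}
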