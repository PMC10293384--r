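fs <- 312.5
L <- 4096L

test_that("spectral grid has the native resolution and analysis range", {
  set.seed(1)
  ss <- epoch_spectra(epoch(white_noise_recording(1, 2 * L, fs), L))
  expect_equal(unique(round(diff(ss$frequencies), 6)), round(fs / L, 6))
  expect_equal(round(fs / L, 3), 0.076)
  expect_gte(min(ss$frequencies), 0.5)
  expect_lte(max(ss$frequencies), 30)
  expect_error(epoch_spectra(bandpass(epoch(white_noise_recording(1, 2 * L, fs), L),
                                      canonical_bands()$theta)),
               "band-tagged")
})

test_that("epoch-averaged white-noise spectrum is flat", {
  set.seed(2)
  ss <- epoch_spectra(epoch(white_noise_recording(1, 100 * L, fs), L))
  expect_lt(max(ss$power) / min(ss$power), 3)
})

test_that("a pure tone concentrates its power at the right grid point", {
  f0 <- 131 * fs / L # bin-centred, ~9.99 Hz
  x <- sin(2 * pi * f0 * (0:(10 * L - 1)) / fs)
  ss <- epoch_spectra(epoch(roi_recording(matrix(x, 1), fs), L))
  # >95% of in-range power within two bins of the tone (Hann main lobe)
  near <- abs(ss$frequencies - f0) <= 2.5 * fs / L
  expect_gt(sum(ss$power[, near]) / sum(ss$power), 0.95)
  expect_lt(abs(peak_frequency(ss) - f0), fs / L + 1e-9)
})

test_that("area normalization yields unit-area, scale-free spectra", {
  set.seed(3)
  rec <- white_noise_recording(3, 4 * L, fs)
  rec$data[3, ] <- 2 * rec$data[2, ] # proportional spectra
  ss <- epoch_spectra(epoch(rec, L))
  norm <- normalize_spectrum(ss)
  df <- diff(norm$frequencies)[1]
  expect_equal(rowSums(norm$power) * df, rep(1, 3), tolerance = 1e-9)
  # scaling the input power changes nothing after normalization
  scaled <- ss
  scaled$power <- ss$power * 7
  expect_equal(normalize_spectrum(scaled)$power, norm$power, tolerance = 1e-12)
  # regions with proportional spectra normalize identically
  expect_equal(norm$power[2, ], norm$power[3, ], tolerance = 1e-9)
  expect_error(normalize_spectrum(norm), "already")
  zero <- ss
  zero$power[1, ] <- 0
  expect_error(normalize_spectrum(zero), "zero total power")
})

test_that("relative band powers tile the analysis range and sum to one", {
  set.seed(4)
  ss <- epoch_spectra(epoch(white_noise_recording(2, 3 * L, fs), L))
  rp <- relative_band_power(ss)
  expect_equal(unname(rowSums(rp)), rep(1, 2), tolerance = 1e-9)
  # identical for raw and unit-area input
  expect_equal(relative_band_power(normalize_spectrum(ss)), rp,
               tolerance = 1e-12)
  # a theta tone is >95% theta power
  f0 <- round(6 / (fs / L)) * fs / L
  tone <- roi_recording(matrix(sin(2 * pi * f0 * (0:(3 * L - 1)) / fs), 1), fs)
  rp_tone <- relative_band_power(epoch_spectra(epoch(tone, L)))
  expect_gt(rp_tone[, "theta"], 0.95)
  # non-tiling band sets warn and do not sum to 1
  expect_warning(rp_part <- relative_band_power(ss, canonical_bands()[c("delta",
                                                                        "beta")]),
                 "tile")
  expect_lt(max(rowSums(rp_part)), 1)
})

test_that("peak frequency uses the grid argmax with a low-frequency tie-break", {
  freqs <- seq(0.5, 30, by = fs / L)
  flat <- spectrum_set(freqs, matrix(1, 2, length(freqs)))
  pf <- peak_frequency(flat)
  expect_equal(pf, rep(min(freqs[freqs >= 4 - 1e-9]), 2))
  expect_true(all(pf >= 4 & pf <= 13))
})

test_that("cortical and subcortical summaries are means over the partition", {
  atlas <- load_atlas()
  v <- rep(5, 90)
  s <- summarize_regions(v, atlas)
  expect_equal(s$cortical_mean, 5)
  expect_equal(s$subcortical_mean, 5)
  g <- region_groups(atlas)
  ind <- numeric(90)
  ind[g$cortical] <- 1
  s2 <- summarize_regions(ind, atlas)
  expect_equal(s2$cortical_mean, 1)
  expect_equal(s2$subcortical_mean, 0)
  set.seed(5)
  m <- matrix(runif(90 * 2), 90, dimnames = list(NULL, c("a", "b")))
  s3 <- summarize_regions(m, atlas)
  for (k in 1:2) {
    expect_gte(s3$cortical_mean[k], min(m[g$cortical, k]))
    expect_lte(s3$cortical_mean[k], max(m[g$cortical, k]))
  }
  expect_error(summarize_regions(runif(89), atlas), "89")
})

test_that("raw spectra conserve variance and average linearly over epochs", {
  set.seed(6)
  # band-limited signal: 0.5-30 Hz integral of the raw spectrum ~ variance
  # (beta band: wide enough for the single-epoch variance estimate to settle)
  es_raw <- epoch(white_noise_recording(1, 10 * L, fs), L)
  filt <- bandpass(es_raw, canonical_bands()$beta)
  es <- epoch_set(filt$epochs, fs) # untagged copy of band-limited data
  ss <- epoch_spectra(es)
  df <- diff(ss$frequencies)[1]
  integral <- sum(ss$power) * df
  v <- mean(apply(filt$epochs[, 1, ], 1, var))
  expect_lt(abs(integral / v - 1), 0.05)
  # spectrum of E epochs equals the mean of the single-epoch spectra
  singles <- sapply(1:10, function(e) {
    one <- epoch_set(es$epochs[e, , , drop = FALSE], fs)
    epoch_spectra(one)$power[1, ]
  })
  expect_equal(ss$power[1, ], rowMeans(singles), tolerance = 1e-12)
})
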