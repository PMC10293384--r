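fs <- 312.5
L <- 4096L

test_that("simulated signals are deterministic and match their target spectrum", {
  sp <- signal_spec(duration = 13.2)
  expect_identical(simulate_roi_signal(sp, seed = 7), simulate_roi_signal(sp, seed = 7))
  expect_false(identical(simulate_roi_signal(sp, seed = 7),
                         simulate_roi_signal(sp, seed = 8)))
  # degenerate spec: no peak, zero exponent -> flat spectrum (log-log slope ~ 0)
  flat <- signal_spec(one_over_f_exponent = 0, peak_power_ratio = 0,
                      duration = 20 * L / fs)
  ssf <- epoch_spectra(epoch(roi_recording(matrix(simulate_roi_signal(flat, 4), 1),
                                           fs), L))
  slope <- coef(lm(log(as.numeric(ssf$power)) ~ log(ssf$frequencies)))[2]
  expect_lt(abs(slope), 0.1)
  # strong narrow 10 Hz peak recovered within one frequency bin (plus the
  # offset of 10 Hz from the nearest grid point)
  peaked <- signal_spec(peak_frequency = 10, peak_power_ratio = 3,
                        peak_width = 0.1, duration = 40 * L / fs)
  ssp <- epoch_spectra(epoch(roi_recording(matrix(simulate_roi_signal(peaked, 5), 1),
                                           fs), L))
  expect_lt(abs(peak_frequency(ssp) - 10), fs / L + 0.006)
  expect_error(signal_spec(peak_frequency = 2), "4, 13")
  expect_error(signal_spec(peak_power_ratio = -1))
  expect_error(signal_spec(one_over_f_exponent = NaN), "finite")
})

test_that("band tilts steer the realized relative band powers to their targets", {
  targets <- c(delta = 0.25, theta = 0.15, alpha1 = 0.1, alpha2 = 0.2, beta = 0.3)
  sp <- signal_spec(duration = 20 * L / fs)
  sp$band_power_tilts <- band_tilts_for_targets(sp, targets)
  expect_equal(unname(expected_band_powers(sp)[names(targets)]), unname(targets),
               tolerance = 1e-9)
  x <- simulate_roi_signal(sp, seed = 3)
  rp <- relative_band_power(epoch_spectra(epoch(roi_recording(matrix(x, 1), fs), L)))
  expect_lt(max(abs(rp[1, names(targets)] - targets)), 0.03)
})

test_that("coupling planting is strength-0 identity and band-local", {
  set.seed(6)
  x <- rnorm(8192)
  y <- rnorm(8192)
  bands <- canonical_bands()
  none <- plant_envelope_coupling(x, y, coupling_spec(c(1, 2), bands$alpha2, 0),
                                  fs)
  expect_identical(none$x, x)
  expect_identical(none$y, y)
  # beta-band coupling leaves the delta-band content untouched
  p <- plant_envelope_coupling(x, y, coupling_spec(c(1, 2), bands$beta, 0.5), fs,
                               seed = 9)
  before <- bandpass(epoch(roi_recording(matrix(x, 1), fs), 8192), bands$delta)
  after <- bandpass(epoch(roi_recording(matrix(p$x, 1), fs), 8192), bands$delta)
  expect_lt(max(abs(before$epochs - after$epochs)), 1e-8)
  expect_error(plant_envelope_coupling(x, y,
                                       coupling_spec(c(1, 2),
                                                     frequency_band("hf", 100, 200),
                                                     0.5), fs),
               "Nyquist")
  expect_error(coupling_spec(c(2, 2), bands$beta, 0.5), "distinct")
  expect_error(coupling_spec(c(1, 2), bands$beta, 1), "\\[0, 1\\)")
})

test_that("cohort tables follow the declared schema and visit structure", {
  d <- cohort_design(seed = 42)
  sim <- simulate_cohort(d)
  expect_identical(names(sim$cohort),
                   c("subject", "group", "visit", "age", "sex", "ISCED",
                     "disease_duration", "LEDD", "UPDRS_III", "CAMCOG"))
  # controls only at baseline
  expect_true(all(sim$cohort$visit[sim$cohort$group == "HC"] == "BL"))
  # monotone dropout: no reappearance after a missed visit
  for (s in unique(sim$cohort$subject)) {
    v <- match(sim$cohort$visit[sim$cohort$subject == s], c("BL", "FU1", "FU2"))
    expect_identical(sort(v), seq_along(v))
  }
  # determinism end to end
  expect_identical(sim, simulate_cohort(cohort_design(seed = 42)))
  # no dropout: every patient appears at all three visits
  full <- simulate_cohort(cohort_design(dropout_probability = 0, seed = 1))
  pats <- table(full$cohort$subject[full$cohort$group != "HC"])
  expect_true(all(pats == 3))
  # de novo patients are drug-naive at baseline
  bl_dn <- sim$cohort$group == "de_novo" & sim$cohort$visit == "BL"
  expect_true(all(sim$cohort$LEDD[bl_dn] == 0))
})

test_that("planted slowing appears in the ground truth by construction", {
  sim <- simulate_cohort(cohort_design(dropout_probability = 0, seed = 3))
  tr <- sim$truth
  pats <- unique(sim$cohort$subject[sim$cohort$group != "HC"])
  bl <- tr$peak_frequency[match(paste(pats, "BL"), paste(tr$subject, tr$visit))]
  fu2 <- tr$peak_frequency[match(paste(pats, "FU2"), paste(tr$subject, tr$visit))]
  expect_equal(bl - fu2, rep(1.0, length(pats)), tolerance = 1e-9)
  # true band powers always sum to one
  rp <- as.matrix(tr[paste0("rp_", names(canonical_bands()))])
  expect_equal(unname(rowSums(rp)), rep(1, nrow(rp)), tolerance = 1e-9)
})

test_that("simulated clinical scores recover the planted peak-frequency slope", {
  sim <- simulate_cohort(cohort_design(seed = 8))
  fit <- lm(sim$cohort$CAMCOG ~ sim$truth$peak_frequency)
  expect_lt(abs(coef(fit)[2] - 4), 1.2)
})

test_that("signals mode produces 90-region recordings that carry the truth", {
  d <- cohort_design(n_controls = 0, n_de_novo = 1, n_treated = 0,
                     dropout_probability = 0, seed = 5,
                     signal = list(sample_rate = fs, epoch_length = 2048L,
                                   n_epochs = 4L, one_over_f_exponent = 1,
                                   peak_power_ratio = 4, peak_width = 0.5))
  sim <- simulate_cohort(d, mode = "signals")
  expect_length(sim$recordings, 3L)
  expect_equal(dim(sim$recordings[[1]]$data), c(90, 4 * 2048))
  expect_identical(sim, simulate_cohort(d, mode = "signals"))
  bands <- names(canonical_bands())
  for (k in seq_len(3)) {
    ss <- epoch_spectra(epoch(sim$recordings[[k]], 2048L))
    # region-averaged relative band powers match the ground truth
    rp <- relative_band_power(ss)
    truth_rp <- as.numeric(sim$truth[k, paste0("rp_", bands)])
    expect_lt(max(abs(colMeans(rp) - truth_rp)), 0.02)
  }
  # region-averaged estimated peak shows the planted slowing (coarsely: the
  # per-band tilting that pins the band powers distorts argmax near edges)
  est <- vapply(seq_len(3), function(k)
    mean(peak_frequency(epoch_spectra(epoch(sim$recordings[[k]], 2048L)))),
    numeric(1))
  expect_lt(max(abs(est - sim$truth$peak_frequency)), 1.0)
  expect_lt(est[3], est[1])
})

test_that("invalid cohort designs are rejected", {
  expect_error(cohort_design(dropout_probability = 1.5), "\\[0, 1\\]")
  expect_error(cohort_design(n_treated = -1), ">= 0")
  expect_error(cohort_design(baseline_band_power = c(delta = 0.5, theta = 0.2,
                                                     alpha1 = 0.1, alpha2 = 0.1,
                                                     beta = 0.2)),
               "sum to 1")
  expect_error(cohort_design(band_shift_per_visit = c(delta = 0.01, theta = 0,
                                                      alpha1 = 0, alpha2 = 0,
                                                      beta = 0)),
               "sum to 0")
})
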