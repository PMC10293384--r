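fs <- 312.5

test_that("orthogonalization removes the zero-lag projection exactly", {
  set.seed(1)
  x <- rnorm(500)
  # collinear pair: the residual is the zero series
  o <- orthogonalize_pair(x, 3 * x)
  expect_lt(max(abs(o$y_on_x)), 1e-10)
  # already-orthogonal pair is untouched
  a <- rep(c(1, -1), 250)
  b <- rep(c(1, 1, -1, -1), 125)
  expect_equal(sum(a * b), 0)
  o2 <- orthogonalize_pair(a, b)
  expect_equal(o2$y_on_x, b, tolerance = 1e-12)
  expect_equal(o2$x_on_y, a, tolerance = 1e-12)
  # random pair: residual uncorrelated with its regressor
  y <- rnorm(500)
  o3 <- orthogonalize_pair(x, y)
  expect_lt(abs(cor(x - mean(x), o3$y_on_x)), 1e-10)
  expect_lt(abs(cor(y - mean(y), o3$x_on_y)), 1e-10)
  expect_error(orthogonalize_pair(x, rep(0, 500)), "constant")
  expect_error(orthogonalize_pair(x, rnorm(10)), "equal length")
})

test_that("epoch AEC-c lies in [0, 1] and flags degenerate envelopes", {
  set.seed(2)
  band <- canonical_bands()$alpha2
  for (i in 1:5) {
    es <- bandpass(epoch(white_noise_recording(2, 2048, fs), 2048), band)
    v <- aec_pair(es$epochs[1, 1, ], es$epochs[1, 2, ])
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  # collinear input: residual envelope has zero variance
  x <- bandpass(epoch(white_noise_recording(1, 2048, fs), 2048), band)$epochs[1, 1, ]
  expect_warning(v <- aec_pair(x, 2 * x), "degenerate envelope")
  expect_true(is.na(v))
})

test_that("AEC-c matrix is symmetric, diagonal-free and region-equivariant", {
  set.seed(3)
  band <- canonical_bands()$alpha2
  es <- bandpass(epoch(white_noise_recording(5, 2 * 1024, fs), 1024), band)
  cm <- aec_matrix(es)
  v <- cm$values
  expect_equal(dim(v), c(5, 5))
  expect_true(all(is.na(diag(v))))
  expect_equal(v, t(v))
  expect_true(all(v[upper.tri(v)] >= 0 & v[upper.tri(v)] <= 1))
  expect_equal(cm$n_epochs, 2L)
  # permuting the region order permutes rows and columns identically
  perm <- c(3, 1, 5, 2, 4)
  es_p <- epoch_set(es$epochs[, perm, , drop = FALSE], fs, band = band)
  cm_p <- aec_matrix(es_p)
  expect_equal(cm_p$values, v[perm, perm], tolerance = 1e-12)
  expect_error(aec_matrix(epoch(white_noise_recording(2, 2048, fs), 1024)),
               "band-filtered")
})

test_that("pipeline AEC-c equals the brute-force reference implementation", {
  set.seed(9)
  es <- bandpass(epoch(white_noise_recording(3, 2 * 512, fs), 512),
                 canonical_bands()$alpha2)
  cm <- aec_matrix(es)
  ref <- oracle_aec_matrix(es)
  expect_lt(max(abs(cm$values - ref), na.rm = TRUE), 1e-10)
})

test_that("region profiles are diagonal-excluding row means", {
  m <- matrix(c(NA, 0.6, 0.5,
                0.6, NA, 0.7,
                0.5, 0.7, NA), 3, byrow = TRUE)
  prof <- roi_profile(connectivity_matrix(m))
  expect_equal(as.numeric(prof), c(0.55, 0.65, 0.60))
  expect_equal(attr(prof, "n_used"), c(2, 2, 2))
  const <- connectivity_matrix(matrix(0.4, 4, 4))
  expect_equal(unname(as.numeric(roi_profile(const))), rep(0.4, 4))
  set.seed(4)
  r <- matrix(runif(16, 0.3, 0.7), 4)
  r <- (r + t(r)) / 2
  pr <- as.numeric(roi_profile(connectivity_matrix(r)))
  for (i in 1:4) {
    expect_gte(pr[i], min(r[i, -i]))
    expect_lte(pr[i], max(r[i, -i]))
  }
})

test_that("measured AEC-c grows monotonically with planted coupling strength", {
  band <- canonical_bands()$alpha2
  means <- vapply(c(0, 0.2, 0.4, 0.6), function(s)
    measure_coupling_aecc(s, band, n_reps = 50, seed = 400 + round(100 * s)),
    numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[4] - means[1], 0.1)
})

test_that("a coupling planted in one band leaves other bands at baseline", {
  set.seed(5)
  bands <- canonical_bands()
  cs <- coupling_spec(c(1, 2), bands$beta, 0.6)
  n <- 2 * 4096
  delta_coupled <- replicate(30, {
    p <- plant_envelope_coupling(rnorm(n), rnorm(n), cs, fs)
    es <- bandpass(epoch(roi_recording(rbind(p$x, p$y), fs), 4096), bands$delta)
    mean(sapply(1:2, function(e) aec_pair(es$epochs[e, 1, ], es$epochs[e, 2, ])))
  })
  delta_null <- replicate(30, aecc_noise_pair(0, n_epochs = 2, band = bands$delta))
  expect_gt(t.test(delta_coupled, delta_null)$p.value, 0.01)
})

test_that("a strongly coupled pair dominates the adjacency matrix", {
  band <- canonical_bands()$alpha2
  hits <- 0L
  for (s in 1:10) {
    set.seed(2000 + s)
    n <- 3 * 4096
    data <- matrix(rnorm(6 * n), 6)
    cs <- coupling_spec(c(2, 5), band, 0.6)
    cp <- plant_envelope_coupling(data[2, ], data[5, ], cs, fs)
    data[2, ] <- cp$x
    data[5, ] <- cp$y
    cm <- aec_matrix(bandpass(epoch(roi_recording(data, fs), 4096), band))
    hits <- hits + (max(cm$values, na.rm = TRUE) == cm$values[2, 5])
  }
  expect_gte(hits, 9L)
})
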