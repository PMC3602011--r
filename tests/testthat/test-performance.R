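test_that("upper-bound regression is exact on collinear bin maxima", {
  set.seed(1)
  rate <- runif(200, 1, 19)
  bw <- -100 * rate + 5000 - runif(200, 250, 1000)
  # plant an exactly-on-line maximum in each bin
  planted <- seq_len(10) * 2 - 1  # one exact maximum in every occupied bin
  rate <- c(rate, planted)
  bw <- c(bw, -100 * planted + 5000)
  fit <- upper_bound_regression(rate, bw, bin_width = 2)
  expect_equal(fit$slope, -100, tolerance = 1e-10)
  expect_equal(fit$intercept, 5000, tolerance = 1e-8)
  expect_error(upper_bound_regression(rep(5, 50), rep(3000, 50)),
               "zero variance")
  expect_error(upper_bound_regression(c(1, 1.2, 3, 3.5), c(1, 2, 3, 4) * 1000,
                                      bin_width = 2), "at least 5")
})

test_that("vocal deviation is signed orthogonal distance to the limit", {
  lim <- list(slope = -168.5, intercept = 6019)
  # points on the line are at zero deviation
  expect_equal(vocal_deviation(7, -168.5 * 7 + 6019, lim), 0)
  # worked value below the limit
  expect_equal(vocal_deviation(10, 2000, lim), 13.8514, tolerance = 1e-4)
  # any point above the line has negative deviation
  expect_lt(vocal_deviation(10, -168.5 * 10 + 6019 + 5, lim), 0)
  expect_error(vocal_deviation(10, 2000, list(slope = NA, intercept = 1)),
               "invalid")
})

test_that("vocal deviation matches a nearest-point search oracle", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, -300, -20)
    b <- runif(1, 3000, 8000)
    T0 <- runif(1, 1, 20)
    B0 <- runif(1, 500, 7000)
    d <- vocal_deviation(T0, B0, list(slope = a, intercept = b))
    nearest <- stats::optimize(function(t)
      sqrt((t - T0)^2 + (a * t + b - B0)^2),
      interval = c(-1e4, 1e4), tol = 1e-12)
    expect_equal(abs(d), nearest$objective, tolerance = 1e-7)
    expect_equal(sign(d), sign(a * T0 + b - B0))
  }
})

test_that("upper-bound regression recovers a known limit from clouds", {
  set.seed(8)
  hits <- 0
  for (r in 1:30) {
    cl <- simulate_trill_cloud(500, slope = -168.5, intercept = 6019)
    fit <- upper_bound_regression(cl$trill_rate, cl$bandwidth, 2)
    hits <- hits + (abs(fit$slope / -168.5 - 1) < 0.15 &&
                      abs(fit$intercept / 6019 - 1) < 0.10)
  }
  expect_gte(hits, 27)
})

test_that("cross-correlation scores behave like a bounded similarity", {
  cp <- correlation_params(48000)
  mk <- function(f0, f1, seed = 1) {
    set.seed(seed)
    w <- synth_syllable(syllable_spec(f0, f1, 0.05), 48000)
    spectrogram(c(w, numeric(max(0, 4096 - length(w)))), cp)
  }
  a <- mk(3000, 5000)
  expect_equal(syllable_xcorr(a, a, c(2800, 5200)), 1, tolerance = 1e-9)
  # disjoint bands are near-orthogonal
  b <- mk(6000, 8000)
  expect_lt(syllable_xcorr(a, b, c(2800, 8200)), 0.05)
  # symmetry and bounds
  c1 <- mk(3200, 5200, seed = 2)
  s_ab <- syllable_xcorr(a, c1, c(2800, 5400))
  expect_equal(s_ab, syllable_xcorr(c1, a, c(2800, 5400)))
  expect_gte(s_ab, 0)
  expect_lte(s_ab, 1)
  # a +500 Hz shifted copy scores below the self score (no frequency shifting)
  sh <- mk(3500, 5500)
  expect_lt(syllable_xcorr(a, sh, c(2800, 6000)),
            syllable_xcorr(a, a, c(2800, 6000)))
  # grid mismatch is an error
  other <- spectrogram(numeric(4096), spectrogram_params(512, 128, 48000))
  expect_error(syllable_xcorr(a, other), "frequency grids")
})

test_that("trill consistency is the mean over unordered syllable pairs", {
  cp <- correlation_params(48000)
  mk <- function(f0, f1, seed) {
    set.seed(seed)
    w <- synth_syllable(syllable_spec(f0, f1, 0.05), 48000, jitter_sd = 0.04)
    spectrogram(c(w, numeric(max(0, 4096 - length(w)))), cp)
  }
  specs <- list(mk(3000, 5000, 1), mk(3000, 5000, 2), mk(3000, 5000, 3))
  fb <- c(2800, 5200)
  pairwise <- c(syllable_xcorr(specs[[1]], specs[[2]], fb),
                syllable_xcorr(specs[[1]], specs[[3]], fb),
                syllable_xcorr(specs[[2]], specs[[3]], fb))
  expect_equal(trill_consistency(specs, fb), mean(pairwise),
               tolerance = 1e-9)
  # identical syllables give exactly 1
  expect_equal(trill_consistency(list(specs[[1]], specs[[1]],
                                      specs[[1]]), fb), 1,
               tolerance = 1e-9)
  expect_error(trill_consistency(specs[1]), "at least 2")
})

test_that("consistency decreases along a rendition-jitter grid", {
  cs <- vapply(c(0, 0.02, 0.05, 0.1), function(j) {
    mean(vapply(1:5, function(s) {
      fx <- measured_synth_trill(10, 2000, 5000, jitter = j, n_syl = 6,
                                 seed = 100 + s)
      measure_consistency(fx$syn$waveform, fx$syn$annotations, 48000,
                          trill_low_hz = fx$measures$low_hz,
                          trill_high_hz = fx$measures$high_hz)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("frequency bounding suppresses out-of-band noise", {
  fx <- measured_synth_trill(10, 1500, 5000, jitter = 0.03, n_syl = 6,
                             snr_db = Inf, seed = 6)
  m <- fx$measures
  c_clean <- measure_consistency(fx$syn$waveform, fx$syn$annotations, 48000,
                                 trill_low_hz = m$low_hz,
                                 trill_high_hz = m$high_hz)
  # loud tone well outside the bounded band
  t <- seq_along(fx$syn$waveform) / 48000
  noisy <- fx$syn$waveform + 0.5 * sin(2 * pi * 900 * t)
  c_noisy <- measure_consistency(noisy, fx$syn$annotations, 48000,
                                 trill_low_hz = m$low_hz,
                                 trill_high_hz = m$high_hz)
  expect_lt(abs(c_clean - c_noisy), 0.01)
})

test_that("the consistency transform is capped natural log", {
  expect_equal(consistency_transform(0), 0)
  expect_equal(consistency_transform(0.9), 2.302585, tolerance = 1e-6)
  expect_equal(consistency_transform(1), -log(1e-6))
  expect_error(consistency_transform(1.2), "0, 1")
  expect_error(consistency_transform(-0.1), "0, 1")
  x <- c(0, 0.3, 0.8, 0.99)
  expect_equal(consistency_backtransform(consistency_transform(x)), x,
               tolerance = 1e-12)
})
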