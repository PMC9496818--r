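# Oracle for filter gain: evaluate the Butterworth transfer function
# H(e^{-iw}) = B(e^{-iw}) / A(e^{-iw}) directly at the tone frequency;
# forward-backward filtering squares the magnitude.
filtfilt_gain <- function(spec, freq, tr) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / nyq, type = "pass")
  w <- pi * freq / nyq
  ew <- function(coef) sum(coef * exp(-1i * w * (seq_along(coef) - 1)))
  Mod(ew(bf$b) / ew(bf$a))^2
}

rms <- function(x) sqrt(mean(x^2))

test_that("zero-phase band-pass matches the filter's frequency response", {
  spec <- bandpass_spec()
  mk <- function(f) subject_ts(cbind(tone(f), tone(f, phase = 1), tone(f, phase = 2)),
                               "s", tr = 2)
  # passband tone: gain ~ 1 (within 5%), and equal to the analytic response
  out <- bandpass_filter(mk(0.055), spec)
  core <- 200:1848   # interior samples, away from filtfilt edge transients
  g_meas <- rms(out$values[core, 1]) / rms(tone(0.055)[core])
  expect_equal(g_meas, 1, tolerance = 0.05)
  expect_equal(g_meas, sqrt(filtfilt_gain(spec, 0.055, 2)), tolerance = 0.01)

  # stopband tone: strongly attenuated, matching the response
  out2 <- bandpass_filter(mk(0.20), spec)
  g2 <- rms(out2$values[core, 1]) / rms(tone(0.20)[core])
  expect_lt(g2, 0.10)
  expect_equal(g2, sqrt(filtfilt_gain(spec, 0.20, 2)), tolerance = 0.01)

  # DC is outside the passband entirely (interior samples; the IIR edge
  # transient decays within ~100 samples at this bandwidth)
  dc <- subject_ts(matrix(1, 512, 3), "dc", tr = 2)
  expect_lt(max(abs(bandpass_filter(dc, spec)$values[100:412, ])), 1e-5)

  # attenuation grows monotonically with distance from the band
  freqs <- c(0.09, 0.12, 0.16, 0.20)
  gains <- vapply(freqs, filtfilt_gain, numeric(1), spec = spec, tr = 2)
  expect_true(all(diff(gains) < 0))

  expect_error(bandpass_filter(mk(0.05), bandpass_spec(0.04, 0.3)), "Nyquist")
})

test_that("instantaneous phase tracks a sinusoid's analytic phase", {
  tr <- 2; n <- 1024
  f <- 100 / (n * tr)   # bin-aligned: an integer number of cycles
  ts <- subject_ts(cbind(tone(f, n, tr), tone(f, n, tr), -tone(f, n, tr)),
                   "s", tr)
  ph <- instantaneous_phase(ts)
  core <- 100:900
  # interior phase increments equal 2*pi*f*tr per sample
  dphi <- diff(ph$phases[core, 1])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(dphi, rep(2 * pi * f * tr, length(dphi)), tolerance = 1e-3)
  # identical columns: zero phase difference everywhere
  expect_equal(max(abs(ph$phases[, 1] - ph$phases[, 2])), 0)
  # negated column: difference pi (mod 2pi)
  d <- abs(ph$phases[core, 1] - ph$phases[core, 3])
  expect_equal(pmin(d, 2 * pi - d), rep(pi, length(core)), tolerance = 1e-6)

  ts0 <- subject_ts(cbind(tone(f, 64), tone(f, 64), 0 * tone(f, 64)), "z", 2)
  expect_error(instantaneous_phase(ts0), "all-zero")
})

test_that("phase coherence is 1 / 0 / -1 for in-, quarter- and anti-phase", {
  lags <- c(inphase = 0, orthogonal = pi / 2, antiphase = pi)
  want <- c(inphase = 1, orthogonal = 0, antiphase = -1)
  tol <- c(inphase = 1e-3, orthogonal = 5e-2, antiphase = 1e-3)
  for (nm in names(lags)) {
    ts <- subject_ts(cbind(tone(0.055), tone(0.055, phase = -lags[[nm]]),
                           tone(0.05, phase = 1)), nm, tr = 2)
    pm <- phase_connectome(ts, trim = 50)
    expect_equal(pm$weights[1, 2], want[[nm]], tolerance = tol[[nm]],
                 ignore_attr = TRUE)
  }
})

test_that("phase-interaction matrix is symmetric, bounded and shift-invariant", {
  set.seed(5)
  ph <- matrix(runif(300 * 4, -pi, pi), 300, 4)
  p1 <- phase_interaction_matrix(structure(list(phases = ph, subject_id = "a"),
                                           class = "phase_series"))
  expect_identical(p1$weights, t(p1$weights))
  expect_true(all(p1$weights >= -1 & p1$weights <= 1))
  expect_equal(diag(p1$weights), rep(1, 4))
  # invariance under a global phase shift of every region
  p2 <- phase_interaction_matrix(structure(list(phases = ph + 1.234, subject_id = "a"),
                                           class = "phase_series"))
  expect_equal(p1$weights, p2$weights, tolerance = 1e-12)
})

test_that("duplicated signals give unit phase coherence through the pipeline", {
  set.seed(6)
  x <- rowSums(vapply(seq(0.045, 0.065, length.out = 5),
                      function(f) tone(f, 1024, 2, runif(1, 0, 2 * pi)),
                      numeric(1024)))
  ts <- subject_ts(cbind(x, x, tone(0.05, 1024)), "dup", 2)
  pm <- phase_connectome(ts, trim = 20)
  expect_equal(pm$weights[1, 2], 1, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pearson connectivity matches cor() semantics and flags zero variance", {
  set.seed(8)
  x <- rnorm(2000)
  ts <- subject_ts(cbind(x, -x, rnorm(2000)), "p", 2)
  pm <- pearson_connectivity(ts)
  expect_identical(pm$kind, "pearson")
  expect_equal(pm$weights[1, 2], -1, ignore_attr = TRUE)
  expect_lt(abs(pm$weights[1, 3]), 0.1)  # independent long columns
  bad <- subject_ts(cbind(x, rep(1, 2000), rnorm(2000)), "b", 2)
  expect_error(pearson_connectivity(bad), "Zero-variance.*2")
})
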