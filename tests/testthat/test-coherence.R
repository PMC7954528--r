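# Multitaper spectra and complex coherence against a reference cell.

mkTone <- function(f, dt = 0.02, dur = 30, phase = 0, amp = 1) {
  t <- seq(0, dur - dt, by = dt)
  amp * cos(2 * pi * f * t - phase)
}

test_that("polynomial detrending removes constants, ramps, and trends", {
  expect_equal(detrendTrace(rep(3.2, 50), 0), rep(0, 50))
  ramp <- seq(0, 5, length.out = 200)
  expect_lt(max(abs(detrendTrace(ramp, 1))), 1e-10)
  tt <- seq(0, 1, length.out = 600)
  sine <- sin(2 * pi * 6 * tt)
  y <- 2 * tt + sine
  resid <- detrendTrace(y, 1)
  expect_equal(resid, unname(residuals(lm(y ~ tt))), tolerance = 1e-10)
  # the sinusoid survives: its amplitude on the tone basis is preserved
  amp <- 2 * sqrt(mean(resid * sin(2 * pi * 6 * tt))^2 +
                  mean(resid * cos(2 * pi * 6 * tt))^2)
  expect_equal(amp, 1, tolerance = 0.05)
  expect_error(detrendTrace(1:3, 2), "too short")
})

test_that("multitaper PSD localises tones and scales quadratically", {
  x <- mkTone(2)
  psd <- multitaperPSD(x, 0.02)
  expect_true(all(psd$power >= 0))
  df <- psd$frequency[2] - psd$frequency[1]
  expect_lte(abs(psd$frequency[which.max(psd$power)] - 2), df)
  psd2 <- multitaperPSD(2 * x, 0.02)
  expect_equal(max(psd2$power) / max(psd$power), 4, tolerance = 1e-6)
})

test_that("white noise shows no spurious dominant line", {
  hits <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(750))
    psd <- multitaperPSD(x, 0.02)
    max(psd$power) <= 10 * median(psd$power)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dominant frequency picks the strongest in-band peak", {
  opts <- spectralOptions(searchBand = c(0.5, 3))
  df <- 1 / 30
  expect_lte(abs(dominantFrequency(mkTone(2), 0.02, opts) - 2), df)
  two <- mkTone(1, amp = 1) + mkTone(2, amp = 2)
  expect_lte(abs(dominantFrequency(two, 0.02, opts) - 2), df)
  expect_error(
    dominantFrequency(mkTone(2), 0.02,
                      spectralOptions(searchBand = c(30, 40))),
    "Nyquist")
})

test_that("self-coherence is exactly 1 and phase measures lag", {
  x <- mkTone(2) + withr::with_seed(1, rnorm(1500, 0, 0.01))
  r <- coherenceAt(x, x, 0.02, 2)
  expect_equal(r$magnitude, 1, tolerance = 1e-9)
  expect_equal(r$phase, 0, tolerance = 1e-9)

  # quarter-period delay at f* = 2 Hz (tau = 0.125 s) at SNR 10
  withr::with_seed(7, {
    ref <- mkTone(2) + rnorm(1500, 0, 1 / sqrt(2) / 10)
    lag <- mkTone(2, phase = pi / 2) + rnorm(1500, 0, 1 / sqrt(2) / 10)
  })
  r <- coherenceAt(lag, ref, 0.02, 2)
  expect_lt(abs(abs(r$phase) - pi / 2), 0.05)
  expect_gt(r$phase, 0)   # the delayed trace LAGS: positive phase

  # exchanging trace and reference flips the phase sign
  r2 <- coherenceAt(ref, lag, 0.02, 2)
  expect_equal(r2$phase, -r$phase, tolerance = 1e-9)
})

test_that("coherence is invariant to gain and offset", {
  withr::with_seed(3, {
    ref <- mkTone(2) + rnorm(1500, 0, 0.1)
    x <- mkTone(2, phase = 1) + rnorm(1500, 0, 0.1)
  })
  r1 <- coherenceAt(x, ref, 0.02, 2)
  r2 <- coherenceAt(5 * x + 2, 0.3 * ref - 1, 0.02, 2)
  expect_equal(r2$magnitude, r1$magnitude, tolerance = 1e-9)
  expect_equal(r2$phase, r1$phase, tolerance = 1e-9)
})

test_that("independent noise shows insignificant coherence", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      a <- rnorm(1500); b <- rnorm(1500)
    })
    r <- coherenceAt(a, b, 0.02, 2)
    r$magnitude < r$ci_magnitude * 2   # below its own 95% scale
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("magnitude confidence interval shrinks with trial length", {
  ciAt <- function(nSamp) {
    mean(vapply(1:8, function(s) {
      withr::with_seed(s, {
        ref <- cos(2 * pi * 2 * seq(0, (nSamp - 1) * 0.02, by = 0.02)) +
          rnorm(nSamp, 0, 0.5)
        x <- cos(2 * pi * 2 * seq(0, (nSamp - 1) * 0.02, by = 0.02) - 1) +
          rnorm(nSamp, 0, 0.5)
      })
      coherenceAt(x, ref, 0.02, 2)$ci_magnitude
    }, numeric(1)))
  }
  expect_lt(ciAt(2000), ciAt(500))
})

test_that("coherence maps share f*, normalise the reference, and recover phases", {
  # all cells copies of the reference -> all magnitudes 1
  x <- mkTone(2) + withr::with_seed(2, rnorm(1500, 0, 0.05))
  tr <- trialRecording(cbind(ref = x, c1 = x, c2 = x), 0.02, "ref")
  cm <- coherenceMap(tr)
  expect_equal(cm$magnitude, rep(1, 3), tolerance = 1e-9)
  expect_equal(length(unique(cm$f_star)), 1L)

  # planted phases from the generator, SNR 10
  cfg <- synthConfig(seed = 5, nPartners = 6, snr = 10)
  trial <- synthTimeseries(cfg)
  cm <- coherenceMap(trial)
  planted <- attr(trial, "phases")
  err <- abs(Arg(exp(1i * (cm$phase - planted[cm$cell_id]))))
  expect_lt(max(err), 0.1)
})
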