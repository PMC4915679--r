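test_that("preprocessing subtracts background and normalizes", {
  wl <- seq(250, 800, 2)
  flat <- spectrumRecord(wl, rep(0.2, length(wl)))
  # background == sample -> all-zero spectrum
  z <- preprocessSpectrum(flat, flat, controlA280 = 1)
  expect_true(all(z@absorbance == 0))
  # arithmetic: 1.0 at 550, control 2.0 -> 0.5
  ab <- rep(0, length(wl)); ab[wl == 550] <- 1.0
  s <- preprocessSpectrum(spectrumRecord(wl, ab),
                          spectrumRecord(wl, rep(0, length(wl))),
                          controlA280 = 2.0)
  expect_equal(s@absorbance[wl == 550], 0.5)
  # linearity in the sample
  s1 <- preprocessSpectrum(spectrumRecord(wl, ab),
                           spectrumRecord(wl, rep(0, length(wl))), 1.5)
  s2 <- preprocessSpectrum(spectrumRecord(wl, 2 * ab),
                           spectrumRecord(wl, rep(0, length(wl))), 1.5)
  expect_equal(s2@absorbance, 2 * s1@absorbance)
  # errors
  expect_error(preprocessSpectrum(spectrumRecord(wl, ab),
                                  spectrumRecord(wl + 1, ab), 1),
               "grids differ")
  expect_error(preprocessSpectrum(spectrumRecord(wl, ab),
                                  spectrumRecord(wl, rep(0, length(wl))), 0),
               "positive")
})

test_that("a canonical 550 nm band is called bound at the right wavelength", {
  s <- generateSpectrum(peakNm = 550, peakSd = 30, amplitude = 0.3,
                        noiseSd = 0.005, seed = 1)
  v <- detectRetinalPeak(s)
  expect_true(v$bound)
  expect_lte(abs(v$lambdaMax - 550), 2)
})

test_that("flat and out-of-window spectra are not called bound", {
  flat <- generateSpectrum(amplitude = 0, noiseSd = 0.005, seed = 2)
  expect_false(detectRetinalPeak(flat)$bound)
  # shoulder peak centered below the window leaves no in-window excess
  # above the chord baseline
  shoulder <- generateSpectrum(peakNm = 470, peakSd = 30, amplitude = 0.3,
                               noiseSd = 0.005, seed = 3)
  expect_false(detectRetinalPeak(shoulder)$bound)
  # window outside the data range errors
  narrow <- spectrumRecord(seq(400, 700, 2), rep(0, 151))
  expect_error(detectRetinalPeak(narrow), "outside the data range")
})

test_that("detection is invariant under positive scaling", {
  s <- generateSpectrum(peakNm = 520, peakSd = 30, amplitude = 0.2,
                        noiseSd = 0.005, seed = 4)
  v1 <- detectRetinalPeak(s)
  v2 <- detectRetinalPeak(spectrumRecord(s@wavelength, 7.3 * s@absorbance))
  expect_equal(v1$bound, v2$bound)
  expect_equal(v1$lambdaMax, v2$lambdaMax)
  expect_equal(v1$prominenceSD, v2$prominenceSD, tolerance = 1e-9)
})

test_that("false positives on flat noise stay at or below one percent", {
  fp <- sum(vapply(1:200, function(i) {
    s <- generateSpectrum(amplitude = 0, noiseSd = 0.005, seed = 1000 + i)
    detectRetinalPeak(s)$bound
  }, logical(1)))
  expect_lte(fp / 200, 0.01)
})
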