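test_that("spectra CSV round trip and unit handling", {
  path <- withr::local_tempfile(fileext = ".csv")
  flat <- data.frame(wl = 300:700, a = 50)
  write.csv(flat, path, row.names = FALSE)
  specs <- readSpectra(path, unit = "percent")
  expect_length(specs, 1L)
  expect_equal(specs$a@values, rep(0.5, 401))

  set.seed(11)
  orig <- list(x = randomSpectrum(), y = randomSpectrum())
  writeSpectra(orig, path)
  back <- readSpectra(path)
  expect_equal(back$x@values, orig$x@values, tolerance = 1e-12)
  expect_equal(back$y@values, orig$y@values, tolerance = 1e-12)
})

test_that("malformed spectra CSVs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wl = c(300, 301, 305), a = 1), path, row.names = FALSE)
  expect_error(readSpectra(path), "not uniform")

  writeLines(c("wl,a", "300,1", "301,oops", "302,3"), path)
  expect_error(readSpectra(path), "row 2, column 'a'")
})

test_that("resampling interpolates linearly without extrapolation", {
  flat <- Spectrum(wlDefault, rep(0.5, 401))
  out <- resampleSpectrum(flat, wavelengthGrid(400, 700, 5))
  expect_equal(out@values, rep(0.5, 61))

  set.seed(4)
  sp <- randomSpectrum()
  expect_identical(resampleSpectrum(sp, wlDefault)@values, sp@values)

  ramp <- Spectrum(wlDefault, (wlDefault - 300) / 400)
  half <- resampleSpectrum(ramp, wavelengthGrid(450, 550, 50))
  expect_equal(half@values[half@wl == 500], 0.5)

  expect_error(resampleSpectrum(ramp, wavelengthGrid(200, 700, 100)),
               "range error")
})

test_that("LOESS smoothing preserves low-degree structure and damps noise", {
  wl <- wlDefault
  const <- smoothSpectrum(Spectrum(wl, rep(0.4, 401)))
  expect_equal(const@values, rep(0.4, 401), tolerance = 1e-9)

  line <- Spectrum(wl, 0.1 + 0.001 * (wl - 300))
  sm <- smoothSpectrum(line)
  interior <- wl > 320 & wl < 680
  expect_equal(sm@values[interior], line@values[interior], tolerance = 1e-6)

  # span chosen so the window resolves the sine's ~126 nm period
  clean <- 0.5 + 0.3 * sin(wl / 20)
  clean <- (clean - min(clean)) / diff(range(clean)) * 0.6 + 0.2
  set.seed(42)
  noisy <- Spectrum(wl, pmax(clean + rnorm(401, 0, 0.01), 0))
  rmseBefore <- sqrt(mean((noisy@values - clean)^2))
  rmseAfter <- sqrt(mean((smoothSpectrum(noisy, span = 0.1)@values - clean)^2))
  expect_lt(rmseAfter, rmseBefore)

  expect_error(smoothSpectrum(noisy, span = 0), "span")
  expect_error(smoothSpectrum(noisy, span = 1.5), "span")
})

test_that("repeated smoothing is contractive on noisy input", {
  set.seed(7)
  wl <- wlDefault
  noisy <- Spectrum(wl, pmax(0.4 + 0.2 * sin(wl / 30) + rnorm(401, 0, 0.02), 0))
  once <- smoothSpectrum(noisy)
  twice <- smoothSpectrum(once)
  changeFirst <- sqrt(mean((once@values - noisy@values)^2))
  changeSecond <- sqrt(mean((twice@values - once@values)^2))
  expect_lt(changeSecond, changeFirst)
})

test_that("brightness, saturation and hue match their definitions", {
  flat <- Spectrum(wlDefault, rep(0.5, 401))
  expect_equal(brightnessB2(flat), 0.5)
  expect_equal(brightnessB2(Spectrum(wlDefault, rep(0, 401))), 0)
  ramp <- Spectrum(wlDefault, seq(0, 1, length.out = 401))
  expect_equal(brightnessB2(ramp), 0.5)

  expect_equal(saturationS8(flat), 0)
  # max 0.6, min 0.1, mean 0.35 by construction
  v <- c(rep(0.1, 200), rep(0.6, 200), 0.35)
  expect_equal(saturationS8(Spectrum(wlDefault, sample(v))),
               0.5 / mean(v), tolerance = 1e-12)
  expect_error(saturationS8(Spectrum(wlDefault, rep(0, 401))),
               "undefined saturation")

  peak <- gaussianPeakSpectrum(center = 550)
  expect_equal(hueH1(peak), 550)
  expect_equal(saturationS8(peak),
               (max(peak@values) - min(peak@values)) / mean(peak@values),
               tolerance = 1e-12)
  expect_equal(hueH1(ramp), 700)
  twin <- Spectrum(wlDefault, 0.1 +
    0.5 * (exp(-(wlDefault - 450)^2 / 200) + exp(-(wlDefault - 650)^2 / 200)))
  expect_equal(twin@values[wlDefault == 450], twin@values[wlDefault == 650])
  expect_equal(hueH1(twin), 450)
})

test_that("colorimetric invariances hold on random spectra", {
  set.seed(13)
  for (rep in 1:20) {
    x <- randomSpectrum(); y <- randomSpectrum()
    a <- runif(1, 0.1, 2); b <- runif(1, 0.1, 2)
    mix <- Spectrum(wlDefault, a * x@values + b * y@values)
    expect_equal(brightnessB2(mix),
                 a * brightnessB2(x) + b * brightnessB2(y),
                 tolerance = 1e-10)
    k <- runif(1, 0.1, 3)
    scaled <- Spectrum(wlDefault, k * x@values)
    expect_equal(saturationS8(scaled), saturationS8(x), tolerance = 1e-10)
    expect_identical(hueH1(scaled), hueH1(x))
    shifted <- Spectrum(wlDefault, x@values + runif(1, 0, 0.5))
    expect_identical(hueH1(shifted), hueH1(x))
  }
})
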