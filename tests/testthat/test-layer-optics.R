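test_that("carotenoid layer follows Beer-Lambert with flat backscatter", {
  lay <- carotenoidLayer(D = 0, sC = 0.3)
  expect_equal(lay@R@values, rep(0.3, 401))
  expect_equal(lay@T@values, rep(0.7, 401))
  expect_equal(lay@A@values, rep(0, 401))

  g <- carotenoidTemplate(wlDefault)
  peakIdx <- which.max(g)
  expect_equal(g[peakIdx], 1)
  lay2 <- carotenoidLayer(D = 1, sC = 0)
  expect_equal(lay2@T@values[peakIdx], 0.1, tolerance = 1e-12)
  expect_equal(lay2@A@values[peakIdx], 0.9, tolerance = 1e-12)
  expect_true(all(g[wlDefault > 550] == 0))
})

test_that("structural layer peak, baseline and absorptance behave as specified", {
  lay <- structuralLayer(lambda0 = 500, Hpk = 0.4, w = 80, sB = 0.1, aS = 0)
  expect_equal(lay@R@values[wlDefault == 500], 0.5)
  expect_equal(lay@T@values, 1 - lay@R@values)
  # half maximum at lambda0 +/- w/2
  expect_equal(lay@R@values[wlDefault == 540] - 0.1, 0.2, tolerance = 1e-12)

  absorber <- structuralLayer(lambda0 = 500, Hpk = 0, w = 80, sB = 0, aS = 1)
  expect_equal(absorber@T@values, rep(0, 401))
  expect_equal(absorber@A@values, rep(1, 401))

  expect_error(structuralLayer(lambda0 = 500, Hpk = 0.7, w = 80, sB = 0.5),
               "invariant violation")
})

test_that("achromatic presets anchor white/black reflectance levels", {
  expect_equal(achromaticLayer("white")@R@values, rep(0.55, 401))
  expect_equal(achromaticLayer("black")@R@values, rep(0.05, 401))
  opaque <- achromaticLayer(Rlevel = 0.4, tau = 0)
  expect_equal(opaque@T@values, rep(0, 401))
  expect_equal(downyLayer()@T@values, rep(0, 401))
})

test_that("every layer conserves energy under parameter fuzzing", {
  set.seed(99)
  for (rep in 1:300) {
    lay <- switch(1 + rep %% 3, randomCarotenoidLayer(),
                  randomStructuralLayer(), randomAchromaticLayer())
    resid <- lay@R@values + lay@T@values + lay@A@values - 1
    expect_lt(max(abs(resid)), 1e-12)
    expect_true(all(lay@R@values >= 0 & lay@R@values <= 1))
    expect_true(all(lay@T@values >= 0 & lay@T@values <= 1))
    expect_true(all(lay@A@values >= -1e-12 & lay@A@values <= 1))
  }
})

test_that("stack reflectance sums the three light paths", {
  wl <- wlDefault
  n <- length(wl)
  transparent <- LayerOptics(wl, rep(0, n), rep(1, n))
  white0 <- achromaticLayer(Rlevel = 0.55, tau = 0)
  st <- FeatherStack(transparent, white0, downyLayer(0.3))
  expect_equal(stackReflectance(st)@values, rep(0.55, n))

  col <- LayerOptics(wl, rep(0.2, n), rep(0.5, n))
  st2 <- FeatherStack(col, white0, downyLayer(0.3))
  expect_equal(stackReflectance(st2)@values, rep(0.3375, n))

  ach <- LayerOptics(wl, rep(0.05, n), rep(0.2, n))
  st3 <- FeatherStack(col, ach, downyLayer(0.3))
  expect_equal(stackReflectance(st3)@values, rep(0.2155, n))
})

test_that("stack reflectance matches the scalar three-path oracle", {
  set.seed(123)
  for (rep in 1:30) {
    st <- randomStack()
    expect_lt(max(abs(stackReflectance(st)@values - bruteStackReflectance(st))),
              1e-14)
  }
})

test_that("brightness rises with achromatic reflectance; hue and saturation move as the mechanism dictates", {
  mets <- lapply(c("white", "gray", "black"), function(bg)
    colorMetrics(stackReflectance(buildStack("carotenoid", bg))))
  names(mets) <- c("white", "gray", "black")
  expect_gt(mets$white["B2"], mets$gray["B2"])
  expect_gt(mets$gray["B2"], mets$black["B2"])
  expect_identical(mets$white[["H1"]], mets$black[["H1"]])
  expect_identical(mets$white[["H1"]], mets$gray[["H1"]])

  set.seed(5)
  for (rep in 1:10) {
    Hpk <- runif(1, 0.05, 0.8)
    p <- list(lambda0 = runif(1, 400, 600), Hpk = Hpk, w = runif(1, 50, 150),
              sB = runif(1, 0, min(0.2, 1 - Hpk)), aS = runif(1, 0, 0.3))
    sBlack <- saturationS8(stackReflectance(buildStack("structural", "black", p)))
    sWhite <- saturationS8(stackReflectance(buildStack("structural", "white", p)))
    expect_gt(sBlack, sWhite)
  }
})

test_that("optical density is recoverable from stack output", {
  obs <- stackReflectance(buildStack("carotenoid", "white", list(D = 1.5, sC = 0.3)))
  fit <- fitOpticalDensity(obs)
  expect_lt(abs(fit$D - 1.5) / 1.5, 0.01)

  obs0 <- stackReflectance(buildStack("carotenoid", "white", list(D = 0, sC = 0.3)))
  expect_lte(fitOpticalDensity(obs0)$D, 0.01)

  noisy <- genFeatherSpectrum("carotenoid", "white", list(D = 1.5, sC = 0.3),
                              noiseSd = 0.01, seed = 8)$spectrum
  expect_lt(abs(fitOpticalDensity(noisy)$D - 1.5) / 1.5, 0.05)
})

test_that("layer and stack validity reject broken objects", {
  wl <- wlDefault
  n <- length(wl)
  expect_error(LayerOptics(wl, rep(0.5, n), rep(0.6, n), rep(0.2, n)),
               "R \\+ T \\+ A")
  leaky <- LayerOptics(wl, rep(0.3, n), rep(0.1, n))
  expect_error(FeatherStack(leaky, leaky, leaky), "downy")
  short <- achromaticLayer("white", wl = wavelengthGrid(400, 700, 1))
  expect_error(FeatherStack(carotenoidLayer(1), short, downyLayer()),
               "grid")
})
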