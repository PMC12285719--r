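test_that("background swap reproduces the qualitative sign pattern", {
  tab <- runBackgroundSwap()
  caro <- tab[tab$mechanism == "carotenoid", ]
  stru <- tab[tab$mechanism == "structural", ]
  expect_gt(caro$dB2, 0)        # carotenoid plumage brighter on white
  expect_equal(caro$dH1, 0)     # hue untouched by the achromatic layer
  expect_lt(stru$dS8, 0)        # structural plumage more saturated on black
  expect_gt(stru$dB2, 0)        # and darker on black
  expect_equal(stru$dH1, 0)
})

test_that("parameter sweeps cover the factorial design and match single-point evaluation", {
  dGrid <- seq(0.1, 3, length.out = 20)
  sw <- runParameterSweep("carotenoid", "D", dGrid)
  expect_equal(nrow(sw), 20 * 3)
  expect_true(all(sw$dB2[sw$background == "white"] > 0))

  # spot-check: each row reproducible by one direct stack evaluation
  row <- sw[17, ]
  m <- colorMetrics(stackReflectance(
    buildStack("carotenoid", row$background, list(D = row$value, sC = 0.3))))
  expect_equal(row$B2, m[["B2"]], tolerance = 1e-12)
  expect_equal(row$S8, m[["S8"]], tolerance = 1e-12)
  expect_equal(row$H1, m[["H1"]], tolerance = 1e-12)

  expect_error(runParameterSweep("carotenoid", "Hpk", 1:3), "unknown")
  expect_error(runParameterSweep("carotenoid", "D", numeric(0)), "empty")
})

test_that("structural saturation enhancement is positive and proportionally largest for weakly reflective nanostructures", {
  hGrid <- seq(0.05, 0.8, length.out = 20)
  sw <- runParameterSweep("structural", "Hpk", hGrid,
                          backgrounds = c("white", "black"))
  w <- sw[sw$background == "white", ]
  expect_true(all(w$dS8 < 0))              # black always enhances saturation
  relEnh <- -w$relS8                       # (S8_black - S8_white)/S8_black
  expect_true(all(diff(relEnh) < 0))       # largest at low reflectance
})

test_that("visual sweeps: luminance favors white, chroma favors black", {
  vsw <- runVisualSweep("carotenoid", "D", seq(0.1, 3, length.out = 8),
                        backgrounds = c("white", "black"))
  expect_true(all(vsw$dLuminance[vsw$background == "white"] > 0))

  vss <- runVisualSweep("structural", "Hpk", seq(0.05, 0.8, length.out = 8),
                        backgrounds = c("white", "black"))
  expect_true(all(vss$dChroma[vss$background == "white"] < 0))

  vs <- buildVisualSystem()
  flat <- Spectrum(wlDefault, rep(0.4, 401))
  expect_lt(tetraPoint(quantumCatch(flat, vs))@chroma, 1e-9)
})

test_that("discriminability flags use strict thresholds", {
  expect_equal(unname(flagDiscriminability(1)), c(FALSE, FALSE))
  expect_equal(unname(flagDiscriminability(1.0001)), c(TRUE, FALSE))
  expect_equal(unname(flagDiscriminability(2)), c(TRUE, FALSE))
  expect_equal(unname(flagDiscriminability(2.5)), c(TRUE, TRUE))
})

test_that("group analysis averages replicates and is deterministic end to end", {
  dd <- genDichromatismDataset(n = 4, noiseSd = 0.01, seed = 77)
  vs <- buildVisualSystem()
  r1 <- runDichromatism(dd$spectra, dd$info$sex, vs)
  r2 <- runDichromatism(genDichromatismDataset(n = 4, noiseSd = 0.01,
                                               seed = 77)$spectra,
                        dd$info$sex, vs)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$dS, t(r1$dS))

  # mean spectra really are the replicate means
  wlN <- length(wlDefault)
  manual <- rowMeans(vapply(dd$spectra[dd$info$sex == "A"], specValues,
                            numeric(wlN)))
  expect_equal(r1$meanSpectra$A@values, manual)

  expect_error(runDichromatism(dd$spectra, rep("A", nrow(dd$info)), vs),
               ">= 2 groups")
})

test_that("YAML experiment configs load with visual-system defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mechanism: carotenoid",
               "background: [white, black]",
               "visual_system:",
               "  weberRef: 0.05",
               "  ocularMedia: false"), path)
  cfg <- readExperimentConfig(path)
  expect_equal(cfg$mechanism, "carotenoid")
  expect_s4_class(cfg$vs, "VisualSystem")
  expect_equal(cfg$vs@e[4], 0.05)
})
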