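# Shared fixtures and independent oracles, built in code at test time.

wlDefault <- wavelengthGrid()

# Gaussian reflectance peak on the default grid.
gaussianPeakSpectrum <- function(center = 550, height = 0.5, sigma = 40,
                                 base = 0.05, wl = wlDefault) {
  Spectrum(wl, base + height * exp(-(wl - center)^2 / (2 * sigma^2)))
}

# Seeded random spectrum, bounded away from 0 so log catches are defined.
randomSpectrum <- function(wl = wlDefault) {
  v <- 0.05 + 0.9 * stats::runif(1) *
    abs(stats::spline(seq(min(wl), max(wl), length.out = 8),
                      stats::runif(8), xout = wl)$y)
  Spectrum(wl, pmin(pmax(v, 0.01), 1))
}

# Seeded random layer of each type (for energy-conservation fuzzing).
randomCarotenoidLayer <- function(wl = wlDefault)
  carotenoidLayer(D = stats::runif(1, 0, 4), sC = stats::runif(1), wl = wl)

randomStructuralLayer <- function(wl = wlDefault) {
  Hpk <- stats::runif(1, 0, 0.9)
  structuralLayer(lambda0 = stats::runif(1, 320, 680), Hpk = Hpk,
                  w = stats::runif(1, 20, 200),
                  sB = stats::runif(1, 0, 1 - Hpk), aS = stats::runif(1),
                  wl = wl)
}

randomAchromaticLayer <- function(wl = wlDefault)
  achromaticLayer(Rlevel = stats::runif(1), tau = stats::runif(1), wl = wl)

randomStack <- function(wl = wlDefault) {
  colorful <- if (stats::runif(1) < 0.5) randomCarotenoidLayer(wl) else
    randomStructuralLayer(wl)
  FeatherStack(colorful, randomAchromaticLayer(wl),
               downyLayer(stats::runif(1), wl = wl))
}

# Independent scalar oracle for the three-path stack formula: a plain loop
# over wavelengths, no vectorized reuse of the implementation.
bruteStackReflectance <- function(stack) {
  wl <- wavelengths(stack)
  out <- numeric(length(wl))
  for (k in seq_along(wl)) {
    Rc <- stack@colorful@R@values[k];   Tc <- stack@colorful@T@values[k]
    Ra <- stack@achromatic@R@values[k]; Ta <- stack@achromatic@T@values[k]
    Rd <- stack@downy@R@values[k]
    r <- Rc + Tc * Tc * Ra + Tc * Tc * Ta * Ta * Rd
    out[k] <- min(max(r, 0), 1)
  }
  out
}

# Independent brute-force tetrachromat receptor-noise distance: the explicit
# six-pair / four-triple form, written out term by term.
bruteTetraDS <- function(f, e) {
  num <- (e[3] * e[4])^2 * (f[1] - f[2])^2 +
         (e[2] * e[4])^2 * (f[1] - f[3])^2 +
         (e[2] * e[3])^2 * (f[1] - f[4])^2 +
         (e[1] * e[4])^2 * (f[2] - f[3])^2 +
         (e[1] * e[3])^2 * (f[2] - f[4])^2 +
         (e[1] * e[2])^2 * (f[3] - f[4])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
         (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}

# Raw quantum catches computed independently (plain loop over channels).
bruteRawCatches <- function(spec, vs) {
  step <- vs@wl[2] - vs@wl[1]
  Q <- numeric(4)
  for (i in 1:4) Q[i] <- sum(spec@values * vs@illuminant * vs@S[, i]) * step
  Q
}
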