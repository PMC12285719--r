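#' Default colorful-layer parameter sets
#'
#' The study conditions for the two color mechanisms: a carotenoid-pigmented
#' layer (optical density 1, keratin backscatter 0.3 — a mid-range yellow
#' feather) and a noniridescent structural layer (Gaussian peak at 480 nm,
#' height 0.35, FWHM 100 nm over a 0.05 baseline — a blue-green barb
#' nanostructure).
#'
#' @param mechanism \code{"carotenoid"} or \code{"structural"}.
#' @return Named list of layer parameters.
#' @export
defaultColorfulParams <- function(mechanism = c("carotenoid", "structural")) {
  switch(match.arg(mechanism),
    carotenoid = list(D = 1, sC = 0.3),
    structural = list(lambda0 = 480, Hpk = 0.35, w = 100, sB = 0.05,
                      aS = 0.1))
}

.makeColorfulLayer <- function(mechanism, params, wl) {
  if (mechanism == "carotenoid")
    carotenoidLayer(D = params$D, sC = params$sC, wl = wl)
  else
    structuralLayer(lambda0 = params$lambda0, Hpk = params$Hpk, w = params$w,
                    sB = params$sB, aS = params$aS, wl = wl)
}

#' Build a default feather stack
#'
#' Assembles the default colorful layer of the given mechanism over an
#' achromatic preset and the gray downy layer.
#'
#' @param mechanism \code{"carotenoid"} or \code{"structural"}.
#' @param background Achromatic preset: \code{"white"}, \code{"gray"} or
#'   \code{"black"}.
#' @param params Colorful-layer parameters; default
#'   [defaultColorfulParams()].
#' @param wl Wavelength grid (nm).
#' @return A \linkS4class{FeatherStack}.
#' @export
buildStack <- function(mechanism = c("carotenoid", "structural"),
                       background = c("white", "gray", "black"),
                       params = NULL, wl = wavelengthGrid()) {
  mechanism <- match.arg(mechanism)
  background <- match.arg(background)
  if (is.null(params)) params <- defaultColorfulParams(mechanism)
  FeatherStack(.makeColorfulLayer(mechanism, params, wl),
               achromaticLayer(background, wl = wl),
               downyLayer(wl = wl))
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a synthetic feather reflectance spectrum
#'
#' Emulates a microspectrophotometry measurement of a feather patch on a
#' given achromatic background: the deterministic stack reflectance plus
#' multiplicative Gaussian measurement noise, clamped to [0, 1]. The clean
#' spectrum is returned alongside as ground truth.
#'
#' @param mechanism,background,params,wl Passed to [buildStack()].
#' @param noiseSd Multiplicative noise standard deviation (0 = noiseless).
#' @param seed RNG seed.
#' @return List with \code{spectrum} (noisy \linkS4class{Spectrum}),
#'   \code{clean}, \code{stack} and \code{seed}.
#' @export
genFeatherSpectrum <- function(mechanism = c("carotenoid", "structural"),
                               background = c("white", "gray", "black"),
                               params = NULL, noiseSd = 0.01, seed = 1L,
                               wl = wavelengthGrid()) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  stack <- buildStack(mechanism, background, params, wl)
  clean <- stackReflectance(stack)
  noisy <- if (noiseSd == 0) clean@values else
    withr::with_seed(as.integer(seed),
      clean@values * (1 + stats::rnorm(length(wl), 0, noiseSd)))
  list(spectrum = Spectrum(wl, .clamp01(noisy)), clean = clean,
       stack = stack, seed = as.integer(seed))
}

# Seeded barb-skeleton point cloud: a vertical rachis with oblique barbs.
.featherSkeleton <- function(h, w) {
  cc <- w / 2 + stats::runif(1, -w / 10, w / 10)
  rtop <- 0.08 * h; rbot <- 0.92 * h
  rachis <- cbind(x = cc + stats::rnorm(1, 0, 0.5), y = seq(rtop, rbot, by = 1))
  pts <- rachis
  for (y0 in seq(rtop, rbot, by = 2.5)) {
    len <- stats::runif(1, 0.18, 0.38) * w
    ang <- (50 + stats::rnorm(1, 0, 6)) * pi / 180
    tvec <- seq(0, 1, length.out = 12)
    for (sgn in c(-1, 1)) {
      pts <- rbind(pts, cbind(x = cc + sgn * len * tvec * cos(ang),
                              y = y0 + len * tvec * sin(ang) * 0.4))
    }
  }
  pts
}

#' Generate a synthetic feather-on-background image
#'
#' Rasterizes stylized barb-like strokes of a target HSL color over a uniform
#' white or black photographic background (white lightness about 80--95%,
#' black about 2--8%, with seeded jitter), and returns the exact boolean
#' feather mask as ground truth. The feather occupies exactly
#' \code{round(featherFraction * npixels)} pixels: the pixels closest to a
#' seeded barb skeleton.
#'
#' Feather lightness jitter is kept inside (10%, 60%), so the standard
#' background lightness rules separate feather from background exactly.
#'
#' @param background \code{"white"} or \code{"black"}.
#' @param featherHsl Target feather color, named vector \code{c(H, S, L)}
#'   (degrees, percent, percent); default a carotenoid-like yellow-orange.
#' @param featherFraction Fraction of pixels covered by feather, in (0, 1).
#' @param size Image size c(height, width).
#' @param seed RNG seed.
#' @return List with \code{image} (\linkS4class{RGBImage}), \code{mask}
#'   (logical matrix, TRUE = feather), \code{featherHsl}, \code{trueCount}
#'   and \code{trueMeanL} (ground-truth feather pixel count and mean
#'   lightness), \code{background}, \code{seed}.
#' @export
genFeatherImage <- function(background = c("white", "black"),
                            featherHsl = c(H = 40, S = 70, L = 45),
                            featherFraction = 0.35, size = c(64, 64),
                            seed = 1L) {
  background <- match.arg(background)
  if (featherFraction <= 0 || featherFraction >= 1)
    stop("featherFraction must be in (0, 1)")
  h <- size[1]; w <- size[2]; N <- h * w
  nf <- round(featherFraction * N)
  withr::with_seed(as.integer(seed), {
    pts <- .featherSkeleton(h, w)
    rows <- rep(0:(h - 1L), times = w); cols <- rep(0:(w - 1L), each = h)
    d2 <- vapply(seq_len(N), function(i) {
      min((cols[i] + 0.5 - pts[, "x"])^2 + (rows[i] + 0.5 - pts[, "y"])^2)
    }, numeric(1))
    score <- d2 + stats::runif(N, 0, 1e-6)   # seeded tiebreak
    feather <- rank(score, ties.method = "first") <= nf
    mask <- matrix(FALSE, h, w)
    mask[cbind(rows + 1L, cols + 1L)] <- feather
    H <- matrix(0, h, w); S <- matrix(0, h, w); L <- matrix(0, h, w)
    bgL <- if (background == "white") stats::runif(N, 82, 93) else
      stats::runif(N, 3, 7)
    L[] <- bgL
    k <- sum(mask)
    H[mask] <- (featherHsl[["H"]] + stats::rnorm(k, 0, 2)) %% 360
    S[mask] <- pmin(pmax(featherHsl[["S"]] + stats::rnorm(k, 0, 2), 0), 100)
    L[mask] <- pmin(pmax(featherHsl[["L"]] + stats::rnorm(k, 0, 2), 12), 58)
  })
  img <- hslToRgb(new("HSLPixels", H = H, S = S, L = L))
  list(image = img, mask = mask, featherHsl = featherHsl,
       trueCount = sum(mask), trueMeanL = mean(L[mask]),
       background = background, seed = as.integer(seed))
}

#' Generate a synthetic hyperspectral cube
#'
#' Paints each polygonal region with its reflectance spectrum (interpolated
#' to the band centres) under multiplicative seeded noise, over a flat
#' background. Regions must not overlap. Ground-truth band spectra per region
#' are returned.
#'
#' @param regions List of \code{list(polygon = , spectrum = )} entries;
#'   polygons as vertex matrices (x = col, y = row, 0-based pixel units),
#'   spectra as \linkS4class{Spectrum} objects covering the band range.
#' @param size Cube size c(height, width).
#' @param bandCenters Ascending band-centre wavelengths (nm).
#' @param noiseSd Multiplicative noise standard deviation.
#' @param backgroundLevel Flat background reflectance.
#' @param seed RNG seed.
#' @return List with \code{cube} (\linkS4class{HyperspectralCube}),
#'   \code{truth} (list per region: \code{pixels}, \code{bandSpectrum}),
#'   \code{seed}.
#' @export
genHyperspectralCube <- function(regions, size = c(48, 48),
                                 bandCenters = seq(400, 700, by = 10),
                                 noiseSd = 0.02, backgroundLevel = 0.2,
                                 seed = 1L) {
  h <- size[1]; w <- size[2]; nb <- length(bandCenters)
  arr <- array(backgroundLevel, c(h, w, nb))
  truth <- vector("list", length(regions))
  claimed <- matrix(FALSE, h, w)
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    px <- pixelsInPolygon(reg$polygon, c(h, w))
    idx <- cbind(px[, 1] + 1L, px[, 2] + 1L)
    if (any(claimed[idx])) stop("configuration error: regions overlap")
    claimed[idx] <- TRUE
    sp <- reg$spectrum
    bandVals <- stats::approx(sp@wl, sp@values, xout = bandCenters)$y
    if (anyNA(bandVals))
      stop("region spectrum does not cover the band range")
    for (b in seq_len(nb)) {
      plane <- arr[, , b]
      plane[idx] <- bandVals[b]
      arr[, , b] <- plane
    }
    truth[[i]] <- list(pixels = px, bandSpectrum = bandVals)
  }
  if (noiseSd > 0) {
    arr <- withr::with_seed(as.integer(seed),
      arr * (1 + array(stats::rnorm(length(arr), 0, noiseSd), dim(arr))))
  }
  list(cube = HyperspectralCube(.clamp01(arr), bandCenters), truth = truth,
       seed = as.integer(seed))
}

#' Generate a synthetic sexual-dichromatism dataset
#'
#' Emulates the design where both sexes share an identical colorful
#' (carotenoid) layer and differ only in the hidden achromatic layer (e.g.
#' white in males, black in females). Produces replicate noisy spectra per
#' sex with full metadata.
#'
#' @param colorfulParams Carotenoid-layer parameters shared by both sexes.
#' @param sexABackground,sexBBackground Achromatic presets for the two sexes.
#' @param n Replicates per sex.
#' @param noiseSd Multiplicative measurement-noise standard deviation.
#' @param seed RNG seed.
#' @param wl Wavelength grid (nm).
#' @return List with \code{spectra} (named list of \linkS4class{Spectrum}),
#'   \code{info} (data.frame: sample, sex, background), \code{seed}.
#' @export
genDichromatismDataset <- function(colorfulParams = defaultColorfulParams("carotenoid"),
                                   sexABackground = "white",
                                   sexBBackground = "black",
                                   n = 5, noiseSd = 0.01, seed = 1L,
                                   wl = wavelengthGrid()) {
  if (n < 1) stop("need n >= 1 replicates per sex")
  cleanA <- stackReflectance(buildStack("carotenoid", sexABackground,
                                        colorfulParams, wl))
  cleanB <- stackReflectance(buildStack("carotenoid", sexBBackground,
                                        colorfulParams, wl))
  specs <- withr::with_seed(as.integer(seed), {
    out <- list()
    for (i in seq_len(n)) {
      for (sx in c("A", "B")) {
        clean <- if (sx == "A") cleanA else cleanB
        v <- if (noiseSd == 0) clean@values else
          clean@values * (1 + stats::rnorm(length(wl), 0, noiseSd))
        out[[paste0(sx, i)]] <- Spectrum(wl, .clamp01(v))
      }
    }
    out
  })
  info <- data.frame(
    sample = names(specs),
    sex = substr(names(specs), 1, 1),
    background = ifelse(substr(names(specs), 1, 1) == "A",
                        sexABackground, sexBBackground),
    stringsAsFactors = FALSE)
  list(spectra = specs, info = info, seed = as.integer(seed))
}
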