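#' A1 visual-pigment absorbance template
#'
#' The Govardovskii et al. (2000) A1 rhodopsin nomogram: alpha band plus beta
#' band, parameterized only by the wavelength of maximum absorbance. Used to
#' construct cone spectral sensitivities at arbitrary lambda-max.
#'
#' @param wl Wavelength grid (nm).
#' @param lmax Wavelength of maximum absorbance (nm).
#' @return Numeric absorbance in [0, 1] (unit peak of the alpha band).
#' @export
pigmentTemplateA1 <- function(wl, lmax) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  b <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((wl - lmb) / b)^2)
  pmax(alpha + beta, 0)
}

#' Ocular media transmission
#'
#' Generic long-pass transmission of the avian cornea, lens and humors: a
#' logistic cut-on around 322 nm (passerine-like), unity in the visible.
#'
#' @param wl Wavelength grid (nm).
#' @param lambdaMid Wavelength of half transmission (nm).
#' @param slope Logistic width (nm).
#' @return Transmission fraction in (0, 1).
#' @export
ocularMediaTransmission <- function(wl, lambdaMid = 322, slope = 12) {
  1 / (1 + exp(-(wl - lambdaMid) / slope))
}

#' Build a tetrachromat visual system
#'
#' Constructs cone sensitivities from the A1 pigment template at each
#' lambda-max, optionally filtered by ocular media transmission, then
#' normalized to unit integral over the grid. Channel noise follows the
#' receptor-noise convention e_i = weberRef * sqrt(nRef / n_i), with nRef the
#' largest cone abundance, so the reference (most abundant) channel has Weber
#' fraction weberRef.
#'
#' Defaults emulate a blue tit (*Cyanistes caeruleus*)-like UVS tetrachromat:
#' lambda-max (371, 448, 503, 563) nm, abundances 1:2:2:4, Weber fraction 0.1
#' on the long-wave cone, double-cone noise 0.1, ideal (flat) illuminant.
#' These are literature-convention defaults and every one is overridable.
#'
#' @param lambdaMax Strictly increasing single-cone lambda-max (nm), length 4
#'   (u, s, m, l).
#' @param abundances Relative cone abundances, length 4.
#' @param weberRef Weber fraction of the most abundant channel.
#' @param eD Double-cone Weber fraction.
#' @param lambdaMaxDouble Double-cone lambda-max (nm).
#' @param wl Wavelength grid (nm).
#' @param ocularMedia Apply the ocular media long-pass filter?
#' @param illuminant Illuminant values on \code{wl}; default constant 1
#'   (ideal illumination).
#' @return A \linkS4class{VisualSystem}.
#' @examples
#' vs <- buildVisualSystem()
#' vs@e # 0.2 0.1414 0.1414 0.1
#' @export
buildVisualSystem <- function(lambdaMax = c(371, 448, 503, 563),
                              abundances = c(1, 2, 2, 4),
                              weberRef = 0.1, eD = 0.1,
                              lambdaMaxDouble = 563,
                              wl = wavelengthGrid(),
                              ocularMedia = TRUE,
                              illuminant = NULL) {
  if (length(lambdaMax) != 4L || any(diff(lambdaMax) <= 0))
    stop("parameter error: lambdaMax must be 4 strictly increasing values")
  if (any(lambdaMax < min(wl)) || any(lambdaMax > max(wl)))
    stop("parameter error: lambdaMax must lie within the grid")
  step <- .gridStep(wl)
  om <- if (ocularMedia) ocularMediaTransmission(wl) else rep(1, length(wl))
  S <- vapply(lambdaMax, function(lm) {
    s <- pigmentTemplateA1(wl, lm) * om
    s / (sum(s) * step)
  }, numeric(length(wl)))
  colnames(S) <- c("u", "s", "m", "l")
  SD <- pigmentTemplateA1(wl, lambdaMaxDouble) * om
  SD <- SD / (sum(SD) * step)
  e <- weberRef * sqrt(max(abundances) / abundances)
  if (is.null(illuminant)) illuminant <- rep(1, length(wl))
  new("VisualSystem", wl = wl, S = S, SD = SD, abundances = abundances,
      e = e, eD = eD, illuminant = illuminant)
}

setMethod("show", "VisualSystem", function(object) {
  lm <- object@wl[apply(object@S, 2, which.max)]
  cat(sprintf("VisualSystem: tetrachromat, peaks at %s nm\n",
              paste(lm, collapse = ", ")))
  cat(sprintf("  noise e = %s; double cone eD = %g\n",
              paste(signif(object@e, 4), collapse = ", "), object@eD))
})

#' Quantum catches of a spectrum
#'
#' Per-channel catch Q_i = sum over wavelength of R * I * S_i * step, for the
#' four single cones and the double cone. In relative mode the single-cone
#' catches are additionally normalized to sum to 1 (the input to tetrahedral
#' color space); receptor-noise distances use the raw catches.
#'
#' @param spec A \linkS4class{Spectrum} on the visual system's grid.
#' @param vs A \linkS4class{VisualSystem}.
#' @param mode \code{"relative"} (default) or \code{"raw"}.
#' @return A \linkS4class{QuantumCatches}.
#' @export
quantumCatch <- function(spec, vs, mode = c("relative", "raw")) {
  mode <- match.arg(mode)
  if (!identical(spec@wl, vs@wl))
    stop("spectrum and visual system must share one grid")
  step <- .gridStep(vs@wl)
  w <- spec@values * vs@illuminant * step
  Q <- as.numeric(crossprod(vs@S, w))
  names(Q) <- colnames(vs@S)
  QD <- sum(vs@SD * w)
  rel <- numeric(0)
  if (mode == "relative") {
    tot <- sum(Q)
    if (tot <= 0) stop("degenerate stimulus: total quantum catch is zero")
    rel <- Q / tot
  }
  new("QuantumCatches", Q = Q, QD = QD, rel = rel)
}

# Regular tetrahedron, circumradius 3/4, centred at the origin; fixed
# orientation: u vertex on +z, s in the +y half-plane.
.tetraVertices <- function() {
  r <- 0.75
  rbind(u = c(0, 0, r),
        s = c(0,  2 * sqrt(2) / 3 * r, -r / 3),
        m = c(-sqrt(6) / 3 * r, -sqrt(2) / 3 * r, -r / 3),
        l = c( sqrt(6) / 3 * r, -sqrt(2) / 3 * r, -r / 3))
}

#' Map quantum catches into tetrahedral color space
#'
#' The point is the abundance-weighted vertex average sum(u_i * V_i) with V_i
#' the vertices of a regular tetrahedron of circumradius 3/4 centred at the
#' achromatic origin. Chroma is the Euclidean distance from the origin (0 for
#' any achromatic stimulus, 3/4 at a vertex); luminance is the raw
#' double-cone catch.
#'
#' @param qc A \linkS4class{QuantumCatches} computed in relative mode.
#' @return A \linkS4class{TetraPoint}.
#' @examples
#' vs <- buildVisualSystem()
#' pt <- tetraPoint(quantumCatch(Spectrum(wavelengthGrid(), rep(0.5, 401)), vs))
#' pt@chroma # ~0: flat spectra are achromatic
#' @export
tetraPoint <- function(qc) {
  if (!length(qc@rel))
    stop("tetraPoint needs relative catches (mode = 'relative')")
  xyz <- as.numeric(qc@rel %*% .tetraVertices())
  new("TetraPoint", xyz = xyz, chroma = sqrt(sum(xyz^2)), luminance = qc@QD)
}

setMethod("show", "TetraPoint", function(object) {
  cat(sprintf("TetraPoint (%.4f, %.4f, %.4f): chroma %.4f, luminance %.4f\n",
              object@xyz[1], object@xyz[2], object@xyz[3], object@chroma,
              object@luminance))
})
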