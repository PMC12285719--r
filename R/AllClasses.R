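#' @import methods
NULL

.isUniformGrid <- function(wl, tol = 1e-9) {
  if (length(wl) < 2L) return(FALSE)
  d <- diff(wl)
  all(d > 0) && (max(d) - min(d)) < tol
}

#' Build a uniform wavelength grid
#'
#' Constructs the uniform wavelength axis (in nm) on which all spectra in the
#' package live. The default, 300--700 nm at 1 nm, spans the avian-visible
#' range.
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm); must exceed \code{start}.
#' @param step Positive increment (nm); \code{stop - start} must be an integer
#'   multiple of \code{step}.
#' @return Numeric vector of wavelengths.
#' @examples
#' wl <- wavelengthGrid()
#' length(wl) # 401
#' @export
wavelengthGrid <- function(start = 300, stop = 700, step = 1) {
  if (step <= 0) stop("wavelength step must be > 0")
  if (stop <= start) stop("wavelength stop must exceed start")
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9)
    stop("(stop - start) must be divisible by step")
  seq(start, stop, by = step)
}

#' Reflectance spectrum on a uniform wavelength grid
#'
#' The universal currency of the pipeline: a reflectance (or transmission, or
#' absorption) fraction at each node of a uniform wavelength grid. Values are
#' unitless fractions; raw measured reflectances may exceed 1 and are accepted,
#' but model outputs are kept within [0, 1].
#'
#' @slot wl Numeric wavelength grid (nm), strictly increasing and uniform.
#' @slot values Numeric vector, one finite non-negative value per grid node.
#' @export
setClass("Spectrum", representation(wl = "numeric", values = "numeric"),
  validity = function(object) {
    if (length(object@values) != length(object@wl))
      return("values length must equal grid node count")
    if (!.isUniformGrid(object@wl))
      return("wavelength grid must be uniform and strictly increasing")
    if (!all(is.finite(object@values)))
      return("all values must be finite")
    if (any(object@values < 0))
      return("all values must be >= 0")
    TRUE
  })

#' Create a Spectrum
#' @param wl Uniform wavelength grid (nm).
#' @param values Reflectance fractions, one per node.
#' @return A \linkS4class{Spectrum}.
#' @examples
#' Spectrum(wavelengthGrid(), rep(0.5, 401))
#' @export
Spectrum <- function(wl, values) new("Spectrum", wl = wl, values = values)

#' Per-layer optical triple
#'
#' Reflectance, transmission and absorption spectra of one feather layer.
#' Energy conservation (R + T + A = 1 at every wavelength) is enforced by the
#' class validity.
#'
#' @slot R,T,A \linkS4class{Spectrum} objects on one shared grid, each within
#'   [0, 1], summing to 1 per wavelength.
#' @export
setClass("LayerOptics",
  representation(R = "Spectrum", T = "Spectrum", A = "Spectrum"),
  validity = function(object) {
    wl <- object@R@wl
    if (!identical(wl, object@T@wl) || !identical(wl, object@A@wl))
      return("R, T, A must share one wavelength grid")
    v <- cbind(object@R@values, object@T@values, object@A@values)
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
      return("each of R, T, A must lie within [0, 1]")
    if (max(abs(rowSums(v) - 1)) > 1e-12)
      return("R + T + A must equal 1 at every wavelength (within 1e-12)")
    TRUE
  })

LayerOptics <- function(wl, R, T, A = NULL) {
  if (is.null(A)) A <- 1 - R - T
  new("LayerOptics", R = Spectrum(wl, R), T = Spectrum(wl, T),
      A = Spectrum(wl, A))
}

#' Three-layer feather stack
#'
#' Ordered colorful + achromatic + downy layers whose optical interaction
#' yields total patch reflectance. The downy layer is terminal: its
#' transmission is identically zero (the body behind it is not modelled).
#'
#' @slot colorful,achromatic,downy \linkS4class{LayerOptics} on one grid.
#' @export
setClass("FeatherStack",
  representation(colorful = "LayerOptics", achromatic = "LayerOptics",
                 downy = "LayerOptics"),
  validity = function(object) {
    wl <- object@colorful@R@wl
    if (!identical(wl, object@achromatic@R@wl) ||
        !identical(wl, object@downy@R@wl))
      return("all three layers must share one wavelength grid")
    if (any(object@downy@T@values != 0))
      return("downy layer transmission must be identically 0")
    TRUE
  })

#' Assemble a FeatherStack
#' @param colorful,achromatic,downy \linkS4class{LayerOptics} layers sharing
#'   one wavelength grid; the downy layer must be opaque (T = 0).
#' @return A \linkS4class{FeatherStack}.
#' @export
FeatherStack <- function(colorful, achromatic, downy)
  new("FeatherStack", colorful = colorful, achromatic = achromatic,
      downy = downy)

#' Tetrachromat visual system
#'
#' Cone spectral sensitivities (ultraviolet-, short-, medium- and
#' long-wave-sensitive single cones plus the double cone), relative cone
#' abundances, per-channel Weber-fraction noise, and the illuminant. Each
#' sensitivity integrates to 1 over the grid so that a flat unit spectrum
#' yields unit quantum catch.
#'
#' @slot wl Wavelength grid (nm).
#' @slot S Matrix (nodes x 4) of single-cone sensitivities, columns
#'   \code{u, s, m, l}.
#' @slot SD Double-cone sensitivity vector.
#' @slot abundances Relative cone abundances (length 4).
#' @slot e Per-channel noise (Weber fractions, length 4).
#' @slot eD Double-cone noise.
#' @slot illuminant Illuminant spectrum values (default constant 1).
#' @export
setClass("VisualSystem",
  representation(wl = "numeric", S = "matrix", SD = "numeric",
                 abundances = "numeric", e = "numeric", eD = "numeric",
                 illuminant = "numeric"),
  validity = function(object) {
    step <- object@wl[2] - object@wl[1]
    if (ncol(object@S) != 4L) return("S must have 4 cone columns")
    if (nrow(object@S) != length(object@wl))
      return("S rows must match grid")
    if (any(object@S < 0) || any(object@SD < 0))
      return("sensitivities must be >= 0")
    ints <- colSums(object@S) * step
    if (max(abs(ints - 1)) > 1e-9)
      return("each cone sensitivity must integrate to 1 (within 1e-9)")
    if (abs(sum(object@SD) * step - 1) > 1e-9)
      return("double-cone sensitivity must integrate to 1")
    if (any(object@e <= 0) || object@eD <= 0)
      return("noise values must be > 0")
    TRUE
  })

#' Quantum catches of a tetrachromat eye
#'
#' Raw per-cone catches, the raw double-cone catch, and (in relative mode)
#' relative catches summing to 1.
#'
#' @slot Q Raw single-cone catches (length 4, named u, s, m, l).
#' @slot QD Raw double-cone catch.
#' @slot rel Relative catches (length 4 summing to 1), or length 0 in raw mode.
#' @export
setClass("QuantumCatches",
  representation(Q = "numeric", QD = "numeric", rel = "numeric"),
  validity = function(object) {
    if (any(object@Q < 0)) return("raw catches must be >= 0")
    if (length(object@rel) &&
        abs(sum(object@rel) - 1) > 1e-12)
      return("relative catches must sum to 1 (within 1e-12)")
    TRUE
  })

#' Point in avian tetrahedral color space
#'
#' Relative catches mapped into the regular tetrahedron (circumradius 3/4)
#' whose vertices are the four cone channels and whose centre is the
#' achromatic point. Chroma is the Euclidean distance from the origin;
#' luminance is the double-cone stimulation.
#'
#' @slot xyz Coordinates (x, y, z).
#' @slot chroma Distance from the achromatic origin, in [0, 0.75].
#' @slot luminance Double-cone catch.
#' @export
setClass("TetraPoint",
  representation(xyz = "numeric", chroma = "numeric", luminance = "numeric"),
  validity = function(object) {
    if (length(object@xyz) != 3L) return("xyz must have length 3")
    if (object@chroma < 0 || object@chroma > 0.75 + 1e-9)
      return("chroma must lie in [0, 0.75]")
    TRUE
  })

#' Receptor-noise contrast between two spectra
#'
#' Per-channel log catch ratios and the noise-weighted chromatic (dS) and
#' luminance (dL) distances, in just-noticeable-difference units.
#'
#' @slot deltaF Per-channel log raw-catch ratios (length 4).
#' @slot dS Chromatic distance (JND).
#' @slot dL Luminance distance (JND).
#' @export
setClass("ContrastResult",
  representation(deltaF = "numeric", dS = "numeric", dL = "numeric"),
  validity = function(object) {
    if (object@dS < 0 || object@dL < 0) return("dS and dL must be >= 0")
    TRUE
  })

#' Reflectance-calibrated RGB image
#'
#' @slot pixels Array height x width x 3 of channel values in [0, 1].
#' @export
setClass("RGBImage", representation(pixels = "array"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be height x width x 3")
    if (!all(is.finite(object@pixels)))
      return("pixel values must be finite")
    if (any(object@pixels < 0) || any(object@pixels > 1))
      return("pixel values must lie in [0, 1]")
    TRUE
  })

#' @rdname RGBImage-class
#' @param pixels height x width x 3 array in [0, 1].
#' @export
RGBImage <- function(pixels) new("RGBImage", pixels = pixels)

#' Per-pixel cylindrical HSL values
#'
#' Hue is the angle around the cylinder axis in degrees [0, 360); saturation
#' the radial distance in percent [0, 100]; lightness the cylinder height in
#' percent [0, 100]. Hue is 0 wherever saturation is 0.
#'
#' @slot H,S,L Numeric matrices (height x width).
#' @export
setClass("HSLPixels",
  representation(H = "matrix", S = "matrix", L = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@H), dim(object@S)) ||
        !identical(dim(object@H), dim(object@L)))
      return("H, S, L must share dimensions")
    if (any(object@H < 0) || any(object@H >= 360))
      return("H must lie in [0, 360)")
    if (any(object@S < 0) || any(object@S > 100))
      return("S must lie in [0, 100]")
    if (any(object@L < 0) || any(object@L > 100))
      return("L must lie in [0, 100]")
    TRUE
  })

#' Hyperspectral reflectance cube
#'
#' @slot pixels Array height x width x bands of reflectance fractions.
#' @slot bandCenters Ascending band-centre wavelengths (nm), >= 2 bands.
#' @export
setClass("HyperspectralCube",
  representation(pixels = "array", bandCenters = "numeric"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L) return("pixels must be height x width x bands")
    if (length(object@bandCenters) != d[3])
      return("bandCenters length must match band count")
    if (length(object@bandCenters) < 2L) return("need >= 2 bands")
    if (any(diff(object@bandCenters) <= 0))
      return("bandCenters must be strictly ascending")
    TRUE
  })

#' @rdname HyperspectralCube-class
#' @param pixels height x width x bands array of reflectance fractions.
#' @param bandCenters ascending band-centre wavelengths (nm).
#' @export
HyperspectralCube <- function(pixels, bandCenters)
  new("HyperspectralCube", pixels = pixels, bandCenters = bandCenters)

#' Seeded median-filtered ROI sample set
#'
#' @slot polygon ROI vertex matrix (x = column, y = row pixel coordinates).
#' @slot n Number of samples drawn.
#' @slot seed RNG seed used.
#' @slot locations n x 2 matrix of (row, col) 0-based pixel coordinates.
#' @slot samples n x bands matrix; each row the per-band 3x3 median spectrum.
#' @slot meanSpectrum Mean of the sample spectra, per band.
#' @slot bandCenters Band-centre wavelengths (nm).
#' @export
setClass("ROISampleSet",
  representation(polygon = "matrix", n = "integer", seed = "integer",
                 locations = "matrix", samples = "matrix",
                 meanSpectrum = "numeric", bandCenters = "numeric"),
  validity = function(object) {
    if (nrow(object@samples) != object@n)
      return("sample count must equal n")
    if (nrow(object@locations) != object@n)
      return("location count must equal n")
    TRUE
  })
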