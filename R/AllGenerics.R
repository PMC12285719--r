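#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname specValues
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))

#' @rdname brightnessB2
#' @export
setGeneric("brightnessB2", function(x) standardGeneric("brightnessB2"))

#' @rdname saturationS8
#' @export
setGeneric("saturationS8", function(x) standardGeneric("saturationS8"))

#' @rdname hueH1
#' @export
setGeneric("hueH1", function(x) standardGeneric("hueH1"))

#' @rdname stackReflectance
#' @export
setGeneric("stackReflectance", function(stack) standardGeneric("stackReflectance"))

#' Accessors for wavelength-indexed objects
#'
#' \code{wavelengths} returns the wavelength grid (nm); \code{specValues} the
#' reflectance values of a \linkS4class{Spectrum}.
#'
#' @param x A \linkS4class{Spectrum}, \linkS4class{LayerOptics},
#'   \linkS4class{FeatherStack} or \linkS4class{VisualSystem}.
#' @return Numeric vector.
#' @name wavelengths
NULL
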