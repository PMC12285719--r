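#' Unit-peak carotenoid absorbance template
#'
#' A generic lutein-like long-pass absorber: the unit-peak sum of two
#' Gaussians centred at 430 and 460 nm (sigma 30 nm), set to zero above
#' 550 nm. Multiplying by an optical density D and exponentiating
#' (Beer-Lambert) gives the internal transmittance of a carotenoid-pigmented
#' layer.
#'
#' @param wl Wavelength grid (nm).
#' @return Numeric absorbance shape in [0, 1] with maximum 1.
#' @export
carotenoidTemplate <- function(wl) {
  g <- exp(-(wl - 430)^2 / (2 * 30^2)) + exp(-(wl - 460)^2 / (2 * 30^2))
  g <- g / max(g)
  g[wl > 550] <- 0
  g
}

#' Carotenoid-pigmented colorful layer
#'
#' Beer-Lambert pigment layer with a wavelength-flat keratin backscatter
#' fraction. With ghat the unit-peak absorbance template and internal
#' transmittance t = 10^(-D * ghat): R = sC * t, T = (1 - sC) * t,
#' A = 1 - R - T. Backscattered light traverses the pigment once at full
#' optical density (down and up through half depth each), so D is the total
#' single-pass density.
#'
#' @param D Pigment optical density, >= 0.
#' @param sC Flat keratin backscatter fraction in [0, 1].
#' @param wl Wavelength grid (nm).
#' @param template Function mapping wl to a unit-peak absorbance shape;
#'   default [carotenoidTemplate()].
#' @return A \linkS4class{LayerOptics}.
#' @examples
#' lay <- carotenoidLayer(D = 1, sC = 0.3)
#' range(lay@R@values + lay@T@values + lay@A@values) # 1 1
#' @export
carotenoidLayer <- function(D, sC = 0.3, wl = wavelengthGrid(),
                            template = carotenoidTemplate) {
  if (D < 0) stop("optical density D must be >= 0")
  if (sC < 0 || sC > 1) stop("backscatter fraction sC must be in [0, 1]")
  t <- 10^(-D * template(wl))
  R <- sC * t
  T <- (1 - sC) * t
  LayerOptics(wl, R, T)
}

#' Structurally colored layer (Gaussian reflectance peak)
#'
#' Noniridescent barb-nanostructure reflectance modelled as a Gaussian peak
#' over an incoherent baseline: R = sB + Hpk * exp(-4 ln2 (wl - lambda0)^2 /
#' w^2) with w the full width at half maximum. A flat internal absorptance
#' acts on the non-reflected light: A = aS * (1 - R), T = 1 - R - A.
#'
#' @param lambda0 Peak wavelength (nm), within the grid.
#' @param Hpk Peak reflectance height in [0, 1]; \code{Hpk + sB <= 1}.
#' @param w Full width at half maximum (nm), > 0.
#' @param sB Incoherent baseline reflectance in [0, 1].
#' @param aS Flat internal absorptance in [0, 1].
#' @param wl Wavelength grid (nm).
#' @return A \linkS4class{LayerOptics}.
#' @export
structuralLayer <- function(lambda0, Hpk, w, sB = 0.05, aS = 0.1,
                            wl = wavelengthGrid()) {
  if (w <= 0) stop("FWHM w must be > 0")
  if (Hpk + sB > 1) stop("invariant violation: Hpk + sB must be <= 1")
  if (lambda0 < min(wl) || lambda0 > max(wl))
    stop("peak wavelength lambda0 must lie within the grid")
  R <- sB + Hpk * exp(-4 * log(2) * (wl - lambda0)^2 / w^2)
  A <- aS * (1 - R)
  LayerOptics(wl, R, 1 - R - A, A)
}

.achromaticPresets <- list(
  # white/black reflectance anchored to measured exposed achromatic layers
  # (~55% peak for white, 5% for black); gray is the midpoint convention.
  white = list(R = 0.55, tau = 0.40),
  gray  = list(R = 0.30, tau = 0.10),
  black = list(R = 0.05, tau = 0.05)
)

#' Achromatic (white/gray/black) feather layer
#'
#' Spectrally flat layer beneath the colorful tips. Transmission is a fixed
#' fraction of the non-reflected light, T = tau * (1 - R); absorption is the
#' remainder. Presets: white R = 0.55, gray R = 0.30, black R = 0.05 with
#' tau = 0.40 / 0.10 / 0.05.
#'
#' @param preset \code{"white"}, \code{"gray"} or \code{"black"}; ignored when
#'   \code{Rlevel} is given.
#' @param Rlevel Flat reflectance fraction in [0, 1] (overrides preset).
#' @param tau Internal transmittance factor in [0, 1] (overrides preset).
#' @param wl Wavelength grid (nm).
#' @return A \linkS4class{LayerOptics}.
#' @examples
#' achromaticLayer("white")@R@values[1] # 0.55
#' @export
achromaticLayer <- function(preset = c("white", "gray", "black"),
                            Rlevel = NULL, tau = NULL,
                            wl = wavelengthGrid()) {
  p <- .achromaticPresets[[match.arg(preset)]]
  if (is.null(Rlevel)) Rlevel <- p$R
  if (is.null(tau)) tau <- p$tau
  if (Rlevel < 0 || Rlevel > 1) stop("Rlevel must be in [0, 1]")
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  R <- rep(Rlevel, length(wl))
  T <- tau * (1 - R)
  LayerOptics(wl, R, T)
}

#' Downy (plumulaceous) terminal layer
#'
#' Opaque gray reflector terminating the stack: T = 0, A = 1 - R. The body
#' behind it is not modelled.
#'
#' @param Rlevel Flat reflectance fraction, default 0.30 (gray down).
#' @param wl Wavelength grid (nm).
#' @return A \linkS4class{LayerOptics} with zero transmission.
#' @export
downyLayer <- function(Rlevel = 0.30, wl = wavelengthGrid()) {
  R <- rep(Rlevel, length(wl))
  LayerOptics(wl, R, rep(0, length(wl)))
}

#' Total patch reflectance of a feather stack
#'
#' Sums the three light paths that build patch color: (i) reflection from the
#' colorful layer, (ii) transmission through the colorful layer, reflection
#' from the achromatic layer, and transmission back out, and (iii) the same
#' double pass continued through the achromatic layer to the downy layer and
#' back. Per wavelength:
#' \deqn{R_{tot} = R_c + T_c^2 R_a + T_c^2 T_a^2 R_d}
#' No higher-order interreflections are included; the result is clamped to
#' [0, 1].
#'
#' @param stack A \linkS4class{FeatherStack}.
#' @return Total reflectance \linkS4class{Spectrum}.
#' @export
setMethod("stackReflectance", "FeatherStack", function(stack) {
  Rc <- stack@colorful@R@values;   Tc <- stack@colorful@T@values
  Ra <- stack@achromatic@R@values; Ta <- stack@achromatic@T@values
  Rd <- stack@downy@R@values
  tot <- Rc + Tc^2 * Ra + Tc^2 * Ta^2 * Rd
  Spectrum(wavelengths(stack), pmin(pmax(tot, 0), 1))
})

setMethod("show", "FeatherStack", function(object) {
  wl <- wavelengths(object)
  cat(sprintf("FeatherStack on %d nodes (%g-%g nm)\n", length(wl), wl[1],
              wl[length(wl)]))
  tot <- stackReflectance(object)
  m <- colorMetrics(tot)
  cat(sprintf("  total reflectance: B2 %.3f, S8 %.3f, H1 %g nm\n",
              m["B2"], m["S8"], m["H1"]))
})

#' Fit carotenoid optical density to an observed spectrum
#'
#' Bounded one-dimensional least squares: finds the pigment optical density D
#' whose model stack output best matches an observed total reflectance
#' spectrum, all other stack parameters held fixed.
#'
#' @param observed Observed total reflectance \linkS4class{Spectrum} on the
#'   model grid.
#' @param sC Keratin backscatter fraction of the colorful layer.
#' @param achromatic,downy The fixed \linkS4class{LayerOptics} beneath the
#'   colorful layer.
#' @param bounds Length-2 numeric search interval for D.
#' @param template Carotenoid absorbance template function.
#' @return List with \code{D} (the estimate) and \code{sse} (residual sum of
#'   squares).
#' @export
fitOpticalDensity <- function(observed, sC = 0.3,
                              achromatic = achromaticLayer("white"),
                              downy = downyLayer(),
                              bounds = c(0, 5),
                              template = carotenoidTemplate) {
  wl <- observed@wl
  if (!identical(wl, wavelengths(achromatic)))
    stop("observed spectrum must be on the model grid")
  obj <- function(D) {
    st <- FeatherStack(carotenoidLayer(D, sC, wl, template), achromatic, downy)
    r <- stackReflectance(st)@values - observed@values
    s <- sum(r^2)
    if (!is.finite(s)) stop("fit error: non-finite residuals")
    s
  }
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-10)
  list(D = opt$minimum, sse = opt$objective)
}
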