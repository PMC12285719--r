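#' Background-swap experiment
#'
#' Simulates the default carotenoid and structural stacks on white and black
#' achromatic layers (noiseless) and reports the brightness, saturation and
#' hue of each together with white-minus-black deltas — the computational
#' counterpart of measuring the same feather on swapped backgrounds.
#'
#' @param wl Wavelength grid (nm).
#' @return data.frame, one row per mechanism, with columns
#'   \code{B2_white, B2_black, dB2, S8_white, S8_black, dS8, H1_white,
#'   H1_black, dH1} (deltas are white minus black).
#' @export
runBackgroundSwap <- function(wl = wavelengthGrid()) {
  rows <- lapply(c("carotenoid", "structural"), function(mech) {
    mw <- colorMetrics(stackReflectance(buildStack(mech, "white", wl = wl)))
    mb <- colorMetrics(stackReflectance(buildStack(mech, "black", wl = wl)))
    data.frame(mechanism = mech,
               B2_white = mw[["B2"]], B2_black = mb[["B2"]],
               dB2 = mw[["B2"]] - mb[["B2"]],
               S8_white = mw[["S8"]], S8_black = mb[["S8"]],
               dS8 = mw[["S8"]] - mb[["S8"]],
               H1_white = mw[["H1"]], H1_black = mb[["H1"]],
               dH1 = mw[["H1"]] - mb[["H1"]])
  })
  do.call(rbind, rows)
}

.sweepParams <- function(mechanism, param, value) {
  p <- defaultColorfulParams(mechanism)
  if (!param %in% names(p))
    stop(sprintf("unknown %s parameter '%s'", mechanism, param))
  p[[param]] <- value
  p
}

#' Factorial parameter sweep over achromatic backgrounds
#'
#' Evaluates the stack model over a grid of one colorful-layer parameter
#' crossed with achromatic presets, reporting spectral color metrics per cell
#' and each metric's delta against the black preset at the same parameter
#' value.
#'
#' @param mechanism \code{"carotenoid"} or \code{"structural"}.
#' @param param Swept parameter name (e.g. \code{"D"} for carotenoid,
#'   \code{"Hpk"} or \code{"w"} for structural).
#' @param values Numeric grid of parameter values (nonempty).
#' @param backgrounds Achromatic presets to cross with the grid.
#' @param wl Wavelength grid (nm).
#' Deltas (\code{dB2, dS8, dH1}) are taken against the black preset at the
#' same parameter value; \code{relB2} and \code{relS8} additionally express
#' the brightness and saturation deltas as fractions of the black-preset
#' value. The proportional form is the natural scale for "how much does the
#' achromatic layer change the color": the absolute saturation delta
#' necessarily shrinks toward zero as the colorful layer loses reflectance
#' (no color, nothing to enhance), while the proportional effect is largest
#' exactly where the layer is weakly reflective.
#'
#' @return data.frame with one row per (value, background):
#'   \code{mechanism, param, value, background, B2, S8, H1, dB2, dS8, dH1,
#'   relB2, relS8} (deltas vs the black preset; NA if black is not included).
#' @export
runParameterSweep <- function(mechanism = c("carotenoid", "structural"),
                              param, values,
                              backgrounds = c("white", "gray", "black"),
                              wl = wavelengthGrid()) {
  mechanism <- match.arg(mechanism)
  if (!length(values)) stop("empty parameter grid")
  rows <- list()
  for (v in values) {
    p <- .sweepParams(mechanism, param, v)
    met <- lapply(backgrounds, function(bg)
      colorMetrics(stackReflectance(buildStack(mechanism, bg, p, wl))))
    names(met) <- backgrounds
    for (bg in backgrounds) {
      m <- met[[bg]]
      blk <- if ("black" %in% backgrounds) met[["black"]] else
        c(B2 = NA_real_, S8 = NA_real_, H1 = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        mechanism = mechanism, param = param, value = v, background = bg,
        B2 = m[["B2"]], S8 = m[["S8"]], H1 = m[["H1"]],
        dB2 = m[["B2"]] - blk[["B2"]], dS8 = m[["S8"]] - blk[["S8"]],
        dH1 = m[["H1"]] - blk[["H1"]],
        relB2 = (m[["B2"]] - blk[["B2"]]) / blk[["B2"]],
        relS8 = (m[["S8"]] - blk[["S8"]]) / blk[["S8"]])
    }
  }
  do.call(rbind, rows)
}

#' Visual-model sweep: luminance and chroma over backgrounds
#'
#' As [runParameterSweep()], but every simulated spectrum is additionally
#' passed through the avian visual model: luminance is the double-cone catch
#' and chroma the distance from the achromatic centre of the tetrahedral
#' color space. Deltas are taken against the black preset.
#'
#' @inheritParams runParameterSweep
#' @param vs A \linkS4class{VisualSystem}; default [buildVisualSystem()] on
#'   \code{wl}.
#' @return data.frame with one row per (value, background):
#'   \code{mechanism, param, value, background, luminance, chroma,
#'   dLuminance, dChroma}.
#' @export
runVisualSweep <- function(mechanism = c("carotenoid", "structural"),
                           param, values,
                           backgrounds = c("white", "gray", "black"),
                           vs = NULL, wl = wavelengthGrid()) {
  mechanism <- match.arg(mechanism)
  if (is.null(vs)) vs <- buildVisualSystem(wl = wl)
  if (!length(values)) stop("empty parameter grid")
  rows <- list()
  for (v in values) {
    p <- .sweepParams(mechanism, param, v)
    pts <- lapply(backgrounds, function(bg) {
      spec <- stackReflectance(buildStack(mechanism, bg, p, wl))
      tetraPoint(quantumCatch(spec, vs, mode = "relative"))
    })
    names(pts) <- backgrounds
    for (bg in backgrounds) {
      pt <- pts[[bg]]
      blk <- if ("black" %in% backgrounds) pts[["black"]] else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        mechanism = mechanism, param = param, value = v, background = bg,
        luminance = pt@luminance, chroma = pt@chroma,
        dLuminance = if (is.null(blk)) NA_real_ else
          pt@luminance - blk@luminance,
        dChroma = if (is.null(blk)) NA_real_ else pt@chroma - blk@chroma)
    }
  }
  do.call(rbind, rows)
}

#' Discriminability bands for a receptor-noise distance
#'
#' Conventional JND thresholds, both strict: distances above 1 are
#' theoretically discriminable; 2 to 3 is considered the more reliable
#' threshold, so "reliable" flags distances strictly above 2. A distance of
#' exactly 1 (or 2) is not flagged.
#'
#' @param d Distance in JND units.
#' @return Named logical vector \code{c(theoretical, reliable)}.
#' @export
flagDiscriminability <- function(d) c(theoretical = d > 1, reliable = d > 2)

#' Group-wise discriminability analysis
#'
#' Averages replicate spectra within each group (sex, morph, ...), then
#' computes pairwise receptor-noise chromatic (dS) and luminance (dL)
#' distances between the group mean spectra, flagging pairs above the
#' conventional discriminability bands: "theoretical" for distances strictly
#' above 1 JND, "reliable" strictly above 2.
#'
#' @param spectra Named list of \linkS4class{Spectrum} objects on one grid.
#' @param groups Character/factor of group labels, one per spectrum.
#' @param vs A \linkS4class{VisualSystem}; default [buildVisualSystem()].
#' @return List with \code{dS} and \code{dL} (symmetric matrices between
#'   groups), \code{pairs} (data.frame: groupA, groupB, dS, dL,
#'   dS_theoretical, dS_reliable, dL_theoretical, dL_reliable) and
#'   \code{meanSpectra}.
#' @export
runDichromatism <- function(spectra, groups, vs = NULL) {
  if (length(spectra) != length(groups))
    stop("need one group label per spectrum")
  lv <- unique(as.character(groups))
  if (length(lv) < 2L) stop("need >= 2 groups")
  wl <- spectra[[1]]@wl
  if (is.null(vs)) vs <- buildVisualSystem(wl = wl)
  meanSpectra <- lapply(lv, function(g) {
    vals <- vapply(spectra[groups == g], specValues, numeric(length(wl)))
    Spectrum(wl, rowMeans(vals))
  })
  names(meanSpectra) <- lv
  k <- length(lv)
  dS <- dL <- matrix(0, k, k, dimnames = list(lv, lv))
  pairs <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    cr <- receptorContrast(meanSpectra[[i]], meanSpectra[[j]], vs)
    dS[i, j] <- dS[j, i] <- cr@dS
    dL[i, j] <- dL[j, i] <- cr@dL
    pairs[[length(pairs) + 1L]] <- data.frame(
      groupA = lv[i], groupB = lv[j], dS = cr@dS, dL = cr@dL,
      dS_theoretical = unname(flagDiscriminability(cr@dS)["theoretical"]),
      dS_reliable = unname(flagDiscriminability(cr@dS)["reliable"]),
      dL_theoretical = unname(flagDiscriminability(cr@dL)["theoretical"]),
      dL_reliable = unname(flagDiscriminability(cr@dL)["reliable"]))
  }
  list(dS = dS, dL = dL, pairs = do.call(rbind, pairs),
       meanSpectra = meanSpectra)
}

#' Read an experiment configuration from YAML
#'
#' Configs hold a mechanism, layer parameter maps, achromatic preset(s) and
#' optionally a visual-system block (lambdaMax, abundances, weberRef,
#' ocularMedia). Missing entries fall back to package defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration entries.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$visual_system)) {
    v <- cfg$visual_system
    cfg$vs <- buildVisualSystem(
      lambdaMax = if (is.null(v$lambdaMax)) c(371, 448, 503, 563) else
        as.numeric(v$lambdaMax),
      abundances = if (is.null(v$abundances)) c(1, 2, 2, 4) else
        as.numeric(v$abundances),
      weberRef = if (is.null(v$weberRef)) 0.1 else v$weberRef,
      ocularMedia = if (is.null(v$ocularMedia)) TRUE else
        isTRUE(v$ocularMedia))
  }
  cfg
}
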