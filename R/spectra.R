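#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wl)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "LayerOptics", function(x) x@R@wl)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "FeatherStack", function(x) x@colorful@R@wl)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "VisualSystem", function(x) x@wl)

#' @rdname specValues
#' @export
setMethod("specValues", "Spectrum", function(x) x@values)

setMethod("show", "Spectrum", function(object) {
  wl <- object@wl
  cat(sprintf("Spectrum: %d nodes, %g-%g nm (step %g)\n", length(wl),
              wl[1], wl[length(wl)], wl[2] - wl[1]))
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
              min(object@values), mean(object@values), max(object@values)))
})

.gridStep <- function(wl) wl[2] - wl[1]

#' Read reflectance spectra from CSV
#'
#' Reads the package's spectra CSV dialect: first column \code{wl} (integer
#' nm, ascending, uniform) and one column per sample. Files conventionally
#' hold reflectance in percent (0--100); values are converted to the internal
#' 0--1 fraction unless \code{unit = "fraction"}.
#'
#' @param path CSV file path.
#' @param unit \code{"percent"} (default; values divided by 100) or
#'   \code{"fraction"}.
#' @return Named list of \linkS4class{Spectrum} objects, one per sample column.
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, unit = c("percent", "fraction")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("spectra CSV needs a 'wl' column plus >= 1 sample")
  if (names(df)[1] != "wl") stop("first column must be named 'wl'")
  wl <- df[[1]]
  if (!is.numeric(wl)) stop("parse error: non-numeric wavelength column")
  if (!.isUniformGrid(wl))
    stop("format error: wavelength grid is not uniform ascending")
  lapply(stats::setNames(seq_len(ncol(df) - 1L) + 1L, names(df)[-1]),
    function(j) {
      v <- df[[j]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
        stop(sprintf("parse error: non-numeric cell at row %d, column '%s'",
                     bad, names(df)[j]))
      }
      if (anyNA(v))
        stop(sprintf("parse error: missing value at row %d, column '%s'",
                     which(is.na(v))[1], names(df)[j]))
      if (unit == "percent") v <- v / 100
      Spectrum(wl, v)
    })
}

#' Write reflectance spectra to CSV
#'
#' Inverse of [readSpectra()]: writes a \code{wl} column plus one column per
#' spectrum, in percent by default.
#'
#' @param specs A \linkS4class{Spectrum} or (named) list of them on one grid.
#' @param path Output CSV path.
#' @param unit \code{"percent"} or \code{"fraction"}.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(specs, path, unit = c("percent", "fraction")) {
  unit <- match.arg(unit)
  if (is(specs, "Spectrum")) specs <- list(spec1 = specs)
  wl <- specs[[1]]@wl
  for (s in specs)
    if (!identical(s@wl, wl)) stop("all spectra must share one grid")
  if (is.null(names(specs)))
    names(specs) <- paste0("spec", seq_along(specs))
  vals <- lapply(specs, function(s)
    if (unit == "percent") s@values * 100 else s@values)
  df <- data.frame(wl = wl, vals, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation onto \code{target}; no extrapolation is performed, so
#' the target range must lie within the source range. Values at nodes shared
#' with the source grid are copied, not interpolated.
#'
#' @param spec A \linkS4class{Spectrum}.
#' @param target Target wavelength grid (see [wavelengthGrid()]).
#' @return A \linkS4class{Spectrum} on \code{target}.
#' @export
resampleSpectrum <- function(spec, target) {
  wl <- spec@wl
  if (min(target) < min(wl) || max(target) > max(wl))
    stop("range error: target grid extends beyond source range")
  out <- stats::approx(wl, spec@values, xout = target, method = "linear")$y
  hit <- match(target, wl)
  keep <- !is.na(hit)
  out[keep] <- spec@values[hit[keep]]
  Spectrum(target, out)
}

#' LOESS-smooth a spectrum
#'
#' Locally weighted quadratic regression (tricube weights) over a window of
#' \code{span} times the node count, the convention used when processing
#' measured reflectance spectra before colorimetry. Constants and straight
#' lines pass through unchanged; high-frequency measurement noise is
#' attenuated.
#'
#' @param spec A \linkS4class{Spectrum} with at least 10 nodes.
#' @param span Smoothing span as a fraction of the grid, in (0, 1]; default
#'   0.3.
#' @return Smoothed \linkS4class{Spectrum} on the same grid; values clamped at
#'   0 (LOESS can slightly undershoot near zero).
#' @export
smoothSpectrum <- function(spec, span = 0.3) {
  if (span <= 0 || span > 1) stop("parameter error: span must be in (0, 1]")
  if (length(spec@wl) < 10L) stop("need >= 10 nodes to smooth")
  fit <- stats::loess(v ~ wl, data = data.frame(wl = spec@wl, v = spec@values),
                      span = span, degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  Spectrum(spec@wl, pmax(stats::predict(fit, spec@wl), 0))
}

#' Brightness (B2): mean reflectance
#'
#' Mean reflectance fraction over the measured wavelength range (plain mean
#' over grid nodes; on a uniform grid this equals the normalized integral up
#' to endpoint treatment).
#'
#' @param x A \linkS4class{Spectrum}.
#' @return Mean reflectance fraction.
#' @examples
#' brightnessB2(Spectrum(wavelengthGrid(), rep(0.5, 401))) # 0.5
#' @export
setMethod("brightnessB2", "Spectrum", function(x) mean(x@values))

#' Saturation (S8): spectral range over mean
#'
#' (max reflectance - min reflectance) / mean reflectance. Unitless;
#' scale-invariant; zero for any flat spectrum.
#'
#' @param x A \linkS4class{Spectrum} with positive mean reflectance.
#' @return Saturation ratio.
#' @export
setMethod("saturationS8", "Spectrum", function(x) {
  b <- mean(x@values)
  if (b <= 0) stop("undefined saturation: mean reflectance is zero")
  (max(x@values) - min(x@values)) / b
})

#' Hue (H1): wavelength of maximum reflectance
#'
#' Ties are broken toward the shortest wavelength.
#'
#' @param x A \linkS4class{Spectrum}.
#' @return Wavelength (nm).
#' @export
setMethod("hueH1", "Spectrum", function(x) x@wl[which.max(x@values)])

#' Summary color metrics of a spectrum
#'
#' Convenience wrapper returning brightness (B2), saturation (S8) and hue (H1)
#' in one named vector.
#'
#' @param spec A \linkS4class{Spectrum}.
#' @return Named numeric vector \code{c(B2, S8, H1)}.
#' @export
colorMetrics <- function(spec) {
  c(B2 = brightnessB2(spec), S8 = saturationS8(spec), H1 = hueH1(spec))
}
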