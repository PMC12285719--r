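#' Convert an RGB image to cylindrical HSL
#'
#' Standard cylindrical HSL: lightness is (max + min)/2 in percent [0, 100];
#' saturation the chroma divided by the headroom 1 - |2L - 1|, in percent;
#' hue the hextant angle in degrees [0, 360). Hue is defined as 0 where
#' saturation is 0.
#'
#' @param img An \linkS4class{RGBImage}.
#' @return An \linkS4class{HSLPixels}.
#' @examples
#' px <- rgbToHsl(RGBImage(array(c(1, 0, 0), c(1, 1, 3))))
#' c(px@H, px@S, px@L) # 0 100 50: pure red
#' @export
rgbToHsl <- function(img) {
  p <- img@pixels
  d <- dim(p)
  r <- matrix(p[, , 1], d[1], d[2])
  g <- matrix(p[, , 2], d[1], d[2])
  b <- matrix(p[, , 3], d[1], d[2])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  c0 <- mx - mn
  L <- (mx + mn) / 2
  S <- ifelse(c0 == 0, 0, c0 / (1 - abs(2 * L - 1)))
  H <- matrix(0, nrow(r), ncol(r))
  i <- c0 > 0 & mx == r
  H[i] <- ((g[i] - b[i]) / c0[i]) %% 6
  i <- c0 > 0 & mx == g & mx != r
  H[i] <- (b[i] - r[i]) / c0[i] + 2
  i <- c0 > 0 & mx == b & mx != r & mx != g
  H[i] <- (r[i] - g[i]) / c0[i] + 4
  H <- (H * 60) %% 360
  new("HSLPixels", H = H, S = pmin(S * 100, 100), L = pmin(L * 100, 100))
}

#' Convert HSL pixels back to an RGB image
#'
#' Inverse of [rgbToHsl()]; round trips are exact to floating-point
#' precision wherever hue is defined.
#'
#' @param px An \linkS4class{HSLPixels}.
#' @return An \linkS4class{RGBImage}.
#' @export
hslToRgb <- function(px) {
  H <- px@H; S <- px@S / 100; L <- px@L / 100
  C <- (1 - abs(2 * L - 1)) * S
  X <- C * (1 - abs((H / 60) %% 2 - 1))
  m <- L - C / 2
  hx <- floor(H / 60) %% 6
  r <- ifelse(hx == 0 | hx == 5, C, ifelse(hx == 1 | hx == 4, X, 0))
  g <- ifelse(hx == 1 | hx == 2, C, ifelse(hx == 0 | hx == 3, X, 0))
  b <- ifelse(hx == 3 | hx == 4, C, ifelse(hx == 2 | hx == 5, X, 0))
  out <- array(0, c(nrow(H), ncol(H), 3))
  out[, , 1] <- r + m; out[, , 2] <- g + m; out[, , 3] <- b + m
  RGBImage(pmin(pmax(out, 0), 1))
}

#' Background threshold rules for HSL masking
#'
#' The lightness rules used to remove achromatic photographic backgrounds:
#' white backgrounds have lightness above 60%, black backgrounds below 10%.
#'
#' @param background \code{"white"}, \code{"black"} or \code{"both"}.
#' @return List of threshold rules for [hslThresholdMask()].
#' @export
backgroundRules <- function(background = c("white", "black", "both")) {
  background <- match.arg(background)
  w <- list(Lmin = 60); b <- list(Lmax = 10)
  switch(background, white = list(w), black = list(b), both = list(w, b))
}

#' Mask background pixels by HSL thresholds
#'
#' Each rule is a named list with any of \code{Hmin, Hmax, Smin, Smax, Lmin,
#' Lmax}; a pixel matches a rule when every stated bound holds (strict
#' inequalities: value > min, value < max). The mask is TRUE where a pixel
#' matches ANY rule — rules describe the background; the retained (feather)
#' pixels are the complement.
#'
#' @param px An \linkS4class{HSLPixels}.
#' @param rules List of threshold rules, e.g. [backgroundRules()].
#' @return Logical matrix, TRUE = background (masked out).
#' @export
hslThresholdMask <- function(px, rules) {
  known <- c("Hmin", "Hmax", "Smin", "Smax", "Lmin", "Lmax")
  mask <- matrix(FALSE, nrow(px@L), ncol(px@L))
  for (rule in rules) {
    if (!length(rule) || !all(names(rule) %in% known))
      stop("malformed rule: bounds must be of ",
           paste(known, collapse = ", "))
    m <- matrix(TRUE, nrow(px@L), ncol(px@L))
    ch <- list(H = px@H, S = px@S, L = px@L)
    for (nm in names(rule)) {
      v <- ch[[substr(nm, 1, 1)]]
      m <- m & if (endsWith(nm, "min")) v > rule[[nm]] else v < rule[[nm]]
    }
    mask <- mask | m
  }
  if (all(mask))
    warning("all pixels matched a background rule; retained set is empty")
  mask
}

#' Summarize retained HSL pixels
#'
#' Means of lightness and saturation over the retained (non-masked) pixels,
#' hue as a circular mean (with the arithmetic mean also reported, for
#' comparability with tools that average hue naively), plus density
#' histograms of each channel.
#'
#' @param px An \linkS4class{HSLPixels}.
#' @param mask Logical background mask (TRUE = masked out); NULL retains all.
#' @return List with \code{meanL}, \code{meanS}, \code{meanHue} (circular),
#'   \code{meanHueArith}, \code{nRetained}, and \code{hist} (per-channel
#'   density histograms from [graphics::hist()]).
#' @export
summarizeHsl <- function(px, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(px@L), ncol(px@L))
  keep <- !mask
  if (!any(keep)) stop("empty summary: all pixels are masked")
  h <- px@H[keep]; s <- px@S[keep]; l <- px@L[keep]
  rad <- h * pi / 180
  circ <- (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
  if (circ > 360 - 1e-6) circ <- 0
  list(meanL = mean(l), meanS = mean(s),
       meanHue = circ, meanHueArith = mean(h),
       nRetained = sum(keep),
       hist = list(
         H = graphics::hist(h, breaks = seq(0, 360, by = 10), plot = FALSE),
         S = graphics::hist(s, breaks = seq(0, 100, by = 2.5), plot = FALSE),
         L = graphics::hist(l, breaks = seq(0, 100, by = 2.5), plot = FALSE)))
}

#' Read / write RGB images
#'
#' Thin PNG/TIFF wrappers keeping pixel values linear in [0, 1]. Grayscale
#' files are expanded to 3 channels; any alpha channel is dropped.
#'
#' @param path Image path; format chosen by extension (.png, .tif/.tiff).
#' @return An \linkS4class{RGBImage}.
#' @export
readRGBImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  p <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(p)) == 2L) p <- array(rep(p, 3), c(dim(p), 3))
  if (dim(p)[3] > 3L) p <- p[, , 1:3, drop = FALSE]
  RGBImage(p)
}

#' @rdname readRGBImage
#' @param img An \linkS4class{RGBImage} (or logical mask matrix for
#'   \code{writeMaskPNG}).
#' @export
writeRGBImage <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img@pixels, path),
    tif = , tiff = tiff::writeTIFF(img@pixels, path, bits.per.sample = 16L),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' @rdname readRGBImage
#' @param mask Logical matrix to store as a black/white PNG.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
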