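#' Pixels inside a polygonal ROI
#'
#' Pixel coordinates are 0-based, row-major (row, col); a pixel belongs to the
#' ROI when its centre (col + 0.5, row + 0.5) lies strictly inside the
#' polygon, which makes polygons half-open on their right/bottom edges.
#'
#' @param polygon Vertex matrix with columns (x = col, y = row), in pixel
#'   units.
#' @param dim Image dimensions c(height, width).
#' @return Integer matrix of (row, col) 0-based coordinates.
#' @export
pixelsInPolygon <- function(polygon, dim) {
  h <- dim[1]; w <- dim[2]
  rows <- rep(0:(h - 1L), times = w)
  cols <- rep(0:(w - 1L), each = h)
  inside <- pracma::inpolygon(cols + 0.5, rows + 0.5,
                              polygon[, 1], polygon[, 2], boundary = FALSE)
  cbind(row = rows[inside], col = cols[inside])
}

#' Seeded median-filtered ROI sampling of a hyperspectral cube
#'
#' Draws \code{n} sample locations uniformly with replacement from the ROI
#' pixels whose full 3x3 neighbourhood lies inside the image, and extracts at
#' each location the per-band median of the 3x3 pixel area. The median makes
#' single-pixel outliers (dead pixels, specular glints) inert. The mean
#' spectrum over all samples is also returned.
#'
#' @param cube A \linkS4class{HyperspectralCube}.
#' @param roi Polygon vertex matrix (x = col, y = row), 0-based pixel units.
#' @param n Number of sample locations (default 500).
#' @param seed RNG seed; the same seed reproduces locations and samples
#'   exactly.
#' @return A \linkS4class{ROISampleSet}.
#' @export
sampleRoiMedian <- function(cube, roi, n = 500, seed = 1L) {
  d <- dim(cube@pixels)
  px <- pixelsInPolygon(roi, d[1:2])
  ok <- px[, 1] >= 1L & px[, 1] <= d[1] - 2L &
        px[, 2] >= 1L & px[, 2] <= d[2] - 2L
  px <- px[ok, , drop = FALSE]
  if (nrow(px) == 0L)
    stop("geometry error: no ROI pixel has a complete 3x3 neighbourhood")
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(nrow(px), n, replace = TRUE))
  loc <- px[idx, , drop = FALSE]
  samples <- t(vapply(seq_len(n), function(k) {
    r <- loc[k, 1]; c <- loc[k, 2]   # 0-based; array indexing is 1-based
    nb <- cube@pixels[(r):(r + 2L), (c):(c + 2L), , drop = FALSE]
    apply(nb, 3, stats::median)
  }, numeric(d[3])))
  new("ROISampleSet", polygon = roi, n = as.integer(n),
      seed = as.integer(seed), locations = loc, samples = samples,
      meanSpectrum = colMeans(samples), bandCenters = cube@bandCenters)
}

setMethod("show", "ROISampleSet", function(object) {
  cat(sprintf("ROISampleSet: %d samples (seed %d), %d bands (%g-%g nm)\n",
              object@n, object@seed, length(object@bandCenters),
              min(object@bandCenters), max(object@bandCenters)))
})

#' Read / write hyperspectral cubes
#'
#' Cubes are stored as multi-directory TIFF files (one directory per band,
#' values linear in [0, 1]) with a JSON sidecar
#' \code{{"band_centers_nm": [...]}} named \code{<path>.json}.
#'
#' @param cube A \linkS4class{HyperspectralCube}.
#' @param path TIFF path (.tif/.tiff).
#' @return \code{readHyperspectralCube} returns a
#'   \linkS4class{HyperspectralCube}; \code{writeHyperspectralCube} returns
#'   \code{path} invisibly.
#' @export
writeHyperspectralCube <- function(cube, path) {
  frames <- lapply(seq_along(cube@bandCenters),
                   function(b) cube@pixels[, , b])
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  jsonlite::write_json(list(band_centers_nm = cube@bandCenters),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeHyperspectralCube
#' @export
readHyperspectralCube <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (b in seq_along(frames)) arr[, , b] <- frames[[b]]
  HyperspectralCube(arr, as.numeric(side$band_centers_nm))
}
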