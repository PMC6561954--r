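## The local-integration operator: near-field weighting, locally integrated
## polarizability, TERS intensity, the far-field limit, and the tip-scan
## engine.

#' Effective Raman polarizability density under a confined field
#'
#' Weights the free-molecule Raman polarizability density by the near-field
#' amplitude twice (once for the incident field, once for the scattered
#' field):
#' \deqn{\delta\rho_{loc}(r, R) = F(r - R)\, \delta\rho(r)\, F(r - R)}
#' i.e. voxelwise multiplication by F^2. Complex values are preserved.
#' The integration domain stays the full grid: the decay of F performs the
#' localization, so no hard cutoff is applied.
#'
#' @param rd a [RamanDensity-class] (or any [VolumetricField-class]).
#' @param nf a [NearField-class].
#' @return a [VolumetricField-class] on the same grid.
#' @export
effectiveDensity <- function(rd, nf) {
  w <- sampleOnGrid(nf, rd@grid)
  out <- rd
  out@values <- rd@values * as.numeric(w * w)
  out
}

#' Locally integrated Raman polarizability
#'
#' The near-field Raman polarizability of one mode at tip position R:
#' \deqn{\alpha'_k(R) = \int F(r-R)\, \delta\rho(r)\, F(r-R)\, dr}
#' evaluated as the midpoint Riemann sum over the density grid. Linear in
#' the density. With a uniform field (F = 1) this reduces to [farField()].
#'
#' @inheritParams effectiveDensity
#' @return complex scalar alpha'_k(R), Angstrom^3 per normal-coordinate
#'   unit.
#' @export
localPolarizability <- function(rd, nf) {
  integrateField(effectiveDensity(rd, nf))
}

#' TERS intensity at one tip position
#'
#' The squared modulus |alpha'_k(R)|^2 of the locally integrated Raman
#' polarizability — the modulus handles the complex resonant case.
#'
#' @inheritParams effectiveDensity
#' @return non-negative real scalar.
#' @export
tersIntensity <- function(rd, nf) {
  Mod(localPolarizability(rd, nf))^2
}

#' Far-field Raman polarizability
#'
#' Integration of the Raman polarizability density over all space without
#' any field weighting — the conventional far-field Raman response obeying
#' the ordinary selection rules. Identical to [localPolarizability()] with
#' a uniform field.
#'
#' @param rd a [RamanDensity-class] (or any [VolumetricField-class]).
#' @return complex scalar.
#' @export
farField <- function(rd) {
  integrateField(rd)
}

#' Create a tip-scan plan
#'
#' @param xrange,yrange scan windows (Angstrom), each numeric(2).
#' @param step scan step, default 0.2 Angstrom.
#' @param height tip (field-centre) height above the molecular plane,
#'   Angstrom.
#' @param field a [NearField-class] template; its centre is replaced by the
#'   tip position at every pixel.
#' @return a [ScanPlan-class].
#' @export
ScanPlan <- function(xrange, yrange, step = 0.2, height,
                     field = NearField()) {
  new("ScanPlan", xrange = as.numeric(xrange), yrange = as.numeric(yrange),
      step = as.numeric(step), height = as.numeric(height), field = field)
}

#' @rdname ScanPlan
#' @param plan a [ScanPlan-class].
#' @export
scanCoords <- function(plan) {
  list(x = seq(plan@xrange[1L], plan@xrange[2L], by = plan@step),
       y = seq(plan@yrange[1L], plan@yrange[2L], by = plan@step))
}

#' Scan a tip over a Raman density to produce a TERS image
#'
#' Evaluates the TERS intensity |alpha'_k(R)|^2 at every tip position of
#' the plan. The density is tip-independent, so one density is reused
#' against many field samplings — this is what makes the scan cheap. Per
#' pixel, the squared per-axis offsets are combined by outer sums, the
#' profile applied, squared, and contracted with the density in one
#' vectorized pass; no interpolation between pixels is performed.
#'
#' If the scan window lies entirely outside the density grid a warning is
#' emitted (the image will be near zero).
#'
#' @param rd a [RamanDensity-class], or a list of them on compatible grids
#'   (one image per mode is returned as a list).
#' @param plan a [ScanPlan-class].
#' @return a [TERSImage-class], or a list of them when `rd` is a list.
#' @export
scanImage <- function(rd, plan) {
  if (is.list(rd)) {
    g <- rd[[1L]]@grid
    for (d in rd) if (!gridsCompatible(g, d@grid))
      stop("densities in a multi-mode scan must share one grid")
    return(lapply(rd, scanImage, plan = plan))
  }
  stopifnot(is(rd, "VolumetricField"), is(plan, "ScanPlan"))
  co <- scanCoords(plan)
  grid <- rd@grid
  gx <- axisCoords(grid, 1L); gy <- axisCoords(grid, 2L)
  gz <- axisCoords(grid, 3L)
  if (min(co$x) > max(gx) || max(co$x) < min(gx) ||
      min(co$y) > max(gy) || max(co$y) < min(gy))
    warning("scan window lies entirely outside the density grid; ",
            "the image will be near zero")
  nf <- plan@field
  w <- nf@fwhm
  lor <- nf@profile == "lorentzian3d"
  ## squared scaled offset along z is the same for every pixel
  qz <- ((gz - plan@height) / w[3L])^2
  vox <- voxelVolume(grid)
  vals <- rd@values
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  intens <- matrix(0, nrow = length(co$x), ncol = length(co$y))
  for (j in seq_along(co$y)) {
    qy <- ((gy - co$y[j]) / w[2L])^2
    for (i in seq_along(co$x)) {
      qx <- ((gx - co$x[i]) / w[1L])^2
      s <- outer(outer(qx, qy, "+"), qz, "+")
      amp <- if (lor) 1 / (1 + 4 * s) else exp(-4 * log(2) * s)
      alpha <- sum(vals * as.numeric(amp * amp)) * vox
      intens[i, j] <- Re(alpha)^2 + Im(alpha)^2
    }
  }
  freq <- if (is(rd, "RamanDensity")) rd@mode@frequency else NA_real_
  idx <- if (is(rd, "RamanDensity")) rd@mode@index else NA_integer_
  new("TERSImage", intensities = intens, x = co$x, y = co$y,
      provenance = list(modes = idx, frequencies = freq,
                        profile = nf@profile, fwhm = w,
                        height = plan@height, step = plan@step,
                        component = rd@component))
}

#' @rdname scanImage
#' @param img a [TERSImage-class].
#' @export
imageIntensities <- function(img) img@intensities

#' @rdname scanImage
#' @export
imageCoords <- function(img) list(x = img@x, y = img@y)

#' @rdname scanImage
#' @export
imageProvenance <- function(img) img@provenance

#' Write / read a TERS image as delimited text plus a JSON sidecar
#'
#' The matrix goes to tab-separated text (rows = x, columns = y); the axes
#' and provenance go to `<path>.json`.
#'
#' @param img a [TERSImage-class].
#' @param path output path for the matrix.
#' @return `path`, invisibly (`readTERSImage`: the image).
#' @export
writeTERSImage <- function(img, path) {
  utils::write.table(img@intensities, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- c(list(x = img@x, y = img@y), img@provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTERSImage
#' @export
readTERSImage <- function(path) {
  intens <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(intens) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("TERSImage", intensities = intens, x = as.numeric(meta$x),
      y = as.numeric(meta$y),
      provenance = meta[setdiff(names(meta), c("x", "y"))])
}

setMethod("show", "TERSImage", function(object) {
  cat("TERSImage:", nrow(object@intensities), "x", ncol(object@intensities),
      "pixels\n")
  cat("  x:", sprintf("[%.2f, %.2f]", min(object@x), max(object@x)),
      " y:", sprintf("[%.2f, %.2f]", min(object@y), max(object@y)),
      "Angstrom\n")
  cat("  max intensity:", sprintf("%.6g", max(object@intensities)), "\n")
  p <- object@provenance
  if (!is.null(p$frequencies))
    cat("  modes:", paste(format(p$frequencies), collapse = ", "), "cm^-1\n")
})

setMethod("show", "ScanPlan", function(object) {
  cat("ScanPlan: x", sprintf("[%.2f, %.2f]", object@xrange[1], object@xrange[2]),
      "y", sprintf("[%.2f, %.2f]", object@yrange[1], object@yrange[2]),
      "step", object@step, "Angstrom\n")
  cat("  tip height:", object@height, "Angstrom;",
      object@field@profile, "FWHM",
      paste(object@field@fwhm, collapse = ", "), "Angstrom\n")
})
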