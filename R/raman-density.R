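## Raman polarizability densities: finite differencing of displaced-geometry
## polarizability densities, display normalization, complex-part handling,
## and the plain-text mode-table / XYZ interfaces.

#' Create a normal mode
#'
#' @param index integer mode index k.
#' @param frequency harmonic wavenumber, cm^-1.
#' @param displacement n_atoms x 3 numeric matrix of dimensionless
#'   displacement direction vectors.
#' @param label free-text label.
#' @return a [NormalMode-class].
#' @export
NormalMode <- function(index, frequency, displacement, label = "") {
  new("NormalMode", index = as.integer(index),
      frequency = as.numeric(frequency),
      displacement = rbind(displacement, deparse.level = 0), label = as.character(label))
}

#' @rdname NormalMode
#' @param mode a [NormalMode-class].
#' @export
modeFrequency <- function(mode) mode@frequency

#' @rdname NormalMode
#' @export
modeIndex <- function(mode) mode@index

#' Create a Raman density directly from a field
#'
#' Used by the synthetic generator (analytic densities) and by
#' [centralDifference()]; `dQ = NA` marks an analytic (non-differenced)
#' density.
#'
#' @param field a [VolumetricField-class].
#' @param mode the [NormalMode-class] the density belongs to.
#' @param dQ displacement step used, normal-coordinate units.
#' @return a [RamanDensity-class].
#' @export
RamanDensity <- function(field, mode, dQ = NA_real_) {
  new("RamanDensity", grid = field@grid, values = field@values,
      component = field@component, meta = field@meta, mode = mode,
      dQ = as.numeric(dQ))
}

#' @rdname RamanDensity
#' @param rd a [RamanDensity-class].
#' @export
densityMode <- function(rd) rd@mode

#' Central difference of displaced-geometry polarizability densities
#'
#' Builds the Raman polarizability density d rho^(alpha)/dQ_k by three-point
#' numerical differentiation of the polarizability densities at geometries
#' displaced by +/- dQ along the normal coordinate:
#' \deqn{\delta\rho = (\rho_+ - \rho_-) / (2 \Delta Q)}
#' voxelwise in complex arithmetic (for a first derivative the midpoint
#' value of the three-point stencil cancels). Exact for densities linear
#' in Q.
#'
#' @param rhoPlus,rhoMinus [VolumetricField-class] densities at the +dQ and
#'   -dQ geometries, on identical grids.
#' @param dQ displacement step (> 0), normal-coordinate units; default 0.01.
#' @param mode the [NormalMode-class] of the displacement.
#' @return a [RamanDensity-class].
#' @export
centralDifference <- function(rhoPlus, rhoMinus, dQ = 0.01,
                              mode = NormalMode(0L, 0, diag(3))) {
  if (!gridsCompatible(rhoPlus@grid, rhoMinus@grid))
    stop("grid mismatch between the +dQ and -dQ densities")
  if (length(dQ) != 1L || !is.finite(dQ) || dQ <= 0)
    stop("'dQ' must be a single positive number")
  vals <- (rhoPlus@values - rhoMinus@values) / (2 * dQ)
  RamanDensity(VolumetricField(rhoPlus@grid, vals,
                               component = rhoPlus@component,
                               meta = c(rhoPlus@meta, list(dQ = dQ))),
               mode = mode, dQ = dQ)
}

#' Normalize a Raman density for display
#'
#' Divides the values by the maximum modulus so isosurface plots can use a
#' common isovalue (e.g. 0.2). This output exists only for visualization:
#' the intensity pipeline never consumes it, because intensities must not
#' depend on per-mode rescaling.
#'
#' @param rd a [RamanDensity-class] (or any [VolumetricField-class]).
#' @return a [VolumetricField-class] with max |value| = 1.
#' @export
normalizeForDisplay <- function(rd) {
  mx <- max(Mod(rd@values))
  if (mx == 0) stop("cannot normalize an all-zero field for display")
  VolumetricField(rd@grid, rd@values / mx, component = rd@component,
                  meta = c(rd@meta, list(displayNormalized = TRUE)))
}

#' Split a complex Raman density into real and imaginary fields
#'
#' In the resonant regime the Raman polarizability density acquires a
#' non-trivial imaginary part; this returns the two parts as real-valued
#' fields such that `rd = re + i * im` exactly.
#'
#' @param rd a [RamanDensity-class] (or any [VolumetricField-class]).
#' @return list with [VolumetricField-class] elements `re` and `im`.
#' @export
splitParts <- function(rd) {
  list(re = VolumetricField(rd@grid, complex(real = Re(rd@values)),
                            component = rd@component,
                            meta = c(rd@meta, list(part = "real"))),
       im = VolumetricField(rd@grid, complex(real = Im(rd@values)),
                            component = rd@component,
                            meta = c(rd@meta, list(part = "imaginary"))))
}

#' Read / write a plain-text normal-mode table
#'
#' The mode table is whitespace-delimited text with one row per
#' (mode, atom) pair and columns `mode` (index), `freq` (cm^-1), `atom`
#' (index), `dx`, `dy`, `dz` (displacement components). A header row with
#' these names is written and tolerated on read.
#'
#' @param path file path.
#' @return `readModeTable`: a list of [NormalMode-class] objects, ordered by
#'   mode index.
#' @export
readModeTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  need <- c("mode", "freq", "atom", "dx", "dy", "dz")
  if (!all(need %in% names(tab)))
    stop("mode table '", path, "' must have columns ",
         paste(need, collapse = ", "))
  lapply(split(tab, tab$mode), function(m) {
    m <- m[order(m$atom), ]
    NormalMode(m$mode[1L], m$freq[1L],
               as.matrix(m[, c("dx", "dy", "dz")]),
               label = paste0("mode", m$mode[1L]))
  })
}

#' @rdname readModeTable
#' @param modes a list of [NormalMode-class] objects.
#' @export
writeModeTable <- function(modes, path) {
  rows <- do.call(rbind, lapply(modes, function(m) {
    d <- m@displacement
    data.frame(mode = m@index, freq = m@frequency, atom = seq_len(nrow(d)),
               dx = d[, 1L], dy = d[, 2L], dz = d[, 3L])
  }))
  utils::write.table(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write XYZ geometry files
#'
#' Minimal XYZ support: atom count, comment, then `element x y z` rows in
#' Angstrom.
#'
#' @param path file path.
#' @return `readXYZ`: list with `elements` (character) and `positions`
#'   (n x 3 matrix, Angstrom).
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || length(lines) < n + 2L)
    stop("malformed XYZ file '", path, "'")
  toks <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  pos <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  list(elements = vapply(toks, `[`, "", 1L), positions = pos,
       comment = lines[2L])
}

#' @rdname readXYZ
#' @param elements character vector of element symbols.
#' @param positions n x 3 matrix, Angstrom.
#' @param comment comment line.
#' @export
writeXYZ <- function(elements, positions, path, comment = "tersim geometry") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(elements)), comment), con)
  writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", elements,
                     positions[, 1L], positions[, 2L], positions[, 3L]), con)
  invisible(path)
}

setMethod("show", "NormalMode", function(object) {
  cat("NormalMode", object@index, ":", sprintf("%.1f cm^-1", object@frequency),
      if (nzchar(object@label)) paste0("(", object@label, ")") else "", "\n")
  cat("  atoms:", nrow(object@displacement), "\n")
})
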