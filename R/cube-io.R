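## Gaussian cube reader/writer.
##
## Cube files carry one scalar per voxel; complex fields are therefore
## stored as paired real cubes (suffix convention "_re"/"_im"). Unit
## convention: positive voxel counts mean the header lengths are in Bohr,
## negative counts mean Angstrom. Internally everything is Angstrom; the
## conversion happens only at this I/O boundary.

BOHR_TO_ANGSTROM <- 0.52917721092

#' Read a Gaussian cube file into a volumetric field
#'
#' Parses a standard Gaussian cube file (two comment lines, origin line,
#' three axis lines, atom block, Fortran-ordered data with z fastest) and
#' returns the grid in Angstrom regardless of the file's native unit.
#' The scalar data are assigned to the requested complex part of the
#' returned field; the other part is zero. The geometry block is preserved
#' in `fieldMeta(x)$atoms`.
#'
#' @param path path to a cube file.
#' @param part `"real"` or `"imaginary"`: which complex part the file holds.
#' @param component tensor-component label to attach, default `"zz"`.
#' @return a [VolumetricField-class].
#' @seealso [writeCube()]
#' @export
readCube <- function(path, part = c("real", "imaginary"), component = "zz") {
  part <- match.arg(part)
  lines <- readLines(path)
  if (length(lines) < 7L)
    stop("malformed cube header in '", path, "': fewer than 7 lines")
  numline <- function(i, nmin) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(x) < nmin || anyNA(x))
      stop("malformed cube header in '", path, "' at line ", i, ": '",
           lines[i], "'")
    x
  }
  l3 <- numline(3L, 4L)
  natoms <- as.integer(l3[1L])
  if (natoms < 0L)
    stop("unsupported cube layout in '", path,
         "': negative atom count signals a multi-orbital (DSET) cube")
  origin <- l3[2:4]
  ax <- lapply(4:6, numline, nmin = 4L)
  counts <- vapply(ax, function(a) as.integer(a[1L]), integer(1))
  if (any(counts == 0L))
    stop("malformed cube header in '", path, "' at lines 4-6: zero voxel count")
  ang <- all(counts < 0L)
  if (!ang && any(counts < 0L))
    stop("malformed cube header in '", path,
         "' at lines 4-6: mixed count sign (unit convention ambiguous)")
  counts <- abs(counts)
  step <- numeric(3)
  for (a in 1:3) {
    vec <- ax[[a]][2:4]
    if (any(vec[-a] != 0))
      stop("unsupported cube layout in '", path, "' at line ", a + 3L,
           ": axis not aligned with Cartesian ", c("x", "y", "z")[a])
    step[a] <- vec[a]
  }
  if (any(step <= 0))
    stop("malformed cube header in '", path, "' at lines 4-6: non-positive step")
  conv <- if (ang) 1 else BOHR_TO_ANGSTROM
  atoms <- NULL
  if (natoms > 0L) {
    rows <- t(vapply(seq_len(natoms) + 6L, numline, numeric(5), nmin = 5L))
    atoms <- data.frame(Z = as.integer(rows[, 1L]), charge = rows[, 2L],
                        x = rows[, 3L] * conv, y = rows[, 4L] * conv,
                        z = rows[, 5L] * conv)
  }
  dataLines <- lines[-seq_len(6L + natoms)]
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(dataLines[nzchar(trimws(dataLines))]), "\\s+"))))
  if (anyNA(vals) || length(vals) != prod(counts))
    stop("malformed cube data block in '", path, "': expected ",
         prod(counts), " values, got ", length(vals),
         if (anyNA(vals)) " (non-numeric tokens present)" else "")
  grid <- GridSpec(origin = origin * conv, step = step * conv, counts = counts)
  arr <- aperm(array(vals, dim = rev(counts)), c(3L, 2L, 1L))  # z fastest on disk
  values <- if (part == "real") complex(real = arr, imaginary = 0)
            else complex(real = 0, imaginary = arr)
  dim(values) <- counts
  VolumetricField(grid, values, component = component,
                  meta = list(atoms = atoms, source = path, part = part,
                              comments = lines[1:2]))
}

#' Write one complex part of a volumetric field as a Gaussian cube
#'
#' Writes in the Angstrom convention (negative voxel counts) so that
#' `readCube(writeCube(x))` round-trips the grid without unit conversion.
#' Data values are written with seven significant digits, so the round trip
#' preserves values to better than 1 part in 1e6 of each value. Any atom block in
#' `fieldMeta(field)$atoms` is written back into the header.
#'
#' @param field a [VolumetricField-class].
#' @param path output path.
#' @param part `"real"` or `"imaginary"`: which part to write.
#' @return `path`, invisibly.
#' @export
writeCube <- function(field, path, part = c("real", "imaginary")) {
  part <- match.arg(part)
  stopifnot(is(field, "VolumetricField"))
  g <- field@grid
  vals <- if (part == "real") Re(field@values) else Im(field@values)
  atoms <- field@meta$atoms
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("tersim volumetric field",
               paste("component", field@component, "part", part)), con)
  fmt <- function(n, v) sprintf("%5d %11.6f %11.6f %11.6f", n, v[1], v[2], v[3])
  writeLines(fmt(natoms, g@origin), con)
  writeLines(fmt(-g@counts[1], c(g@step[1], 0, 0)), con)
  writeLines(fmt(-g@counts[2], c(0, g@step[2], 0)), con)
  writeLines(fmt(-g@counts[3], c(0, 0, g@step[3])), con)
  if (natoms > 0L)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", atoms$Z,
                       atoms$charge, atoms$x, atoms$y, atoms$z), con)
  flat <- as.vector(aperm(vals, c(3L, 2L, 1L)))  # z fastest on disk
  full <- seq_len(length(flat) %/% 6L * 6L)
  rows <- apply(matrix(sprintf("% .6E", flat[full]), nrow = 6L), 2L,
                paste, collapse = " ")
  rest <- flat[setdiff(seq_along(flat), full)]
  if (length(rest))
    rows <- c(rows, paste(sprintf("% .6E", rest), collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

#' Read a complex field from a pair of real/imaginary cubes
#'
#' @param rePath cube holding the real part.
#' @param imPath cube holding the imaginary part, or `NULL` for a purely
#'   real field.
#' @param component tensor-component label.
#' @return a [VolumetricField-class] with both parts populated.
#' @export
readComplexCube <- function(rePath, imPath = NULL, component = "zz") {
  fre <- readCube(rePath, "real", component)
  if (is.null(imPath)) return(fre)
  fim <- readCube(imPath, "imaginary", component)
  if (!gridsCompatible(fre@grid, fim@grid))
    stop("real and imaginary cubes are on different grids")
  fre@values <- fre@values + fim@values
  fre@meta$imSource <- imPath
  fre
}
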