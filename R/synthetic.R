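## Synthetic Raman-density generator.
##
## Analytic stand-ins for quantum-chemical Raman polarizability densities:
## atom-localized Gaussian lobes multiplied by an odd factor that encodes
## the sign topology of the vibration (opposite signs across the molecular
## plane for out-of-plane modes, in-plane sign alternation for
## anti-symmetric modes). The mechanism under study depends only on that
## sign topology and localization, not on real electron structure, so the
## generator makes every downstream module testable without any
## quantum-chemistry software. No randomness is involved.

#' Construct a toy molecule
#'
#' @param positions n x 3 matrix of atom positions (Angstrom), normally in
#'   the z = 0 plane.
#' @param amplitudes complex(n) lobe amplitudes c_i; a single value is
#'   recycled.
#' @param disp numeric(n) signed displacements d_i; a single value is
#'   recycled.
#' @param tangents n x 3 in-plane displacement directions (in-plane modes
#'   only); default zero.
#' @param modeKind `"oop"` or `"inplane"`.
#' @param sigmaXY,sigmaZ lobe widths, Angstrom. The defaults (0.5, 0.4) are
#'   arbitrary but resolve on the default raster steps.
#' @param imagScale scale of the plane-asymmetric imaginary part
#'   (0 = purely real).
#' @param frequency nominal wavenumber, cm^-1.
#' @param label free text.
#' @return a [ToyMolecule-class].
#' @export
ToyMolecule <- function(positions, amplitudes = 1 + 0i, disp = 1,
                        tangents = NULL, modeKind = c("oop", "inplane"),
                        sigmaXY = 0.5, sigmaZ = 0.4, imagScale = 0,
                        frequency = 1000, label = "") {
  modeKind <- match.arg(modeKind)
  positions <- rbind(positions, deparse.level = 0)
  n <- nrow(positions)
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, n)
  if (length(disp) == 1L) disp <- rep(disp, n)
  if (is.null(tangents)) tangents <- matrix(0, n, 3L)
  new("ToyMolecule", positions = positions,
      amplitudes = as.complex(amplitudes), disp = as.numeric(disp),
      tangents = rbind(tangents, deparse.level = 0), modeKind = modeKind,
      sigmaXY = as.numeric(sigmaXY), sigmaZ = as.numeric(sigmaZ),
      imagScale = as.numeric(imagScale), frequency = as.numeric(frequency),
      label = as.character(label))
}

#' Build a ring molecule with a chosen vibrational sign pattern
#'
#' Places `nAtoms` atoms evenly on a circle of the given radius in the
#' z = 0 plane and assigns the displacement pattern of one of three mode
#' families:
#' \describe{
#'   \item{symmetric_oop}{all atoms bend out of plane in phase
#'     (d_i = +1 everywhere) — the symmetric out-of-plane bend.}
#'   \item{antisymmetric_oop}{d_i alternates +1 / -1 around the ring, so
#'     atoms across the ring (para pairs, for even n) vibrate in opposite
#'     directions — the anti-symmetric out-of-plane bend. Requires even n.}
#'   \item{inplane}{tangential in-plane displacement pattern.}
#' }
#'
#' @param nAtoms number of atoms (>= 2; even for `antisymmetric_oop`).
#' @param radius ring radius, Angstrom; default 2.5 (a benzene-like
#'   hydrogen ring).
#' @param mode one of `"symmetric_oop"`, `"antisymmetric_oop"`,
#'   `"inplane"`.
#' @param frequency nominal wavenumber attached to the mode, cm^-1. The
#'   default picks 664 for the symmetric and 835 for the anti-symmetric
#'   bend (the benzene out-of-plane pair), 1000 otherwise.
#' @param ... further arguments passed to [ToyMolecule()] (widths,
#'   `imagScale`, amplitudes).
#' @return a [ToyMolecule-class].
#' @examples
#' buildRing(6, mode = "antisymmetric_oop")  # d = (+1,-1,+1,-1,+1,-1)
#' @export
buildRing <- function(nAtoms, radius = 2.5,
                      mode = c("symmetric_oop", "antisymmetric_oop",
                               "inplane"),
                      frequency = NULL, ...) {
  mode <- match.arg(mode)
  if (nAtoms < 2L) stop("'nAtoms' must be at least 2")
  if (mode == "antisymmetric_oop" && nAtoms %% 2L != 0L)
    stop("the anti-symmetric out-of-plane pattern needs an even atom count")
  theta <- 2 * pi * (seq_len(nAtoms) - 1L) / nAtoms
  pos <- cbind(radius * cos(theta), radius * sin(theta), 0)
  if (is.null(frequency))
    frequency <- switch(mode, symmetric_oop = 664, antisymmetric_oop = 835,
                        inplane = 1000)
  disp <- switch(mode,
                 symmetric_oop = rep(1, nAtoms),
                 antisymmetric_oop = rep(c(1, -1), length.out = nAtoms),
                 inplane = rep(1, nAtoms))
  tang <- cbind(-sin(theta), cos(theta), 0)
  ToyMolecule(pos, disp = disp, tangents = tang,
              modeKind = if (mode == "inplane") "inplane" else "oop",
              frequency = frequency, label = mode, ...)
}

#' Evaluate the analytic Raman density of a toy molecule
#'
#' For an out-of-plane molecule the density is a sum of atom lobes, each a
#' lateral Gaussian times an odd factor in (z - z_i):
#' \deqn{\delta\rho(r) = \sum_i c_i d_i \frac{z - z_i}{\sigma_z}
#'   \exp\left(-\frac{(x-x_i)^2 + (y-y_i)^2}{2\sigma_{xy}^2}
#'             -\frac{(z-z_i)^2}{2\sigma_z^2}\right)}
#' so the density has opposite signs above and below the molecular plane by
#' construction, and its integral over a plane-symmetric box is zero. The
#' in-plane variant replaces the odd factor by the in-plane projection
#' `((r - r_i) . t_i) / sigma_xy` along each atom's displacement direction.
#'
#' With `imagScale > 0` an imaginary part is added: a `imagScale`-scaled
#' copy with the same in-plane sign pattern whose z-envelope is a Gaussian
#' centred one sigma_z *below* the plane — a plane-asymmetric distribution
#' concentrated underneath the molecule, as substrate mutual polarization
#' produces in the resonant regime.
#'
#' @param mol a [ToyMolecule-class].
#' @param points a 3-vector or n x 3 matrix (Angstrom).
#' @return complex vector of density values.
#' @export
analyticDensity <- function(mol, points) {
  points <- rbind(points, deparse.level = 0)
  out <- complex(nrow(points))
  sxy2 <- 2 * mol@sigmaXY^2; sz2 <- 2 * mol@sigmaZ^2
  for (i in seq_len(nrow(mol@positions))) {
    ci <- mol@amplitudes[i] * mol@disp[i]
    if (ci == 0) next
    dx <- points[, 1L] - mol@positions[i, 1L]
    dy <- points[, 2L] - mol@positions[i, 2L]
    dz <- points[, 3L] - mol@positions[i, 3L]
    env <- exp(-(dx^2 + dy^2) / sxy2 - dz^2 / sz2)
    odd <- if (mol@modeKind == "oop") dz / mol@sigmaZ
           else (dx * mol@tangents[i, 1L] + dy * mol@tangents[i, 2L] +
                 dz * mol@tangents[i, 3L]) / mol@sigmaXY
    out <- out + ci * odd * env
    if (mol@imagScale != 0) {
      below <- exp(-(dx^2 + dy^2) / sxy2 - (dz + mol@sigmaZ)^2 / sz2)
      out <- out + 1i * mol@imagScale * ci * below
    }
  }
  out
}

#' Rasterize a toy molecule's analytic density onto a grid
#'
#' Samples [analyticDensity()] at every voxel centre. When no grid is
#' given, one is built with [boundingGrid()]: 3 Angstrom margins beyond
#' the atoms, 0.4 Angstrom lateral and 0.1 Angstrom vertical steps — the
#' same box conventions the quantum-chemical densities use.
#'
#' @param mol a [ToyMolecule-class].
#' @param grid a [GridSpec-class], or `NULL` for the default box.
#' @return a [RamanDensity-class] (with `dQ = NA`, analytic).
#' @export
rasterizeDensity <- function(mol, grid = NULL) {
  if (is.null(grid)) grid <- boundingGrid(mol@positions)
  vals <- analyticDensity(mol, gridCoordinates(grid))
  dim(vals) <- gridDim(grid)
  mode <- NormalMode(1L, mol@frequency, toyDisplacement(mol),
                     label = mol@label)
  RamanDensity(VolumetricField(grid, vals, component = "zz",
                               meta = list(generator = "analytic",
                                           label = mol@label)),
               mode = mode)
}

## per-atom displacement vectors implied by the toy mode pattern
toyDisplacement <- function(mol) {
  if (mol@modeKind == "oop") cbind(0, 0, mol@disp)
  else mol@tangents * mol@disp
}

#' Write a +/- dQ displaced-density cube pair for a toy molecule
#'
#' Emits densities exactly linear in the normal coordinate,
#' `rho_+/-(r) = +/- dQ * delta rho(r)`, so that [centralDifference()] on
#' the pair must recover the analytic derivative exactly regardless of dQ.
#' Files follow the `<mode>_<plus|minus>_<re|im>.cube` naming convention
#' (`_im` files only for complex densities).
#'
#' @param mol a [ToyMolecule-class].
#' @param dQ displacement step (> 0); default 0.01.
#' @param dir output directory.
#' @param grid optional [GridSpec-class] (default box otherwise).
#' @param modeName stem for the file names; default `"mode1"`.
#' @return named list of the written paths (`plusRe`, `minusRe`, and
#'   `plusIm`, `minusIm` when complex), plus `dQ`.
#' @export
pairedDisplacementCubes <- function(mol, dQ = 0.01, dir = ".", grid = NULL,
                                    modeName = "mode1") {
  stopifnot(dQ > 0)
  rd <- rasterizeDensity(mol, grid)
  atoms <- data.frame(Z = 1L, charge = 1,
                      x = mol@positions[, 1L], y = mol@positions[, 2L],
                      z = mol@positions[, 3L])
  mk <- function(sign, part, suffix) {
    f <- VolumetricField(rd@grid, sign * dQ * rd@values,
                         component = rd@component,
                         meta = list(atoms = atoms,
                                     displacement = if (sign > 0) "plus"
                                                    else "minus"))
    p <- file.path(dir, paste0(modeName, "_",
                               if (sign > 0) "plus" else "minus",
                               "_", suffix, ".cube"))
    writeCube(f, p, part)
    p
  }
  out <- list(plusRe = mk(1, "real", "re"), minusRe = mk(-1, "real", "re"))
  if (any(Im(rd@values) != 0)) {
    out$plusIm <- mk(1, "imaginary", "im")
    out$minusIm <- mk(-1, "imaginary", "im")
  }
  out$dQ <- dQ
  out
}

#' Write a complete synthetic fixture bundle
#'
#' Emits everything the ingestion pipeline consumes: the displaced-density
#' cube pair(s), an XYZ geometry, and a mode table, for one or more toy
#' molecules (one vibrational mode each, sharing the same atoms and grid).
#'
#' @param mols a [ToyMolecule-class] or list of them (same atom positions).
#' @param dir output directory (created if missing).
#' @param dQ displacement step; default 0.01.
#' @param grid optional shared [GridSpec-class]; default: the bounding box
#'   of the first molecule.
#' @return list with `dir`, `xyz`, `modeTable`, and per-mode cube path
#'   lists.
#' @export
writeFixtureBundle <- function(mols, dir, dQ = 0.01, grid = NULL) {
  if (is(mols, "ToyMolecule")) mols <- list(mols)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(grid)) grid <- boundingGrid(mols[[1L]]@positions)
  pos <- mols[[1L]]@positions
  xyz <- file.path(dir, "geometry.xyz")
  writeXYZ(rep("H", nrow(pos)), pos, xyz)
  modes <- lapply(seq_along(mols), function(k)
    NormalMode(k, mols[[k]]@frequency, toyDisplacement(mols[[k]]),
               label = mols[[k]]@label))
  modeTable <- file.path(dir, "modes.txt")
  writeModeTable(modes, modeTable)
  cubes <- lapply(seq_along(mols), function(k)
    pairedDisplacementCubes(mols[[k]], dQ = dQ, dir = dir, grid = grid,
                            modeName = paste0("mode", k)))
  names(cubes) <- paste0("mode", seq_along(mols))
  list(dir = dir, xyz = xyz, modeTable = modeTable, cubes = cubes)
}

setMethod("show", "ToyMolecule", function(object) {
  cat("ToyMolecule:", nrow(object@positions), "atoms,",
      object@modeKind, "mode",
      if (nzchar(object@label)) paste0("(", object@label, ")") else "", "\n")
  cat("  sigma_xy", object@sigmaXY, "sigma_z", object@sigmaZ, "Angstrom;",
      "imagScale", object@imagScale, "\n")
})
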