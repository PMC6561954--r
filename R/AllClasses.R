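## S4 class definitions for the whole package.

#' @import methods
NULL

TENSOR_COMPONENTS <- c("xx", "xy", "xz", "yx", "yy", "yz", "zx", "zy", "zz")

#' Rectilinear volumetric grid specification
#'
#' A `GridSpec` describes an axis-aligned rectilinear grid of voxel centres:
#' an origin (the centre of the first voxel), a per-axis step and per-axis
#' voxel counts. All lengths are in Angstrom; axes are parallel to the
#' Cartesian x, y, z axes (non-orthogonal grids are unsupported).
#'
#' @slot origin numeric(3), position of the first voxel centre (Angstrom).
#' @slot step numeric(3), strictly positive per-axis spacings (Angstrom).
#' @slot counts integer(3), voxel counts per axis, each at least 2.
#'
#' @seealso [GridSpec()], [axisCoords()], [voxelVolume()]
#' @export
setClass("GridSpec",
  representation(origin = "numeric", step = "numeric", counts = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 3L || !all(is.finite(object@origin)))
      msg <- c(msg, "'origin' must be 3 finite numbers")
    if (length(object@step) != 3L || !all(is.finite(object@step)) ||
        any(object@step <= 0))
      msg <- c(msg, "'step' must be 3 strictly positive numbers")
    if (length(object@counts) != 3L || any(is.na(object@counts)) ||
        any(object@counts < 2L))
      msg <- c(msg, "'counts' must be 3 integers >= 2")
    if (length(msg)) msg else TRUE
  })

#' Complex scalar field on a rectilinear grid
#'
#' A `VolumetricField` holds one complex scalar value per voxel of a
#' [GridSpec-class] grid. It is the container for polarizability densities
#' rho^(alpha)(r) and Raman polarizability densities d rho^(alpha)/dQ_k.
#' The `component` slot labels the Cartesian tensor component the field
#' represents (the default pipeline only uses `"zz"`, the channel along the
#' tip axis). `meta` carries free-form provenance such as mode id and the
#' displacement sign of the geometry the density came from.
#'
#' @slot grid a [GridSpec-class].
#' @slot values complex 3-d array with `dim` equal to `counts(grid)`.
#' @slot component one of the nine Cartesian pair labels ("xx" ... "zz").
#' @slot meta named list of provenance.
#'
#' @seealso [VolumetricField()], [readCube()], [integrateField()]
#' @export
setClass("VolumetricField",
  representation(grid = "GridSpec", values = "array", component = "character",
                 meta = "list"),
  validity = function(object) {
    msg <- character()
    if (!is.complex(object@values))
      msg <- c(msg, "'values' must be a complex array")
    if (!identical(dim(object@values), gridDim(object@grid)))
      msg <- c(msg, "dim(values) must match the grid counts exactly")
    if (length(object@component) != 1L ||
        !(object@component %in% TENSOR_COMPONENTS))
      msg <- c(msg, "'component' must be one of the nine Cartesian pairs")
    if (length(msg)) msg else TRUE
  })

#' Confined plasmonic near-field distribution
#'
#' Parametrizes the scalar amplitude profile F(r - R) of the plasmon-confined
#' near field under the tip: a 3D Lorentzian (default) or Gaussian of unit
#' peak amplitude, with independent full widths at half maximum per Cartesian
#' axis and centre R. Along any single axis the profile falls to exactly 0.5
#' at an offset of half that axis' FWHM, for both shapes.
#'
#' @slot profile `"lorentzian3d"` or `"gaussian3d"`.
#' @slot fwhm numeric(3), per-axis FWHM (w_x, w_y, w_z) in Angstrom, all > 0.
#' @slot center numeric(3), field centre R in Angstrom.
#'
#' @seealso [NearField()], [evaluateNearField()], [nearFieldPreset()]
#' @export
setClass("NearField",
  representation(profile = "character", fwhm = "numeric", center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@profile) != 1L ||
        !(object@profile %in% c("lorentzian3d", "gaussian3d")))
      msg <- c(msg, "'profile' must be \"lorentzian3d\" or \"gaussian3d\"")
    if (length(object@fwhm) != 3L || !all(is.finite(object@fwhm)) ||
        any(object@fwhm <= 0))
      msg <- c(msg, "'fwhm' must be 3 strictly positive numbers")
    if (length(object@center) != 3L || !all(is.finite(object@center)))
      msg <- c(msg, "'center' must be 3 finite numbers")
    if (length(msg)) msg else TRUE
  })

#' Vibrational normal mode
#'
#' Holds the harmonic frequency (wavenumber), per-atom displacement pattern
#' and label of one molecular normal mode Q_k.
#'
#' @slot index integer mode index k.
#' @slot frequency wavenumber nu_k in cm^-1; must be > 0 for any mode that
#'   enters a cross section.
#' @slot displacement numeric matrix (n_atoms x 3) of dimensionless
#'   normal-coordinate direction vectors; must not be all zero.
#' @slot label free-text label.
#'
#' @seealso [NormalMode()], [readModeTable()]
#' @export
setClass("NormalMode",
  representation(index = "integer", frequency = "numeric",
                 displacement = "matrix", label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@frequency) != 1L || !is.finite(object@frequency))
      msg <- c(msg, "'frequency' must be a single finite number (cm^-1)")
    if (!is.numeric(object@displacement) || ncol(object@displacement) != 3L)
      msg <- c(msg, "'displacement' must be an n_atoms x 3 numeric matrix")
    else if (all(object@displacement == 0))
      msg <- c(msg, "'displacement' must not be identically zero")
    if (length(msg)) msg else TRUE
  })

#' Raman polarizability density of a normal mode
#'
#' The derivative d rho^(alpha)/dQ_k of the polarizability density along a
#' normal coordinate, stored as a [VolumetricField-class] (it inherits all
#' field behaviour) together with the mode it belongs to and the
#' displacement step dQ used in the finite difference. Its values may be
#' complex in the resonant regime.
#'
#' @slot mode the [NormalMode-class] the density belongs to.
#' @slot dQ displacement step used by the central difference (normal-mode
#'   coordinate units); `NA_real_` for analytic densities.
#'
#' @seealso [centralDifference()], [localPolarizability()], [farField()]
#' @export
setClass("RamanDensity", contains = "VolumetricField",
  representation(mode = "NormalMode", dQ = "numeric"),
  validity = function(object) {
    if (any(!is.finite(Re(object@values))) || any(!is.finite(Im(object@values))))
      return("Raman density values must be finite everywhere")
    TRUE
  })

#' Tip-scan plan
#'
#' Defines the raster of tip positions for TERS imaging: x and y ranges with
#' a common step, a fixed tip height z (the near-field centre height above
#' the molecular plane), and a field template whose centre is replaced at
#' each scan position.
#'
#' @slot xrange,yrange numeric(2) scan windows (Angstrom).
#' @slot step scan step (Angstrom), default 0.2.
#' @slot height field-centre height z (Angstrom above the molecular plane).
#' @slot field a [NearField-class] used as template (its centre is ignored).
#'
#' @seealso [ScanPlan()], [scanImage()]
#' @export
setClass("ScanPlan",
  representation(xrange = "numeric", yrange = "numeric", step = "numeric",
                 height = "numeric", field = "NearField"),
  validity = function(object) {
    msg <- character()
    if (length(object@xrange) != 2L || diff(object@xrange) < 0)
      msg <- c(msg, "'xrange' must be numeric(2) with xrange[2] >= xrange[1]")
    if (length(object@yrange) != 2L || diff(object@yrange) < 0)
      msg <- c(msg, "'yrange' must be numeric(2) with yrange[2] >= yrange[1]")
    if (length(object@step) != 1L || !is.finite(object@step) ||
        object@step <= 0)
      msg <- c(msg, "'step' must be a single positive number")
    if (length(object@height) != 1L || !is.finite(object@height))
      msg <- c(msg, "'height' must be a single finite number")
    if (length(msg)) msg else TRUE
  })

#' TERS image
#'
#' A 2D map of TERS intensities |alpha'_k(R)|^2 over tip positions at fixed
#' height, with provenance (mode ids, field parameters, height, band).
#'
#' @slot intensities non-negative real matrix, `length(x)` rows by
#'   `length(y)` columns.
#' @slot x,y tip-position coordinates (Angstrom).
#' @slot provenance named list (modes, frequencies, field, height, band).
#'
#' @seealso [scanImage()], [combineBand()], [writeTERSImage()]
#' @export
setClass("TERSImage",
  representation(intensities = "matrix", x = "numeric", y = "numeric",
                 provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@intensities))
      msg <- c(msg, "'intensities' must be a numeric matrix")
    else {
      if (nrow(object@intensities) != length(object@x) ||
          ncol(object@intensities) != length(object@y))
        msg <- c(msg, "dim(intensities) must be length(x) x length(y)")
      if (any(object@intensities < 0))
        msg <- c(msg, "intensities must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Analytic toy molecule for synthetic Raman densities
#'
#' A planar arrangement of atom-localized Gaussian lobes with signed
#' displacement amplitudes, used to generate analytic Raman polarizability
#' densities with the sign topology characteristic of out-of-plane and
#' in-plane vibrations: odd in (z - z_i) across the molecular plane for
#' out-of-plane modes, odd along the in-plane displacement direction for
#' in-plane modes.
#'
#' @slot positions numeric matrix (n x 3) of atom positions, Angstrom,
#'   conventionally in the z = 0 plane.
#' @slot amplitudes complex(n) lobe amplitudes c_i.
#' @slot disp numeric(n) signed mode displacements d_i.
#' @slot tangents numeric matrix (n x 3) of in-plane displacement unit
#'   directions (used only by in-plane modes).
#' @slot modeKind `"oop"` (out-of-plane) or `"inplane"`.
#' @slot sigmaXY,sigmaZ lobe widths (Angstrom), > 0.
#' @slot imagScale scale of the plane-asymmetric imaginary part (0 = purely
#'   real density).
#' @slot frequency nominal mode wavenumber, cm^-1.
#' @slot label free text.
#'
#' @seealso [buildRing()], [analyticDensity()], [rasterizeDensity()]
#' @export
setClass("ToyMolecule",
  representation(positions = "matrix", amplitudes = "complex",
                 disp = "numeric", tangents = "matrix", modeKind = "character",
                 sigmaXY = "numeric", sigmaZ = "numeric", imagScale = "numeric",
                 frequency = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@positions)
    if (ncol(object@positions) != 3L)
      msg <- c(msg, "'positions' must be an n x 3 matrix")
    if (length(object@amplitudes) != n || length(object@disp) != n)
      msg <- c(msg, "'amplitudes' and 'disp' must have one entry per atom")
    if (all(Mod(object@amplitudes) * abs(object@disp) == 0))
      msg <- c(msg, "at least one atom must have non-zero amplitude")
    if (object@sigmaXY <= 0 || object@sigmaZ <= 0)
      msg <- c(msg, "lobe widths must be > 0")
    if (!(object@modeKind %in% c("oop", "inplane")))
      msg <- c(msg, "'modeKind' must be \"oop\" or \"inplane\"")
    if (length(msg)) msg else TRUE
  })
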