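---
title: "Simulating TERS images by local integration of Raman polarizability densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TERS images by local integration of Raman polarizability densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tersim)
```

## The model

Tip-enhanced Raman spectroscopy (TERS) records Raman scattering of a single
molecule sitting in the sub-nanometre gap under a sharp plasmonic tip. The
tip confines the optical near field to a volume of a few Ångström, and as
the tip is rastered over the molecule the Raman intensity of each
vibrational mode varies — the 2D map of those intensities is the TERS image
of the mode.

`tersim` implements the local-integration picture of this experiment. The
molecular polarizability is the spatial integral of a *polarizability
density* $\rho^{(\alpha)}(\mathbf r)$. Differentiating along a normal
coordinate $Q_k$ gives the *Raman polarizability density*

$$\delta\rho^{(\alpha)}(\mathbf r) \;=\;
  \frac{\partial \rho^{(\alpha)}(\mathbf r)}{\partial Q_k},$$

a genuinely local, mode-specific field: its sign structure follows the
atomic displacement pattern of the vibration. Under the tip, both the
incident and the scattered field are modulated by the confined near-field
amplitude $F(\mathbf r - \mathbf R)$ centred at the tip position
$\mathbf R$, so the effective density is weighted by $F$ twice:

$$\delta\rho_{\mathrm{loc}}(\mathbf r, \mathbf R)
  = F(\mathbf r - \mathbf R)\,\delta\rho^{(\alpha)}(\mathbf r)\,
    F(\mathbf r - \mathbf R),$$

and the near-field Raman polarizability and TERS intensity at that tip
position are

$$\alpha'_k(\mathbf R) = \int \delta\rho_{\mathrm{loc}}
  (\mathbf r, \mathbf R)\, d\mathbf r,
  \qquad I_k(\mathbf R) \propto \bigl|\alpha'_k(\mathbf R)\bigr|^2.$$

The squared modulus covers the resonant regime, where the density — and
hence $\alpha'_k$ — is complex. With a uniform field ($F \equiv 1$) the
integral reduces to the conventional far-field Raman response, which obeys
the ordinary selection rules: modes whose density integrates to zero are
silent. A confined field breaks that cancellation locally, which is both
the origin of the modified selection rules in plasmon-enhanced Raman and of
the image contrast: hotspots are tip positions where the field selects
density of predominantly one sign.

Two assumptions define the scope of the model. First, the density is a
*free-molecule* property: the tip enters only through the scalar weighting
$F$, never through a self-consistent molecule–tip response. This is what
makes a scan cheap — one density, many field positions — at the price of
neglecting non-local response. Second, only the $zz$ tensor channel (along
the tip axis) is computed by default; the API carries component labels so
other channels are additive work, not a redesign.

## Data model and numerics

All fields live on axis-aligned rectilinear voxel grids (`GridSpec`,
lengths in Å) as complex arrays (`VolumetricField`). Spatial integration is
the midpoint Riemann sum — the sum of voxel values times the voxel volume.
This choice mirrors the grid-summation character of the local integration,
is exactly linear in the values, and commutes with voxelwise field
weighting; higher-order quadrature appears in the test suite only as a
refinement oracle. Grids must match exactly (to $10^{-8}$ Å) wherever two
fields are combined; nothing is ever silently resampled, because
interpolation corrupts finite-differenced densities.

Densities arrive as Gaussian cube files, one real scalar per voxel, one
file per tensor component per displaced geometry; complex densities use
paired `_re`/`_im` cubes, since the cube format has no complex dialect. The
cube unit convention (positive voxel counts = Bohr, negative = Å) is
resolved at the I/O boundary — internally everything is Å. Cubes with
negative atom counts (multi-orbital layout) and non-axis-aligned grids are
rejected with explicit errors.

The Raman density is built by the central (three-point) difference
$(\rho_+ - \rho_-)/(2\Delta Q)$ of densities at $\pm\Delta Q$ displaced
geometries; for a first derivative the midpoint term of the three-point
stencil cancels. The default $\Delta Q = 0.01$ (normal-coordinate units) is
a config knob: on densities linear in $Q$ the result is exactly
step-independent, and the displacement normalization convention is owned by
whatever produced the upstream densities. Display normalization (unit
maximum, for isosurface plots at a common isovalue such as 0.2) is
quarantined from the physics path — intensities never depend on per-mode
rescaling.

## The near field

The near field is a scalar amplitude profile of unit peak, with independent
full widths at half maximum per axis:

* `lorentzian3d` (default): $F(\Delta) = 1 / \bigl(1 + \sum_a
  (2\Delta_a/w_a)^2\bigr)$
* `gaussian3d`: $F(\Delta) = \exp\bigl(-4\ln 2 \sum_a
  (\Delta_a/w_a)^2\bigr)$

Both equal $1/2$ at an offset of $w_a/2$ along any single axis — that is
the FWHM semantics — and the Lorentzian has the heavier tails, which better
captures the residual substrate field away from the tip apex. A 3D
"Lorentzian" is not unique (the radial-additive form above vs. a per-axis
product); we chose the additive-quadratic form as the minimal 3D
generalization with the required per-axis FWHM and tail behaviour, expose
the Gaussian alongside it, and test that the imaging pattern is insensitive
to the profile shape rather than guessing further structure. The amplitude
is pinned to 1 (unit external field): absolute enhancement is a constant
prefactor that cancels in image contrast.

Tip "height" is measured from the molecular plane ($z = 0$, the mean plane
of the heavy atoms) to the field centre. Four presets bundle the field
parameters used for the reference systems: benzene (FWHM 1.3 Å, height
1.0 Å), porphyrin (2 Å, 1.5 Å), H2TBPP (12, 12, 6 Å, height 2.7 Å — a
junction field squeezed along $z$), and porphycene (5 Å, 2 Å).

## Scanning, spectra, bands

A `ScanPlan` fixes the x/y window, the step (default 0.2 Å) and the tip
height; `scanImage()` evaluates $|\alpha'_k|^2$ at every pixel by reusing
the one tip-independent density against many field samplings. Pixels are
independent; there is no interpolation. The integration domain is always
the full grid — the decay of $F^2$ performs the localization, so no hard
cutoff sphere is imposed.

`crossSection()` turns $\alpha'_k$ (Å$^3$ at the API boundary, converted to
SI via $4\pi\epsilon_0 \cdot 10^{-30}$) into the Stokes differential cross
section

$$\frac{d\sigma}{d\Omega} = \frac{\pi^2}{\epsilon_0^2}
 (\tilde\nu_{in} - \tilde\nu_k)^4 \frac{h}{8\pi^2 c \tilde\nu_k}
 \frac{|\alpha'_k|^2}{1 - \exp(-hc\tilde\nu_k/k_B T)}$$

with CODATA constants and default $T = 298$ K. The normal coordinate is
treated as dimensionless; absolute magnitudes therefore carry the
$Q$-normalization convention of the upstream densities, while the
$(\tilde\nu_{in}-\tilde\nu_k)^4$ and Boltzmann factors are
convention-free and are what the tests pin down. `tipSpectrum()` broadens
the per-mode cross sections with area-normalized Lorentzian lines (default
FWHM 10 cm$^{-1}$ — a display parameter, not physics; 0 gives sticks).

Near-degenerate modes that a spectrometer integrates together are combined
with `combineBand()`: a pixelwise *sum of intensities* of all modes within
$\pm w/2$ of the band centre (default width 20 cm$^{-1}$, symmetric
window). The combination is incoherent because distinct modes scatter at
distinct vibrational frequencies; this is how four-fold-symmetric images
arise from degenerate side-group modes even though each individual mode's
image is asymmetric.

## The synthetic generator

Real Raman polarizability densities come from TDDFT-level response
calculations that this package deliberately does not perform. To make every
module testable without them, `buildRing()`/`rasterizeDensity()` generate
analytic stand-ins with the structural features that drive the mechanism:

* atom-localized lobes — a lateral Gaussian of width $\sigma_{xy}$ per
  atom;
* opposite signs across the molecular plane for out-of-plane modes — an
  odd factor $(z - z_i)/\sigma_z$;
* in-plane sign alternation for anti-symmetric modes — signed
  displacements $d_i$ alternating around the ring ($+1,-1,\dots$), so
  para atoms vibrate in opposite directions; the symmetric variant uses
  $d_i = +1$ everywhere.

Default widths are $\sigma_{xy} = 0.5$ Å, $\sigma_z = 0.4$ Å (arbitrary,
chosen to resolve on the default raster), ring radius 2.5 Å with 6 atoms (a
benzene-scale hydrogen ring), and the out-of-plane pair carries the nominal
wavenumbers 664 (symmetric) and 835 cm$^{-1}$ (anti-symmetric). Default
grids follow the conventions of the reference densities: box margins 3 Å
beyond the atoms, steps 0.4 Å laterally and 0.1 Å vertically. Resonant
fixtures add an imaginary part: a scaled (default $0.2\times$) copy with
the same in-plane sign pattern whose $z$-envelope is centred one
$\sigma_z$ *below* the plane — plane-asymmetric and concentrated
underneath the molecule, the qualitative signature of substrate-dominated
mutual polarization. The generator is fully deterministic.

By construction both out-of-plane fixtures are exactly far-field silent
(odd in $z$), yet a confined field activates them — the selection-rule
behaviour the model exists to describe. What passing tests on these
fixtures do *not* show: quantitative agreement with any real molecule's
density, non-local response effects, or multipolar (field-gradient beyond
$F^2$) corrections.

## Numerical choices and edge cases

* Linear scan cost: each pixel is one vectorized contraction over the
  grid; a 41 × 41 scan over a ~50k-voxel density takes on the order of a
  second.
* Fully cancelled pixels (symmetry-zero intensities) are numerically
  $\sim 10^{-16}$ of the image maximum; comparisons of images are made
  relative to the image maximum for this reason.
* Degenerate inputs: all-zero fields cannot be display-normalized (error);
  empty band windows warn and return a zero image; a scan window wholly
  outside the density grid warns and returns a near-zero image; grid
  mismatches, non-positive $\Delta Q$, non-Stokes wavenumber orderings and
  non-positive temperatures are hard errors.
* Ties in hotspot location are broken by the first maximum in column-major
  order (only relevant to diagnostics, never to computed intensities).

The test-suite problem sizes (grids up to $\sim 10^5$ voxels, brute-force
oracle grids of $17^3$, scans up to $81 \times 81$) were chosen so the
whole suite completes in well under a minute while still exercising every
code path at meaningful resolution.

## Worked example

```{r example}
## anti-symmetric out-of-plane ring: far-field silent...
rd <- rasterizeDensity(buildRing(6, 2.5, "antisymmetric_oop"))
Mod(farField(rd)) / (sum(Mod(fieldValues(rd))) * voxelVolume(fieldGrid(rd)))

## ...but active under the atomically confined preset, with a dark centre
p <- nearFieldPreset("benzene")
img <- scanImage(rd, ScanPlan(c(-4, 4), c(-4, 4), step = 0.2,
                              height = p$height, field = p$field))
max(imageIntensities(img))
co <- imageCoords(img)
imageIntensities(img)[which.min(abs(co$x)), which.min(abs(co$y))] /
  max(imageIntensities(img))
```

## Known limitations

The local approximation ignores the non-local part of the molecular
response, so fields must be chosen somewhat narrower than in fully
self-consistent simulations to reach comparable resolution. Only the $zz$
channel is produced by the default pipeline. Grids must be Cartesian
axis-aligned — densities from relaxed adsorption geometries must be
generated on such grids upstream. The synthetic densities are structural
caricatures; conclusions about real molecules require real response
densities fed through the same pipeline.
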