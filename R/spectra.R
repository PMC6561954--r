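## Differential Raman cross sections, band combination of near-degenerate
## modes, and per-tip-position spectra.

## CODATA 2018 constants (SI)
PLANCK_H  <- 6.62607015e-34    # J s
LIGHT_C   <- 2.99792458e8      # m s^-1
BOLTZ_KB  <- 1.380649e-23      # J K^-1
EPSILON_0 <- 8.8541878128e-12  # F m^-1

#' Differential Raman scattering cross section
#'
#' Computes the Stokes differential cross section of one vibrational mode
#' from its (near-field) Raman polarizability:
#' \deqn{\frac{d\sigma}{d\Omega} = \frac{\pi^2}{\epsilon_0^2}
#'   (\tilde\nu_{in} - \tilde\nu_k)^4 \frac{h}{8 \pi^2 c\, \tilde\nu_k}
#'   \frac{|\alpha'_k|^2}{1 - \exp(-h c \tilde\nu_k / k_B T)}}
#' All quantities are converted to SI internally: wavenumbers from cm^-1 to
#' m^-1 and the polarizability from the Angstrom^3 volume convention to
#' C m^2 V^-1 via `4 pi epsilon_0 1e-30`. The Boltzmann denominator is the
#' thermal vibrational population factor; it increases the cross section
#' monotonically with temperature.
#'
#' @param alphaPrime complex near-field Raman polarizability alpha'_k,
#'   Angstrom^3.
#' @param nuIn incident wavenumber, cm^-1; must exceed `nuK`.
#' @param nuK mode wavenumber, cm^-1, > 0.
#' @param temperature temperature, K (> 0); default 298.
#' @return non-negative real, m^2 sr^-1.
#' @examples
#' crossSection(1 + 0i, nuIn = 18797, nuK = 664)  # 532 nm excitation
#' @export
crossSection <- function(alphaPrime, nuIn, nuK, temperature = 298) {
  if (any(temperature <= 0)) stop("'temperature' must be > 0 K")
  if (any(nuK <= 0)) stop("'nuK' must be > 0 cm^-1")
  if (any(nuK >= nuIn))
    stop("'nuK' must be below 'nuIn': the Stokes-shifted line ",
         "(nuIn - nuK) must stay at positive wavenumber")
  nuInM <- nuIn * 100; nuKM <- nuK * 100            # cm^-1 -> m^-1
  alphaSI <- alphaPrime * 4 * pi * EPSILON_0 * 1e-30 # A^3 -> C m^2 V^-1
  boltz <- 1 - exp(-PLANCK_H * LIGHT_C * nuKM / (BOLTZ_KB * temperature))
  (pi^2 / EPSILON_0^2) * (nuInM - nuKM)^4 *
    PLANCK_H / (8 * pi^2 * LIGHT_C * nuKM) * Mod(alphaSI)^2 / boltz
}

#' Raman records for a set of modes at one tip position
#'
#' Convenience wrapper: locally integrates each density at the given field
#' and tabulates alpha'_k and the differential cross section.
#'
#' @param densities list of [RamanDensity-class] objects.
#' @param nf a [NearField-class] (the fixed tip).
#' @param nuIn incident wavenumber, cm^-1.
#' @param temperature temperature, K; default 298.
#' @return data.frame with columns `mode`, `frequency`, `alphaRe`,
#'   `alphaIm`, `crossSection`, `nuIn`, `temperature`.
#' @export
ramanRecords <- function(densities, nf, nuIn, temperature = 298) {
  rows <- lapply(densities, function(rd) {
    a <- localPolarizability(rd, nf)
    data.frame(mode = rd@mode@index, frequency = rd@mode@frequency,
               alphaRe = Re(a), alphaIm = Im(a),
               crossSection = crossSection(a, nuIn, rd@mode@frequency,
                                           temperature),
               nuIn = nuIn, temperature = temperature)
  })
  do.call(rbind, rows)
}

#' Combine TERS images of near-degenerate modes into one band image
#'
#' Pixelwise sum of the intensity maps of all modes whose frequency lies
#' within `width / 2` of the band centre — incoherent combination, because
#' distinct normal modes scatter at distinct vibrational frequencies. This
#' is what a finite spectrometer integration window records, and it is how
#' the four-fold patterns of large molecules arise from degenerate
#' side-group modes.
#'
#' @param images list of [TERSImage-class] objects on identical scan
#'   geometry.
#' @param frequencies mode wavenumbers (cm^-1), one per image; when
#'   missing, taken from each image's provenance.
#' @param center band centre, cm^-1.
#' @param width full band width, cm^-1; default 20.
#' @return a [TERSImage-class]; if no mode falls in the band, a zero image
#'   with a warning.
#' @export
combineBand <- function(images, frequencies = NULL, center, width = 20) {
  stopifnot(width > 0, length(images) >= 1L)
  if (is.null(frequencies))
    frequencies <- vapply(images, function(im)
      as.numeric(im@provenance$frequencies[1L]), numeric(1))
  if (length(frequencies) != length(images))
    stop("'frequencies' must have one entry per image")
  ref <- images[[1L]]
  for (im in images)
    if (!identical(dim(im@intensities), dim(ref@intensities)) ||
        max(abs(im@x - ref@x)) > 1e-8 || max(abs(im@y - ref@y)) > 1e-8)
      stop("images must share one scan geometry to be band-combined")
  inBand <- abs(frequencies - center) <= width / 2
  total <- matrix(0, nrow(ref@intensities), ncol(ref@intensities))
  if (!any(inBand))
    warning("no mode falls inside the band [",
            center - width / 2, ", ", center + width / 2, "] cm^-1")
  for (k in which(inBand)) total <- total + images[[k]]@intensities
  new("TERSImage", intensities = total, x = ref@x, y = ref@y,
      provenance = list(modes = unlist(lapply(images[inBand], function(im)
                          im@provenance$modes)),
                        frequencies = frequencies[inBand],
                        band = c(center = center, width = width),
                        fwhm = ref@provenance$fwhm,
                        height = ref@provenance$height))
}

#' Broadened Raman spectrum at a fixed tip position
#'
#' Sums area-normalized Lorentzian lines centred at each mode frequency,
#' each with integrated area equal to the mode's cross section. With
#' `broadeningFwhm = 0` a stick spectrum (one row per mode) is returned.
#' The line width is a display parameter, not a physical prediction.
#'
#' @param records data.frame from [ramanRecords()] (columns `frequency`,
#'   `crossSection`).
#' @param broadeningFwhm Lorentzian FWHM in cm^-1; default 10.
#' @param wavenumbers sampling grid, cm^-1; default covers all modes with a
#'   5-FWHM margin at 0.5 cm^-1 resolution.
#' @return data.frame with columns `wavenumber` (cm^-1) and `intensity`
#'   (m^2 sr^-1 per cm^-1 for broadened output; m^2 sr^-1 for sticks), with
#'   attribute `"broadeningFwhm"`.
#' @export
tipSpectrum <- function(records, broadeningFwhm = 10, wavenumbers = NULL) {
  stopifnot(nrow(records) >= 1L)
  if (broadeningFwhm == 0) {
    out <- data.frame(wavenumber = records$frequency,
                      intensity = records$crossSection)
    attr(out, "broadeningFwhm") <- 0
    return(out)
  }
  if (is.null(wavenumbers)) {
    lo <- max(0, min(records$frequency) - 5 * broadeningFwhm)
    hi <- max(records$frequency) + 5 * broadeningFwhm
    wavenumbers <- seq(lo, hi, by = 0.5)
  }
  gamma <- broadeningFwhm / 2
  intensity <- rep(0, length(wavenumbers))
  for (k in seq_len(nrow(records)))
    intensity <- intensity + records$crossSection[k] * (gamma / pi) /
      ((wavenumbers - records$frequency[k])^2 + gamma^2)
  out <- data.frame(wavenumber = wavenumbers, intensity = intensity)
  attr(out, "broadeningFwhm") <- broadeningFwhm
  out
}

#' Write a spectrum as two-column delimited text with a JSON sidecar
#'
#' @param spectrum data.frame from [tipSpectrum()].
#' @param path output path.
#' @param meta extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path, meta = list()) {
  utils::write.table(spectrum, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    c(list(columns = names(spectrum),
           broadeningFwhm = attr(spectrum, "broadeningFwhm")), meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
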