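#' Optical configuration for 4Pi detection
#'
#' Collects the optical constants that define the four-channel interferometric
#' point spread function (PSF) and the simulator's scalar model of it. The
#' four detection channels (p1, s1, p2, s2) correspond to relative
#' interference phases of 0, 90, 180 and 270 degrees, so a fluorophore that
#' interferes constructively in p1 is destructive in p2.
#'
#' The scalar PSF model used by the simulator is
#' \deqn{I_c(x,y,z) \propto w_c \, G(x,y;\sigma(z)) \,
#'   [1 + m\, e^{-z^2/2\sigma_{env}^2} \cos(k_z z + \delta_c - \varphi)]}
#' with \eqn{k_z = 2\pi/p} and fringe period \eqn{p = \lambda_0/(2 n_s)},
#' a unit-integral lateral Gaussian whose width grows with defocus,
#' \eqn{\sigma(z) = \sqrt{\sigma_0^2 + (\rho z)^2}}, and a Gaussian coherence
#' envelope on the modulation contrast. The model conserves detected flux
#' along z (both objectives collect the light; defocus only spreads it),
#' while fringe contrast decays away from focus.
#'
#' @param wavelength_vacuum fluorescence vacuum wavelength \eqn{\lambda_0}, nm
#' @param n_sample refractive index of the sample medium
#' @param n_immersion refractive index of the immersion oil
#' @param pixel_size_lateral back-projected camera pixel size, nm/pixel
#' @param channel_phase_offsets the four channel phase delays
#'   \eqn{\delta_c}, radians
#' @param envelope_axial_sigma Gaussian sigma of the interference-contrast
#'   envelope along z, nm
#' @param envelope_lateral_sigma0 in-focus lateral Gaussian sigma, nm
#' @param defocus_spread_rate lateral sigma growth per nm of defocus
#'   (dimensionless)
#' @param focus_offset axial offset between the lateral defocus minimum
#'   and the center of the interference envelope, nm. Real 4Pi PSFs are not
#'   mirror-symmetric in z: the cavity's coherence envelope and the
#'   objectives' common focus do not coincide exactly, which gives the PSF
#'   the asymmetric components that reduce its self-similarity between z
#'   planes (and thereby let the fit discriminate mirror-image and
#'   adjacent-fringe candidates). A perfectly z-symmetric PSF
#'   (`focus_offset = 0`) is a degenerate special case.
#' @param modulation_depth fringe modulation depth at focus, in (0, 1]
#' @param sp_amplitude_ratio amplitude scale of the s-polarized channels
#'   relative to the p channels (1 for single-color detection; ~0.6 for
#'   Alexa Fluor 647 and ~0.9 for Cy5.5 with the multicolor filters in place)
#' @param phase interference phase offset \eqn{\varphi} of the generated PSF,
#'   radians; positive values move the fringes towards +z
#' @return an object of class `fourpi_config`
#' @export
fourpi_config <- function(wavelength_vacuum = 680,
                          n_sample = 1.346,
                          n_immersion = 1.406,
                          pixel_size_lateral = 138.2,
                          channel_phase_offsets = c(0, pi / 2, pi, 3 * pi / 2),
                          envelope_axial_sigma = 500,
                          envelope_lateral_sigma0 = 110,
                          defocus_spread_rate = 0.25,
                          focus_offset = 100,
                          modulation_depth = 0.9,
                          sp_amplitude_ratio = 1,
                          phase = 0) {
  stopifnot(wavelength_vacuum > 0, n_sample > 0, n_immersion > 0,
            pixel_size_lateral > 0, envelope_axial_sigma > 0,
            envelope_lateral_sigma0 > 0, defocus_spread_rate >= 0,
            length(channel_phase_offsets) == 4)
  if (!(modulation_depth > 0 && modulation_depth <= 1))
    stop("modulation_depth must lie in (0, 1]")
  if (!(sp_amplitude_ratio > 0 && sp_amplitude_ratio <= 1))
    stop("sp_amplitude_ratio must lie in (0, 1]")
  structure(list(
    wavelength_vacuum = wavelength_vacuum,
    n_sample = n_sample,
    n_immersion = n_immersion,
    pixel_size_lateral = pixel_size_lateral,
    channel_phase_offsets = channel_phase_offsets,
    envelope_axial_sigma = envelope_axial_sigma,
    envelope_lateral_sigma0 = envelope_lateral_sigma0,
    defocus_spread_rate = defocus_spread_rate,
    focus_offset = focus_offset,
    modulation_depth = modulation_depth,
    sp_amplitude_ratio = sp_amplitude_ratio,
    phase = phase
  ), class = "fourpi_config")
}

#' @export
print.fourpi_config <- function(x, ...) {
  cat("4Pi optical configuration\n")
  cat(sprintf("  lambda0 %g nm | n_sample %g | n_immersion %g\n",
              x$wavelength_vacuum, x$n_sample, x$n_immersion))
  cat(sprintf("  pixel %g nm | fringe period %.1f nm\n",
              x$pixel_size_lateral, fringe_period(x)))
  cat(sprintf("  modulation depth %g | s/p ratio %g | phase %.3f rad\n",
              x$modulation_depth, x$sp_amplitude_ratio, x$phase))
  invisible(x)
}

#' Axial interference fringe period
#'
#' The period of the axial modulation of the 4Pi PSF,
#' \eqn{p = \lambda_0 / (2 n_{sample})}, approximately \eqn{\lambda/2}.
#'
#' @param cfg a [fourpi_config()]
#' @return fringe period in nm
#' @export
fringe_period <- function(cfg) {
  cfg$wavelength_vacuum / (2 * cfg$n_sample)
}

#' Back-projected camera pixel size
#'
#' Physical camera pixel pitch divided by the total magnification of the
#' imaging system, giving the sample-plane extent of one pixel.
#'
#' @param camera_pixel_um camera (possibly binned) pixel pitch in micrometers
#' @param magnification total system magnification
#' @return pixel size at the sample, nm
#' @examples
#' pixel_size_on_sample(32, 231.48) # ~138.2 nm
#' @export
pixel_size_on_sample <- function(camera_pixel_um = 32,
                                 magnification = 231.48) {
  stopifnot(camera_pixel_um > 0, magnification > 0)
  camera_pixel_um * 1000 / magnification
}

#' Wavelength and refractive-index constants for z rescaling
#'
#' Constants entering the linear z-coordinate corrections: the calibration
#' bead and dye emission wavelengths, and the sample and immersion refractive
#' indices whose mismatch matters because the PSF is calibrated by scanning a
#' bead with the piezo stage rather than moving an emitter inside the sample
#' medium.
#'
#' @param lambda_bead mean detected wavelength of the calibration bead, nm
#' @param lambda_dyes named vector of mean detected dye wavelengths, nm
#' @param n_sample,n_immersion refractive indices
#' @return an object of class `index_wavelength_config`
#' @export
index_wavelength_config <- function(lambda_bead = 712,
                                    lambda_dyes = c(AF647 = 680, Cy5.5 = 699),
                                    n_sample = 1.346,
                                    n_immersion = 1.406) {
  stopifnot(lambda_bead > 0, all(lambda_dyes > 0), n_sample > 0,
            n_immersion > 0, !is.null(names(lambda_dyes)))
  structure(list(lambda_bead = lambda_bead, lambda_dyes = lambda_dyes,
                 n_sample = n_sample, n_immersion = n_immersion),
            class = "index_wavelength_config")
}
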