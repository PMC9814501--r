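# Laser pulses and the pump-probe instrument response.
#
# Durations are quoted, as in the experimental literature, as the FWHM of
# the *intensity* envelope. field_at() evaluates the field (amplitude)
# envelope; for both supported shapes the amplitude envelope equals 1/sqrt(2)
# at +/- fwhm/2, so gaussian and cos^2 pulses of equal FWHM agree exactly at
# the peak and at the intensity half-maximum points.

#' Describe a laser pulse
#'
#' @param central_photon_energy Photon energy in eV (1.77 eV for the
#'   near-infrared probe; an XUV pump is typically 15-35 eV broadband, here
#'   represented by its central energy).
#' @param fwhm_duration Intensity-envelope FWHM in fs. Must be positive
#'   (use a very small value for a quasi-delta attosecond pump).
#' @param peak_intensity Peak intensity in W/cm^2.
#' @param carrier_envelope_phase Carrier-envelope phase in radians.
#' @param envelope `"cos2"` (default; compact support `center_time +/-
#'   fwhm_duration`) or `"gaussian"`.
#' @param polarization Unit 3-vector; normalised on input, rejected if zero.
#' @param center_time Envelope peak time in fs.
#'
#' @return An object of class `laser_pulse` (a named list).
#' @export
#' @examples
#' nir <- laser_pulse(1.77, 4, 1e13)
#' field_at(nir, 0)
laser_pulse <- function(central_photon_energy,
                        fwhm_duration,
                        peak_intensity,
                        carrier_envelope_phase = 0,
                        envelope = c("cos2", "gaussian"),
                        polarization = c(0, 0, 1),
                        center_time = 0) {
  envelope <- match.arg(envelope)
  if (!is.numeric(fwhm_duration) || fwhm_duration <= 0)
    stop_invalid("fwhm_duration must be > 0 fs")
  if (peak_intensity < 0) stop_invalid("peak_intensity must be >= 0")
  if (central_photon_energy <= 0) stop_invalid("central_photon_energy must be > 0 eV")
  nrm <- sqrt(sum(polarization^2))
  if (nrm < 1e-12) stop_invalid("polarization must be a nonzero 3-vector")
  structure(
    list(
      central_photon_energy = central_photon_energy,
      fwhm_duration = fwhm_duration,
      peak_intensity = peak_intensity,
      carrier_envelope_phase = carrier_envelope_phase,
      envelope = envelope,
      polarization = polarization / nrm,
      center_time = center_time
    ),
    class = "laser_pulse"
  )
}

#' @export
print.laser_pulse <- function(x, ...) {
  cat(sprintf(
    "<laser_pulse> %.3g eV, FWHM %.3g fs, %.3g W/cm2, %s envelope, center %.3g fs\n",
    x$central_photon_energy, x$fwhm_duration, x$peak_intensity,
    x$envelope, x$center_time
  ))
  invisible(x)
}

#' Peak field amplitude from intensity
#'
#' Converts a peak intensity in W/cm^2 to the peak electric field in atomic
#' units, `E0 = sqrt(I / 3.50945e16)`.
#'
#' @param intensity Peak intensity in W/cm^2 (scalar or vector, `>= 0`).
#' @return Field amplitude(s) in atomic units.
#' @export
peak_field_from_intensity <- function(intensity) {
  if (any(intensity < 0)) stop_invalid("intensity must be >= 0")
  sqrt(intensity / cm_constants$intensity_au)
}

# amplitude envelope, unit peak, intensity-FWHM parameterisation
pulse_envelope <- function(pulse, t) {
  u <- t - pulse$center_time
  f <- pulse$fwhm_duration
  switch(pulse$envelope,
    gaussian = exp(-2 * log(2) * (u / f)^2),
    cos2 = ifelse(abs(u) <= f, cos(pi * u / (2 * f)), 0)
  )
}

#' Electric field of a pulse at given times
#'
#' `E(t) = E0 * env(t - center) * cos(omega (t - center) + CEP)`, with the
#' amplitude envelope normalised to unit peak and zero outside the cos^2
#' support. The returned amplitude is in atomic units along the pulse
#' polarization.
#'
#' @param pulse A [laser_pulse()].
#' @param t Time(s) in fs.
#' @return Field amplitude(s) in atomic units.
#' @export
field_at <- function(pulse, t) {
  e0 <- peak_field_from_intensity(pulse$peak_intensity)
  omega <- pulse$central_photon_energy / cm_constants$hbar_ev_fs # rad/fs
  u <- t - pulse$center_time
  e0 * pulse_envelope(pulse, t) * cos(omega * u + pulse$carrier_envelope_phase)
}

#' Instrument response of a pump-probe scan
#'
#' A Gaussian temporal response of standard deviation `sigma` (fs),
#' representing the pump-probe intensity cross-correlation.
#'
#' @param sigma Gaussian standard deviation in fs, `>= 0`.
#' @return An object of class `instrument_response`.
#' @export
instrument_response <- function(sigma) {
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  structure(list(sigma = sigma), class = "instrument_response")
}

#' @export
print.instrument_response <- function(x, ...) {
  cat(sprintf("<instrument_response> sigma = %.4g fs (FWHM %.4g fs)\n",
              x$sigma, x$sigma * 2 * sqrt(2 * log(2))))
  invisible(x)
}

#' Instrument response from the two pulse durations
#'
#' The cross-correlation of two Gaussian intensity envelopes is Gaussian
#' with `FWHM_cc = sqrt(FWHM_pump^2 + FWHM_probe^2)`; the response sigma is
#' `FWHM_cc / (2 sqrt(2 log 2))`. Symmetric in its arguments and monotone in
#' each duration; a zero duration is allowed as the delta-pulse limit.
#'
#' @param pump,probe [laser_pulse()] objects, or bare FWHM durations in fs.
#' @return An [instrument_response()].
#' @export
#' @examples
#' irf_from_pulses(0.3, 4)   # sub-300-as pump, 4 fs probe
irf_from_pulses <- function(pump, probe) {
  dur <- function(p) {
    if (inherits(p, "laser_pulse")) p$fwhm_duration
    else if (is.numeric(p) && length(p) == 1) p
    else stop_invalid("pump/probe must be laser_pulse objects or durations")
  }
  f1 <- dur(pump); f2 <- dur(probe)
  if (f1 < 0 || f2 < 0) stop_invalid("durations must be >= 0")
  fwhm_cc <- sqrt(f1^2 + f2^2)
  instrument_response(fwhm_cc / (2 * sqrt(2 * log(2))))
}

#' Serialise / restore a pulse as JSON
#'
#' @param pulse A [laser_pulse()].
#' @param path File path.
#' @return `write_pulse()` returns `path` invisibly; `read_pulse()` a
#'   [laser_pulse()].
#' @export
write_pulse <- function(pulse, path) {
  jsonlite::write_json(unclass(pulse), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pulse
#' @export
read_pulse <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  laser_pulse(
    central_photon_energy = x$central_photon_energy,
    fwhm_duration = x$fwhm_duration,
    peak_intensity = x$peak_intensity,
    carrier_envelope_phase = x$carrier_envelope_phase %||% 0,
    envelope = x$envelope %||% "cos2",
    polarization = x$polarization %||% c(0, 0, 1),
    center_time = x$center_time %||% 0
  )
}
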