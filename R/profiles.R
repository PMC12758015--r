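#' Machine acquisition profile
#'
#' Parametric description of an ultrasound scanner's system response: a
#' Gaussian transmit/receive pulse spectrum plus digitizer settings. The
#' system response is the machine-dependent factor of the received RF
#' spectrum; the simulator and the transfer-function calibration both treat
#' it as multiplicative on the tissue spectrum.
#'
#' @param machine_id Short identifier, e.g. `"victim"`.
#' @param center_frequency Pulse centre frequency in MHz.
#' @param fractional_bandwidth -6 dB bandwidth divided by the centre
#'   frequency, in (0, 1].
#' @param sampling_rate RF sampling rate in MHz; must exceed twice the
#'   centre frequency.
#' @param gain Linear amplitude scale (transmit power/receive gain lump).
#' @param noise_floor Electronic noise level in dB relative to the in-band
#'   spectral peak; `-Inf` for a noiseless machine.
#' @param transducer_id Transducer identifier (bookkeeping only).
#' @return An object of class `machine_profile`.
#' @seealso [victim_machine()], [perpetrator_machine()], [pulse_spectrum()]
#' @export
machine_profile <- function(machine_id, center_frequency, fractional_bandwidth,
                            sampling_rate, gain = 1, noise_floor = -50,
                            transducer_id = "generic") {
  stopifnot_scalar(center_frequency, "center_frequency", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(fractional_bandwidth, "fractional_bandwidth", positive = TRUE)
  stopifnot_scalar(gain, "gain", positive = TRUE)
  if (fractional_bandwidth > 1) {
    stop("fractional_bandwidth must be in (0, 1]", call. = FALSE)
  }
  if (center_frequency >= sampling_rate / 2) {
    stop("center_frequency must be below the Nyquist rate", call. = FALSE)
  }
  structure(
    list(machine_id = as.character(machine_id),
         center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth,
         sampling_rate = sampling_rate,
         gain = gain,
         noise_floor = noise_floor,
         transducer_id = as.character(transducer_id)),
    class = "machine_profile")
}

#' Phantom (imaging substrate) profile
#'
#' Describes a tissue-mimicking phantom by its attenuation coefficient
#' slope (ACS), speed of sound, scatterer density and a power-law exponent
#' for the backscatter spectrum. The two classification phantoms differ in
#' ACS (0.4 vs 0.1 dB/cm/MHz), which is the spectral contrast the
#' classifiers learn; the calibration phantom (0.74 dB/cm/MHz) is imaged by
#' both machines to isolate their system-response ratio.
#'
#' @param phantom_id Short identifier.
#' @param acs Attenuation coefficient slope in dB/cm/MHz (two-way losses
#'   are `2 * acs * depth_cm * f_MHz` dB).
#' @param sos Speed of sound in m/s.
#' @param scatterer_density Scatterers per square millimetre; at least
#'   about 4/mm^2 for fully developed speckle.
#' @param backscatter_exponent Spectral power-law exponent of the
#'   backscatter intensity (0 = frequency-flat scatterers).
#' @param class_label `0`, `1` for classification phantoms or
#'   `"calibration"`.
#' @return An object of class `phantom_profile`.
#' @export
phantom_profile <- function(phantom_id, acs, sos, scatterer_density,
                            backscatter_exponent = 0,
                            class_label = c("0", "1", "calibration")) {
  stopifnot_scalar(acs, "acs")
  if (acs < 0) stop("acs must be >= 0", call. = FALSE)
  stopifnot_scalar(sos, "sos", positive = TRUE)
  stopifnot_scalar(scatterer_density, "scatterer_density")
  if (scatterer_density < 0) {
    stop("scatterer_density must be >= 0", call. = FALSE)
  }
  label <- as.character(class_label)[1]
  if (!label %in% c("0", "1", "calibration")) {
    stop("class_label must be 0, 1 or 'calibration'", call. = FALSE)
  }
  structure(
    list(phantom_id = as.character(phantom_id),
         acs = acs, sos = sos,
         scatterer_density = scatterer_density,
         backscatter_exponent = backscatter_exponent,
         class_label = label),
    class = "phantom_profile")
}

#' Default machine and phantom profiles
#'
#' The bundled study conditions: a 9 MHz victim machine sampling at 40 MHz
#' and a 5 MHz perpetrator machine sampling at 50 MHz, imaging a
#' liver-mimicking phantom (ACS 0.4 dB/cm/MHz, large glass beads, class
#' 0), a low-attenuation phantom (ACS 0.1 dB/cm/MHz, smaller beads and
#' hence a steeper backscatter power law, class 1) and a calibration
#' phantom (ACS 0.74 dB/cm/MHz). Bandwidths and noise floors are chosen
#' so the two machines' received bands overlap substantially, as they do
#' when two scanners drive comparable broadband linear arrays — without
#' overlap a finite transfer function cannot exist.
#'
#' @return A `machine_profile` or `phantom_profile`.
#' @export
victim_machine <- function() {
  machine_profile("victim", center_frequency = 9, fractional_bandwidth = 0.5,
                  sampling_rate = 40, gain = 1, noise_floor = -40,
                  transducer_id = "victim-linear")
}

#' @rdname victim_machine
#' @export
perpetrator_machine <- function() {
  machine_profile("perpetrator", center_frequency = 5,
                  fractional_bandwidth = 1, sampling_rate = 50, gain = 1.5,
                  noise_floor = -60, transducer_id = "perpetrator-linear")
}

#' @rdname victim_machine
#' @export
liver_phantom <- function() {
  phantom_profile("phantom-1", acs = 0.4, sos = 1540, scatterer_density = 8,
                  backscatter_exponent = 0.5, class_label = "0")
}

#' @rdname victim_machine
#' @export
low_attenuation_phantom <- function() {
  phantom_profile("phantom-2", acs = 0.1, sos = 1539, scatterer_density = 8,
                  backscatter_exponent = 1.5, class_label = "1")
}

#' @rdname victim_machine
#' @export
calibration_phantom <- function() {
  phantom_profile("calibration", acs = 0.74, sos = 1545,
                  scatterer_density = 8, backscatter_exponent = 0,
                  class_label = "calibration")
}

#' @export
print.machine_profile <- function(x, ...) {
  cat(sprintf("<machine_profile '%s'> fc %.3g MHz, bw %.0f%%, fs %g MHz, gain %.3g, noise floor %g dB (%s)\n",
              x$machine_id, x$center_frequency,
              100 * x$fractional_bandwidth, x$sampling_rate, x$gain,
              x$noise_floor, x$transducer_id))
  invisible(x)
}

#' @export
print.phantom_profile <- function(x, ...) {
  cat(sprintf("<phantom_profile '%s'> ACS %.3g dB/cm/MHz, SOS %g m/s, %.3g scatterers/mm^2, class %s\n",
              x$phantom_id, x$acs, x$sos, x$scatterer_density, x$class_label))
  invisible(x)
}

#' Frame geometry
#'
#' Frame dimensions shared by a simulated dataset. Depth is fixed in
#' physical units through a reference sampling rate and nominal speed of
#' sound, so machines digitizing at different rates produce different axial
#' sample counts over the same depth span. The full-scale geometry
#' (2080 x 256 at 40 MHz, i.e. about 4 cm x 38 mm) mirrors a clinical
#' linear-array frame; the desk-scale default (1040 x 128) halves both axes
#' for fast experimentation.
#'
#' @param n_axial_ref Axial sample count at the reference rate.
#' @param n_lines Number of lateral A-lines.
#' @param pitch_mm Lateral spacing between lines in mm.
#' @param ref_rate Reference sampling rate in MHz used to convert
#'   `n_axial_ref` to depth.
#' @param ref_sos Nominal speed of sound in m/s assumed by the scanners.
#' @param full_scale If `TRUE`, return the 2080 x 256 full-scale geometry.
#' @return An object of class `frame_geometry`.
#' @export
frame_geometry <- function(n_axial_ref = 1040, n_lines = 128,
                           pitch_mm = 0.1484, ref_rate = 40, ref_sos = 1540,
                           full_scale = FALSE) {
  if (full_scale) {
    n_axial_ref <- 2080
    n_lines <- 256
  }
  depth_mm <- n_axial_ref * (ref_sos / 1000) / (2 * ref_rate)
  structure(
    list(n_axial_ref = as.integer(n_axial_ref),
         n_lines = as.integer(n_lines),
         pitch_mm = pitch_mm, ref_rate = ref_rate, ref_sos = ref_sos,
         depth_mm = depth_mm),
    class = "frame_geometry")
}

# Axial sample count for a machine digitizing this geometry's depth span.
geometry_axial_samples <- function(geometry, machine) {
  as.integer(round(geometry$n_axial_ref * machine$sampling_rate /
                     geometry$ref_rate))
}
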