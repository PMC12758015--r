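#' Analytic pulse amplitude spectrum of a machine
#'
#' The machine's system response is modelled as a Gaussian amplitude
#' spectrum centred on the transmit frequency whose -6 dB full width equals
#' `fractional_bandwidth * center_frequency`, scaled by the machine gain.
#' The time-domain pulse used by the simulator is normalized so that its
#' continuous-frequency amplitude peak equals `gain`, making this function
#' the closed-form reference for simulated spectra and for
#' transfer-function oracles.
#'
#' @param machine A [machine_profile()].
#' @param freq_grid Frequencies in MHz, inside `[0, sampling_rate/2]`.
#' @return Nonnegative amplitudes, one per frequency.
#' @export
pulse_spectrum <- function(machine, freq_grid) {
  if (!inherits(machine, "machine_profile")) {
    stop("'machine' must be a machine_profile", call. = FALSE)
  }
  if (any(freq_grid < 0 | freq_grid > machine$sampling_rate / 2)) {
    stop("freq_grid must lie within [0, sampling_rate/2]", call. = FALSE)
  }
  if (machine$center_frequency < min(freq_grid) ||
      machine$center_frequency > max(freq_grid)) {
    stop("center frequency lies outside the frequency grid", call. = FALSE)
  }
  sigma_f <- pulse_sigma_f(machine)
  machine$gain * exp(-(freq_grid - machine$center_frequency)^2 /
                       (2 * sigma_f^2))
}

# Gaussian spectral sigma (MHz) from the -6 dB fractional bandwidth.
pulse_sigma_f <- function(machine) {
  (machine$fractional_bandwidth * machine$center_frequency / 2) /
    sqrt(2 * log(2))
}

# Sampled pulse-echo wavelet: Gaussian-enveloped cosine whose continuous
# Fourier amplitude peaks at `gain`. Truncated at +/- 4 envelope sigmas.
pulse_waveform <- function(machine) {
  sigma_f <- pulse_sigma_f(machine)       # MHz
  sigma_t <- 1 / (2 * pi * sigma_f)       # microseconds
  fs <- machine$sampling_rate
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  amp <- 2 * machine$gain / (sigma_t * sqrt(2 * pi))
  amp * exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * machine$center_frequency * t)
}

#' Simulate one beamformed RF frame
#'
#' Realizes the multiplicative spectral model of pulse-echo imaging: the
#' received spectrum is the product of the machine's system response and
#' the tissue spectrum. Per frame, a random point-scatterer field is drawn
#' from the phantom, deposited on each A-line with a band-limited
#' (Kaiser-windowed sinc) interpolation kernel, convolved with the
#' machine's pulse, attenuated depth-dependently with the phantom's ACS
#' using piecewise-stationary overlap-add segments, and overlaid with white
#' electronic noise at the machine's noise floor. Identical
#' `(machine, phantom, seed)` inputs reproduce the frame bit for bit.
#'
#' @param machine A [machine_profile()].
#' @param phantom A [phantom_profile()].
#' @param seed Integer seed; drives the scatterer field and the noise.
#' @param geometry A [frame_geometry()].
#' @param frame_index Bookkeeping index stored in the frame.
#' @return An object of class `rf_frame` with fields `samples`
#'   (axial x lateral matrix), `sampling_rate` (MHz), `axial_spacing`
#'   (mm per sample under the nominal speed of sound), `machine_id`,
#'   `phantom_id`, `class_label` and `frame_index`.
#' @export
simulate_frame <- function(machine, phantom, seed,
                           geometry = frame_geometry(), frame_index = 1L) {
  field <- scatterer_field(phantom, geometry, derive_seed(seed, 1L, 11L))
  render_field(machine, phantom, field, geometry,
               noise_seed = derive_seed(seed, 2L, 13L),
               frame_index = frame_index)
}

# Random point-scatterer field in continuous (depth, lateral) coordinates.
# Margins keep the speckle statistics stationary at the frame edges and
# leave room for free-hand lateral jitter.
scatterer_field <- function(phantom, geometry, seed, lateral_margin = 3) {
  depth_margin <- 1.5   # mm beyond both axial ends
  width <- geometry$n_lines * geometry$pitch_mm
  area <- (geometry$depth_mm + 2 * depth_margin) *
    (width + 2 * lateral_margin)
  n <- as.integer(round(phantom$scatterer_density * area))
  with_seed(seed, {
    list(z = stats::runif(n, -depth_margin, geometry$depth_mm + depth_margin),
         x = stats::runif(n, -lateral_margin, width + lateral_margin),
         amp = stats::rnorm(n))
  })
}

# Render a scatterer field through one machine: deposit, convolve with the
# pulse, attenuate, add noise. `lateral_shift` (mm) implements free-hand
# probe translation.
render_field <- function(machine, phantom, field, geometry, noise_seed,
                         frame_index = 1L, lateral_shift = 0) {
  fs <- machine$sampling_rate
  n_ax <- geometry_axial_samples(geometry, machine)
  n_lines <- geometry$n_lines
  sos_mm_us <- phantom$sos / 1000

  # --- band-limited deposit of point scatterers onto the sample grid
  half <- 32L
  kern_w <- kaiser_sinc_kernel(half)
  r <- matrix(0, n_ax + 2L * half, n_lines)   # padded axially
  line <- as.integer(round((field$x - lateral_shift) / geometry$pitch_mm)) + 1L
  keep <- line >= 1L & line <= n_lines
  pos <- 2 * field$z[keep] / sos_mm_us * fs   # 0-based fractional sample
  # fs scale: the band-limited representation of a unit impulse at t_k is
  # fs * sinc(fs (t - t_k)), keeping amplitudes comparable across rates
  amp <- field$amp[keep] * fs
  line <- line[keep]
  base <- floor(pos)
  frac <- pos - base
  offs <- (-half + 1L):half
  for (i in seq_along(pos)) {
    rows <- base[i] + offs + 1L + half       # padded, 1-based
    ok <- rows >= 1L & rows <= nrow(r)
    if (!any(ok)) next
    u <- offs - frac[i]
    r[rows[ok], line[i]] <- r[rows[ok], line[i]] + amp[i] * kern_w(u[ok])
  }
  r <- r[(half + 1L):(half + n_ax), , drop = FALSE]

  # --- backscatter power-law shaping of the reflectivity (tissue spectrum)
  if (phantom$backscatter_exponent != 0) {
    freqs <- rfft_freqs(n_ax, fs)
    f_ref <- max(freqs) / 2
    g <- (pmax(freqs, freqs[2]) / f_ref)^(phantom$backscatter_exponent / 2)
    r <- apply_rfft_gain_mat(r, g)
  }

  # --- convolution with the machine pulse ('same', pulse centre aligned);
  # 1/fs approximates the continuous convolution so amplitudes are
  # comparable across sampling rates
  p <- pulse_waveform(machine)
  m <- length(p)
  nfft <- stats::nextn(n_ax + m - 1L, 2)
  P <- stats::fft(c(p, numeric(nfft - m)))
  R <- stats::mvfft(rbind(r, matrix(0, nfft - n_ax, n_lines)))
  y_full <- Re(stats::mvfft(R * P, inverse = TRUE)) / nfft
  lead <- (m - 1L) %/% 2L
  y <- y_full[(lead + 1L):(lead + n_ax), , drop = FALSE] / fs

  # --- depth-dependent attenuation, piecewise-stationary overlap-add
  if (phantom$acs > 0) {
    seg <- 64L
    freqs_seg <- rfft_freqs(seg, fs)
    acs <- phantom$acs
    y <- stft_apply(y, seg, 0.5, function(centre) {
      z_cm <- pmax(0, (centre - 1)) / fs * sos_mm_us / 2 / 10
      10^(-(2 * acs * z_cm * freqs_seg) / 20)
    })
  }

  # --- electronic noise at the configured floor (dB re in-band peak of the
  # noiseless frame's average periodogram)
  if (is.finite(machine$noise_floor)) {
    pgram <- rowMeans(Mod(stats::mvfft(y))^2) / n_ax
    nf <- floor(n_ax / 2) + 1L
    peak <- max(pgram[seq_len(nf)])
    sigma <- sqrt(peak * 10^(machine$noise_floor / 10))
    noise <- with_seed(noise_seed,
                       matrix(stats::rnorm(n_ax * n_lines, sd = sigma),
                              n_ax, n_lines))
    y <- y + noise
  }

  new_rf_frame(y, sampling_rate = fs,
               axial_spacing = (geometry$ref_sos / 1000) / (2 * fs),
               machine_id = machine$machine_id,
               phantom_id = phantom$phantom_id,
               class_label = phantom$class_label,
               frame_index = frame_index)
}

# Continuous Kaiser-windowed sinc interpolation kernel of half-width `half`.
kaiser_sinc_kernel <- function(half, beta = 8) {
  denom <- besselI(beta, 0)
  function(u) {
    w <- abs(u) < half
    out <- numeric(length(u))
    uu <- u[w]
    s <- ifelse(uu == 0, 1, sin(pi * uu) / (pi * uu))
    out[w] <- s * besselI(beta * sqrt(pmax(0, 1 - (uu / half)^2)), 0) / denom
    out
  }
}

new_rf_frame <- function(samples, sampling_rate, axial_spacing, machine_id,
                         phantom_id, class_label = NA_character_,
                         frame_index = 1L) {
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         axial_spacing = axial_spacing, machine_id = machine_id,
         phantom_id = phantom_id, class_label = class_label,
         frame_index = as.integer(frame_index)),
    class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d x %d samples @ %g MHz (%s on %s, class %s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              x$machine_id, x$phantom_id, x$class_label))
  invisible(x)
}

#' Simulate a labeled dataset of RF frames
#'
#' Draws `n_frames_per_phantom` frames from each classification phantom on
#' one machine, with per-frame seeds derived deterministically from the
#' master seed, giving a balanced labeled dataset.
#'
#' @param machine A [machine_profile()].
#' @param phantoms List of [phantom_profile()]s with class labels 0/1.
#' @param n_frames_per_phantom Frames per phantom (>= 1).
#' @param seed Master seed.
#' @param geometry A [frame_geometry()].
#' @return A list with `frames` (list of `rf_frame`) and `labels`
#'   (integer vector of 0/1).
#' @export
simulate_dataset <- function(machine, phantoms, n_frames_per_phantom, seed,
                             geometry = frame_geometry()) {
  if (length(phantoms) == 0) stop("empty phantom list", call. = FALSE)
  if (n_frames_per_phantom < 1) {
    stop("n_frames_per_phantom must be >= 1", call. = FALSE)
  }
  frames <- list()
  labels <- integer(0)
  k <- 0L
  for (ph in phantoms) {
    for (i in seq_len(n_frames_per_phantom)) {
      k <- k + 1L
      frames[[k]] <- simulate_frame(machine, ph,
                                    seed = derive_seed(seed, k, 17L),
                                    geometry = geometry, frame_index = k)
      labels[k] <- as.integer(ph$class_label)
    }
  }
  list(frames = frames, labels = labels)
}

#' Simulate paired calibration views from two machines
#'
#' Both machines image the same calibration-phantom realization, which is
#' what lets their depth-gated spectral ratio isolate the system-response
#' ratio. In `stable` mode the transducer is fixed: every view shares one
#' scatterer field and views differ only in electronic noise. In
#' `freehand` mode each view translates the field laterally by a random
#' offset (uniform on [0, 2] mm), shared between the two machines at the
#' same view index, emulating a recorded free-hand sweep.
#'
#' @param victim,perp [machine_profile()]s for the two machines.
#' @param cal The calibration [phantom_profile()].
#' @param n_views Number of paired views (>= 1).
#' @param mode `"stable"` or `"freehand"`.
#' @param seed Master seed.
#' @param geometry A [frame_geometry()].
#' @return A list with `victim` and `perp`, each a list of `rf_frame`.
#' @export
simulate_calibration_views <- function(victim, perp, cal, n_views = 10,
                                       mode = c("stable", "freehand"),
                                       seed = 1L,
                                       geometry = frame_geometry()) {
  mode <- match.arg(mode)
  if (n_views < 1) stop("n_views must be >= 1", call. = FALSE)
  if (cal$class_label != "calibration") {
    stop("'cal' must be a calibration phantom", call. = FALSE)
  }
  field <- scatterer_field(cal, geometry, derive_seed(seed, 0L, 19L))
  v_list <- vector("list", n_views)
  p_list <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    shift <- if (mode == "freehand") {
      with_seed(derive_seed(seed, v, 23L), stats::runif(1, 0, 2))
    } else 0
    noise_seed <- derive_seed(seed, v, 29L)
    v_list[[v]] <- render_field(victim, cal, field, geometry, noise_seed,
                                frame_index = v, lateral_shift = shift)
    p_list[[v]] <- render_field(perp, cal, field, geometry, noise_seed,
                                frame_index = v, lateral_shift = shift)
  }
  list(victim = v_list, perp = p_list)
}
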