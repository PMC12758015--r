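#' Depth-gating grid for spectral estimation
#'
#' Defines the short-time windows ("depth gates") over which spectra and
#' the transfer function are resolved along the axial direction. The
#' default — 200-sample Hann windows with 50 percent overlap — matches the
#' axial patch height, so one gate spans roughly one patch.
#'
#' @param window_length Gate length in samples.
#' @param window_overlap Fractional overlap in `[0, 1)`.
#' @param start_offset Samples skipped before the first gate.
#' @param taper Taper name; only `"hann"` is implemented.
#' @return An object of class `depth_grid`.
#' @export
depth_grid <- function(window_length = 200, window_overlap = 0.5,
                       start_offset = 0, taper = "hann") {
  stopifnot_scalar(window_length, "window_length", positive = TRUE)
  if (window_overlap < 0 || window_overlap >= 1) {
    stop("window_overlap must be in [0, 1)", call. = FALSE)
  }
  taper <- match.arg(taper, "hann")
  structure(
    list(window_length = as.integer(window_length),
         window_overlap = window_overlap,
         start_offset = as.integer(start_offset), taper = taper),
    class = "depth_grid")
}

grid_starts <- function(grid, n_axial) {
  hop <- max(1L, as.integer(round(grid$window_length *
                                    (1 - grid$window_overlap))))
  first <- grid$start_offset + 1L
  if (first + grid$window_length - 1L > n_axial) {
    stop("depth window exceeds frame depth", call. = FALSE)
  }
  seq(first, n_axial - grid$window_length + 1L, by = hop)
}

#' Depth-gated average power spectrum of calibration views
#'
#' Estimates the power spectrum at each depth gate as the tapered
#' periodogram averaged over every lateral line of every view. Averaging
#' across views suppresses electrical noise; the per-gate averaging count
#' is recorded.
#'
#' @param views A list of [simulate_frame()] frames (or a single frame)
#'   sharing geometry and sampling rate.
#' @param grid A [depth_grid()].
#' @return An object of class `depth_spectrum` with `power`
#'   (gates x frequencies), `freq_grid` (MHz), `depth_centers` (mm) and
#'   `n_views_averaged`.
#' @export
depth_gated_spectrum <- function(views, grid = depth_grid()) {
  if (inherits(views, "rf_frame")) views <- list(views)
  if (length(views) < 1) stop("need at least one view", call. = FALSE)
  fs <- views[[1]]$sampling_rate
  n_ax <- nrow(views[[1]]$samples)
  for (v in views) {
    if (v$sampling_rate != fs || nrow(v$samples) != n_ax) {
      stop("views must share geometry and sampling rate", call. = FALSE)
    }
  }
  L <- grid$window_length
  starts <- grid_starts(grid, n_ax)
  w <- hann_taper(L)
  nf <- floor(L / 2) + 1L
  power <- matrix(0, length(starts), nf)
  for (v in views) {
    for (k in seq_along(starts)) {
      seg <- v$samples[starts[k]:(starts[k] + L - 1L), , drop = FALSE] * w
      pg <- rowMeans(Mod(stats::mvfft(seg))^2)[seq_len(nf)] / L
      power[k, ] <- power[k, ] + pg
    }
  }
  power <- power / length(views)
  structure(
    list(power = power,
         freq_grid = rfft_freqs(L, fs),
         depth_centers = (starts - 1 + (L - 1) / 2) * views[[1]]$axial_spacing,
         n_views_averaged = length(views),
         n_lines = ncol(views[[1]]$samples),
         sampling_rate = fs, axial_spacing = views[[1]]$axial_spacing,
         n_axial = n_ax, grid = grid),
    class = "depth_spectrum")
}

#' Per-gate signal-to-noise ratio from an out-of-band noise floor
#'
#' The noise floor is measured outside the analysis bandwidth — in the
#' bins above 1.2 times the upper band edge — and the per-gate SNR is the
#' mean in-band power divided by that floor, capped at `1e6` so noiseless
#' synthetic data stay finite.
#'
#' @param spec A [depth_gated_spectrum()].
#' @param band_mask Logical vector over `spec$freq_grid` marking the
#'   analysis band.
#' @param cap Upper cap on the linear SNR.
#' @return Numeric vector of linear SNRs, one per depth gate.
#' @export
estimate_snr <- function(spec, band_mask, cap = 1e6) {
  if (!any(band_mask)) stop("band_mask selects no bins", call. = FALSE)
  f <- spec$freq_grid
  upper <- max(f[band_mask])
  floor_bins <- f > 1.2 * upper
  if (!any(floor_bins)) {
    stop("no out-of-band bins above 1.2x the band edge", call. = FALSE)
  }
  inb <- rowMeans(spec$power[, band_mask, drop = FALSE])
  out <- rowMeans(spec$power[, floor_bins, drop = FALSE])
  snr <- inb / pmax(out, .Machine$double.xmin)
  pmin(pmax(snr, .Machine$double.xmin), cap)
}

#' Wiener-regularized transfer function magnitude
#'
#' Shrinks the raw magnitude ratio where noise dominates:
#' `gamma_wiener = |gamma|^-1 / (|gamma|^-2 + SNR^-1)`. In the
#' infinite-SNR limit this equals `|gamma|`; for finite SNR it is strictly
#' smaller.
#'
#' @param gamma_raw Positive magnitude ratio, a matrix (gates x
#'   frequencies) or vector.
#' @param snr Positive linear SNR: a scalar, one value per gate (recycled
#'   across frequencies), or a full gates x frequencies matrix for a
#'   frequency-resolved floor.
#' @return Same shape as `gamma_raw`.
#' @export
wiener_gamma <- function(gamma_raw, snr) {
  if (any(!is.finite(gamma_raw)) || any(gamma_raw <= 0)) {
    stop("gamma_raw must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(snr)) || any(snr <= 0)) {
    stop("snr must be positive and finite", call. = FALSE)
  }
  g <- gamma_raw
  if (is.matrix(g) && !is.matrix(snr)) {
    if (length(snr) == 1L) snr <- rep(snr, nrow(g))
    if (length(snr) != nrow(g)) {
      stop("need one snr per depth gate", call. = FALSE)
    }
  }
  if (is.matrix(snr) && !identical(dim(snr), dim(g))) {
    stop("matrix snr must match gamma_raw's shape", call. = FALSE)
  }
  (1 / g) / ((1 / g^2) + 1 / snr)
}

#' Estimate the depth-resolved transfer function between two machines
#'
#' From paired calibration-phantom views, the per-gate ratio of the two
#' machines' averaged power spectra isolates their system-response ratio:
#' the shared tissue term cancels. The raw magnitude ratio
#' `sqrt(P_victim / P_perp)` is restricted to the band where both spectra
#' sit above a floor relative to their in-band peaks, clamped to its
#' band-edge values outside, and Wiener-regularized with a
#' frequency-resolved SNR: each machine's per-gate, per-bin power over its
#' own out-of-band noise-floor level, combined pessimistically across the
#' two machines. Outside either machine's usable band the SNR falls to
#' about one and the Wiener form shrinks the ratio towards zero instead of
#' amplifying noise; the classical per-gate scalar SNR of the perpetrator
#' spectrum is also reported in `snr`.
#'
#' Perpetrator views must already be resampled to the victim sampling rate
#' (see [resample_rate()]) so both spectra live on one frequency grid.
#'
#' @param victim_views,perp_views Lists of calibration `rf_frame`s.
#' @param grid A [depth_grid()].
#' @param band_floor_db Band threshold in dB relative to each machine's
#'   in-band spectral peak (default -20).
#' @param snr_cap Cap for [estimate_snr()].
#' @return An object of class `transfer_function` with `gamma_raw`,
#'   `gamma_wiener` (gates x frequencies), `snr` (per gate), `band_mask`,
#'   `freq_grid`, `depth_centers`.
#' @export
compute_gamma <- function(victim_views, perp_views, grid = depth_grid(),
                          band_floor_db = -20, snr_cap = 1e6) {
  sv <- depth_gated_spectrum(victim_views, grid)
  sp <- depth_gated_spectrum(perp_views, grid)
  if (sv$sampling_rate != sp$sampling_rate) {
    stop("perpetrator views must be resampled to the victim sampling rate ",
         "before computing the transfer function", call. = FALSE)
  }
  if (nrow(sv$power) != nrow(sp$power)) {
    stop("victim and perpetrator views must share the depth grid",
         call. = FALSE)
  }
  mv <- colMeans(sv$power)
  mp <- colMeans(sp$power)
  thr <- 10^(band_floor_db / 10)
  mask <- (mv >= thr * max(mv)) & (mp >= thr * max(mp))
  if (!any(mask)) stop("machines share no analysis band", call. = FALSE)
  # contiguous band containing both peaks
  idx <- range(which(mask))
  mask <- seq_along(mv) >= idx[1] & seq_along(mv) <= idx[2]
  if (any(sp$power[, mask] <= 0)) {
    stop("zero perpetrator power inside the analysis band", call. = FALSE)
  }
  gamma_raw <- sqrt(sv$power / pmax(sp$power, .Machine$double.xmin))
  # clamp to band-edge values outside the mask: never amplify pure noise
  lo <- idx[1]; hi <- idx[2]
  clamped <- gamma_raw
  if (lo > 1) clamped[, seq_len(lo - 1)] <- gamma_raw[, lo]
  nf <- ncol(gamma_raw)
  if (hi < nf) clamped[, (hi + 1):nf] <- gamma_raw[, hi]
  snr <- estimate_snr(sp, mask, cap = snr_cap)
  # Frequency-resolved SNR for the Wiener regularization: each machine's
  # per-gate, per-bin power over its own out-of-band noise-floor level,
  # combined pessimistically. Where either machine has no signal the SNR
  # drops to about one and the Wiener form shrinks the (clamped) ratio
  # towards zero instead of amplifying pure noise.
  floor_bins <- sv$freq_grid > 1.2 * max(sv$freq_grid[mask])
  floor_v <- rowMeans(sv$power[, floor_bins, drop = FALSE])
  floor_p <- rowMeans(sp$power[, floor_bins, drop = FALSE])
  snr_v <- sv$power / pmax(floor_v, .Machine$double.xmin)
  snr_p <- sp$power / pmax(floor_p, .Machine$double.xmin)
  snr_fr <- pmin(pmax(pmin(snr_v, snr_p), .Machine$double.xmin), snr_cap)
  structure(
    list(gamma_raw = gamma_raw, gamma_wiener = wiener_gamma(clamped, snr_fr),
         snr = snr, band_mask = mask,
         freq_grid = sv$freq_grid, depth_centers = sv$depth_centers,
         window_length = grid$window_length,
         window_overlap = grid$window_overlap,
         sampling_rate = sv$sampling_rate,
         axial_spacing = sv$axial_spacing, n_axial = sv$n_axial,
         victim_id = victim_views[[1]]$machine_id,
         perp_id = perp_views[[1]]$machine_id),
    class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %s -> %s: %d depth gates x %d bins @ %g MHz\n",
              x$perp_id, x$victim_id, nrow(x$gamma_raw),
              ncol(x$gamma_raw), x$sampling_rate))
  cat(sprintf("  band %.2f-%.2f MHz, SNR %.3g-%.3g\n",
              min(x$freq_grid[x$band_mask]), max(x$freq_grid[x$band_mask]),
              min(x$snr), max(x$snr)))
  invisible(x)
}

# gamma_wiener row interpolated at an arbitrary depth (mm), clamped to the
# first/last gate outside the covered range.
gamma_row_at_depth <- function(tf, depth_mm) {
  dc <- tf$depth_centers
  if (depth_mm <= dc[1]) return(tf$gamma_wiener[1, ])
  n <- length(dc)
  if (depth_mm >= dc[n]) return(tf$gamma_wiener[n, ])
  k <- findInterval(depth_mm, dc)
  a <- (depth_mm - dc[k]) / (dc[k + 1] - dc[k])
  (1 - a) * tf$gamma_wiener[k, ] + a * tf$gamma_wiener[k + 1, ]
}

#' Apply a transfer function to perpetrator data
#'
#' Converts perpetrator-machine data into the victim machine's spectral
#' domain: within each depth gate the spectral magnitude is multiplied by
#' the Wiener-regularized transfer function (linearly interpolated between
#' gate centres) while the phase — which carries the tissue speckle — is
#' preserved. Frames are processed with overlapping Hann gates and
#' overlap-add reconstruction; patches, whose height equals one gate, are
#' filtered in a single zero-phase pass at their own depth.
#'
#' @param x An `rf_frame` or [extract_patches()] `patch_set`, already at
#'   the victim sampling rate.
#' @param tf A [compute_gamma()] transfer function.
#' @param ... Unused.
#' @return Same class as `x`, with calibrated samples.
#' @export
apply_gamma <- function(x, tf, ...) UseMethod("apply_gamma")

#' @rdname apply_gamma
#' @export
apply_gamma.rf_frame <- function(x, tf, ...) {
  if (x$sampling_rate != tf$sampling_rate) {
    stop("input sampling rate must equal the transfer function's ",
         "(victim) rate", call. = FALSE)
  }
  if (nrow(x$samples) > tf$n_axial) {
    stop("input depth span exceeds the transfer function's coverage",
         call. = FALSE)
  }
  L <- tf$window_length
  sp <- x$axial_spacing
  out <- stft_apply(x$samples, L, tf$window_overlap, function(centre) {
    gamma_row_at_depth(tf, (centre - 1) * sp)
  })
  y <- x
  y$samples <- out
  y$machine_id <- paste0(x$machine_id, "->", tf$victim_id)
  y
}

#' @rdname apply_gamma
#' @export
apply_gamma.patch_set <- function(x, tf, ...) {
  if (!is.null(x$sampling_rate) && x$sampling_rate != tf$sampling_rate) {
    stop("patch sampling rate must equal the transfer function's ",
         "(victim) rate", call. = FALSE)
  }
  h <- dim(x$patches)[2]
  if (h != tf$window_length) {
    stop("patch height must equal the transfer function window length",
         call. = FALSE)
  }
  out <- x$patches
  w <- dim(x$patches)[3]
  sp <- tf$axial_spacing
  for (a0 in unique(x$coords$axial_start)) {
    sel <- which(x$coords$axial_start == a0)
    gain <- gamma_row_at_depth(tf, (a0 + (h - 1) / 2) * sp)
    block <- matrix(aperm(x$patches[sel, , , drop = FALSE], c(2, 1, 3)),
                    nrow = h)
    filt <- apply_rfft_gain_mat(block, gain)
    out[sel, , ] <- aperm(array(filt, c(h, length(sel), w)), c(2, 1, 3))
  }
  y <- x
  y$patches <- out
  y$provenance <- "calibrated"
  y
}
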