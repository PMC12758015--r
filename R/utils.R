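# Unit conventions used throughout the package:
#   frequency   MHz        sampling_rate MHz (samples per microsecond)
#   time        microseconds
#   depth       mm (axial), pulse-echo: depth = t * sos / 2
#   attenuation dB / cm / MHz (two-way losses are 2 * acs * depth * f)

# Run `code` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed from a master seed and a stream index; keeps
# values inside the positive 32-bit integer range R requires.
derive_seed <- function(seed, index, salt = 0L) {
  x <- (as.double(seed) %% 2147483647) + 1
  for (k in c(as.double(index), as.double(salt))) {
    x <- (x * 48271 + k * 9973 + 1) %% 2147483647
  }
  as.integer(x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Periodic Hann taper; sums to one over shifts of length/2 (constant
# overlap-add at 50 percent), which the short-time filters rely on.
hann_taper <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

# Frequencies (MHz) of the non-negative FFT bins for a window of `n` samples.
rfft_freqs <- function(n, fs) {
  seq(0, floor(n / 2)) * fs / n
}

# Apply a real, frequency-dependent gain to a length-n real signal block
# (zero phase): multiply the rFFT bins and mirror Hermitian symmetry.
# `gain` has floor(n/2)+1 entries matching rfft_freqs(n, fs).
apply_rfft_gain <- function(x, gain) {
  n <- length(x)
  nf <- floor(n / 2) + 1L
  X <- stats::fft(x)
  g <- numeric(n)
  g[seq_len(nf)] <- gain
  if (n > 2L) {
    idx <- seq(2L, n - nf + 1L)
    g[n + 2L - idx] <- gain[idx]
  }
  Re(stats::fft(X * g, inverse = TRUE)) / n
}

# Matrix version: columns are independent signals sharing one gain vector.
apply_rfft_gain_mat <- function(x, gain) {
  n <- nrow(x)
  nf <- floor(n / 2) + 1L
  g <- numeric(n)
  g[seq_len(nf)] <- gain
  if (n > 2L) {
    idx <- seq(2L, n - nf + 1L)
    g[n + 2L - idx] <- gain[idx]
  }
  X <- stats::mvfft(x)
  Re(stats::mvfft(X * g, inverse = TRUE)) / n
}

# Short-time zero-phase spectral filtering with Hann analysis windows and
# overlap-add reconstruction. `x` is an axial-samples x lines matrix;
# `gain_fun(center_index)` returns the rFFT-bin gain for the window centred
# at that (1-based, unpadded) axial sample. Identity gains reconstruct the
# input exactly away from round-off.
stft_apply <- function(x, window_length, overlap, gain_fun) {
  n <- nrow(x)
  hop <- max(1L, as.integer(round(window_length * (1 - overlap))))
  w <- hann_taper(window_length)
  pad <- window_length
  xp <- rbind(matrix(0, pad, ncol(x)), x, matrix(0, pad, ncol(x)))
  np <- nrow(xp)
  out <- matrix(0, np, ncol(x))
  wsum <- numeric(np)
  starts <- seq(1L, np - window_length + 1L, by = hop)
  for (s in starts) {
    rows <- s:(s + window_length - 1L)
    centre <- s + window_length / 2 - pad   # unpadded coordinates
    g <- gain_fun(centre)
    seg <- xp[rows, , drop = FALSE] * w
    out[rows, ] <- out[rows, ] + apply_rfft_gain_mat(seg, g)
    wsum[rows] <- wsum[rows] + w
  }
  wsum[wsum < 1e-12] <- 1
  out <- out / wsum
  out[(pad + 1L):(pad + n), , drop = FALSE]
}

# Envelope of an RF line via the analytic signal (FFT implementation).
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}
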