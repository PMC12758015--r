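test_that("machine and phantom profiles enforce their invariants", {
  expect_s3_class(victim_machine(), "machine_profile")
  expect_error(machine_profile("m", 25, 0.5, 40), "Nyquist")
  expect_error(machine_profile("m", 5, 1.5, 40), "fractional_bandwidth")
  expect_error(phantom_profile("p", -1, 1540, 8), "acs")
  expect_error(phantom_profile("p", 0.5, 1540, 8, class_label = "7"),
               "class_label")
  expect_output(print(perpetrator_machine()), "perpetrator")
  expect_output(print(liver_phantom()), "ACS 0.4")
})

test_that("pulse spectrum is the closed-form Gaussian with -6 dB bandwidth", {
  m <- machine_profile("m", 9, 0.5, 40, gain = 2)
  f <- seq(0, 20, by = 0.01)
  s <- pulse_spectrum(m, f)
  # peak at fc equals the gain
  expect_equal(s[f == 9], 2, tolerance = 1e-12)
  # -6 dB (amplitude half) at fc +/- bw*fc/2
  expect_equal(s[f == 9 + 0.5 * 9 / 2], 1, tolerance = 1e-10)
  expect_equal(s[f == 9 - 0.5 * 9 / 2], 1, tolerance = 1e-10)
  # matches the explicit Gaussian formula everywhere
  sigma_f <- (0.5 * 9 / 2) / sqrt(2 * log(2))
  expect_equal(s, 2 * exp(-(f - 9)^2 / (2 * sigma_f^2)), tolerance = 1e-12)
  expect_error(pulse_spectrum(m, c(-1, 5)), "within")
  expect_error(pulse_spectrum(m, seq(12, 20, 0.5)), "outside")
})

test_that("sampled pulse has continuous-FT amplitude peak equal to the gain", {
  m <- machine_profile("m", 9, 0.5, 40, gain = 1.7)
  p <- pulse_waveform(m)
  nfft <- 8192L
  # continuous FT ~ discrete FT / fs
  amp <- Mod(stats::fft(c(p, numeric(nfft - length(p)))))[1:(nfft / 2)] /
    m$sampling_rate
  expect_equal(max(amp), 1.7, tolerance = 1e-3)
  # and the peak sits at the centre frequency
  f_peak <- (which.max(amp) - 1) * m$sampling_rate / nfft
  expect_equal(f_peak, 9, tolerance = 0.05)
})

test_that("simulated frames are deterministic and correctly dimensioned", {
  geo <- tiny_geometry()
  f1 <- simulate_frame(victim_machine(), liver_phantom(), seed = 5,
                       geometry = geo)
  f2 <- simulate_frame(victim_machine(), liver_phantom(), seed = 5,
                       geometry = geo)
  expect_identical(f1$samples, f2$samples)
  expect_equal(dim(f1$samples), c(260L, 32L))
  # a 50 MHz machine digitizes the same depth with 25% more samples
  f3 <- simulate_frame(perpetrator_machine(), liver_phantom(), seed = 5,
                       geometry = geo)
  expect_equal(nrow(f3$samples), 325L)
  # different seeds give different speckle
  f4 <- simulate_frame(victim_machine(), liver_phantom(), seed = 6,
                       geometry = geo)
  expect_false(identical(f1$samples, f4$samples))
})

test_that("average periodogram peaks near the pulse centre frequency", {
  geo <- tiny_geometry()
  m <- machine_profile("m", 9, 0.5, 40, noise_floor = -Inf)
  fr <- simulate_frame(m, phantom_profile("p", 0, 1540, 8), seed = 2,
                       geometry = geo)
  x <- fr$samples
  pg <- rowMeans(Mod(stats::mvfft(x))^2)
  nf <- floor(nrow(x) / 2) + 1
  freqs <- rfft_freqs(nrow(x), 40)
  f_peak <- freqs[which.max(pg[seq_len(nf)])]
  expect_lt(abs(f_peak - 9), 1)
})

test_that("attenuation follows the two-way ACS law in dB", {
  # same scatterer seed, flat backscatter, no noise; only ACS differs, so
  # the depth-gated spectral ratio must equal 10^(-2*dACS*z_cm*f/20).
  geo <- tiny_geometry()
  m <- machine_profile("m", 9, 0.5, 40, noise_floor = -Inf)
  p0 <- phantom_profile("p0", 0.0, 1540, 8)
  p1 <- phantom_profile("p1", 0.8, 1540, 8)
  f0 <- simulate_frame(m, p0, seed = 31, geometry = geo)
  f1 <- simulate_frame(m, p1, seed = 31, geometry = geo)
  grid <- depth_grid(window_length = 128, window_overlap = 0.5)
  s0 <- depth_gated_spectrum(f0, grid)
  s1 <- depth_gated_spectrum(f1, grid)
  band <- s0$freq_grid >= 7 & s0$freq_grid <= 11
  gate <- nrow(s0$power)                       # deepest gate
  z_cm <- s0$depth_centers[gate] / 10
  ratio_db <- 10 * log10(s1$power[gate, band] / s0$power[gate, band])
  expected_db <- -2 * 0.8 * z_cm * s0$freq_grid[band]
  expect_lt(max(abs(ratio_db - expected_db)), 0.6)
})

test_that("electronic noise sits at the configured floor", {
  geo <- tiny_geometry()
  quiet <- machine_profile("m", 9, 0.5, 40, noise_floor = -Inf)
  noisy <- machine_profile("m", 9, 0.5, 40, noise_floor = -30)
  f_q <- simulate_frame(quiet, liver_phantom(), seed = 8, geometry = geo)
  f_n <- simulate_frame(noisy, liver_phantom(), seed = 8, geometry = geo)
  resid <- f_n$samples - f_q$samples
  pg <- rowMeans(Mod(stats::mvfft(f_q$samples))^2) / nrow(f_q$samples)
  peak <- max(pg[seq_len(floor(nrow(f_q$samples) / 2) + 1)])
  expected_var <- peak * 10^(-30 / 10)
  expect_equal(stats::var(as.vector(resid)), expected_var, tolerance = 0.05)
})

test_that("simulate_dataset returns balanced labeled frames", {
  geo <- tiny_geometry()
  ds <- simulate_dataset(victim_machine(),
                         list(liver_phantom(), low_attenuation_phantom()),
                         2, seed = 3, geometry = geo)
  expect_length(ds$frames, 4)
  expect_equal(ds$labels, c(0L, 0L, 1L, 1L))
  # per-frame seeds differ
  expect_false(identical(ds$frames[[1]]$samples, ds$frames[[2]]$samples))
  expect_error(simulate_dataset(victim_machine(), list(), 2, seed = 1),
               "empty")
})

test_that("stable calibration views share the scatterer realization", {
  geo <- tiny_geometry()
  v <- machine_profile("v", 9, 0.5, 40, noise_floor = -Inf)
  p <- machine_profile("p", 5, 1, 50, noise_floor = -Inf)
  cal <- simulate_calibration_views(v, p, calibration_phantom(),
                                    n_views = 2, mode = "stable", seed = 4,
                                    geometry = geo)
  # noiseless + fixed transducer: the views are bit-identical
  expect_identical(cal$victim[[1]]$samples, cal$victim[[2]]$samples)
  expect_identical(cal$perp[[1]]$samples, cal$perp[[2]]$samples)
  # freehand views are laterally shifted, hence different
  calf <- simulate_calibration_views(v, p, calibration_phantom(),
                                     n_views = 2, mode = "freehand",
                                     seed = 4, geometry = geo)
  expect_false(identical(calf$victim[[1]]$samples,
                         calf$victim[[2]]$samples))
  expect_error(
    simulate_calibration_views(v, p, liver_phantom(), 2, "stable", 1,
                               geometry = geo),
    "calibration")
})
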