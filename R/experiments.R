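#' Build the default synthetic two-machine benchmark
#'
#' Assembles everything the migration pipeline needs, at desk scale, from
#' the bundled simulator: a labeled victim-machine dataset with a trained
#' victim classifier (wrapped as a black-box interface), paired
#' calibration views and the transfer function estimated from them, and a
#' perpetrator-machine dataset split at frame level into an unlabeled
#' working set and a held-out labeled test set. Perpetrator frames are
#' rate-matched to the victim grid (up 4 / down 5) before patch
#' extraction.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_frames_per_phantom Frames per classification phantom and
#'   machine.
#' @param n_cal_views Paired calibration views.
#' @param cal_mode Calibration acquisition mode, `"stable"` or
#'   `"freehand"`.
#' @param geometry A [frame_geometry()].
#' @param victim A victim [machine_profile()].
#' @param perp A perpetrator [machine_profile()].
#' @param victim_spec,perp_spec [classifier_spec()]s for the two sides.
#' @param train_cfg A [train_config()] for the victim model.
#' @param cfg A [patch_config()]; on the desk-scale geometry the default
#'   yields a 4 x 4 patch grid per frame.
#' @return A list of benchmark components; see Details.
#' @details The returned list contains `victim_iface` (black-box score
#'   oracle), `victim_model`, `victim_val` (victim validation metrics),
#'   `tf` (the estimated transfer function), `x_perp` (unlabeled working
#'   `patch_set`), `perp_labels` (hidden ground truth for the working
#'   set, used only by evaluation), `x_test`/`test_labels` (held-out
#'   perpetrator test patches), and the profiles and configs used.
#' @export
synthetic_benchmark <- function(seed = 1L, n_frames_per_phantom = 50,
                                n_cal_views = 10,
                                cal_mode = c("stable", "freehand"),
                                geometry = frame_geometry(),
                                victim = victim_machine(),
                                perp = perpetrator_machine(),
                                victim_spec = victim_classifier_spec(),
                                perp_spec = perpetrator_classifier_spec(),
                                train_cfg = train_config(),
                                cfg = patch_config()) {
  cal_mode <- match.arg(cal_mode)
  phantoms <- list(liver_phantom(), low_attenuation_phantom())

  # victim side: data, split, model
  vds <- simulate_dataset(victim, phantoms, n_frames_per_phantom,
                          seed = derive_seed(seed, 1L, 61L),
                          geometry = geometry)
  vps <- extract_patches(vds, cfg)
  vsp <- split_frames(vds$labels, victim_split_scheme(),
                      seed = derive_seed(seed, 2L, 67L))
  vtr <- which(vps$coords$frame_index %in% vsp$train)
  vva <- which(vps$coords$frame_index %in% vsp$validation)
  vX <- zscore_patches(vps$patches)
  vcfg <- train_cfg
  vcfg$seed <- derive_seed(seed, 3L, 71L)
  victim_model <- build_classifier(victim_spec,
                                   seed = derive_seed(seed, 4L, 73L))
  victim_model <- train(victim_model, vX[vtr, , , drop = FALSE],
                        vps$labels[vtr], vcfg)
  victim_val <- evaluate(predict_scores(victim_model,
                                        vX[vva, , , drop = FALSE]),
                         vps$labels[vva])

  # calibration: paired views, perpetrator side rate-matched first
  cal <- simulate_calibration_views(victim, perp, calibration_phantom(),
                                    n_views = n_cal_views, mode = cal_mode,
                                    seed = derive_seed(seed, 5L, 79L),
                                    geometry = geometry)
  perp_cal <- lapply(cal$perp, resample_rate, up = 4, down = 5)
  tf <- compute_gamma(cal$victim, perp_cal)

  # perpetrator side: data, frame-level split, rate matching
  pds <- simulate_dataset(perp, phantoms, n_frames_per_phantom,
                          seed = derive_seed(seed, 6L, 83L),
                          geometry = geometry)
  pds$frames <- lapply(pds$frames, resample_rate, up = 4, down = 5)
  psp <- split_frames(pds$labels, perpetrator_split_scheme(),
                      seed = derive_seed(seed, 7L, 89L))
  pps <- extract_patches(pds, cfg)
  work_frames <- sort(c(psp$train, psp$validation))
  widx <- which(pps$coords$frame_index %in% work_frames)
  tidx <- which(pps$coords$frame_index %in% psp$test)
  x_perp <- subset_patches(pps, widx)
  perp_labels <- x_perp$labels
  x_perp$labels <- NULL          # the working set is unlabeled by contract
  x_test <- subset_patches(pps, tidx)

  list(victim_iface = victim_interface(victim_model),
       victim_model = victim_model, victim_val = victim_val,
       tf = tf, x_perp = x_perp, perp_labels = perp_labels,
       x_test = x_test, test_labels = x_test$labels,
       victim_profile = victim, perp_profile = perp,
       victim_spec = victim_spec, perp_spec = perp_spec,
       train_cfg = train_cfg, patch_cfg = cfg, geometry = geometry,
       seed = as.integer(seed))
}

#' Accuracy of victim pseudo-labels on the working set
#'
#' Scores the (optionally calibrated) working patches through the victim
#' interface, thresholds at the label percentile and compares with the
#' hidden ground truth — the quantity the transfer function is meant to
#' improve.
#'
#' @param bench A [synthetic_benchmark()].
#' @param use_tf Apply the transfer function before querying.
#' @param percentile Label percentile for [pseudo_label()].
#' @return Accuracy in percent.
#' @export
pseudo_label_accuracy <- function(bench, use_tf = TRUE, percentile = 50) {
  x <- if (use_tf) apply_gamma(bench$x_perp, bench$tf) else bench$x_perp
  scores <- query(bench$victim_iface, zscore_patches(patch_array(x)))
  y <- pseudo_label(scores, percentile)
  100 * mean(y == bench$perp_labels)
}

#' Run one migration on a benchmark and evaluate it
#'
#' Convenience wrapper: runs [run_iterlnl()] with the benchmark's victim
#' interface and working set and evaluates the migrated model on the
#' held-out perpetrator test patches.
#'
#' @param bench A [synthetic_benchmark()].
#' @param seed Seed for the denoising cycles.
#' @param use_tf Use the transfer function (`FALSE` gives the ablation
#'   arm).
#' @param cfg An [iterlnl_config()]; its seed is overridden by `seed`.
#' @param train_cfg A [train_config()] for cycle training; the default
#'   follows [run_iterlnl()]'s longer 20-epoch schedule.
#' @return List with the `qus_migration` object, test metrics, and the
#'   initial/final pseudo-label accuracies on the working set.
#' @export
run_benchmark_migration <- function(bench, seed = 1L, use_tf = TRUE,
                                    cfg = iterlnl_config(n_cycles = 2),
                                    train_cfg = train_config(epochs = 20)) {
  cfg$seed <- as.integer(seed)
  mig <- run_iterlnl(bench$victim_iface,
                     if (use_tf) bench$tf else NULL,
                     bench$x_perp, bench$perp_spec, cfg, train_cfg)
  test_metrics <- evaluate(mig, bench$test_labels, patches = bench$x_test)
  list(migration = mig,
       test = test_metrics,
       initial_label_accuracy = 100 * mean(mig$initial_labels ==
                                             bench$perp_labels),
       final_label_accuracy = 100 * mean(mig$final_labels ==
                                           bench$perp_labels))
}

#' Experiment grid over migration factors
#'
#' Runs the migration once per (cell, seed) over the requested factor
#' levels — transfer function on/off, label percentile, noise rate,
#' denoising cycles — on a shared benchmark, and aggregates mean and
#' standard deviation per cell. Results are deterministic given the
#' seeds. With `out_dir` the per-run table is written to CSV together
#' with a JSON-like manifest, and completed (cell, seed) runs found there
#' are skipped on re-run (resume).
#'
#' @param bench A [synthetic_benchmark()].
#' @param factors Named list of factor levels; recognized names are
#'   `tf` (logical), `percentile`, `noise_rate`, `n_cycles`.
#' @param n_seeds Replicates per cell (seeds `1..n_seeds` combined with
#'   the benchmark seed).
#' @param out_dir Optional output directory for CSV results and the
#'   manifest.
#' @return List with `runs` (one row per run) and `cells` (aggregates).
#' @export
run_grid <- function(bench,
                     factors = list(tf = c(TRUE, FALSE), percentile = 50,
                                    noise_rate = 0.2, n_cycles = 2),
                     n_seeds = 5, out_dir = NULL) {
  stopifnot(n_seeds >= 1)
  defaults <- list(tf = TRUE, percentile = 50, noise_rate = 0.2,
                   n_cycles = 2)
  unknown <- setdiff(names(factors), names(defaults))
  if (length(unknown)) {
    stop("unknown factors: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(defaults)) {
    if (is.null(factors[[nm]])) factors[[nm]] <- defaults[[nm]]
  }
  cells <- expand.grid(factors, stringsAsFactors = FALSE)
  runs <- NULL
  csv_path <- if (!is.null(out_dir)) file.path(out_dir, "runs.csv")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (file.exists(csv_path)) {
      runs <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
    }
  }
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, , drop = FALSE]
    for (sd in seq_len(n_seeds)) {
      done <- !is.null(runs) && any(
        runs$tf == cell$tf & runs$percentile == cell$percentile &
          runs$noise_rate == cell$noise_rate &
          runs$n_cycles == cell$n_cycles & runs$seed == sd)
      if (done) next
      res <- run_benchmark_migration(
        bench, seed = derive_seed(bench$seed, sd, 97L + ci),
        use_tf = cell$tf,
        cfg = iterlnl_config(noise_rate = cell$noise_rate,
                             label_percentile = cell$percentile,
                             n_cycles = cell$n_cycles))
      row <- data.frame(tf = cell$tf, percentile = cell$percentile,
                        noise_rate = cell$noise_rate,
                        n_cycles = cell$n_cycles, seed = sd,
                        accuracy = res$test$accuracy, auc = res$test$auc,
                        initial_label_accuracy = res$initial_label_accuracy,
                        query_count = res$migration$query_count)
      runs <- rbind(runs, row)
      if (!is.null(out_dir)) {
        utils::write.csv(runs, csv_path, row.names = FALSE)
      }
    }
  }
  agg <- stats::aggregate(cbind(accuracy, auc) ~ tf + percentile +
                            noise_rate + n_cycles, data = runs,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  if (!is.null(out_dir)) {
    manifest <- list(benchmark_seed = bench$seed, n_seeds = n_seeds,
                     factors = factors,
                     timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    writeLines(paste(names(manifest),
                     vapply(manifest, function(x)
                       paste(deparse(x), collapse = " "), ""),
                     sep = ": "),
               file.path(out_dir, "manifest.txt"))
  }
  list(runs = runs, cells = agg)
}

#' Perpetrator profile with a mismatched transducer
#'
#' Emulates switching the perpetrator machine to a different transducer:
#' the centre frequency shifts and the fractional bandwidth widens while
#' the imaging configuration (sampling rate, gain, noise floor) is
#' unchanged.
#'
#' @param base A perpetrator [machine_profile()].
#' @param shift_mhz Centre-frequency shift in MHz (default +1.5).
#' @param bw_scale Multiplier on the fractional bandwidth (default 1.2,
#'   capped at 1).
#' @return A new [machine_profile()].
#' @export
transducer_mismatch_config <- function(base, shift_mhz = 1.5,
                                       bw_scale = 1.2) {
  fc <- base$center_frequency + shift_mhz
  if (fc >= base$sampling_rate / 2) {
    stop("shifted centre frequency reaches the Nyquist rate",
         call. = FALSE)
  }
  machine_profile(base$machine_id, fc,
                  min(1, base$fractional_bandwidth * bw_scale),
                  base$sampling_rate, base$gain, base$noise_floor,
                  transducer_id = paste0(base$transducer_id, "-alt"))
}

#' B-mode rendering of an RF frame
#'
#' Envelope detection by analytic-signal magnitude per line, log
#' compression relative to the frame maximum, and clamping to the dynamic
#' range — for visual inspection only.
#'
#' @param frame An `rf_frame`.
#' @param dynamic_range Display range in dB (> 0).
#' @return Matrix of values in `[-dynamic_range, 0]` dB.
#' @export
render_bmode <- function(frame, dynamic_range = 50) {
  if (dynamic_range <= 0) stop("dynamic_range must be > 0", call. = FALSE)
  x <- frame$samples
  if (all(x == 0)) stop("cannot render an all-zero frame", call. = FALSE)
  env <- apply(x, 2, analytic_envelope)
  db <- 20 * log10(pmax(env / max(env), .Machine$double.xmin))
  pmax(db, -dynamic_range)
}

#' In-band log-spectral distance between two depth spectra
#'
#' Mean absolute difference of the per-gate log power spectra over the
#' analysis band, in dB — the quantitative measure of how far apart two
#' machines' calibration spectra are, and of how much a transfer function
#' closes the gap.
#'
#' @param spec_a,spec_b [depth_gated_spectrum()] objects on the same
#'   grid.
#' @param band_mask Logical vector over the shared frequency grid.
#' @return Mean absolute log-spectral difference in dB.
#' @export
log_spectral_distance <- function(spec_a, spec_b, band_mask) {
  if (!identical(dim(spec_a$power), dim(spec_b$power))) {
    stop("spectra must share the depth/frequency grid", call. = FALSE)
  }
  pa <- spec_a$power[, band_mask, drop = FALSE]
  pb <- spec_b$power[, band_mask, drop = FALSE]
  mean(abs(10 * log10(pa / pb)))
}
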