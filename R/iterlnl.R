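#' Configuration for iterative learning with noisy labels
#'
#' The two priors the migration relies on: the assumed pseudo-label noise
#' rate (default 20 percent, from the known accuracy of transfer-function
#' calibration alone) which sets the small-loss anchor fraction, and the
#' label-distribution percentile (default the median, for a balanced
#' binary task) used to threshold victim scores into pseudo-labels.
#'
#' @param noise_rate Assumed fraction of wrong pseudo-labels, in
#'   `[0, 1)`.
#' @param label_percentile Score percentile assigned to class 0, in
#'   `(0, 100)`.
#' @param n_cycles Denoising cycles (>= 0).
#' @param validation_fraction Fraction of patches held out (fresh each
#'   cycle) to monitor training; tunes nothing automatically.
#' @param seed Integer seed for cycle-level randomness.
#' @return An object of class `iterlnl_config`.
#' @export
iterlnl_config <- function(noise_rate = 0.2, label_percentile = 50,
                           n_cycles = 10, validation_fraction = 0.1,
                           seed = 1L) {
  if (noise_rate < 0 || noise_rate >= 1) {
    stop("noise_rate must be in [0, 1)", call. = FALSE)
  }
  if (label_percentile <= 0 || label_percentile >= 100) {
    stop("label_percentile must be in (0, 100)", call. = FALSE)
  }
  if (n_cycles < 0) stop("n_cycles must be >= 0", call. = FALSE)
  structure(
    list(noise_rate = noise_rate, label_percentile = label_percentile,
         n_cycles = as.integer(n_cycles),
         validation_fraction = validation_fraction,
         seed = as.integer(seed)),
    class = "iterlnl_config")
}

#' Percentile pseudo-labeling
#'
#' Thresholds continuous scores into binary labels using prior knowledge
#' of the label distribution: the lowest `percentile` percent of scores
#' become class 0 and the rest class 1. Ties are broken by stable score
#' order then index, so with distinct scores exactly
#' `floor(n * percentile / 100)` patches are labeled 0.
#'
#' @param scores Finite numeric scores.
#' @param percentile Percent of scores assigned to class 0.
#' @return Integer labels 0/1.
#' @export
pseudo_label <- function(scores, percentile = 50) {
  n <- length(scores)
  if (n == 0) stop("empty scores", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n0 <- floor(n * percentile / 100)
  labels <- rep(1L, n)
  if (n0 > 0) {
    ord <- order(scores, seq_len(n))
    labels[ord[seq_len(n0)]] <- 0L
  }
  labels
}

#' Small-loss anchor selection
#'
#' Under an assumed noise rate, the `(1 - noise_rate)` fraction of samples
#' with the smallest current training loss are treated as reliably
#' labeled ("anchors") and are the only samples trained on in that epoch.
#' With the default 20 percent noise rate this keeps 80 percent of the
#' data. Ties are broken by index; selection is deterministic.
#'
#' @param losses Finite per-sample losses.
#' @param noise_rate Assumed label noise rate in `[0, 1)`.
#' @return Indices of the `round((1 - noise_rate) * n)` smallest losses.
#' @export
select_anchors <- function(losses, noise_rate) {
  n <- length(losses)
  if (n == 0) stop("no losses supplied", call. = FALSE)
  if (any(!is.finite(losses))) stop("losses must be finite", call. = FALSE)
  if (noise_rate < 0 || noise_rate >= 1) {
    stop("noise_rate must be in [0, 1)", call. = FALSE)
  }
  k <- round((1 - noise_rate) * n)
  sort(order(losses, seq_len(n))[seq_len(max(k, 1L))])
}

#' Migrate a black-box classifier to the perpetrator machine
#'
#' The full migration engine. Perpetrator patches are spectrally
#' converted into the victim domain with the transfer function, scored
#' through the opaque victim interface, and thresholded into pseudo-labels
#' at the label-distribution percentile. Each denoising cycle then holds
#' out a fresh validation slice, re-initializes a perpetrator-side model,
#' trains it on the calibrated patches using per-epoch small-loss anchors
#' at the assumed noise rate, and re-acquires the pseudo-labels from the
#' refined model. Finally a fresh model is trained on the raw (native
#' domain) perpetrator patches with the refined labels — the migrated
#' classifier needs no transfer function at deployment.
#'
#' With `tf = NULL` the calibration step is skipped (the ablation arm):
#' raw patches are scored directly through the victim interface.
#'
#' @param victim A [victim_interface()]; the engine touches the victim
#'   model only through [query()].
#' @param tf A [compute_gamma()] transfer function, or `NULL`.
#' @param x_perp Unlabeled perpetrator `patch_set` at the victim sampling
#'   rate (see [resample_rate()]).
#' @param perp_spec [classifier_spec()] for the perpetrator model.
#' @param cfg An [iterlnl_config()].
#' @param train_cfg A [train_config()] shared by all cycle trainings and
#'   the final training. The default uses a longer schedule (20 epochs)
#'   than plain supervised training: anchor selection trains on only a
#'   `(1 - noise_rate)` subset each epoch, and a cycle student must
#'   reliably out-label its teacher for refinement to converge rather
#'   than drift.
#' @param final_mode `"scratch"` trains the final native-domain model
#'   from a fresh initialization; `"finetune"` continues from the last
#'   cycle's calibrated-domain model.
#' @return An object of class `qus_migration` holding the final model,
#'   initial and final pseudo-labels, scores, per-cycle trace and query
#'   count.
#' @export
run_iterlnl <- function(victim, tf, x_perp, perp_spec = perpetrator_classifier_spec(),
                        cfg = iterlnl_config(),
                        train_cfg = train_config(epochs = 20),
                        final_mode = c("scratch", "finetune")) {
  final_mode <- match.arg(final_mode)
  if (!inherits(victim, "victim_interface")) {
    stop("'victim' must be a victim_interface", call. = FALSE)
  }
  x_cal <- if (!is.null(tf)) apply_gamma(x_perp, tf) else x_perp
  xz_cal <- zscore_patches(patch_array(x_cal))
  n <- dim(xz_cal)[1]

  scores0 <- query(victim, xz_cal)
  y0 <- pseudo_label(scores0, cfg$label_percentile)
  y <- y0

  trace <- data.frame(cycle = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0), label_flip_fraction = numeric(0))
  model <- NULL
  for (cyc in seq_len(cfg$n_cycles)) {
    cyc_seed <- derive_seed(cfg$seed, cyc, 41L)
    val_idx <- with_seed(cyc_seed,
                         sample(n, max(1L, round(cfg$validation_fraction * n))))
    train_idx <- setdiff(seq_len(n), val_idx)
    model <- build_classifier(perp_spec, seed = derive_seed(cyc_seed, 1L, 43L))
    tc <- train_cfg
    tc$seed <- derive_seed(cyc_seed, 2L, 47L)
    model <- train(model, xz_cal[train_idx, , , drop = FALSE], y[train_idx],
                   tc, anchor_noise_rate = cfg$noise_rate)
    val_logits <- nn_predict_logits(model$params, perp_spec,
                                    xz_cal[val_idx, , , drop = FALSE])
    val_loss <- mean(bce_from_logits(val_logits, y[val_idx]))
    y_new <- pseudo_label(predict_scores(model, xz_cal),
                          cfg$label_percentile)
    trace <- rbind(trace, data.frame(
      cycle = cyc,
      train_loss = utils::tail(model$loss_history, 1),
      val_loss = val_loss,
      label_flip_fraction = mean(y_new != y)))
    y <- y_new
  }

  xz_raw <- zscore_patches(patch_array(x_perp))
  final_cfg <- train_cfg
  final_cfg$seed <- derive_seed(cfg$seed, 9999L, 53L)
  final_model <- if (final_mode == "finetune" && !is.null(model)) {
    model
  } else {
    build_classifier(perp_spec, seed = derive_seed(cfg$seed, 9998L, 59L))
  }
  final_model <- train(final_model, xz_raw, y, final_cfg)

  structure(
    list(model = final_model, perp_spec = perp_spec,
         initial_scores = scores0, initial_labels = y0, final_labels = y,
         trace = trace, cfg = cfg, train_cfg = train_cfg,
         used_transfer_function = !is.null(tf),
         query_count = query_count(victim)),
    class = "qus_migration")
}

#' @export
print.qus_migration <- function(x, ...) {
  cat(sprintf("<qus_migration> %d denoising cycles (%s transfer function), %d patches\n",
              x$cfg$n_cycles,
              if (x$used_transfer_function) "with" else "without",
              length(x$final_labels)))
  cat(sprintf("  labels changed by refinement: %.1f%%; victim queries: %d\n",
              100 * mean(x$final_labels != x$initial_labels),
              x$query_count))
  invisible(x)
}

#' @export
summary.qus_migration <- function(object, ...) {
  cat("Black-box model migration\n")
  print(object)
  if (nrow(object$trace)) {
    cat("Per-cycle trace:\n")
    print(object$trace, row.names = FALSE)
  }
  invisible(object)
}

#' @export
predict.qus_migration <- function(object, newdata, ...) {
  predict_scores(object$model, zscore_patches(patch_array(newdata)))
}

#' @export
plot.qus_migration <- function(x, ...) {
  if (!nrow(x$trace)) {
    stop("no denoising cycles to plot", call. = FALSE)
  }
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$trace$cycle, x$trace$val_loss, type = "b",
                 xlab = "denoising cycle", ylab = "validation loss", ...)
  graphics::plot(x$trace$cycle, 100 * x$trace$label_flip_fraction,
                 type = "b", xlab = "denoising cycle",
                 ylab = "pseudo-labels changed (%)", ...)
  invisible(x)
}

#' Patch-wise evaluation: accuracy and AUC
#'
#' Accuracy thresholds scores at 0.5; the AUC follows the
#' pairwise-comparison definition with ties counted as one half
#' (computed via average ranks, which is algebraically identical).
#'
#' @param scores Scores in `[0, 1]`, or a `qus_classifier` /
#'   `qus_migration` to score `patches` with.
#' @param labels True binary labels.
#' @param patches Required when `scores` is a model: raw patches to
#'   standardize and score.
#' @return List with `accuracy` (percent), `auc` and `n`.
#' @export
evaluate <- function(scores, labels, patches = NULL) {
  if (inherits(scores, "qus_migration")) {
    scores <- predict(scores, patches)
  } else if (inherits(scores, "qus_classifier")) {
    scores <- predict_scores(scores, zscore_patches(patch_array(patches)))
  }
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) {
    stop("AUC is undefined for a single-class test set", call. = FALSE)
  }
  acc <- 100 * mean((scores >= 0.5) == (y == 1L))
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = acc, auc = auc, n = length(y))
}

#' Aggregate per-seed metrics
#'
#' @param results List of [evaluate()] results (one per seed).
#' @return Data frame with mean and standard deviation of accuracy and
#'   AUC.
#' @export
aggregate_runs <- function(results) {
  acc <- vapply(results, function(r) r$accuracy, 1)
  auc <- vapply(results, function(r) r$auc, 1)
  data.frame(n_seeds = length(results),
             accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
             auc_mean = mean(auc), auc_sd = stats::sd(auc))
}
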