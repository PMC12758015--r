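#' Classifier architecture specification
#'
#' Reduced convolutional classifiers sized for CPU training. Two
#' deliberately different families are provided so the victim and
#' perpetrator sides can use mismatched architectures — mirroring the
#' realistic situation where the perpetrator cannot know the victim's
#' network — plus a linear baseline. All families map a single-channel RF
#' patch to one sigmoid score.
#'
#' @param family `"dense_style"` (each block convolves the concatenation
#'   of all previous feature maps), `"residual_style"` (identity skip
#'   connections), or `"linear_baseline"` (logistic regression on the raw
#'   patch).
#' @param n_blocks Number of conv blocks.
#' @param base_channels Channels per block (growth rate for the dense
#'   family).
#' @param input_shape Patch `c(height, width)` in samples x lines.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("dense_style", "residual_style",
                                       "linear_baseline"),
                            n_blocks = 3, base_channels = 8,
                            input_shape = c(200, 26)) {
  family <- match.arg(family)
  stopifnot_scalar(n_blocks, "n_blocks")
  stopifnot_scalar(base_channels, "base_channels", positive = TRUE)
  if (n_blocks < 0) stop("n_blocks must be >= 0", call. = FALSE)
  structure(
    list(family = family, n_blocks = as.integer(n_blocks),
         base_channels = as.integer(base_channels),
         input_shape = as.integer(input_shape)),
    class = "classifier_spec")
}

#' Default victim and perpetrator architectures
#'
#' The victim uses the dense-concatenation family and the perpetrator the
#' residual family, preserving the architecture mismatch between the two
#' sides.
#'
#' @param input_shape Patch `c(height, width)`.
#' @return A [classifier_spec()].
#' @export
victim_classifier_spec <- function(input_shape = c(200, 26)) {
  classifier_spec("dense_style", n_blocks = 3, base_channels = 8,
                  input_shape = input_shape)
}

#' @rdname victim_classifier_spec
#' @export
perpetrator_classifier_spec <- function(input_shape = c(200, 26)) {
  classifier_spec("residual_style", n_blocks = 2, base_channels = 12,
                  input_shape = input_shape)
}

#' Training configuration
#'
#' Adam optimization of the binary cross-entropy
#' `-(y log(p) + (1 - y) log(1 - p))` with per-epoch horizontal-flip
#' augmentation. Desk-scale defaults (learning rate 2e-3, 12 epochs,
#' batches of 64 patches) suit the reduced architectures; the full-scale
#' protocol for the large networks would be learning rate 1e-5, 10
#' epochs, batches of 2048.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (no early stopping).
#' @param batch_size Patches per batch.
#' @param augment_probability Horizontal flip probability.
#' @param seed Integer seed for shuffling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-3, epochs = 12,
                         batch_size = 64, augment_probability = 0.5,
                         seed = 1L) {
  stopifnot_scalar(learning_rate, "learning_rate", positive = TRUE)
  stopifnot_scalar(epochs, "epochs", positive = TRUE)
  stopifnot_scalar(batch_size, "batch_size", positive = TRUE)
  if (augment_probability < 0 || augment_probability > 1) {
    stop("augment_probability must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         augment_probability = augment_probability,
         seed = as.integer(seed)),
    class = "train_config")
}

#' Build an untrained classifier
#'
#' Parameters are initialized from a uniform distribution bounded by
#' `1/sqrt(fan_in)`, deterministically given the seed.
#'
#' @param spec A [classifier_spec()].
#' @param seed Integer seed.
#' @return An object of class `qus_classifier`.
#' @export
build_classifier <- function(spec, seed = 1L) {
  if (!inherits(spec, "classifier_spec")) {
    stop("'spec' must be a classifier_spec", call. = FALSE)
  }
  params <- with_seed(seed, nn_init_params(spec))
  structure(
    list(spec = spec, params = params, seed = as.integer(seed),
         loss_history = numeric(0)),
    class = "qus_classifier")
}

#' @export
print.qus_classifier <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<qus_classifier> %s, %d blocks, %d channels, %s parameters (%s)\n",
              x$spec$family, x$spec$n_blocks, x$spec$base_channels,
              format(n_par, big.mark = ","),
              if (length(x$loss_history)) "trained" else "untrained"))
  invisible(x)
}

# Pull the (n, h, w) sample array out of a patch_set or pass arrays through.
patch_array <- function(patches) {
  if (inherits(patches, "patch_set")) patches$patches else patches
}

#' Train a classifier on standardized patches
#'
#' Minimizes the mean binary cross-entropy with Adam. Each epoch shuffles
#' the data, applies flip augmentation at batch assembly and records the
#' mean batch loss. When `anchor_noise_rate` is given, every epoch first
#' scores all samples in a no-update pass and trains only on the
#' `(1 - noise_rate)` fraction with the smallest losses (small-loss
#' anchors); this is the training mode the iterative denoising engine
#' uses on pseudo-labeled data.
#'
#' @param model A [build_classifier()] model.
#' @param patches A `patch_set` or n x h x w array of standardized
#'   patches.
#' @param labels Binary labels (0/1), one per patch.
#' @param cfg A [train_config()].
#' @param anchor_noise_rate Optional assumed label noise rate in `[0, 1)`.
#' @return The trained model, with `loss_history` (per epoch).
#' @export
train <- function(model, patches, labels, cfg = train_config(),
                  anchor_noise_rate = NULL) {
  X <- patch_array(patches)
  n <- dim(X)[1]
  y <- as.numeric(labels)
  if (length(y) != n) stop("one label per patch required", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    warning("training labels contain a single class")
  }
  params <- model$params
  state <- adam_init(params)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    keep <- seq_len(n)
    if (!is.null(anchor_noise_rate)) {
      logits <- nn_predict_logits(params, model$spec, X)
      keep <- select_anchors(bce_from_logits(logits, y), anchor_noise_rate)
    }
    res <- with_seed(derive_seed(cfg$seed, ep, 37L), {
      idx <- sample(keep)
      nn_epoch(params, state, model$spec, X, y, idx, cfg$learning_rate,
               cfg$batch_size, cfg$augment_probability)
    })
    params <- res$params
    state <- res$state
    history[ep] <- res$loss
  }
  model$params <- params
  model$loss_history <- c(model$loss_history, history)
  model
}

#' Score patches with a classifier
#'
#' @param model A `qus_classifier`.
#' @param patches A `patch_set` or n x h x w array, standardized with the
#'   same patch-wise z-score rule used in training.
#' @return Scores in (0, 1), one per patch, independent of batch order.
#' @export
predict_scores <- function(model, patches) {
  X <- patch_array(patches)
  if (!identical(as.integer(dim(X)[2:3]), model$spec$input_shape)) {
    stop("patch shape does not match the classifier input shape",
         call. = FALSE)
  }
  sigmoid(nn_predict_logits(model$params, model$spec, X))
}

#' @export
predict.qus_classifier <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}
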