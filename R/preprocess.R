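#' Multirate FIR resampling of an RF frame
#'
#' Changes the sampling rate by a rational factor `up/down` with a
#' polyphase anti-aliasing FIR filter, the standard way to harmonize data
#' from machines digitizing at different rates. Converting 50 MHz
#' perpetrator data to the victim's 40 MHz grid uses the default factors
#' up = 4, down = 5.
#'
#' @param frame An `rf_frame`.
#' @param up,down Positive integer rate factors.
#' @return An `rf_frame` at `sampling_rate * up / down` with
#'   `ceiling(n * up / down)` axial samples.
#' @export
resample_rate <- function(frame, up = 4, down = 5) {
  if (up != round(up) || down != round(down) || up < 1 || down < 1) {
    stop("up and down must be positive integers", call. = FALSE)
  }
  up <- as.integer(up); down <- as.integer(down)
  if (up == 1L && down == 1L) return(frame)
  x <- frame$samples
  y <- apply(x, 2, function(col) signal::resample(col, up, down))
  n_out <- as.integer(ceiling(nrow(x) * up / down))
  if (nrow(y) != n_out) {
    y <- if (nrow(y) > n_out) y[seq_len(n_out), , drop = FALSE] else
      rbind(y, matrix(0, n_out - nrow(y), ncol(y)))
  }
  out <- frame
  out$samples <- y
  out$sampling_rate <- frame$sampling_rate * up / down
  out$axial_spacing <- frame$axial_spacing * down / up
  out
}

#' Patch-extraction configuration
#'
#' Defaults follow the full-scale frame layout: skip the first 540 axial
#' samples (dead zone / near field), then tile 200 x 26-sample patches
#' (about 4 x 4 mm) with axial step 100 and lateral step 26. On a
#' 2080 x 256 frame this yields a 9 x 9 grid of 81 patches. With
#' `equalize_counts` the axial count is truncated to the lateral count so
#' both directions contribute equally.
#'
#' @param axial_skip Axial samples skipped before the first patch row.
#' @param patch_height,patch_width Patch size in samples x lines.
#' @param axial_step,lateral_step Grid strides.
#' @param equalize_counts Truncate the axial count to the lateral count.
#' @return An object of class `patch_config`.
#' @export
patch_config <- function(axial_skip = 540, patch_height = 200,
                         patch_width = 26, axial_step = 100,
                         lateral_step = 26, equalize_counts = TRUE) {
  for (nm in c("axial_skip", "patch_height", "patch_width", "axial_step",
               "lateral_step")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 ||
        (nm != "axial_skip" && v <= 0)) {
      stop(sprintf("'%s' must be a positive scalar", nm), call. = FALSE)
    }
  }
  structure(
    list(axial_skip = as.integer(axial_skip),
         patch_height = as.integer(patch_height),
         patch_width = as.integer(patch_width),
         axial_step = as.integer(axial_step),
         lateral_step = as.integer(lateral_step),
         equalize_counts = isTRUE(equalize_counts)),
    class = "patch_config")
}

#' Extract a regular grid of RF patches
#'
#' Tiles each frame with patches on a 0-based, half-open grid: lateral
#' starts run `0, lateral_step, ...` while a full patch still fits, axial
#' starts run `axial_skip, axial_skip + axial_step, ...` likewise, and
#' with `equalize_counts` the axial list is truncated to the lateral
#' count. Patches are emitted row-major (axial outer, lateral inner).
#'
#' @param x An `rf_frame`, or a dataset list with `frames` and `labels`
#'   as returned by [simulate_dataset()].
#' @param cfg A [patch_config()].
#' @return An object of class `patch_set`: `patches` (array n x height x
#'   width), `coords` (data frame of `frame_index`, `axial_start`,
#'   `lateral_start`; 0-based), optional `labels`, and a `provenance`
#'   flag.
#' @export
extract_patches <- function(x, cfg = patch_config()) {
  if (inherits(x, "rf_frame")) {
    frames <- list(x)
    labels <- NULL
  } else if (is.list(x) && !is.null(x$frames)) {
    frames <- x$frames
    labels <- x$labels
  } else {
    stop("'x' must be an rf_frame or a dataset list", call. = FALSE)
  }
  grid <- patch_grid(dim(frames[[1]]$samples), cfg)
  n_per <- nrow(grid)
  n <- n_per * length(frames)
  patches <- array(0, c(n, cfg$patch_height, cfg$patch_width))
  coords <- data.frame(frame_index = rep(seq_along(frames), each = n_per),
                       axial_start = rep(grid$axial_start, length(frames)),
                       lateral_start = rep(grid$lateral_start, length(frames)))
  k <- 0L
  for (f in seq_along(frames)) {
    s <- frames[[f]]$samples
    if (!identical(dim(s), dim(frames[[1]]$samples))) {
      stop("all frames must share dimensions", call. = FALSE)
    }
    for (g in seq_len(n_per)) {
      k <- k + 1L
      a0 <- grid$axial_start[g]; l0 <- grid$lateral_start[g]
      patches[k, , ] <- s[(a0 + 1L):(a0 + cfg$patch_height),
                          (l0 + 1L):(l0 + cfg$patch_width)]
    }
  }
  structure(
    list(patches = patches, coords = coords,
         labels = if (!is.null(labels)) rep(labels, each = n_per),
         provenance = "raw",
         sampling_rate = frames[[1]]$sampling_rate,
         axial_spacing = frames[[1]]$axial_spacing),
    class = "patch_set")
}

# Admissible 0-based patch starts for a frame of the given dimensions.
patch_grid <- function(frame_dim, cfg) {
  height <- frame_dim[1]; width <- frame_dim[2]
  if (height < cfg$axial_skip + cfg$patch_height ||
      width < cfg$patch_width) {
    stop("frame too small for the patch configuration", call. = FALSE)
  }
  lat <- seq(0L, width - cfg$patch_width, by = cfg$lateral_step)
  ax <- seq(cfg$axial_skip, height - cfg$patch_height, by = cfg$axial_step)
  if (cfg$equalize_counts && length(ax) > length(lat)) {
    ax <- ax[seq_len(length(lat))]
  }
  data.frame(axial_start = rep(ax, each = length(lat)),
             lateral_start = rep(lat, times = length(ax)))
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf("<patch_set> %d patches of %d x %d (%s%s)\n", d[1], d[2], d[3],
              x$provenance,
              if (is.null(x$labels)) ", unlabeled" else ", labeled"))
  invisible(x)
}

#' Subset a patch_set by patch indices
#'
#' @param ps A `patch_set`.
#' @param idx Patch indices to keep.
#' @return A `patch_set` with the selected patches, coordinates and (if
#'   present) labels.
#' @export
subset_patches <- function(ps, idx) {
  ps$patches <- ps$patches[idx, , , drop = FALSE]
  ps$coords <- ps$coords[idx, , drop = FALSE]
  if (!is.null(ps$labels)) ps$labels <- ps$labels[idx]
  ps
}

#' Patch-wise z-score standardization
#'
#' Subtracts each patch's mean and divides by its population standard
#' deviation, the standardization applied before every classifier
#' training or scoring pass.
#'
#' @param x A `patch_set`, a single patch matrix, or an n x h x w array.
#' @return Same shape, each patch with mean 0 and standard deviation 1.
#' @export
zscore_patches <- function(x) {
  if (inherits(x, "patch_set")) {
    x$patches <- zscore_patches(x$patches)
    return(x)
  }
  if (is.matrix(x)) {
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s == 0) stop("zero-variance patch cannot be standardized",
                     call. = FALSE)
    return((x - m) / s)
  }
  if (length(dim(x)) != 3L) stop("expected a matrix or 3-d array",
                                 call. = FALSE)
  n <- dim(x)[1]
  flat <- matrix(x, nrow = n)   # patches are rows
  m <- rowMeans(flat)
  s <- sqrt(rowMeans((flat - m)^2))
  if (any(s == 0)) stop("zero-variance patch cannot be standardized",
                        call. = FALSE)
  array((flat - m) / s, dim(x))
}

#' Random horizontal flip augmentation
#'
#' Reverses the lateral axis of each patch independently with the given
#' probability, using the current RNG stream (training seeds it).
#'
#' @param x A single patch matrix or an n x h x w array.
#' @param probability Flip probability in `[0, 1]`.
#' @return Same shape as `x`.
#' @export
augment_flip <- function(x, probability = 0.5) {
  if (probability < 0 || probability > 1) {
    stop("probability must be in [0, 1]", call. = FALSE)
  }
  if (is.matrix(x)) {
    if (stats::runif(1) < probability) x[, rev(seq_len(ncol(x)))] else x
  } else {
    n <- dim(x)[1]
    flip <- stats::runif(n) < probability
    if (any(flip)) {
      x[flip, , ] <- x[flip, , rev(seq_len(dim(x)[3])), drop = FALSE]
    }
    x
  }
}

#' Frame-level dataset splits
#'
#' Splits frames (never individual patches, so no patch leakage across
#' subsets) into named subsets with class-stratified, seed-deterministic
#' allocation. Rounding remainders are balanced across classes so that
#' subsets hit their target sizes as closely as possible.
#'
#' @param labels Integer class label per frame.
#' @param scheme Named fractions summing to 1; see
#'   [victim_split_scheme()] and [perpetrator_split_scheme()].
#' @param seed Integer seed.
#' @return Named list of frame-index vectors (disjoint, covering all
#'   frames).
#' @export
split_frames <- function(labels, scheme, seed = 1L) {
  if (abs(sum(scheme) - 1) > 1e-8) {
    stop("scheme fractions must sum to 1", call. = FALSE)
  }
  if (is.null(names(scheme)) || any(names(scheme) == "")) {
    stop("scheme must be a named vector", call. = FALSE)
  }
  subsets <- stats::setNames(vector("list", length(scheme)), names(scheme))
  for (j in seq_along(subsets)) subsets[[j]] <- integer(0)
  deficit <- stats::setNames(numeric(length(scheme)), names(scheme))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- with_seed(derive_seed(seed, as.integer(cl), 31L), sample(idx))
    n <- length(idx)
    base <- floor(n * scheme)
    rem <- n - sum(base)
    frac_part <- n * scheme - base
    if (rem > 0) {
      ord <- order(-frac_part, -deficit, seq_along(scheme))
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    }
    deficit <- deficit + n * scheme - base
    pos <- 0L
    for (j in seq_along(scheme)) {
      if (base[j] > 0) {
        subsets[[j]] <- c(subsets[[j]], idx[(pos + 1L):(pos + base[j])])
        pos <- pos + base[j]
      }
    }
  }
  if (any(vapply(subsets, length, 1L) == 0L)) {
    stop("scheme yields an empty subset", call. = FALSE)
  }
  lapply(subsets, sort)
}

#' Standard split schemes
#'
#' The victim machine's frames are split 80/20 into training and
#' validation. The perpetrator machine's frames are split 50/50 into a
#' held-out test set and a working set, and the working set into 90/10
#' training/validation — for 2000 frames: 1000 test, 900 training, 100
#' validation.
#'
#' @return Named fraction vector for [split_frames()].
#' @export
victim_split_scheme <- function() {
  c(train = 0.8, validation = 0.2)
}

#' @rdname victim_split_scheme
#' @export
perpetrator_split_scheme <- function() {
  c(test = 0.5, train = 0.45, validation = 0.05)
}
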