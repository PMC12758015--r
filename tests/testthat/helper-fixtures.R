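# Shared fixtures for the unit tests. Everything here is deliberately
# small: a short-depth geometry and a matching patch configuration so
# simulator-backed tests run in seconds. Expensive end-to-end runs live
# in test-acceptance.R only.

# Memoized store so several test files can reuse one simulation.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Quarter-depth geometry: 260 x 32 at 40 MHz (about 5 mm x 4.7 mm).
tiny_geometry <- function() frame_geometry(n_axial_ref = 260, n_lines = 32)

# Patch layout matched to the tiny geometry: 100 x 8 patches.
tiny_patch_config <- function() {
  patch_config(axial_skip = 40, patch_height = 100, patch_width = 8,
               axial_step = 50, lateral_step = 8)
}

# Synthetic separable "patches": two classes of filtered noise textures
# that a small model can tell apart without running the RF simulator.
toy_patches <- function(n_per_class = 40, h = 32, w = 8, seed = 99) {
  with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(stats::rnorm(n * h * w), c(n, h, w))
    labels <- rep(0:1, each = n_per_class)
    t_ax <- seq_len(h)
    for (i in which(labels == 1)) {
      x[i, , ] <- x[i, , ] + 2 * sin(2 * pi * t_ax / 8)
    }
    list(x = zscore_patches(x), labels = labels)
  })
}
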