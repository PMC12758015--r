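test_that("percentile pseudo-labeling follows the rank rule", {
  expect_equal(pseudo_label(c(0.1, 0.2, 0.6, 0.9), 50), c(0L, 0L, 1L, 1L))
  # ties broken by index: exactly two zeros at the first two positions
  expect_equal(pseudo_label(rep(0.5, 4), 50), c(0L, 0L, 1L, 1L))
  # order of the scores, not their values, decides
  expect_equal(pseudo_label(c(5, 1, 3), 50), c(1L, 0L, 1L))
  expect_error(pseudo_label(numeric(0)), "empty")
  expect_error(pseudo_label(c(1, NA)), "finite")
})

test_that("pseudo-labeling matches a sort-based oracle on 1000 scores", {
  s <- with_seed(10, stats::runif(1000))
  y <- pseudo_label(s, 40)
  expect_equal(sum(y == 0), 400)
  # oracle: the 400 smallest scores get label 0
  oracle <- as.integer(!(seq_along(s) %in% order(s)[1:400]))
  expect_equal(y, oracle)
  # label balance at the median: counts differ by <= 1
  y50 <- pseudo_label(s[1:999], 50)
  expect_lte(abs(sum(y50 == 0) - sum(y50 == 1)), 1)
})

test_that("anchor selection keeps the (1 - noise_rate) smallest losses", {
  losses <- c(5, 1, 3, 2, 4, 0.5, 6, 2.5, 7, 1.5)
  expect_equal(select_anchors(losses, 0.2), sort(order(losses)[1:8]))
  expect_equal(select_anchors(losses, 0), 1:10)
  # randomized agreement with a brute-force full sort
  l2 <- with_seed(3, stats::rnorm(500))
  for (eps in c(0.1, 0.37, 0.8)) {
    k <- round((1 - eps) * 500)
    expect_equal(select_anchors(l2, eps), sort(order(l2)[1:k]))
  }
  expect_error(select_anchors(numeric(0), 0.2), "no losses")
  expect_error(select_anchors(losses, 1), "noise_rate")
})

test_that("evaluate computes accuracy and the pairwise-tie AUC", {
  s <- c(0.9, 0.8, 0.2, 0.1)
  y <- c(1, 1, 0, 0)
  r <- evaluate(s, y)
  expect_equal(r$accuracy, 100)
  expect_equal(r$auc, 1)
  # all-tied scores on balanced labels: AUC one half
  expect_equal(evaluate(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(evaluate(s, c(1, 1, 1, 1)), "single-class")
})

test_that("rank AUC equals the brute-force pairwise oracle and pROC", {
  set.seed(17)
  s <- round(stats::runif(200), 2)             # rounding forces ties
  y <- stats::rbinom(200, 1, 0.5)
  auc <- evaluate(s, y)$auc
  pos <- s[y == 1]
  neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc, mean(cmp), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc, ref, tolerance = 1e-9)
  }
})

test_that("aggregate_runs reports mean and sd across seeds", {
  res <- list(list(accuracy = 90, auc = 0.9, n = 10),
              list(accuracy = 94, auc = 1.0, n = 10))
  agg <- aggregate_runs(res)
  expect_equal(agg$n_seeds, 2)
  expect_equal(agg$accuracy_mean, 92)
  expect_equal(agg$accuracy_sd, stats::sd(c(90, 94)))
  expect_equal(agg$auc_mean, 0.95)
})

test_that("iterlnl_config validates the priors", {
  expect_error(iterlnl_config(noise_rate = 1), "noise_rate")
  expect_error(iterlnl_config(label_percentile = 0), "percentile")
  expect_error(iterlnl_config(n_cycles = -1), "n_cycles")
  expect_equal(iterlnl_config()$noise_rate, 0.2)
  expect_equal(iterlnl_config()$label_percentile, 50)
})

test_that("an oracle victim with no domain shift reduces to supervised learning", {
  # scores equal to the true labels, Gamma absent: pseudo-labels are exact
  # and the migration is plain supervised training
  toy <- toy_patches(n_per_class = 40)
  # build an unlabeled patch_set around the toy data
  ps <- structure(list(patches = toy$x,
                       coords = data.frame(frame_index = seq_len(80),
                                           axial_start = 0L,
                                           lateral_start = 0L),
                       labels = NULL, provenance = "raw",
                       sampling_rate = 40, axial_spacing = 0.01925),
                  class = "patch_set")
  oracle <- victim_interface(local({
    labs <- toy$labels
    function(X) labs
  }), input_shape = c(32, 8))
  spec <- classifier_spec("residual_style", n_blocks = 1, base_channels = 4,
                          input_shape = c(32, 8))
  mig <- run_iterlnl(oracle, NULL, ps, spec,
                     iterlnl_config(n_cycles = 0, seed = 1),
                     train_config(epochs = 20, batch_size = 16, seed = 2))
  expect_s3_class(mig, "qus_migration")
  expect_equal(mig$initial_labels, toy$labels)
  expect_identical(mig$final_labels, mig$initial_labels)  # no cycles
  expect_equal(nrow(mig$trace), 0)
  expect_equal(mig$query_count, 80)
  expect_false(mig$used_transfer_function)
  r <- evaluate(mig, toy$labels, patches = ps)
  expect_gte(r$accuracy, 99)
})

test_that("denoising cycles run, trace and stay reproducible", {
  toy <- toy_patches(n_per_class = 30)
  ps <- structure(list(patches = toy$x,
                       coords = data.frame(frame_index = seq_len(60),
                                           axial_start = 0L,
                                           lateral_start = 0L),
                       labels = NULL, provenance = "raw",
                       sampling_rate = 40, axial_spacing = 0.01925),
                  class = "patch_set")
  # noisy oracle: 20% of scores flipped, fixed pattern
  noisy_scores <- with_seed(8, {
    s <- as.numeric(toy$labels)
    fl <- sample(60, 12)
    s[fl] <- 1 - s[fl]
    s
  })
  vic <- victim_interface(local({
    sc <- noisy_scores
    function(X) sc
  }), input_shape = c(32, 8))
  spec <- classifier_spec("residual_style", n_blocks = 1, base_channels = 4,
                          input_shape = c(32, 8))
  cfg <- iterlnl_config(n_cycles = 2, seed = 4)
  tc <- train_config(epochs = 10, batch_size = 16, seed = 2)
  mig1 <- run_iterlnl(vic, NULL, ps, spec, cfg, tc)
  mig2 <- run_iterlnl(vic, NULL, ps, spec, cfg, tc)
  expect_identical(mig1$model$params, mig2$model$params)
  expect_identical(mig1$final_labels, mig2$final_labels)
  expect_equal(nrow(mig1$trace), 2)
  expect_named(mig1$trace,
               c("cycle", "train_loss", "val_loss", "label_flip_fraction"))
  expect_true(all(is.finite(unlist(mig1$trace))))
  # label balance is conserved by percentile relabeling
  expect_lte(abs(sum(mig1$final_labels == 0) -
                   sum(mig1$final_labels == 1)), 1)
  # the victim was queried exactly once for the working set
  expect_equal(query_count(vic), 2 * 60)       # two runs, one pass each
  expect_output(print(mig1), "2 denoising cycles")
  expect_output(summary(mig1), "Per-cycle trace")
})

test_that("the engine touches the victim only through query", {
  # a victim that counts calls proves the engine cannot bypass query():
  # the score function is opaque and carries no parameters
  calls <- new.env(); calls$n <- 0L
  vic <- victim_interface(function(X) {
    calls$n <- calls$n + 1L
    rowMeans(matrix(X, nrow = dim(X)[1]))^0 * 0.5
  }, input_shape = c(32, 8))
  toy <- toy_patches(n_per_class = 8)
  ps <- structure(list(patches = toy$x,
                       coords = data.frame(frame_index = seq_len(16),
                                           axial_start = 0L,
                                           lateral_start = 0L),
                       labels = NULL, provenance = "raw",
                       sampling_rate = 40, axial_spacing = 0.01925),
                  class = "patch_set")
  spec <- classifier_spec("linear_baseline", input_shape = c(32, 8))
  mig <- run_iterlnl(vic, NULL, ps, spec,
                     iterlnl_config(n_cycles = 0, seed = 1),
                     train_config(epochs = 1, batch_size = 8, seed = 1))
  expect_equal(calls$n, 1L)                    # exactly one scoring pass
  expect_error(run_iterlnl(list(), NULL, ps, spec), "victim_interface")
})
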