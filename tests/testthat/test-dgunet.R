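test_that("the Gaussian kernel matches direct formula evaluation", {
  # independent oracle: elementwise evaluation of the Gaussian, then
  # normalization — written separately from the implementation
  oracle <- function(k, sigma) {
    mu <- (k - 1) / 2
    m <- matrix(0, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        m[i, j] <- 1 / (2 * pi * sigma^2) *
          exp(-(((i - 1) - mu)^2 + ((j - 1) - mu)^2) / (2 * sigma^2))
      }
    }
    m / sum(m)
  }
  for (k in c(1L, 3L, 9L)) {
    for (sigma in c(0.5, 1.7, 5)) {
      expect_equal(gaussian_kernel(k, sigma), oracle(k, sigma),
                   tolerance = 1e-12)
    }
  }
  expect_equal(gaussian_kernel(1L, 2), matrix(1), tolerance = 1e-12)

  # conservation and symmetry across the parameter grid
  for (k in c(1L, 3L, 5L, 7L, 9L, 13L)) {
    for (sigma in c(0.5, 1, 1.7, 5)) {
      g <- gaussian_kernel(k, sigma)
      expect_lt(abs(sum(g) - 1), 1e-9)
      expect_equal(g, t(g))
      expect_equal(g, g[k:1, k:1, drop = FALSE])
    }
  }

  # flat limit
  expect_equal(gaussian_kernel(9L, 1e6), matrix(1 / 81, 9, 9),
               tolerance = 1e-9)

  expect_error(gaussian_kernel(9L, 0), "positive")
  expect_error(gaussian_kernel(8L, 1), "odd")
})

test_that("Gaussian smoothing preserves constants and never adds variance", {
  const <- matrix(0.37, 20, 20)
  expect_equal(gaussian_smooth(const, 9, 1.7), const, tolerance = 1e-12)

  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 1
  sm <- gaussian_smooth(imp, 9, 1.7)
  expect_equal(sm[17:25, 17:25], gaussian_kernel(9, 1.7), tolerance = 1e-12)

  set.seed(10)
  for (i in 1:100) {
    x <- matrix(rnorm(24 * 24), 24, 24)
    expect_lte(var(as.vector(gaussian_smooth(x, 5, 1))),
               var(as.vector(x)) + 1e-12)
  }
})

test_that("all variants forward to same-size probability maps", {
  x <- matrix(runif(64 * 64), 64, 64)
  for (v in c("unet", "gu_net", "du_net", "dgu_net")) {
    net <- build_network(network_config(v, base_channels = 2L, depth = 5L,
                                        seed = 3))
    p <- predict_prob(net, x)
    expect_equal(dim(p), c(64L, 64L))
    expect_true(all(p > 0 & p < 1))
  }

  # non-divisible sizes reflect-pad then crop back
  net <- build_network(network_config("dgu_net", base_channels = 2L,
                                      depth = 5L, seed = 3))
  p <- predict_prob(net, matrix(runif(70 * 90), 70, 90))
  expect_equal(dim(p), c(70L, 90L))

  # unet and gu_net differ only by fixed (parameter-free) smoothing stages
  n_params <- function(v) {
    net <- build_network(network_config(v, base_channels = 2L, depth = 5L,
                                        seed = 3))
    sum(vapply(clemosaic:::network_params(net),
               function(p) length(p$value), 0))
  }
  expect_identical(n_params("unet"), n_params("gu_net"))
})

test_that("segmentation metrics agree with hand-counted confusion tables", {
  m <- matrix(0, 10, 10)
  m[3:6, 3:6] <- 1
  perfect <- segmentation_metrics(m, m)
  for (v in perfect) expect_equal(v, 100)

  disj <- matrix(0, 10, 10)
  disj[8:9, 8:9] <- 1
  md <- segmentation_metrics(disj, m)
  expect_equal(md$dice, 0)
  expect_equal(md$ja, 0)
  expect_equal(md$se, 0)

  # 2x2 image: TP=1, FP=1, FN=1, TN=1
  pred <- matrix(c(1, 1, 0, 0), 2, 2)
  truth <- matrix(c(1, 0, 1, 0), 2, 2)
  ms <- segmentation_metrics(pred, truth)
  expect_equal(ms$ac, 50)
  expect_equal(ms$dice, 50)
  expect_equal(ms$ja, 100 / 3)
  expect_equal(ms$se, 50)
  expect_equal(ms$sp, 50)

  expect_error(segmentation_metrics(m, matrix(0, 5, 5)), "differ")

  # Dice = 200 JA / (100 + JA) from the same counts
  set.seed(2)
  for (i in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    mm <- segmentation_metrics(a, b)
    expect_equal(mm$dice, 200 * mm$ja / (100 + mm$ja), tolerance = 1e-9)
  }
})

test_that("mask prediction thresholds behave monotonically", {
  net <- build_network(network_config("unet", base_channels = 2L, depth = 2L,
                                      seed = 5))
  x <- matrix(runif(32 * 32), 32, 32)
  expect_true(all(predict_mask(net, x, threshold = 0) == 1))
  expect_true(all(predict_mask(net, x, threshold = 1) == 0))
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8),
                  function(t) sum(predict_mask(net, x, t)), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("training runs deterministically with finite losses", {
  ds <- fixture("tiny_train_ds", make_seg_dataset(6, size = 64L))
  tc <- train_config(learning_rate = 1e-3, epochs = 3L, batch_size = 2L,
                     split_fraction = 0.8, split_seed = 2, max_steps = 12)
  net <- build_network(network_config("dgu_net", base_channels = 4L,
                                      depth = 3L, seed = 7))
  res <- train_network(net, ds, tc)
  expect_true(all(is.finite(res$loss_history)))
  expect_true(all(is.finite(res$val_dice)))
  expect_length(intersect(res$train_idx, res$val_idx), 0)
  expect_setequal(c(res$train_idx, res$val_idx), 1:6)

  # identical configuration reproduces the identical split
  res2 <- train_network(build_network(network_config("dgu_net",
                                                     base_channels = 4L,
                                                     depth = 3L, seed = 7)),
                        ds, tc)
  expect_identical(res$train_idx, res2$train_idx)
  expect_equal(res$loss_history, res2$loss_history, tolerance = 1e-12)

  # reference training protocol is the default configuration
  tc_default <- train_config()
  expect_equal(tc_default$learning_rate, 5e-5)
  expect_identical(tc_default$epochs, 100L)
  expect_identical(tc_default$batch_size, 2L)
  expect_equal(tc_default$split_fraction, 0.8)
  expect_identical(tc_default$loss, "bce")
})

test_that("every variant learns the synthetic gland benchmark", {
  ds <- fixture("variant_ds", make_seg_dataset(12, size = 64L, seed0 = 300L))
  for (v in c("unet", "gu_net", "du_net", "dgu_net")) {
    net <- build_network(network_config(v, base_channels = 4L, depth = 3L,
                                        seed = 2))
    res <- train_network(net, ds,
                         train_config(learning_rate = 2e-3, epochs = 20L,
                                      batch_size = 2L, split_fraction = 0.75,
                                      split_seed = 3, max_steps = 60))
    dice <- evaluate_segmentation(net, ds[res$val_idx])$dice
    expect_gt(dice, 70)
  }
})
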