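zero_flow <- function(h, w) list(fx = matrix(0, h, w), fy = matrix(0, h, w))

test_that("flow interpolation honours its endpoint and blend identities", {
  g <- fixture("flow_frame", generate_gland_image(scene_textured(96,
                                                                 n_glands = 8,
                                                                 seed = 41)))
  i1 <- g$frame
  i2 <- pmin(i1 + 0.1, 1)
  z <- zero_flow(96, 96)

  expect_identical(interpolate_frame(i1, i2, z, z, 0), i1)
  expect_identical(interpolate_frame(i1, i2, z, z, 1), i2)
  expect_equal(interpolate_frame(i1, i2, z, z, 0.5), (i1 + i2) / 2,
               tolerance = 1e-12)
  expect_error(interpolate_frame(i1, i2, z, z, 1.5), "alpha")

  # integer translation with exact constant flow: midpoint is the
  # half-shifted frame (oracle: direct shifted-average construction)
  d <- 6
  i2t <- matrix(0.25, 96, 96)
  i2t[, (d + 1):96] <- i1[, 1:(96 - d)]
  cf <- list(fx = matrix(-d, 96, 96), fy = matrix(0, 96, 96))
  mid <- interpolate_frame(i1, i2t, cf, cf, 0.5)
  oracle <- matrix(0.25, 96, 96)
  oracle[, (d / 2 + 1):96] <- i1[, 1:(96 - d / 2)]
  expect_equal(mid[, 8:90], oracle[, 8:90], tolerance = 1e-9)
})

test_that("dense flow recovers translations", {
  g <- fixture("flow_frame", generate_gland_image(scene_textured(96,
                                                                 n_glands = 8,
                                                                 seed = 41)))
  f2 <- warp_with_homography(g$frame, translation_h(3, -2), fill = 0.25)
  fl <- estimate_flow(g$frame, f2)
  expect_equal(median(fl$fx), 3, tolerance = 0.05)
  expect_equal(median(fl$fy), -2, tolerance = 0.05)
})

test_that("frame-count restoration is exact over random removal patterns", {
  frames <- replicate(4, matrix(runif(32 * 32), 32, 32), simplify = FALSE)

  # nothing removed
  out <- align_frame_count(frames, 1:4, 4)
  expect_identical(out, frames)

  # one frame removed between identical neighbours
  stat <- list(frames[[1]], frames[[1]])
  out2 <- align_frame_count(stat, c(1L, 3L), 3)
  expect_equal(out2[[2]], frames[[1]], tolerance = 1e-6)

  # output length restored for 50 random removal patterns
  set.seed(99)
  base <- replicate(12, matrix(0.5, 24, 24), simplify = FALSE)
  for (i in 1:50) {
    keep <- sort(sample(1:12, sample(2:11, 1)))
    out3 <- align_frame_count(base[keep], keep, 12)
    expect_length(out3, 12)
    expect_false(any(vapply(out3, is.null, TRUE)))
  }

  expect_error(align_frame_count(list(), integer(0), 5), "empty")
})

test_that("camera paths accumulate neighbouring transforms correctly", {
  g <- fixture("flow_frame", generate_gland_image(scene_textured(96,
                                                                 n_glands = 8,
                                                                 seed = 41)))
  static <- replicate(4, g$frame, simplify = FALSE)
  cp <- estimate_camera_path(static)
  expect_equal(cp$tx, rep(0, 4), tolerance = 1e-6)
  expect_equal(cp$ty, rep(0, 4), tolerance = 1e-6)
  for (tm in cp$transforms) expect_equal(tm, diag(3), tolerance = 1e-6)

  # constant probe translation (2, 0)/frame: tx after frame i ~ 2 i
  sc <- motion_script(5, unstable_fraction = 0, drift_px = 0, seed = 2)
  sc$displacements <- cbind(c(0, 2, 2, 2, 2), rep(0, 5))
  sc$stable <- rep(TRUE, 5)
  sq <- generate_sequence(scene_textured(128, seed = 51), sc)
  cp2 <- estimate_camera_path(sq$frames)
  expect_equal(cp2$tx, c(0, 2, 4, 6, 8), tolerance = 0.25)
  expect_equal(cp2$ty, rep(0, 5), tolerance = 0.5)

  # reversing the sequence negates the endpoint translation
  cp3 <- estimate_camera_path(rev(sq$frames))
  expect_equal(cp3$tx[5], -cp2$tx[5], tolerance = 0.25)

  expect_error(estimate_camera_path(sq$frames[1]), "at least 2")
})

test_that("jitter variance is the variance of path first differences", {
  mkpath <- function(tx, ty) list(tx = tx, ty = ty)
  # constant velocity: zero variance
  expect_equal(jitter_variance(mkpath(seq(0, 18, by = 2), rep(0, 10))),
               c(var_x = 0, var_y = 0))
  # alternating +/- d displacements: variance d^2 exactly
  d <- 3
  pos <- cumsum(c(0, rep(c(d, -d), 4))) # 8 first differences
  expect_equal(jitter_variance(mkpath(pos, pos)),
               c(var_x = d^2, var_y = d^2))
  # non-negativity on random walks
  set.seed(12)
  for (i in 1:10) {
    jv <- jitter_variance(mkpath(cumsum(rnorm(20)), cumsum(rnorm(20))))
    expect_true(all(jv >= 0))
  }
})

test_that("block sharpness scores match explicit operator evaluation", {
  const <- matrix(0.5, 128, 128)
  for (met in c("laplacian", "sobel", "brenner")) {
    gr <- block_sharpness(const, 64, met)
    expect_true(all(gr$valid))
    expect_equal(as.vector(gr$scores), rep(0, 4), tolerance = 1e-18)
  }

  # one textured block among constant blocks
  tex <- const
  set.seed(3)
  tex[1:64, 1:64] <- 0.5 + 0.2 * matrix(runif(64 * 64) - 0.5, 64)
  gt <- block_sharpness(tex, 64, "laplacian")
  expect_gt(gt$scores[1, 1], 0)
  expect_equal(gt$scores[2, 2], 0, tolerance = 1e-18)

  # checkerboard block: oracle = explicit 3x3 Laplacian + variance
  cb <- matrix(((row(matrix(0, 128, 128)) + col(matrix(0, 128, 128))) %% 2),
               128, 128) * 0.5 + 0.25
  gcb <- block_sharpness(cb, 64, "laplacian")
  ref <- cb * 255
  # mirror (reflect-101) padding, matching the stated boundary convention
  pad <- rbind(ref[2, ], ref, ref[127, ])
  pad <- cbind(pad[, 2], pad, pad[, 127])
  lap <- matrix(0, 128, 128)
  for (i in 1:128) {
    for (j in 1:128) {
      lap[i, j] <- pad[i, j + 1] + pad[i + 2, j + 1] + pad[i + 1, j] +
        pad[i + 1, j + 2] - 4 * pad[i + 1, j + 1]
    }
  }
  blk <- lap[1:64, 1:64]
  expect_equal(gcb$scores[1, 1], mean((blk - mean(blk))^2), tolerance = 1e-9)

  # margin-containing blocks are invalid
  marg <- const
  marg[1:10, 1:10] <- 0
  gm <- block_sharpness(marg, 64, "laplacian")
  expect_false(gm$valid[1, 1])
  expect_true(gm$valid[2, 2])

  expect_error(block_sharpness(const, 64, "unknown"))
  expect_error(block_sharpness(const, 4), ">= 8")

  # uniformity equals the brute-force variance of valid scores
  g2 <- block_sharpness(tex, 32, "sobel")
  expect_equal(sharpness_uniformity(g2), var(g2$scores[g2$valid]))
  one_block <- block_sharpness(const, 128, "laplacian")
  expect_error(sharpness_uniformity(one_block), "2 valid")
})

test_that("registered-pair quality reports SSIM and RMSE faithfully", {
  g <- fixture("flow_frame", generate_gland_image(scene_textured(96,
                                                                 n_glands = 8,
                                                                 seed = 41)))
  frames <- replicate(3, g$frame, simplify = FALSE)
  q <- sequence_quality(frames, list(diag(3), diag(3)))
  expect_equal(q$ssim_mean, 1, tolerance = 1e-9)
  expect_equal(q$rmse_mean, 0, tolerance = 1e-9)

  # additive Gaussian noise of sd sigma: RMSE ~ 255 sigma
  set.seed(7)
  sigma <- 0.02
  rmses <- vapply(1:20, function(i) {
    noisy <- g$frame + matrix(rnorm(96 * 96, sd = sigma), 96, 96)
    sequence_quality(list(g$frame, noisy), list(diag(3)))$rmse_mean
  }, 0)
  expect_equal(mean(rmses), 255 * sigma, tolerance = 0.05)

  # bounds
  q2 <- sequence_quality(list(g$frame, 1 - g$frame), list(diag(3)))
  expect_true(q2$ssim_mean >= -1 && q2$ssim_mean <= 1)
  expect_gte(q2$rmse_mean, 0)
})
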