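test_that("mask filtering of keypoints is exact", {
  g <- fixture("kp_frame", generate_gland_image(scene_textured(128, seed = 21)))

  kp_all <- detect_keypoints(g$frame)
  ones <- matrix(1, 128, 128)
  kp_ones <- extract_masked_keypoints(g$frame, ones)
  expect_equal(kp_ones$pts, kp_all$pts)

  expect_warning(kp_none <- extract_masked_keypoints(g$frame,
                                                     matrix(0, 128, 128)),
                 "empty")
  expect_identical(nrow(kp_none$pts), 0L)

  # exhaustive per-keypoint mask lookup
  kp <- extract_masked_keypoints(g$frame, g$mask)
  expect_gt(nrow(kp$pts), 0)
  r <- pmin(pmax(round(kp$pts$y) + 1, 1), 128)
  c <- pmin(pmax(round(kp$pts$x) + 1, 1), 128)
  expect_true(all(g$mask[cbind(r, c)] == 1))

  # a mask covering only part of the scene removes exactly the outside points
  half <- matrix(0, 128, 128)
  half[, 1:64] <- g$mask[, 1:64]
  kph <- extract_masked_keypoints(g$frame, half)
  expect_true(all(round(kph$pts$x) <= 64))
})

test_that("ratio-test matching agrees with the brute-force oracle", {
  set.seed(15)
  mk_set <- function(d) {
    d <- d / sqrt(rowSums(d^2))
    structure(list(pts = data.frame(x = seq_len(nrow(d)), y = 1,
                                    scale = 1, orientation = 0),
                   desc = d),
              class = "keypoint_set")
  }
  a <- mk_set(matrix(runif(40 * 128), 40))
  # b holds perturbed copies of half of a (true correspondences) plus clutter
  b <- mk_set(rbind(matrix(runif(35 * 128), 35),
                    a$desc[1:20, ] + matrix(rnorm(20 * 128, sd = 0.02), 20)))

  m <- match_features(a, b, ratio = 0.8)
  expect_gt(nrow(m$pairs), 0)
  # oracle: all-pairs distances, two nearest neighbours, strict ratio test
  kept <- list()
  for (i in 1:40) {
    dd <- sqrt(colSums((t(b$desc) - a$desc[i, ])^2))
    o <- order(dd)
    if (dd[o[1]] < 0.8 * dd[o[2]]) {
      kept[[length(kept) + 1L]] <- c(i, o[1])
    }
  }
  expect_equal(unname(m$pairs), unname(do.call(rbind, kept)))

  # identical descriptor sets self-match at (numerically) zero distance
  ms <- match_features(a, a, ratio = 0.75)
  expect_equal(ms$pairs[, 1], ms$pairs[, 2])
  expect_lt(max(ms$distances), 1e-6)

  expect_identical(nrow(match_features(a, b, ratio = 0)$pairs), 0L)
  empty <- structure(list(pts = data.frame(x = numeric(0), y = numeric(0),
                                           scale = numeric(0),
                                           orientation = numeric(0)),
                          desc = matrix(0, 0, 128)), class = "keypoint_set")
  expect_identical(nrow(match_features(empty, b)$pairs), 0L)
})

synthetic_matchset <- function(pa, pb) {
  n <- nrow(pa)
  list(m = structure(list(pairs = cbind(seq_len(n), seq_len(n)),
                          distances = rep(0, n), ratio_used = 0.75),
                     class = "match_set"),
       a = structure(list(pts = data.frame(x = pa[, 1], y = pa[, 2],
                                           scale = 1, orientation = 0),
                          desc = matrix(0, n, 128)), class = "keypoint_set"),
       b = structure(list(pts = data.frame(x = pb[, 1], y = pb[, 2],
                                           scale = 1, orientation = 0),
                          desc = matrix(0, n, 128)), class = "keypoint_set"))
}

test_that("RANSAC homography estimation recovers exact and noisy models", {
  set.seed(22)
  pa <- cbind(runif(20, 0, 100), runif(20, 0, 100))

  # exact translation
  pb <- pa + matrix(rep(c(10, -4), each = 20), ncol = 2)
  s <- synthetic_matchset(pa, pb)
  h <- estimate_homography(s$m, s$a, s$b, seed = 5)
  expect_equal(h$matrix, translation_h(10, -4), tolerance = 1e-6)
  expect_identical(h$inlier_count, 20L)

  # identity correspondences
  s2 <- synthetic_matchset(pa, pa)
  h2 <- estimate_homography(s2$m, s2$a, s2$b, seed = 5)
  expect_equal(h2$matrix, diag(3), tolerance = 1e-6)
  expect_true(all(h2$inlier_mask))

  # 70% inliers from a known homography + 30% uniform outliers
  htrue <- matrix(c(1.02, 0.01, 1e-5, -0.015, 0.98, -2e-5, 8, -5, 1), 3, 3,
                  byrow = TRUE)
  set.seed(41)
  pin <- cbind(runif(140, 0, 200), runif(140, 0, 200))
  qin <- apply_h(htrue, pin)
  pout <- cbind(runif(60, 0, 200), runif(60, 0, 200))
  qout <- cbind(runif(60, 0, 200), runif(60, 0, 200))
  s3 <- synthetic_matchset(rbind(pin, pout), rbind(qin, qout))
  h3 <- estimate_homography(s3$m, s3$a, s3$b, seed = 9, max_iters = 1000)
  err <- mean(sqrt(rowSums((apply_h(h3$matrix, rbind(c(0, 0), c(199, 0),
                                                     c(0, 199), c(199, 199))) -
                              apply_h(htrue, rbind(c(0, 0), c(199, 0),
                                                   c(0, 199), c(199, 199))))^2)))
  expect_lt(err, 1)

  s4 <- synthetic_matchset(pa[1:3, ], pb[1:3, ])
  expect_error(estimate_homography(s4$m, s4$a, s4$b), "at least 4")
})

test_that("gain compensation solves the overlap normal equations", {
  f1 <- matrix(0.5, 48, 48)
  # identical intensities: regularizer optimum is unit gain
  g0 <- compensate_gain(list(f1, f1), list(diag(3), diag(3)))
  expect_equal(g0, c(1, 1), tolerance = 1e-9)

  # 1.2x brighter second frame in full overlap: closed-form 2x2 oracle
  f2 <- matrix(0.6, 48, 48)
  g <- compensate_gain(list(f1, f2), list(diag(3), diag(3)))
  sn <- 10 / 255; sg <- 0.1; nij <- 48 * 48
  amat <- matrix(c(nij * (0.5^2 / sn^2 + 1 / sg^2), -nij * 0.5 * 0.6 / sn^2,
                   -nij * 0.5 * 0.6 / sn^2, nij * (0.6^2 / sn^2 + 1 / sg^2)),
                 2, 2)
  oracle <- solve(amat, rep(nij / sg^2, 2))
  expect_equal(g, as.numeric(oracle), tolerance = 1e-9)
  expect_lt(abs(g[1] / g[2] - oracle[1] / oracle[2]), 0.02)
  # the unit-gain prior pulls both gains toward 1, so the recovered ratio
  # sits between 1 and the raw 1.2 brightness ratio
  expect_gt(g[1] / g[2], 1.1)
  expect_lte(g[1] / g[2], 1.2)

  # objective scaling: doubling both sigmas leaves the minimizer unchanged
  g2 <- compensate_gain(list(f1, f2), list(diag(3), diag(3)),
                        sigma_n = 2 * sn, sigma_g = 2 * sg)
  expect_equal(g2, g, tolerance = 1e-9)

  # disjoint placement: no overlap, gains fall back to 1
  off <- translation_h(200, 0)
  g3 <- compensate_gain(list(f1, f2), list(diag(3), off))
  expect_equal(g3, c(1, 1))
})

test_that("multi-band blending satisfies its reconstruction identities", {
  set.seed(6)
  img <- matrix(runif(96 * 128), 96, 128)
  full <- matrix(1, 96, 128)

  expect_equal(multiband_blend(list(img), list(full), n_bands = 4), img,
               tolerance = 1e-6)

  w <- matrix(runif(96 * 128, 0.1, 1), 96, 128)
  expect_equal(multiband_blend(list(img, img), list(w, 1 - w / 2),
                               n_bands = 4),
               img, tolerance = 1e-6)

  # n_bands = 1 is plain weighted averaging
  a <- matrix(0.2, 96, 128); b <- matrix(0.8, 96, 128)
  wa <- matrix(0, 96, 128); wa[, 1:64] <- 1
  direct <- 0.2 * wa + 0.8 * (1 - wa)
  expect_equal(multiband_blend(list(a, b), list(wa, 1 - wa), n_bands = 1),
               direct, tolerance = 1e-12)

  # hard seam between constants transitions monotonically across the seam
  mb <- multiband_blend(list(a, b), list(wa, 1 - wa), n_bands = 4)
  profile <- colMeans(mb)
  expect_true(all(diff(profile) >= -1e-9))
  expect_equal(profile[1], 0.2, tolerance = 1e-3)
  expect_equal(profile[128], 0.8, tolerance = 1e-3)

  expect_warning(multiband_blend(list(img), list(full), n_bands = 10),
                 "clamped")
})

test_that("stitching a stable sequence recovers the known translations", {
  sc <- motion_script(6, unstable_fraction = 0, drift_px = 0, seed = 2)
  sc$displacements <- cbind(c(0, 6, 5, -4, 6, 3), c(0, 3, -4, 5, 2, -3))
  sc$stable <- rep(TRUE, 6)
  p <- scene_textured(160, n_glands = 16, seed = 31)
  sq <- generate_sequence(p, sc)
  st <- stitch_sequence(sq$frames, sq$masks,
                        cfg = stitch_config(max_iters = 500))
  expect_identical(st$retained, 1:6)

  offs <- apply(sc$displacements, 2, cumsum)
  ref <- st$retained[ceiling(length(st$retained) / 2)]
  errs <- vapply(seq_along(st$retained), function(k) {
    d <- offs[st$retained[k], ] - offs[ref, ]
    corner_transfer_error(st$homographies[[k]], translation_h(d[1], d[2]),
                          c(160, 160))
  }, 0)
  expect_true(all(errs < 2))

  # canvas contains every warped frame corner
  for (k in seq_along(st$retained)) {
    crn <- apply_h(st$homographies[[k]],
                   rbind(c(0, 0), c(159, 0), c(0, 159), c(159, 159)))
    crn <- sweep(crn, 2, st$canvas_origin)
    expect_true(all(crn[, 1] >= -1 & crn[, 1] <= ncol(st$panorama)))
    expect_true(all(crn[, 2] >= -1 & crn[, 2] <= nrow(st$panorama)))
  }

  # two identical full-foreground frames: panorama reproduces the frame
  f <- sq$frames[[1]]
  st2 <- stitch_sequence(list(f, f), list(matrix(1, 160, 160),
                                          matrix(1, 160, 160)),
                         cfg = stitch_config(max_iters = 200))
  expect_equal(dim(st2$panorama), dim(f))
  expect_lt(mean(abs(st2$panorama - f)), 0.01)

  expect_error(stitch_sequence(sq$frames[1], sq$masks[1]), "2")
})
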