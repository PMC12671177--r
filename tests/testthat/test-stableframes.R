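test_that("projection profiles are exact foreground counts", {
  z <- matrix(0, 6, 6)
  pz <- projection_profiles(z, "raw")
  expect_equal(pz$row, rep(0, 6))
  expect_equal(pz$col, rep(0, 6))

  m <- matrix(c(1, 0, 0, 1), 2, 2)
  pm <- projection_profiles(m, "raw")
  expect_equal(pm$row, c(1, 1))
  expect_equal(pm$col, c(1, 1))

  # fraction mode: per-line fractions
  pf <- projection_profiles(m, "fraction")
  expect_equal(pf$row, c(0.5, 0.5))

  set.seed(31)
  for (i in 1:100) {
    r <- matrix(rbinom(2500, 1, runif(1, 0.1, 0.6)), 50, 50)
    pr <- projection_profiles(r, "raw")
    expect_equal(sum(pr$row), sum(r))
    expect_equal(sum(pr$col), sum(r))
  }

  expect_error(projection_profiles(matrix(0.5, 3, 3)), "binary")
})

test_that("the projection difference metric matches hand evaluation", {
  a <- matrix(0, 4, 4); a[1, ] <- 1
  b <- matrix(0, 4, 4); b[2, ] <- 1
  pa <- projection_profiles(a, "raw")
  pb <- projection_profiles(b, "raw")
  # row profiles (4,0,0,0) vs (0,4,0,0): 16 + 16; column profiles equal
  expect_equal(projection_difference(pa, pb), 32)
  expect_equal(projection_difference(pa, pa), 0)

  set.seed(8)
  for (i in 1:20) {
    x <- projection_profiles(matrix(rbinom(100, 1, 0.3), 10, 10), "raw")
    y <- projection_profiles(matrix(rbinom(100, 1, 0.3), 10, 10), "raw")
    expect_identical(projection_difference(x, y), projection_difference(y, x))
    expect_gte(projection_difference(x, y), 0)
  }

  expect_error(projection_difference(pa, projection_profiles(matrix(0, 5, 5),
                                                             "raw")),
               "lengths")
  expect_error(projection_difference(pa, projection_profiles(a, "fraction")),
               "normalization")
})

test_that("D grows monotonically with mask translation", {
  g <- generate_gland_image(scene_noise_free(seed = 12))
  base <- projection_profiles(g$mask)
  d <- vapply(c(0, 1, 2, 4, 8, 16), function(t) {
    shifted <- (warp_with_homography(g$mask, translation_h(t, 0),
                                     fill = 0) >= 0.5) * 1
    projection_difference(base, projection_profiles(shifted))
  }, 0)
  expect_true(all(diff(d) >= 0))
  expect_equal(d[1], 0)
})

test_that("stable-frame selection applies the adjacent-pair rule", {
  g <- generate_gland_image(scene_noise_free(seed = 13))
  static <- replicate(8, g$mask, simplify = FALSE)

  sel <- select_stable_frames(static, threshold = 0.8)
  expect_identical(sel$stable_indices, 1:8)
  expect_true(all(sel$scores$d == 0))

  # one wildly displaced mask: exactly that frame is removed
  displaced <- static
  displaced[[4]] <- (warp_with_homography(g$mask, translation_h(40, 25),
                                          fill = 0) >= 0.5) * 1
  sel2 <- select_stable_frames(displaced, threshold = 0.8)
  expect_identical(sel2$stable_indices, setdiff(1:8, 4L))
  expect_true(all(!sel2$scores$below[3:4]))

  # infinite threshold keeps everything
  sel3 <- select_stable_frames(displaced, threshold = Inf)
  expect_identical(sel3$stable_indices, 1:8)

  expect_error(select_stable_frames(list()), "empty")
  expect_error(select_stable_frames(static[1]), "at least 2")
})

test_that("the suggested threshold maximizes between-class variance", {
  t1 <- suggest_threshold(c(0.1, 0.1, 0.1, 5, 5, 5))
  expect_gt(as.numeric(t1), 0.1)
  expect_lt(as.numeric(t1), 5)
  expect_false(attr(t1, "degenerate"))

  # an evenly graded (unimodal) spread carries no bimodality
  t2 <- suggest_threshold(0.2 * 1.2^(0:11))
  expect_true(attr(t2, "degenerate"))

  # all-identical scores: degenerate, returns that value
  t3 <- suggest_threshold(rep(0.4, 5))
  expect_equal(as.numeric(t3), 0.4)
  expect_true(attr(t3, "degenerate"))

  # brute-force oracle: exhaustive between-class variance over all midpoints
  # of the sorted unique scores, on the documented log(d + eps) scale
  brute_otsu <- function(d) {
    eps <- max(d) / 100 + 1e-12
    ld <- log(d + eps)
    u <- sort(unique(ld))
    mids <- (u[-1] + u[-length(u)]) / 2
    best <- -Inf; thr <- NA
    for (m in mids) {
      lo <- ld[ld < m]; hi <- ld[ld >= m]
      bc <- (length(lo) / length(ld)) * (length(hi) / length(ld)) *
        (mean(lo) - mean(hi))^2
      if (bc > best) { best <- bc; thr <- exp(m) - eps }
    }
    thr
  }
  set.seed(77)
  for (i in 1:10) {
    d <- c(rgamma(12, 2, 20), 1 + rgamma(6, 2, 4))
    expect_equal(as.numeric(suggest_threshold(d)), brute_otsu(d),
                 tolerance = 1e-12)
  }

  expect_error(suggest_threshold(c(1, 2)), "at least 4")
})

test_that("fraction-mode D follows its linear frame-size scaling law", {
  # per-line fractions make the summands size-free, so the summed metric
  # grows linearly with the line count: a uniform 2x upscale doubles D
  g <- generate_gland_image(scene_noise_free(seed = 14))
  m1 <- g$mask
  m2 <- (warp_with_homography(m1, translation_h(3, 2), fill = 0) >= 0.5) * 1
  d1 <- projection_difference(projection_profiles(m1), projection_profiles(m2))
  up <- function(m) {
    s <- matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 1), 3, 3)
    (warp_with_homography(m, s, out_size = 2 * dim(m), fill = 0) >= 0.5) * 1
  }
  d2 <- projection_difference(projection_profiles(up(m1)),
                              projection_profiles(up(m2)))
  expect_lt(abs(d2 / 2 - d1) / d1, 0.15)
})
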