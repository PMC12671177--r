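# Stabilization and stitching-quality evaluation: dense optical flow frame
# interpolation to restore frame counts, accumulated affine camera paths and
# jitter variance, block-wise sharpness uniformity, and SSIM/RMSE over
# registered consecutive overlaps.

# ---- dense optical flow (polynomial-expansion, pyramidal) -----------------

# Quadratic polynomial expansion of an image under a separable Gaussian
# applicability: returns per-pixel A (2x2 symmetric) and b (2-vector) of
# f(x) ~ x'Ax + b'x + c.
poly_expansion <- function(img, sigma = 1.5) {
  r <- max(2L, ceiling(3 * sigma))
  xk <- -r:r
  g <- exp(-xk^2 / (2 * sigma^2))
  gx <- g * xk
  gxx <- g * xk^2
  corr_sep <- function(im, kx, ky) {
    # correlate rows with kx then columns with ky
    x <- as_tensor(im)
    x <- dwconv_fwd_cpp(x, matrix(ky, ncol = 1))
    x <- dwconv_fwd_cpp(x, matrix(kx, nrow = 1))
    tensor_to_matrix(x)
  }
  # separable moments of the applicability
  a0 <- sum(g); a2 <- sum(gxx); a4 <- sum(g * xk^4)
  m00 <- a0 * a0; m20 <- a2 * a0; m40 <- a4 * a0; m22 <- a2 * a2
  # projections onto the basis (1, x, y, x^2, y^2, xy)
  p1 <- corr_sep(img, g, g)
  p2 <- corr_sep(img, gx, g)
  p3 <- corr_sep(img, g, gx)
  p4 <- corr_sep(img, gxx, g)
  p5 <- corr_sep(img, g, gxx)
  p6 <- corr_sep(img, gx, gx)
  # invert the Gram matrix: x and y (and xy) are decoupled; (1, x^2, y^2)
  # couple through a 3x3 block
  gblk <- matrix(c(m00, m20, m20,
                   m20, m40, m22,
                   m20, m22, m40), 3, 3, byrow = TRUE)
  gi <- solve(gblk)
  b1 <- p2 / m20
  b2 <- p3 / m20
  r4 <- gi[2, 1] * p1 + gi[2, 2] * p4 + gi[2, 3] * p5
  r5 <- gi[3, 1] * p1 + gi[3, 2] * p4 + gi[3, 3] * p5
  r6 <- p6 / m22
  list(a11 = r4, a12 = r6 / 2, a22 = r5, b1 = b1, b2 = b2)
}

base_grid <- function(h, w) {
  list(x = matrix(rep(seq_len(w) - 1, each = h), h, w),
       y = matrix(rep(seq_len(h) - 1, times = w), h, w))
}

clamp_map <- function(m, lim) pmin(pmax(m, 0), lim)

#' Dense optical flow between two frames
#'
#' Pyramidal polynomial-expansion flow: each image is locally approximated by
#' a quadratic polynomial under a Gaussian applicability window and the
#' displacement solved from the per-pixel polynomial coefficients, averaged
#' over a Gaussian integration window, with coarse-to-fine refinement. The
#' returned field `F = (fx, fy)` is the content displacement from `f1` to
#' `f2`: `f2(x + F(x)) ~ f1(x)`.
#'
#' @param f1,f2 H x W intensity matrices.
#' @param n_levels Pyramid levels (scale 0.5).
#' @param win_sigma Integration window scale in pixels.
#' @param iters Warping iterations per level.
#' @param poly_sigma Applicability scale of the polynomial expansion.
#' @return `list(fx = , fy = )` H x W displacement components in pixels.
#' @export
estimate_flow <- function(f1, f2, n_levels = 3L, win_sigma = 4,
                          iters = 3L, poly_sigma = 1.5) {
  stopifnot(all(dim(f1) == dim(f2)))
  pyr1 <- list(f1); pyr2 <- list(f2)
  for (k in seq_len(n_levels - 1)) {
    if (min(dim(pyr1[[k]])) < 24) break
    pyr1[[k + 1]] <- decimate2(blur_mat(pyr1[[k]], 1))
    pyr2[[k + 1]] <- decimate2(blur_mat(pyr2[[k]], 1))
  }
  nl <- length(pyr1)
  fx <- NULL; fy <- NULL
  for (lev in rev(seq_len(nl))) {
    i1 <- pyr1[[lev]]; i2 <- pyr2[[lev]]
    h <- nrow(i1); w <- ncol(i1)
    if (is.null(fx)) {
      fx <- matrix(0, h, w); fy <- matrix(0, h, w)
    } else {
      fx <- tensor_to_matrix(up2_fwd_cpp(as_tensor(fx)))[seq_len(h),
                                                         seq_len(w)] * 2
      fy <- tensor_to_matrix(up2_fwd_cpp(as_tensor(fy)))[seq_len(h),
                                                         seq_len(w)] * 2
    }
    e1 <- poly_expansion(i1, poly_sigma)
    e2 <- poly_expansion(i2, poly_sigma)
    bg <- base_grid(h, w)
    for (it in seq_len(iters)) {
      mx <- clamp_map(bg$x + fx, w - 1)
      my <- clamp_map(bg$y + fy, h - 1)
      w2 <- lapply(e2, function(f) remap_cpp(f, mx, my, 0))
      a11 <- (e1$a11 + w2$a11) / 2
      a12 <- (e1$a12 + w2$a12) / 2
      a22 <- (e1$a22 + w2$a22) / 2
      db1 <- -(w2$b1 - e1$b1) / 2 + a11 * fx + a12 * fy
      db2 <- -(w2$b2 - e1$b2) / 2 + a12 * fx + a22 * fy
      g11 <- blur_mat(a11 * a11 + a12 * a12, win_sigma)
      g12 <- blur_mat(a12 * (a11 + a22), win_sigma)
      g22 <- blur_mat(a12 * a12 + a22 * a22, win_sigma)
      h1 <- blur_mat(a11 * db1 + a12 * db2, win_sigma)
      h2 <- blur_mat(a12 * db1 + a22 * db2, win_sigma)
      det <- g11 * g22 - g12 * g12
      ok <- abs(det) > 1e-12
      fx <- ifelse(ok, (g22 * h1 - g12 * h2) / det, 0)
      fy <- ifelse(ok, (g11 * h2 - g12 * h1) / det, 0)
    }
  }
  list(fx = fx, fy = fy)
}

#' Flow-based intermediate frame
#'
#' Computes the temporally weighted interpolant
#' `(1 - alpha) * I1(x') + alpha * I2(x')`, where `I1` is sampled through the
#' forward flow at `(x + alpha * Fx, y + alpha * Fy)` and `I2` through the
#' backward flow at `(x - (1 - alpha) * Fx, y - (1 - alpha) * Fy)`.
#' Out-of-range samples clamp to the frame edge.
#'
#' @param i1,i2 Flanking frames (H x W).
#' @param flow_fwd,flow_bwd `list(fx, fy)` flow fields (see
#'   [estimate_flow()]; for a static-convention field F from `i1` to `i2`
#'   pass `-F` for both, as [align_frame_count()] does).
#' @param alpha Temporal weight in \[0, 1\]: 0 returns `i1`, 1 returns `i2`.
#' @return Interpolated H x W frame.
#' @export
interpolate_frame <- function(i1, i2, flow_fwd, flow_bwd, alpha) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be in [0, 1]", call. = FALSE)
  }
  stopifnot(all(dim(i1) == dim(i2)))
  h <- nrow(i1); w <- ncol(i1)
  bg <- base_grid(h, w)
  w1 <- remap_cpp(i1, clamp_map(bg$x + alpha * flow_fwd$fx, w - 1),
                  clamp_map(bg$y + alpha * flow_fwd$fy, h - 1), 0)
  w2 <- remap_cpp(i2, clamp_map(bg$x - (1 - alpha) * flow_bwd$fx, w - 1),
                  clamp_map(bg$y - (1 - alpha) * flow_bwd$fy, h - 1), 0)
  (1 - alpha) * w1 + alpha * w2
}

#' Restore the original frame count of a stabilized sequence
#'
#' Fills each gap left by removed frames with flow-interpolated frames: a gap
#' of `T` frames between retained neighbours gets interpolants at
#' `alpha = t / (T + 1)`, `t = 1..T`, using dense flow between the flanking
#' stable frames. Leading/trailing gaps replicate the nearest stable frame.
#'
#' @param stable List of retained frames.
#' @param stable_indices Their (strictly increasing) indices in the original
#'   sequence, in `[1, original_count]`.
#' @param original_count Length of the original sequence.
#' @return List of `original_count` frames.
#' @export
align_frame_count <- function(stable, stable_indices, original_count) {
  if (length(stable) == 0) stop("empty stable list", call. = FALSE)
  stopifnot(length(stable) == length(stable_indices),
            all(diff(stable_indices) > 0),
            stable_indices[1] >= 1,
            stable_indices[length(stable_indices)] <= original_count)
  out <- vector("list", original_count)
  for (k in seq_along(stable)) out[[stable_indices[k]]] <- stable[[k]]
  for (i in seq_len(stable_indices[1] - 1)) out[[i]] <- stable[[1]]
  last <- stable_indices[length(stable_indices)]
  for (i in seq_len(original_count - last)) out[[last + i]] <- stable[[length(stable)]]
  for (k in seq_len(length(stable) - 1)) {
    i0 <- stable_indices[k]; i1 <- stable_indices[k + 1]
    tt <- i1 - i0 - 1L
    if (tt == 0) next
    fl <- estimate_flow(stable[[k]], stable[[k + 1]])
    neg <- list(fx = -fl$fx, fy = -fl$fy)
    for (t in seq_len(tt)) {
      out[[i0 + t]] <- interpolate_frame(stable[[k]], stable[[k + 1]],
                                         neg, neg, t / (tt + 1))
    }
  }
  out
}

# ---- camera path ----------------------------------------------------------

ransac_affine <- function(pa, pb, thresh = 3, iters = 500L, seed = 1L) {
  n <- nrow(pa)
  if (n < 3) return(NULL)
  solve_affine <- function(pa, pb) {
    x <- cbind(pa, 1)
    fit <- tryCatch(qr.solve(x, pb), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    t(cbind(fit[, 1], fit[, 2])) # 2 x 3: rows (a11 a12 tx; a21 a22 ty)
  }
  best <- NULL; best_cnt <- -1L; best_inl <- NULL
  with_seed(seed, {
    for (it in seq_len(iters)) {
      s <- sample.int(n, 3)
      if (collinear3(pa[s, , drop = FALSE], tol = 1e-3)) next
      m <- solve_affine(pa[s, , drop = FALSE], pb[s, , drop = FALSE])
      if (is.null(m)) next
      pred <- cbind(pa, 1) %*% t(m)
      err <- sqrt(rowSums((pred - pb)^2))
      inl <- err < thresh
      if (sum(inl) > best_cnt) {
        best_cnt <- sum(inl); best <- m; best_inl <- inl
      }
    }
  })
  if (is.null(best) || best_cnt < 3) return(NULL)
  refit <- solve_affine(pa[best_inl, , drop = FALSE],
                        pb[best_inl, , drop = FALSE])
  if (!is.null(refit)) refit else best
}

#' Accumulated affine camera path of a sequence
#'
#' Estimates a robust affine transform between each neighbouring frame pair
#' (feature matches + RANSAC; dense-flow median translation when features are
#' insufficient; identity with a warning when both fail), inverts it to the
#' camera/probe motion (content shifting left means the probe moved right),
#' accumulates the per-pair transforms by right multiplication, and extracts
#' the translation components.
#'
#' @param frames List of H x W matrices (>= 2).
#' @param seed Seed for the robust estimation.
#' @return A `camera_path`: `list(transforms = list of accumulated 3 x 3
#'   affine matrices (first = identity), tx = , ty = )`.
#' @export
estimate_camera_path <- function(frames, seed = 1L) {
  n <- length(frames)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  kps <- lapply(frames, detect_keypoints)
  acc <- diag(3)
  transforms <- vector("list", n)
  transforms[[1]] <- acc
  tx <- numeric(n); ty <- numeric(n)
  for (i in 2:n) {
    m <- match_features(kps[[i - 1]], kps[[i]])
    tmat <- NULL
    if (nrow(m$pairs) >= 3) {
      pa <- as.matrix(kps[[i - 1]]$pts[m$pairs[, 1], c("x", "y")])
      pb <- as.matrix(kps[[i]]$pts[m$pairs[, 2], c("x", "y")])
      aff <- ransac_affine(pa, pb, seed = derive_seed(seed, i))
      if (!is.null(aff)) tmat <- rbind(aff, c(0, 0, 1))
    }
    if (is.null(tmat)) {
      fl <- tryCatch(estimate_flow(frames[[i - 1]], frames[[i]]),
                     error = function(e) NULL)
      if (!is.null(fl)) {
        tmat <- translation_homography(median(fl$fx), median(fl$fy))
      } else {
        warning(sprintf("camera-path estimation failed for pair %d-%d; ",
                        i - 1, i), "substituting identity", call. = FALSE)
        tmat <- diag(3)
      }
    }
    # content transform -> camera motion
    tmat <- tryCatch(solve(tmat), error = function(e) diag(3))
    acc <- acc %*% tmat
    transforms[[i]] <- acc
    tx[i] <- acc[1, 3]
    ty[i] <- acc[2, 3]
  }
  structure(list(transforms = transforms, tx = tx, ty = ty),
            class = "camera_path")
}

#' Frame-to-frame jitter variance of a camera path
#'
#' Population variance of the first differences of the accumulated
#' translation components — steady drift contributes nothing, frame-to-frame
#' jitter everything.
#'
#' @param path A [estimate_camera_path()] result (or any list with `tx`,
#'   `ty`).
#' @return `c(var_x = , var_y = )` in pixels squared.
#' @export
jitter_variance <- function(path) {
  stopifnot(length(path$tx) >= 2)
  pvar <- function(v) mean((v - mean(v))^2)
  c(var_x = pvar(diff(path$tx)), var_y = pvar(diff(path$ty)))
}

# ---- sharpness ------------------------------------------------------------

#' Block-wise sharpness map
#'
#' Tiles the image into non-overlapping `block_size` squares (partial edge
#' blocks invalid) and scores each block: `"laplacian"` = variance of the
#' 3 x 3 Laplacian response, `"sobel"` = mean squared Sobel gradient
#' magnitude, `"brenner"` = mean squared two-pixel horizontal difference.
#' Intensities are taken on the 8-bit \[0, 255\] scale. Blocks whose fraction
#' of exactly-zero (canvas margin) pixels exceeds `margin_frac` are invalid.
#'
#' @param image H x W matrix in \[0, 1\].
#' @param block_size Block side in pixels (>= 8; 64/128/256 for the standard
#'   protocol).
#' @param metric `"laplacian"`, `"sobel"` or `"brenner"`.
#' @param margin_frac Maximum tolerated fraction of exactly-zero (margin)
#'   pixels; the default 0 invalidates any block touching a black margin.
#' @return A `sharpness_grid`: `list(scores = , valid = , block_size = ,
#'   metric = )`, scores `NA` where invalid.
#' @export
block_sharpness <- function(image, block_size = 128L,
                            metric = c("laplacian", "sobel", "brenner"),
                            margin_frac = 0) {
  metric <- match.arg(metric)
  if (block_size < 8) stop("block_size must be >= 8", call. = FALSE)
  img <- image * 255
  h <- nrow(img); w <- ncol(img)
  nbr <- h %/% block_size; nbc <- w %/% block_size
  if (nbr < 1 || nbc < 1) stop("image smaller than one block", call. = FALSE)
  resp <- switch(metric,
    laplacian = tensor_to_matrix(dwconv_fwd_cpp(as_tensor(img),
      matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))),
    sobel = {
      sx <- tensor_to_matrix(dwconv_fwd_cpp(as_tensor(img),
        matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)))
      sy <- tensor_to_matrix(dwconv_fwd_cpp(as_tensor(img),
        matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)))
      sx^2 + sy^2
    },
    brenner = {
      d <- img[, c(3:w, w, w), drop = FALSE] - img
      d^2
    })
  scores <- matrix(NA_real_, nbr, nbc)
  valid <- matrix(FALSE, nbr, nbc)
  for (br in seq_len(nbr)) {
    for (bc in seq_len(nbc)) {
      ri <- ((br - 1) * block_size + 1):(br * block_size)
      ci <- ((bc - 1) * block_size + 1):(bc * block_size)
      blk <- image[ri, ci]
      if (mean(blk == 0) > margin_frac) next
      rb <- resp[ri, ci]
      valid[br, bc] <- TRUE
      scores[br, bc] <- switch(metric,
        laplacian = mean((rb - mean(rb))^2),
        sobel = mean(rb),
        brenner = mean(rb))
    }
  }
  structure(list(scores = scores, valid = valid,
                 block_size = as.integer(block_size), metric = metric),
            class = "sharpness_grid")
}

#' Sharpness uniformity of a panorama
#'
#' Variance of the valid block scores of a [block_sharpness()] grid; lower
#' values mean more uniform sharpness across the mosaic.
#'
#' @param grid A `sharpness_grid`.
#' @return Scalar variance.
#' @export
sharpness_uniformity <- function(grid) {
  sc <- grid$scores[grid$valid]
  if (length(sc) < 2) stop("need at least 2 valid blocks", call. = FALSE)
  var(sc)
}

# ---- registered-pair quality ---------------------------------------------

ssim_map <- function(x, y, win = 7L, sigma = 1.5, data_range = 1) {
  k <- gaussian_kernel(win, sigma)
  bl <- function(m) tensor_to_matrix(dwconv_fwd_cpp(as_tensor(m), k))
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- bl(x); my <- bl(y)
  sxx <- bl(x * x) - mx^2
  syy <- bl(y * y) - my^2
  sxy <- bl(x * y) - mx * my
  ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
}

#' SSIM and RMSE over registered consecutive frame pairs
#'
#' For each consecutive pair, warps frame `i + 1` into frame `i` through the
#' relative homography and computes the structural similarity index
#' (Gaussian-weighted, window 7, data range 1) and the root-mean-square error
#' (reported on the 8-bit \[0, 255\] scale) over the valid overlap.
#'
#' @param frames List of H x W matrices.
#' @param homs List of `length(frames) - 1` homographies, `homs[[i]]` mapping
#'   frame `i + 1` coordinates into frame `i` coordinates (identity for an
#'   already-aligned sequence).
#' @return `list(ssim_mean, ssim_sd, rmse_mean, rmse_sd, pairs)` where
#'   `pairs` is a per-pair data.frame; pairs with empty overlap are skipped
#'   with a warning.
#' @export
sequence_quality <- function(frames, homs) {
  n <- length(frames)
  stopifnot(n >= 2, length(homs) == n - 1)
  ssims <- numeric(0); rmses <- numeric(0); kept <- integer(0)
  for (i in seq_len(n - 1)) {
    a <- frames[[i]]
    b <- warp_with_homography(frames[[i + 1]], homs[[i]],
                              out_size = dim(a), fill = -1)
    ov <- b >= 0
    if (!any(ov)) {
      warning(sprintf("pair %d-%d has empty overlap; skipped", i, i + 1),
              call. = FALSE)
      next
    }
    b[!ov] <- a[!ov] # neutral outside the overlap for the windowed SSIM
    sm <- ssim_map(a, b)
    ssims <- c(ssims, mean(sm[ov]))
    rmses <- c(rmses, sqrt(mean((a[ov] - b[ov])^2)) * 255)
    kept <- c(kept, i)
  }
  if (length(kept) == 0) stop("no pairs with overlap", call. = FALSE)
  list(ssim_mean = mean(ssims), ssim_sd = if (length(ssims) > 1) sd(ssims) else 0,
       rmse_mean = mean(rmses), rmse_sd = if (length(rmses) > 1) sd(rmses) else 0,
       pairs = data.frame(i = kept, ssim = ssims, rmse = rmses))
}
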