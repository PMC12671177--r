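# Mask-constrained feature-based mosaicking: robust pairwise homographies,
# composition to a central reference frame, per-image gain compensation and
# Laplacian-pyramid multi-band blending.

hom_apply <- function(h, pts) {
  # pts: n x 2 (x, y) 0-based; returns n x 2
  p <- cbind(pts, 1) %*% t(h)
  p[, 1:2] / p[, 3]
}

normalize_pts <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  t <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  list(p = hom_apply(t, p), t = t)
}

dlt_homography <- function(pa, pb) {
  # direct linear transform, Hartley-normalized; maps pa -> pb
  na <- normalize_pts(pa)
  nb <- normalize_pts(pb)
  x <- na$p[, 1]; y <- na$p[, 2]
  u <- nb$p[, 1]; v <- nb$p[, 2]
  n <- nrow(pa)
  a <- matrix(0, 2 * n, 9)
  a[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  a[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- svd(a, nu = 0, nv = 9)
  h <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  h <- solve(nb$t) %*% h %*% na$t
  if (abs(h[3, 3]) < 1e-12) return(NULL)
  h / h[3, 3]
}

collinear3 <- function(p, tol = 1e-6) {
  # TRUE if any 3 of the (up to 4) points are collinear
  idx <- utils::combn(nrow(p), 3)
  for (k in seq_len(ncol(idx))) {
    q <- p[idx[, k], ]
    area <- abs((q[2, 1] - q[1, 1]) * (q[3, 2] - q[1, 2]) -
                  (q[3, 1] - q[1, 1]) * (q[2, 2] - q[1, 2]))
    if (area < tol) return(TRUE)
  }
  FALSE
}

#' Robust homography estimation from matched keypoints
#'
#' Random-sample consensus over 4-point direct-linear-transform solves; the
#' model with the most inliers (symmetric-free forward transfer error below
#' `reproj_threshold`) is re-fit on all its inliers.
#'
#' @param m A [match_features()] result.
#' @param a,b The `keypoint_set` objects the matches index into; the
#'   estimated homography maps `a` coordinates to `b` coordinates.
#' @param reproj_threshold Inlier transfer-error threshold in pixels.
#' @param max_iters RANSAC iterations.
#' @param seed Seed making the sampling reproducible.
#' @return A `homography` object: `list(matrix = 3 x 3 with bottom-right 1,
#'   inlier_count = , inlier_mask = )`.
#' @export
estimate_homography <- function(m, a, b, reproj_threshold = 3,
                                max_iters = 2000L, seed = 1L) {
  n <- nrow(m$pairs)
  if (n < 4) stop("need at least 4 matches", call. = FALSE)
  pa <- as.matrix(a$pts[m$pairs[, 1], c("x", "y")])
  pb <- as.matrix(b$pts[m$pairs[, 2], c("x", "y")])
  best <- NULL
  best_inl <- rep(FALSE, n)
  best_count <- -1L
  with_seed(seed, {
    for (it in seq_len(max_iters)) {
      s <- sample.int(n, 4)
      if (collinear3(pa[s, , drop = FALSE]) ||
            collinear3(pb[s, , drop = FALSE])) next
      h <- dlt_homography(pa[s, , drop = FALSE], pb[s, , drop = FALSE])
      if (is.null(h)) next
      err <- sqrt(rowSums((hom_apply(h, pa) - pb)^2))
      inl <- err < reproj_threshold
      cnt <- sum(inl)
      if (cnt > best_count) {
        best_count <- cnt
        best_inl <- inl
        best <- h
      }
    }
  })
  if (is.null(best) || best_count < 4) {
    stop("homography estimation failed (degenerate matches)", call. = FALSE)
  }
  refit <- dlt_homography(pa[best_inl, , drop = FALSE],
                          pb[best_inl, , drop = FALSE])
  if (!is.null(refit)) {
    err <- sqrt(rowSums((hom_apply(refit, pa) - pb)^2))
    inl <- err < reproj_threshold
    if (sum(inl) >= best_count) {
      best <- refit
      best_inl <- inl
      best_count <- sum(inl)
    }
  }
  structure(list(matrix = best / best[3, 3], inlier_count = best_count,
                 inlier_mask = best_inl),
            class = "homography")
}

#' Mean corner-transfer error between two homographies
#'
#' Warps the four frame corners with both transforms and returns the mean
#' Euclidean distance between the results — the standard summary of how far
#' an estimated homography is from a reference one over a frame.
#'
#' @param h_est,h_true 3 x 3 homography matrices.
#' @param size `c(H, W)` frame size in pixels.
#' @return Mean corner distance in pixels.
#' @export
corner_transfer_error <- function(h_est, h_true, size) {
  h <- size[1]; w <- size[2]
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  mean(sqrt(rowSums((hom_apply(h_est, corners) -
                       hom_apply(h_true, corners))^2)))
}

#' Per-image gain compensation
#'
#' Solves the linear system minimizing, over all overlapping frame pairs, the
#' weighted mean-intensity discrepancy
#' `N_ij ((g_i Ibar_ij - g_j Ibar_ji)^2 / sigma_n^2 + (1 - g_i)^2 /
#' sigma_g^2)`, where `Ibar_ij` is the mean intensity of frame i over its
#' overlap with j and `N_ij` the overlap pixel count. The overlap-weighted
#' unit-gain prior keeps the trivial all-zero solution out of reach no matter
#' how many frames overlap.
#'
#' @param frames List of H x W intensity matrices in \[0, 1\].
#' @param homs List of 3 x 3 homographies mapping each frame into the
#'   common reference coordinates.
#' @param sigma_n Intensity-error scale (default 10/255, i.e. 10 grey
#'   levels on the 8-bit scale).
#' @param sigma_g Gain-prior scale.
#' @return Numeric vector of multiplicative gains, one per frame.
#' @export
compensate_gain <- function(frames, homs, sigma_n = 10 / 255, sigma_g = 0.1) {
  n <- length(frames)
  stopifnot(length(homs) == n)
  geo <- panorama_geometry(frames, homs)
  warped <- lapply(seq_len(n), function(i) {
    warp_with_homography(frames[[i]], geo$homs[[i]],
                         out_size = c(geo$h, geo$w), fill = -1)
  })
  cover <- lapply(warped, function(w) w >= 0)
  a <- matrix(0, n, n)
  bvec <- rep(0, n)
  any_overlap <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ov <- cover[[i]] & cover[[j]]
      nij <- sum(ov)
      if (nij == 0) next
      any_overlap <- TRUE
      mi <- mean(warped[[i]][ov])
      mj <- mean(warped[[j]][ov])
      a[i, i] <- a[i, i] + nij * (mi * mi / sigma_n^2 + 1 / sigma_g^2)
      a[j, j] <- a[j, j] + nij * (mj * mj / sigma_n^2 + 1 / sigma_g^2)
      a[i, j] <- a[i, j] - nij * mi * mj / sigma_n^2
      a[j, i] <- a[j, i] - nij * mi * mj / sigma_n^2
      bvec[i] <- bvec[i] + nij / sigma_g^2
      bvec[j] <- bvec[j] + nij / sigma_g^2
    }
  }
  if (!any_overlap) return(rep(1, n))
  g <- solve(a, bvec)
  pmax(as.numeric(g), 1e-6)
}

# Gaussian pyramid downsample / Laplacian helpers for blending.
pyr_down <- function(img) decimate2(blur_mat(img, 1))
pyr_up <- function(img) tensor_to_matrix(up2_fwd_cpp(as_tensor(img)))

#' Multi-band (Laplacian pyramid) blending
#'
#' Decomposes each warped image into frequency bands, blends band `k` with
#' weight maps smoothed at that band's scale, and recombines: low frequencies
#' mix over wide regions (hiding seams and brightness steps) while high
#' frequencies mix narrowly (preserving detail).
#'
#' @param warped List of images on a shared canvas.
#' @param weights List of non-negative per-pixel weight matrices; pixels with
#'   zero total weight are uncovered and emit 0.
#' @param n_bands Number of frequency bands; clamped (with a warning) so the
#'   coarsest level keeps at least 4 pixels per side. `n_bands = 1` is plain
#'   weighted averaging.
#' @return Blended canvas matrix.
#' @export
multiband_blend <- function(warped, weights, n_bands = 5L) {
  stopifnot(length(warped) == length(weights), length(warped) >= 1)
  h <- nrow(warped[[1]]); w <- ncol(warped[[1]])
  for (i in seq_along(warped)) {
    stopifnot(all(dim(warped[[i]]) == c(h, w)),
              all(dim(weights[[i]]) == c(h, w)), all(weights[[i]] >= 0))
  }
  max_bands <- max(1L, floor(log2(min(h, w) / 4)))
  if (n_bands > max_bands) {
    warning(sprintf("n_bands clamped from %d to %d for a %dx%d canvas",
                    n_bands, max_bands, h, w), call. = FALSE)
    n_bands <- max_bands
  }
  wsum <- Reduce(`+`, weights)
  covered <- wsum > 0
  nw <- lapply(weights, function(x) ifelse(covered, x / pmax(wsum, 1e-12), 0))
  if (n_bands == 1) {
    out <- Reduce(`+`, Map(`*`, warped, nw))
    out[!covered] <- 0
    return(out)
  }
  # pad to a multiple of 2^(n_bands - 1) so every level halves exactly
  m <- 2^(n_bands - 1)
  pads <- lapply(warped, pad_to_multiple, m = m)
  wpads <- lapply(nw, function(x) {
    p <- pad_to_multiple(x, m)
    p$img
  })
  lap_pyr <- function(img) {
    gs <- list(img)
    for (k in seq_len(n_bands - 1)) gs[[k + 1]] <- pyr_down(gs[[k]])
    lp <- vector("list", n_bands)
    for (k in seq_len(n_bands - 1)) lp[[k]] <- gs[[k]] - pyr_up(gs[[k + 1]])
    lp[[n_bands]] <- gs[[n_bands]]
    lp
  }
  gauss_pyr <- function(img) {
    gs <- list(img)
    for (k in seq_len(n_bands - 1)) gs[[k + 1]] <- pyr_down(gs[[k]])
    gs
  }
  lps <- lapply(pads, function(p) lap_pyr(p$img))
  wps <- lapply(wpads, gauss_pyr)
  blended <- vector("list", n_bands)
  for (k in seq_len(n_bands)) {
    num <- Reduce(`+`, Map(function(lp, wp) lp[[k]] * wp[[k]], lps, wps))
    den <- Reduce(`+`, lapply(wps, `[[`, k))
    blended[[k]] <- num / pmax(den, 1e-12)
  }
  out <- blended[[n_bands]]
  for (k in rev(seq_len(n_bands - 1))) out <- pyr_up(out) + blended[[k]]
  out <- out[seq_len(h), seq_len(w), drop = FALSE]
  out[!covered] <- 0
  out
}

# Border-distance feathering weight for a frame.
feather_weight <- function(h, w) {
  dr <- pmin(seq_len(h), rev(seq_len(h)))
  dc <- pmin(seq_len(w), rev(seq_len(w)))
  outer(dr, dc, pmin) / min(max(dr), max(dc))
}

# Compose to-reference homographies and the canvas bounds; returns shifted
# homographies (frame -> canvas), canvas size.
panorama_geometry <- function(frames, homs) {
  n <- length(frames)
  corners_all <- do.call(rbind, lapply(seq_len(n), function(i) {
    h <- nrow(frames[[i]]); w <- ncol(frames[[i]])
    hom_apply(homs[[i]], rbind(c(0, 0), c(w - 1, 0), c(0, h - 1),
                               c(w - 1, h - 1)))
  }))
  # round away sub-1e-4 numerical fuzz so near-integer corners do not
  # inflate the canvas by a pixel
  corners_all <- round(corners_all, 4)
  x0 <- floor(min(corners_all[, 1])); x1 <- ceiling(max(corners_all[, 1]))
  y0 <- floor(min(corners_all[, 2])); y1 <- ceiling(max(corners_all[, 2]))
  shift <- translation_homography(-x0, -y0)
  list(homs = lapply(homs, function(h) shift %*% h),
       w = as.integer(x1 - x0 + 1), h = as.integer(y1 - y0 + 1),
       origin = c(x0, y0))
}

#' Stitching parameters
#'
#' @param ratio Ratio-test threshold for descriptor matching.
#' @param reproj_threshold,max_iters,seed RANSAC settings.
#' @param n_bands Blending bands.
#' @param sigma_n,sigma_g Gain-compensation scales.
#' @param min_matches Minimum matches required per pair.
#' @export
stitch_config <- function(ratio = 0.75, reproj_threshold = 3,
                          max_iters = 2000L, seed = 1L, n_bands = 5L,
                          sigma_n = 10 / 255, sigma_g = 0.1,
                          min_matches = 6L) {
  structure(list(ratio = ratio, reproj_threshold = reproj_threshold,
                 max_iters = as.integer(max_iters), seed = as.integer(seed),
                 n_bands = as.integer(n_bands), sigma_n = sigma_n,
                 sigma_g = sigma_g, min_matches = as.integer(min_matches)),
            class = "stitch_config")
}

#' Stitch a frame sequence into a panorama
#'
#' Full mask-constrained pipeline: masked keypoints per frame, consecutive
#' pair matching, RANSAC pairwise homographies, composition to the middle
#' retained frame as reference, canvas construction from warped corners, gain
#' compensation and multi-band blending. Frames whose pairwise estimation
#' fails are dropped with a logged gap and the chain re-attempted across
#' them.
#'
#' @param frames List of H x W intensity matrices (>= 2).
#' @param masks List of binary masks aligned to `frames`.
#' @param cfg A [stitch_config()].
#' @param verbose Log per-pair progress.
#' @return `list(panorama = , homographies = list of frame-to-reference
#'   3 x 3 matrices (for retained frames), retained = indices, gains = ,
#'   dropped = indices)`.
#' @export
stitch_sequence <- function(frames, masks, cfg = stitch_config(),
                            verbose = FALSE) {
  n <- length(frames)
  stopifnot(n >= 2, length(masks) == n)
  kps <- lapply(seq_len(n), function(i) {
    extract_masked_keypoints(frames[[i]], masks[[i]])
  })
  # chain pairwise homographies, skipping frames whose estimation fails
  retained <- 1L
  pair_h <- list() # maps retained[k] coords -> retained[k+1] coords
  i <- 1L
  while (i < n) {
    linked <- FALSE
    for (j in (i + 1):n) {
      h <- tryCatch({
        m <- match_features(kps[[i]], kps[[j]], ratio = cfg$ratio)
        if (nrow(m$pairs) < cfg$min_matches) stop("too few matches")
        estimate_homography(m, kps[[i]], kps[[j]],
                            reproj_threshold = cfg$reproj_threshold,
                            max_iters = cfg$max_iters,
                            seed = derive_seed(cfg$seed, i * n + j))
      }, error = function(e) NULL)
      if (!is.null(h)) {
        if (verbose) message(sprintf("pair %d -> %d: %d inliers", i, j,
                                     h$inlier_count))
        pair_h[[length(pair_h) + 1L]] <- h$matrix
        retained <- c(retained, j)
        i <- j
        linked <- TRUE
        break
      } else if (verbose) {
        message(sprintf("pair %d -> %d: estimation failed, widening gap",
                        i, j))
      }
    }
    if (!linked) break
  }
  if (length(retained) < 2) {
    stop("fewer than 2 stitchable frames", call. = FALSE)
  }
  dropped <- setdiff(seq_len(n), retained)
  if (length(dropped) > 0 && verbose) {
    message("dropped frames: ", paste(dropped, collapse = ", "))
  }
  k <- length(retained)
  ref <- ceiling(k / 2) # middle of the retained sequence
  homs <- vector("list", k)
  homs[[ref]] <- diag(3)
  if (ref > 1) {
    for (t in (ref - 1):1) {
      homs[[t]] <- homs[[t + 1]] %*% pair_h[[t]]
    }
  }
  if (ref < k) {
    for (t in (ref + 1):k) {
      homs[[t]] <- homs[[t - 1]] %*% solve(pair_h[[t - 1]])
    }
  }
  homs <- lapply(homs, function(h) h / h[3, 3])

  sub_frames <- frames[retained]
  gains <- compensate_gain(sub_frames, homs, sigma_n = cfg$sigma_n,
                           sigma_g = cfg$sigma_g)
  geo <- panorama_geometry(sub_frames, homs)
  warped <- lapply(seq_len(k), function(t) {
    warp_with_homography(sub_frames[[t]] * gains[t], geo$homs[[t]],
                         out_size = c(geo$h, geo$w), fill = 0)
  })
  wts <- lapply(seq_len(k), function(t) {
    fw <- feather_weight(nrow(sub_frames[[t]]), ncol(sub_frames[[t]]))
    warp_with_homography(fw, geo$homs[[t]], out_size = c(geo$h, geo$w),
                         fill = 0)
  })
  pano <- multiband_blend(warped, wts, n_bands = cfg$n_bands)
  list(panorama = clamp01(pano), homographies = homs, retained = retained,
       gains = gains, dropped = dropped, canvas_origin = geo$origin)
}
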