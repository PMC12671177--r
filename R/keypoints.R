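# Scale-invariant keypoint detection and description.
#
# A SIFT-style pipeline: difference-of-Gaussians scale-space extrema with
# contrast and edge-response filtering, a dominant gradient orientation per
# keypoint, and the classical 4 x 4 x 8 = 128-component gradient-orientation
# histogram descriptor (Gaussian-weighted, normalized, clipped at 0.2,
# renormalized).

gauss1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a single matrix with reflective padding.
blur_mat <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss1d(sigma)
  x <- as_tensor(img)
  x <- dwconv_fwd_cpp(x, matrix(k, ncol = 1))
  x <- dwconv_fwd_cpp(x, matrix(k, nrow = 1))
  tensor_to_matrix(x)
}

decimate2 <- function(img) img[seq(1, nrow(img), 2), seq(1, ncol(img), 2),
                               drop = FALSE]

grad_xy <- function(img) {
  h <- nrow(img); w <- ncol(img)
  dx <- img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]
  dy <- img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]
  list(dx = dx / 2, dy = dy / 2)
}

# 26-neighborhood extrema of a DoG triplet (prev, cur, nxt), interior only.
local_extrema <- function(prev, cur, nxt, thresh) {
  h <- nrow(cur); w <- ncol(cur)
  if (h < 3 || w < 3) return(NULL)
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  ctr <- cur[ri, ci]
  is_max <- abs(ctr) >= thresh
  is_min <- is_max
  for (lay in list(prev, cur, nxt)) {
    for (dr in -1:1) {
      for (dc in -1:1) {
        nb <- lay[ri + dr, ci + dc]
        same <- identical(lay, cur) && dr == 0 && dc == 0
        if (same) next
        is_max <- is_max & (ctr > nb)
        is_min <- is_min & (ctr < nb)
      }
    }
  }
  which(is_max | is_min, arr.ind = TRUE) + 1L # back to full-image indices
}

edge_ok <- function(cur, r, c, edge_thresh = 10) {
  dxx <- cur[r, c + 1] + cur[r, c - 1] - 2 * cur[r, c]
  dyy <- cur[r + 1, c] + cur[r - 1, c] - 2 * cur[r, c]
  dxy <- (cur[r + 1, c + 1] - cur[r + 1, c - 1] -
            cur[r - 1, c + 1] + cur[r - 1, c - 1]) / 4
  tr <- dxx + dyy
  det <- dxx * dyy - dxy * dxy
  det > 0 & tr^2 / det < (edge_thresh + 1)^2 / edge_thresh
}

#' Detect scale-invariant keypoints
#'
#' Difference-of-Gaussians extrema over a small scale-space pyramid with
#' contrast and edge filtering, dominant-orientation assignment and 128-d
#' gradient-histogram descriptors.
#'
#' @param img H x W grayscale matrix in \[0, 1\].
#' @param n_octaves Number of pyramid octaves (capped by image size).
#' @param scales_per_octave Scale samples per octave.
#' @param contrast_thresh Minimum absolute DoG response.
#' @param edge_thresh Hessian trace/determinant edge-rejection ratio.
#' @param sigma0 Base blur of the scale space.
#' @return A `keypoint_set`: `list(pts = data.frame(x, y, scale,
#'   orientation), desc = n x 128 matrix)`. Coordinates are 0-based pixels.
#' @export
detect_keypoints <- function(img, n_octaves = 3L, scales_per_octave = 3L,
                             contrast_thresh = 0.005, edge_thresh = 10,
                             sigma0 = 1.6) {
  stopifnot(is.matrix(img))
  S <- scales_per_octave
  n_octaves <- max(1L, min(n_octaves,
                           floor(log2(min(dim(img)) / 16)) + 1L))
  base <- img
  pts <- list()
  descs <- list()
  for (o in seq_len(n_octaves) - 1L) {
    sigmas <- sigma0 * 2^((0:(S + 2)) / S)
    G <- lapply(sigmas, function(s) blur_mat(base, s))
    D <- lapply(seq_len(S + 2), function(i) G[[i + 1]] - G[[i]])
    grads <- vector("list", length(G))
    for (s in 2:(S + 1)) {
      ex <- local_extrema(D[[s - 1]], D[[s]], D[[s + 1]], contrast_thresh)
      if (is.null(ex) || nrow(ex) == 0) next
      keep <- vapply(seq_len(nrow(ex)), function(i) {
        edge_ok(D[[s]], ex[i, 1], ex[i, 2], edge_thresh)
      }, TRUE)
      ex <- ex[keep, , drop = FALSE]
      dimnames(ex) <- NULL
      if (nrow(ex) == 0) next
      if (is.null(grads[[s]])) grads[[s]] <- grad_xy(G[[s]])
      gr <- grads[[s]]
      dcur <- D[[s]]
      # sub-pixel spatial refinement: 2-d quadratic fit of the DoG
      r0 <- ex[, 1]; c0 <- ex[, 2]
      gx1 <- (dcur[cbind(r0, c0 + 1)] - dcur[cbind(r0, c0 - 1)]) / 2
      gy1 <- (dcur[cbind(r0 + 1, c0)] - dcur[cbind(r0 - 1, c0)]) / 2
      hxx <- dcur[cbind(r0, c0 + 1)] + dcur[cbind(r0, c0 - 1)] -
        2 * dcur[cbind(r0, c0)]
      hyy <- dcur[cbind(r0 + 1, c0)] + dcur[cbind(r0 - 1, c0)] -
        2 * dcur[cbind(r0, c0)]
      hxy <- (dcur[cbind(r0 + 1, c0 + 1)] - dcur[cbind(r0 + 1, c0 - 1)] -
                dcur[cbind(r0 - 1, c0 + 1)] + dcur[cbind(r0 - 1, c0 - 1)]) / 4
      det <- hxx * hyy - hxy * hxy
      offx <- ifelse(abs(det) > 1e-12, -(hyy * gx1 - hxy * gy1) / det, 0)
      offy <- ifelse(abs(det) > 1e-12, -(hxx * gy1 - hxy * gx1) / det, 0)
      xo <- c0 - 1 + pmin(pmax(offx, -0.5), 0.5)
      yo <- r0 - 1 + pmin(pmax(offy, -0.5), 0.5)
      sig_rel <- sigma0 * 2^((s - 1) / S)
      dd <- sift_describe_cpp(gr$dx, gr$dy, cbind(xo, yo, sig_rel))
      pts[[length(pts) + 1L]] <- cbind(x = xo * 2^o, y = yo * 2^o,
                                       scale = sig_rel * 2^o,
                                       orientation = dd$orientation)
      descs[[length(descs) + 1L]] <- dd$desc
    }
    base <- decimate2(G[[S + 1]])
    if (min(dim(base)) < 16) break
  }
  if (length(pts) == 0) {
    return(structure(list(pts = data.frame(x = numeric(0), y = numeric(0),
                                           scale = numeric(0),
                                           orientation = numeric(0)),
                          desc = matrix(0, 0, 128)),
                     class = "keypoint_set"))
  }
  structure(list(pts = as.data.frame(do.call(rbind, pts)),
                 desc = do.call(rbind, descs)),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d keypoints\n", nrow(x$pts)))
  invisible(x)
}

subset_keypoints <- function(kp, keep) {
  structure(list(pts = kp$pts[keep, , drop = FALSE],
                 desc = kp$desc[keep, , drop = FALSE]),
            class = "keypoint_set")
}

#' Mask-constrained keypoint extraction
#'
#' Detects keypoints on the full frame and keeps only those whose rounded
#' position falls on mask foreground (mask value 1), so matching is driven by
#' glandular structure rather than background clutter.
#'
#' @param frame H x W grayscale matrix.
#' @param mask Binary H x W segmentation mask.
#' @param ... Passed to [detect_keypoints()].
#' @return A `keypoint_set` restricted to the mask foreground.
#' @export
extract_masked_keypoints <- function(frame, mask, ...) {
  stopifnot(all(dim(frame) == dim(mask)))
  stopifnot_binary(mask)
  if (sum(mask) == 0) {
    warning("mask is empty; no keypoints retained", call. = FALSE)
    return(structure(list(pts = data.frame(x = numeric(0), y = numeric(0),
                                           scale = numeric(0),
                                           orientation = numeric(0)),
                          desc = matrix(0, 0, 128)),
                     class = "keypoint_set"))
  }
  kp <- detect_keypoints(frame, ...)
  if (nrow(kp$pts) == 0) return(kp)
  r <- pmin(pmax(round(kp$pts$y) + 1, 1), nrow(mask))
  c <- pmin(pmax(round(kp$pts$x) + 1, 1), ncol(mask))
  keep <- mask[cbind(r, c)] == 1
  subset_keypoints(kp, keep)
}

#' Match keypoint descriptors with the ratio test
#'
#' For each descriptor in `a`, finds its two nearest neighbours in `b` by
#' Euclidean descriptor distance and keeps the pair iff
#' `d1 < ratio * d2` (Lowe's ratio test). Each `a` index appears at most
#' once.
#'
#' @param a,b `keypoint_set` objects.
#' @param ratio Ratio-test threshold (default 0.75).
#' @return A `match_set`: `list(pairs = n x 2 matrix of indices into a and
#'   b, distances = , ratio_used = )`.
#' @export
match_features <- function(a, b, ratio = 0.75) {
  na <- nrow(a$pts); nb <- nrow(b$pts)
  empty <- structure(list(pairs = matrix(0L, 0, 2), distances = numeric(0),
                          ratio_used = ratio), class = "match_set")
  if (na == 0 || nb == 0) return(empty)
  d2 <- outer(rowSums(a$desc^2), rep(1, nb)) +
    outer(rep(1, na), rowSums(b$desc^2)) - 2 * a$desc %*% t(b$desc)
  d2[d2 < 0] <- 0
  pairs <- matrix(0L, 0, 2)
  dist <- numeric(0)
  for (i in seq_len(na)) {
    di <- d2[i, ]
    j1 <- which.min(di)
    d1 <- sqrt(di[j1])
    if (nb == 1) next # no second neighbour to test against
    d2nd <- sqrt(min(di[-j1]))
    if (d1 < ratio * d2nd) {
      pairs <- rbind(pairs, c(i, j1))
      dist <- c(dist, d1)
    }
  }
  structure(list(pairs = pairs, distances = dist, ratio_used = ratio),
            class = "match_set")
}
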