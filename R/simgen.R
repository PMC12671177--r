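# Synthetic CLE-like glandular imagery with known ground truth.
#
# The generator emulates probe-based confocal endomicroscopy of gastric
# mucosa: bright tubular/elliptical glands on a darker speckled background,
# a "slow translation - brief pause" probe motion model, and row-progressive
# (rolling shutter) shear on moving frames. A global scene is rendered at 2x
# the frame size and frames are windowed views of it, so the inter-frame
# transforms are known exactly.

#' Parameters of a synthetic gland scene
#'
#' @param image_size `c(H, W)` frame size in pixels (default 892 x 892, the
#'   acquisition frame size of the probe this generator emulates).
#' @param n_glands Number of glands per frame-sized area (>= 1); the default
#'   gives the dense glandular coverage typical of gastric mucosa.
#' @param gland_axis_range `c(min, max)` semi-axis lengths in pixels.
#' @param gland_intensity,background_intensity Intensities in \[0, 1\];
#'   glands must be brighter than background.
#' @param speckle_sigma Standard deviation of additive speckle noise.
#' @param speckle_scale Correlation length of the speckle in pixels:
#'   microscopy speckle and cellular granularity are spatially correlated,
#'   not white, and this is what gives the imagery its local texture.
#' @param vignetting_strength Radial falloff strength in \[0, 1\].
#' @param tube_prob Probability that a gland is a short tube (a chain of
#'   overlapping ellipses) rather than a single ellipse.
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return A `gland_scene_params` list.
#' @export
gland_scene_params <- function(image_size = c(892L, 892L), n_glands = 20L,
                               gland_axis_range = c(18, 60),
                               gland_intensity = 0.75,
                               background_intensity = 0.25,
                               speckle_sigma = 0.05, speckle_scale = 2,
                               vignetting_strength = 0.25,
                               tube_prob = 0.5, seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8),
            n_glands >= 1, length(gland_axis_range) == 2,
            all(gland_axis_range > 0),
            gland_axis_range[1] <= gland_axis_range[2],
            gland_intensity > background_intensity,
            gland_intensity <= 1, background_intensity >= 0,
            speckle_sigma >= 0, speckle_scale >= 0,
            vignetting_strength >= 0,
            vignetting_strength <= 1, tube_prob >= 0, tube_prob <= 1)
  if (3 * gland_axis_range[2] > min(image_size)) {
    stop("gland axes exceed image size", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 n_glands = as.integer(n_glands),
                 gland_axis_range = gland_axis_range,
                 gland_intensity = gland_intensity,
                 background_intensity = background_intensity,
                 speckle_sigma = speckle_sigma,
                 speckle_scale = speckle_scale,
                 vignetting_strength = vignetting_strength,
                 tube_prob = tube_prob, seed = as.integer(seed)),
            class = "gland_scene_params")
}

# Rasterize one gland (a chain of ellipse lobes) over its bounding box.
# Returns the linear pixel indices of the footprint; `pad` dilates the
# ellipse axes (used to enforce separation between glands).
gland_footprint <- function(g, h, w, pad = 0) {
  ct <- cos(g$theta); st <- sin(g$theta)
  idx <- integer(0)
  for (cc in g$centers) {
    a <- g$a + pad; b <- g$b + pad
    r <- ceiling(max(a, b)) + 1
    c0 <- max(1, floor(cc[1] + 1 - r)); c1 <- min(w, ceiling(cc[1] + 1 + r))
    r0 <- max(1, floor(cc[2] + 1 - r)); r1 <- min(h, ceiling(cc[2] + 1 + r))
    if (c0 > c1 || r0 > r1) next
    xs <- matrix(rep((c0:c1) - 1 - cc[1], each = r1 - r0 + 1),
                 nrow = r1 - r0 + 1)
    ys <- matrix(rep((r0:r1) - 1 - cc[2], times = c1 - c0 + 1),
                 nrow = r1 - r0 + 1)
    u <- xs * ct + ys * st
    v <- -xs * st + ys * ct
    inside <- (u / a)^2 + (v / b)^2 <= 1
    rows <- matrix(rep(r0:r1, times = c1 - c0 + 1), nrow = r1 - r0 + 1)
    cols <- matrix(rep(c0:c1, each = r1 - r0 + 1), nrow = r1 - r0 + 1)
    idx <- c(idx, rows[inside] + (cols[inside] - 1L) * h)
  }
  unique(idx)
}

# Sequential placement of non-overlapping glands by rejection on the true
# rasterized footprints (dilated by 2 px so components stay separated);
# packs far denser than bounding-circle rejection.
sample_glands <- function(n_glands, h, w, axr, tube_prob) {
  occ <- rep(FALSE, h * w)
  glands <- list()
  guard <- 0L
  while (length(glands) < n_glands && guard < 20000L) {
    guard <- guard + 1L
    a <- runif(1, axr[1], axr[2])
    b <- runif(1, axr[1], min(axr[2], a)) # a = major semi-axis
    theta <- runif(1, 0, pi)
    n_lobes <- if (runif(1) < tube_prob) sample(2:3, 1) else 1L
    # chain lobes along the major axis, overlapping by half an axis
    step <- a
    span <- a + (n_lobes - 1) * step / 2 # rough half-extent of the chain
    if (2 * (span + 3) >= min(h, w)) next
    cx <- runif(1, span + 3, w - span - 3)
    cy <- runif(1, span + 3, h - span - 3)
    centers <- lapply(seq_len(n_lobes), function(k) {
      o <- (k - 1 - (n_lobes - 1) / 2) * step
      c(cx + o * cos(theta), cy + o * sin(theta))
    })
    g <- list(cx = cx, cy = cy, a = a, b = b, theta = theta,
              centers = centers)
    dil <- gland_footprint(g, h, w, pad = 2)
    if (any(occ[dil])) next
    occ[dil] <- TRUE
    g$footprint <- gland_footprint(g, h, w, pad = 0)
    glands[[length(glands) + 1L]] <- g
  }
  if (length(glands) < n_glands) {
    stop("could not place glands without overlap; reduce n_glands or axes",
         call. = FALSE)
  }
  glands
}

rasterize_glands <- function(glands, h, w) {
  mask <- matrix(0, h, w)
  for (g in glands) mask[g$footprint] <- 1
  mask
}

vignette_field <- function(h, w, strength) {
  if (strength == 0) return(matrix(1, h, w))
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  rmax2 <- cx^2 + cy^2
  xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  1 - strength * ((xs - cx)^2 + (ys - cy)^2) / rmax2
}

#' Generate one synthetic gland frame with its ground-truth mask
#'
#' Renders non-overlapping bright glands (rotated filled ellipses, optionally
#' chained into short tubes) on a darker background, then applies vignetting
#' and additive speckle noise. The mask marks exactly the pixels inside a
#' gland body.
#'
#' @param params A [gland_scene_params()].
#' @param size Optional `c(H, W)` override of `params$image_size`.
#' @param n_glands Optional override of `params$n_glands`.
#' @return `list(frame = , mask = )` of H x W matrices; frame in \[0, 1\],
#'   mask binary.
#' @export
generate_gland_image <- function(params, size = NULL, n_glands = NULL) {
  stopifnot(inherits(params, "gland_scene_params"))
  hw <- if (is.null(size)) params$image_size else as.integer(size)
  ng <- if (is.null(n_glands)) params$n_glands else as.integer(n_glands)
  if (3 * params$gland_axis_range[2] > min(hw)) {
    stop("gland axes exceed image size", call. = FALSE)
  }
  with_seed(params$seed, {
    glands <- sample_glands(ng, hw[1], hw[2], params$gland_axis_range,
                            params$tube_prob)
    mask <- rasterize_glands(glands, hw[1], hw[2])
    frame <- params$background_intensity +
      mask * (params$gland_intensity - params$background_intensity)
    frame <- frame * vignette_field(hw[1], hw[2], params$vignetting_strength)
    if (params$speckle_sigma > 0) {
      noise <- matrix(rnorm(prod(hw)), hw[1], hw[2])
      if (params$speckle_scale > 0) {
        noise <- blur_mat(noise, params$speckle_scale)
        noise <- noise / sd(noise)
      }
      frame <- frame + params$speckle_sigma * noise
    }
    list(frame = clamp01(frame), mask = mask, glands = glands)
  })
}

#' Apply row-progressive (rolling shutter) shear to a frame
#'
#' Emulates a top-to-bottom line scan during probe motion: row `y` (0-based)
#' of the output shows the scene displaced by
#' `shear_gain * (y / H) * velocity`, so the top row is undisplaced and the
#' shear grows linearly down the frame. The mask is warped identically and
#' re-binarized.
#'
#' @param frame H x W intensity matrix.
#' @param mask H x W binary mask.
#' @param velocity `c(vx, vy)` probe velocity in pixels/frame.
#' @param shear_gain Row-displacement per unit probe velocity.
#' @param fill Intensity for out-of-bounds samples (scene background).
#' @param origin Scan origin; `"top"` (default) or `"bottom"`.
#' @return `list(frame = , mask = )`.
#' @export
apply_rolling_shutter <- function(frame, mask, velocity, shear_gain = 1,
                                  fill = 0, origin = c("top", "bottom")) {
  origin <- match.arg(origin)
  stopifnot(all(dim(frame) == dim(mask)), length(velocity) == 2)
  h <- nrow(frame); w <- ncol(frame)
  frac <- (seq_len(h) - 1) / h
  if (origin == "bottom") frac <- rev(frac)
  sx <- shear_gain * frac * velocity[1]
  sy <- shear_gain * frac * velocity[2]
  base_x <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  base_y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  mapx <- base_x - matrix(sx, h, w)
  mapy <- base_y - matrix(sy, h, w)
  list(frame = remap_cpp(frame, mapx, mapy, fill),
       mask = (remap_cpp(mask, mapx, mapy, 0) >= 0.5) * 1)
}

#' Probe motion script
#'
#' Builds a "slow translation - brief pause" motion script: alternating runs
#' of moving frames (rolling-shutter-distorted) and paused frames (stable).
#' Stability labels derive deterministically from the per-frame displacement
#' magnitude against `pause_threshold`.
#'
#' @param n_frames Number of frames (>= 2).
#' @param unstable_fraction Approximate fraction of moving frames.
#' @param move_px `c(min, max)` displacement magnitude of moving frames in
#'   pixels/frame.
#' @param pause_threshold Displacement magnitude below which a frame counts
#'   as paused/stable.
#' @param shear_gain Rolling-shutter shear gain applied to moving frames.
#' @param drift_px Small residual displacement magnitude during pauses
#'   (probe is never perfectly still); must stay below `pause_threshold`.
#' @param max_excursion Soft bound (pixels) on the cumulative displacement:
#'   beyond it the heading steers back toward the starting position, as an
#'   operator surveying a bounded lesion area does. Keep below half the
#'   frame size so windowed views stay inside the global scene.
#' @param seed Integer seed.
#' @return A `motion_script` list with `displacements` (n x 2), `stable`
#'   (logical n), `shear_gain`, `pause_threshold`.
#' @export
motion_script <- function(n_frames, unstable_fraction = 0.2,
                          move_px = c(8, 14), pause_threshold = 2,
                          shear_gain = 1, drift_px = 0.3,
                          max_excursion = 40, seed = 1L) {
  stopifnot(n_frames >= 2, unstable_fraction >= 0, unstable_fraction <= 1,
            drift_px < pause_threshold, move_px[1] <= move_px[2],
            max_excursion > 0)
  with_seed(seed, {
    disp <- matrix(0, n_frames, 2)
    moving <- logical(n_frames)
    # alternating phases: multi-frame slow translations (every frame moving)
    # separated by pauses whose mean length sets the unstable fraction; the
    # heading persists with slow turns and steers back toward the origin
    # when the excursion bound is reached
    heading <- runif(1, 0, 2 * pi)
    pos <- c(0, 0)
    move_len <- function() sample(5:8, 1)
    pause_len <- function() {
      if (unstable_fraction == 0) return(n_frames)
      target <- 6.5 * (1 - unstable_fraction) / unstable_fraction
      max(2L, round(target * runif(1, 0.7, 1.3)))
    }
    i <- 1L
    in_pause <- TRUE
    left <- pause_len()
    while (i <= n_frames) {
      if (left == 0L) {
        in_pause <- !in_pause
        left <- if (in_pause) pause_len() else move_len()
      }
      if (sqrt(sum(pos^2)) > max_excursion) {
        heading <- atan2(-pos[2], -pos[1]) + rnorm(1, sd = 0.2)
      } else {
        heading <- heading + rnorm(1, sd = 0.15)
      }
      if (!in_pause) {
        r <- runif(1, move_px[1], move_px[2])
        moving[i] <- TRUE
      } else {
        r <- runif(1, 0, drift_px)
      }
      disp[i, ] <- r * c(cos(heading), sin(heading))
      pos <- pos + disp[i, ]
      left <- left - 1L
      i <- i + 1L
    }
    # frame 1 is the anchor view: no displacement into it
    disp[1, ] <- 0
    moving[1] <- FALSE
    mag <- sqrt(rowSums(disp^2))
    structure(list(displacements = disp, stable = mag < pause_threshold,
                   shear_gain = shear_gain,
                   pause_threshold = pause_threshold, seed = as.integer(seed)),
              class = "motion_script")
  })
}

translation_homography <- function(dx, dy) {
  matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3)
}

#' Generate a synthetic CLE sequence with ground truth
#'
#' Renders one global gland scene at twice the frame size and extracts
#' translated windowed views per the motion script. Frames labelled unstable
#' receive rolling-shutter shear at that frame's velocity. The exact pure
#' translation homography between consecutive windows is returned per pair
#' (mapping frame `i` pixel coordinates to frame `i + 1` coordinates).
#'
#' @param scene A [gland_scene_params()].
#' @param script A [motion_script()].
#' @return A `synthetic_sequence` list: `frames`, `masks`, `stability_labels`,
#'   `true_pair_transforms` (list of 3 x 3 matrices, length n - 1), `script`.
#' @export
generate_sequence <- function(scene, script) {
  stopifnot(inherits(scene, "gland_scene_params"),
            inherits(script, "motion_script"))
  n <- nrow(script$displacements)
  h <- scene$image_size[1]; w <- scene$image_size[2]
  gh <- 2L * h; gw <- 2L * w
  # density-preserving gland count for the 4x area of the global scene
  global <- generate_gland_image(scene, size = c(gh, gw),
                                 n_glands = scene$n_glands * 4L)
  offsets <- apply(script$displacements, 2, cumsum)
  if (n == 1) offsets <- matrix(offsets, 1)
  # window origin starts at the global-scene centre
  x0 <- (gw - w) / 2 + offsets[, 1]
  y0 <- (gh - h) / 2 + offsets[, 2]
  if (any(x0 < 0 | y0 < 0 | x0 > gw - w | y0 > gh - h)) {
    stop("cumulative displacement pushes the window outside the scene",
         call. = FALSE)
  }
  vfield <- vignette_field(h, w, scene$vignetting_strength)
  frames <- vector("list", n)
  masks <- vector("list", n)
  base_x <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  base_y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  for (i in seq_len(n)) {
    mapx <- base_x + x0[i]
    mapy <- base_y + y0[i]
    fr <- remap_cpp(global$frame, mapx, mapy, scene$background_intensity)
    mk <- (remap_cpp(global$mask, mapx, mapy, 0) >= 0.5) * 1
    fr <- clamp01(fr * vfield)
    if (!script$stable[i]) {
      rs <- apply_rolling_shutter(fr, mk, script$displacements[i, ],
                                  shear_gain = script$shear_gain,
                                  fill = scene$background_intensity)
      fr <- rs$frame; mk <- rs$mask
    }
    frames[[i]] <- fr
    masks[[i]] <- mk
  }
  transforms <- lapply(seq_len(n - 1), function(i) {
    translation_homography(-script$displacements[i + 1, 1],
                           -script$displacements[i + 1, 2])
  })
  structure(list(frames = frames, masks = masks,
                 stability_labels = script$stable,
                 true_pair_transforms = transforms, script = script,
                 scene = scene),
            class = "synthetic_sequence")
}

#' Warp a frame with a homography
#'
#' Inverse-mapped bilinear resampling: output pixel `p` takes the value of
#' the input at `h^{-1} p` (0-based `(x, y)` pixel coordinates). The identity
#' homography reproduces the frame exactly.
#'
#' @param frame H x W matrix.
#' @param h 3 x 3 invertible homography mapping source to output coordinates.
#' @param out_size `c(H, W)` of the output canvas (default: input size).
#' @param fill Fill value for unmapped pixels.
#' @return Warped matrix of size `out_size`.
#' @export
warp_with_homography <- function(frame, h, out_size = dim(frame), fill = 0) {
  stopifnot(is.matrix(h), all(dim(h) == c(3, 3)))
  if (abs(det(h)) < 1e-12) stop("homography is singular", call. = FALSE)
  hinv <- solve(h)
  warp_homography_cpp(frame, hinv, as.integer(out_size[1]),
                      as.integer(out_size[2]), fill)
}
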