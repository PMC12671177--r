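# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# A small, noise-free three-gland scene (deterministic geometry checks).
scene_noise_free <- function(seed = 7) {
  gland_scene_params(image_size = c(128L, 128L), n_glands = 3L,
                     gland_axis_range = c(6, 14), speckle_sigma = 0,
                     vignetting_strength = 0, tube_prob = 0, seed = seed)
}

# A textured scene at the density used for stitching checks.
scene_textured <- function(size = 128L, n_glands = 10L, seed = 61) {
  gland_scene_params(image_size = c(size, size), n_glands = n_glands,
                     gland_axis_range = c(6, 12), seed = seed)
}

make_seg_dataset <- function(n, size = 128L, seed0 = 200L,
                             n_glands = max(3L, round(10 * (size / 128)^2))) {
  lapply(seq_len(n), function(i) {
    g <- generate_gland_image(scene_textured(size, n_glands = n_glands,
                                             seed = seed0 + i))
    list(image = g$frame, mask = g$mask)
  })
}

# Flood-fill connected-component count (4-connectivity) — an oracle
# independent of the generator's placement bookkeeping.
count_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] == 1 && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        while (length(stack) > 0) {
          q <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          a <- q[1]; b <- q[2]
          if (a < 1 || b < 1 || a > nrow(m) || b > ncol(m)) next
          if (m[a, b] != 1 || lab[a, b] != 0L) next
          lab[a, b] <- cur
          stack <- c(stack, list(c(a - 1, b), c(a + 1, b),
                                 c(a, b - 1), c(a, b + 1)))
        }
      }
    }
  }
  cur
}

translation_h <- function(dx, dy) matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3)

apply_h <- function(h, pts) {
  p <- cbind(pts, 1) %*% t(h)
  p[, 1:2] / p[, 3]
}
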