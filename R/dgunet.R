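#' Normalized 2-D Gaussian convolution kernel
#'
#' Builds the fixed smoothing kernel used by the Gaussian convolution layers:
#' entry \eqn{(x, y)} is proportional to
#' \eqn{\exp(-((x-\mu)^2 + (y-\mu)^2) / (2\sigma^2))} with \eqn{\mu = (k-1)/2}
#' at the kernel centre, explicitly renormalized so the weights sum to one.
#'
#' @param size Odd kernel side length in pixels (default 9, the network's
#'   fixed smoothing kernel size).
#' @param sigma Standard deviation in pixels; must be positive.
#' @return A `size` x `size` numeric matrix summing to 1.
#' @examples
#' k <- gaussian_kernel(9, 1.7)
#' sum(k) # 1
#' @export
gaussian_kernel <- function(size = 9L, sigma = 1.7) {
  if (length(size) != 1L || size < 1 || !is_odd(size)) {
    stop("`size` must be a single odd integer >= 1", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  mu <- (size - 1) / 2
  d <- (seq_len(size) - 1) - mu
  k <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2)) / (2 * pi * sigma^2)
  k / sum(k)
}

#' Smooth a feature map with a fixed Gaussian kernel
#'
#' Depthwise convolution of each channel with the normalized Gaussian kernel,
#' using reflective (mirror) padding so output dimensions equal input
#' dimensions and constant regions are preserved exactly.
#'
#' @param features An H x W matrix or an (H, W, C, N) array.
#' @param size,sigma Kernel specification passed to [gaussian_kernel()].
#' @return Smoothed raster with the same dimensions as the input.
#' @export
gaussian_smooth <- function(features, size = 9L, sigma = 1.7) {
  k <- gaussian_kernel(size, sigma)
  was_matrix <- is.matrix(features)
  x <- as_tensor(features)
  y <- dwconv_fwd_cpp(x, k)
  if (was_matrix) tensor_to_matrix(y) else y
}

#' Network configuration
#'
#' @param variant One of `"unet"` (single-path baseline), `"gu_net"`
#'   (single path with fixed Gaussian smoothing before each DoubleConv),
#'   `"du_net"` (dual path, no Gaussian), `"dgu_net"` (dual path + Gaussian).
#' @param in_channels Input channels (grayscale = 1).
#' @param base_channels Width of the first stage; subsequent stages double.
#' @param depth Number of downsampling stages (5 for the reference layout).
#' @param gauss_size,gauss_sigma Fixed Gaussian kernel specification.
#' @param seed Seed for weight initialization.
#' @return A `network_config` list.
#' @export
network_config <- function(variant = c("dgu_net", "unet", "gu_net", "du_net"),
                           in_channels = 1L, base_channels = 64L, depth = 5L,
                           gauss_size = 9L, gauss_sigma = 1.7, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(depth >= 1, base_channels >= 1, in_channels >= 1)
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), gauss_size = as.integer(gauss_size),
                 gauss_sigma = gauss_sigma, seed = as.integer(seed)),
            class = "network_config")
}

conv_init <- function(kh, kw, cin, cout) {
  sdv <- sqrt(2 / (kh * kw * cin))
  w <- array(rnorm(kh * kw * cin * cout, sd = sdv), c(kh, kw, cin, cout))
  list(w = ag_param(w), b = ag_param(rep(0, cout)))
}

bn_init <- function(c) {
  st <- new.env(parent = emptyenv())
  st$r_mean <- rep(0, c)
  st$r_var <- rep(1, c)
  list(gamma = ag_param(rep(1, c)), beta = ag_param(rep(0, c)), state = st)
}

# DoubleConv: two (3x3 conv -> batch norm -> ReLU) blocks; when `gauss` is a
# 1-D kernel vector, a fixed (separable) Gaussian smoothing precedes the
# block (GaussDoubleConv).
mod_doubleconv <- function(cin, cout, gauss = NULL) {
  p <- list(conv1 = conv_init(3, 3, cin, cout), bn1 = bn_init(cout),
            conv2 = conv_init(3, 3, cout, cout), bn2 = bn_init(cout))
  fwd <- function(tape, x, training) {
    if (!is.null(gauss)) x <- op_gauss_sep(tape, x, gauss)
    x <- op_relu(tape, op_bn(tape, op_conv(tape, x, p$conv1$w, p$conv1$b),
                             p$bn1, training))
    op_relu(tape, op_bn(tape, op_conv(tape, x, p$conv2$w, p$conv2$b),
                        p$bn2, training))
  }
  list(p = p, fwd = fwd)
}

mod_conv1x1 <- function(cin, cout) {
  p <- conv_init(1, 1, cin, cout)
  fwd <- function(tape, x) op_conv(tape, x, p$w, p$b)
  list(p = p, fwd = fwd)
}

#' Build a segmentation network
#'
#' Constructs the gland segmentation network for one of the four variants.
#' The dual-path variants run two parallel five-stage encoders (the first
#' Gaussian-smoothed, the second plain), fuse them by channel concatenation
#' plus 1x1 reduction at downsampling levels 4 and 5, decode through two
#' mirrored paths (Gaussian processing at the first upsampling stage of path
#' one and the fourth upsampling stage of path two), concatenate the decoder
#' outputs, and apply a final upsampling followed by two convolutional layers
#' to emit a single-channel logit map.
#'
#' @param cfg A [network_config()].
#' @return An object of class `cle_network`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(cfg$seed, build_network_impl(cfg))
}

build_network_impl <- function(cfg) {
  d <- cfg$depth
  ch <- cfg$base_channels * 2^(seq_len(d) - 1)
  # 1-D factor of the (separable) normalized Gaussian kernel
  mu <- (cfg$gauss_size - 1) / 2
  gk <- exp(-((seq_len(cfg$gauss_size) - 1) - mu)^2 / (2 * cfg$gauss_sigma^2))
  gk <- gk / sum(gk)
  dual <- cfg$variant %in% c("du_net", "dgu_net")
  gaussy <- cfg$variant %in% c("gu_net", "dgu_net")

  make_encoder <- function(use_gauss) {
    lapply(seq_len(d), function(i) {
      cin <- if (i == 1) cfg$in_channels else ch[i - 1]
      mod_doubleconv(cin, ch[i], gauss = if (use_gauss) gk else NULL)
    })
  }
  # decoder stage i consumes the skip at level `lev` and halves the width
  make_decoder <- function(levels, gauss_stage) {
    lapply(seq_along(levels), function(s) {
      lev <- levels[s]
      # upsampled feature width equals the skip width at every stage
      cin <- 2L * ch[lev]
      cout <- ch[max(lev - 1, 1)]
      mod_doubleconv(cin, cout,
                     gauss = if (!is.na(gauss_stage) && s == gauss_stage) gk else NULL)
    })
  }

  mods <- list()
  if (!dual) {
    mods$enc <- make_encoder(gaussy)
    mods$bottleneck <- mod_doubleconv(ch[d], ch[d],
                                      gauss = if (gaussy) gk else NULL)
    # full single-path decoder: levels d..1, ends at full resolution
    mods$dec <- make_decoder(rev(seq_len(d)), NA_integer_)
    mods$head <- mod_conv1x1(ch[1], 1L)
  } else {
    mods$enc1 <- make_encoder(gaussy) # Gaussian path
    mods$enc2 <- make_encoder(FALSE)  # plain path
    mods$fuse4 <- mod_conv1x1(2L * ch[d - 1], ch[d - 1])
    mods$fuse5 <- mod_conv1x1(2L * ch[d], ch[d])
    mods$bottleneck <- mod_doubleconv(ch[d], ch[d], gauss = NULL)
    # dual decoders stop one level short (at 1/2 resolution): levels d..2
    mods$dec1 <- make_decoder(rev(seq_len(d))[1:(d - 1)],
                              if (gaussy) 1L else NA_integer_)
    mods$dec2 <- make_decoder(rev(seq_len(d))[1:(d - 1)],
                              if (gaussy) min(4L, d - 1L) else NA_integer_)
    # final upsampling then two convolutional layers -> logits
    mods$head_dc <- mod_doubleconv(2L * ch[1], ch[1], gauss = NULL)
    mods$head <- mod_conv1x1(ch[1], 1L)
  }

  net <- list(cfg = cfg, mods = mods)
  class(net) <- "cle_network"
  net
}

#' @export
print.cle_network <- function(x, ...) {
  np <- sum(vapply(network_params(x), function(p) length(p$value), 0))
  cat(sprintf("<cle_network> variant=%s depth=%d base=%d params=%s\n",
              x$cfg$variant, x$cfg$depth, x$cfg$base_channels,
              format(np, big.mark = ",")))
  invisible(x)
}

network_params <- function(net) collect_params(net$mods)

# Forward pass; x is an (H, W, C, N) array. Returns the logits node.
network_forward <- function(net, tape, x, training = FALSE) {
  d0 <- dim(x)
  if (d0[1L] %% 2^net$cfg$depth != 0 || d0[2L] %% 2^net$cfg$depth != 0) {
    stop(sprintf("input size must be divisible by 2^depth = %d",
                 2^net$cfg$depth), call. = FALSE)
  }
  m <- net$mods
  d <- net$cfg$depth
  xn <- ag_node(NULL, x)
  run_encoder <- function(enc) {
    skips <- vector("list", d)
    h <- xn
    for (i in seq_len(d)) {
      skips[[i]] <- enc[[i]]$fwd(tape, h, training)
      h <- op_maxpool(tape, skips[[i]])
    }
    list(skips = skips, out = h)
  }
  run_decoder <- function(dec, start, skips, levels) {
    h <- start
    for (s in seq_along(levels)) {
      h <- op_up2(tape, h)
      h <- dec[[s]]$fwd(tape, op_concat(tape, h, skips[[levels[s]]]), training)
    }
    h
  }
  if (!net$cfg$variant %in% c("du_net", "dgu_net")) {
    e <- run_encoder(m$enc)
    b <- m$bottleneck$fwd(tape, e$out, training)
    h <- run_decoder(m$dec, b, e$skips, rev(seq_len(d)))
    m$head$fwd(tape, h)
  } else {
    e1 <- run_encoder(m$enc1)
    e2 <- run_encoder(m$enc2)
    f4 <- m$fuse4$fwd(tape, op_concat(tape, e1$skips[[d - 1]], e2$skips[[d - 1]]))
    f5 <- m$fuse5$fwd(tape, op_concat(tape, e1$skips[[d]], e2$skips[[d]]))
    b <- m$bottleneck$fwd(tape, op_maxpool(tape, f5), training)
    levels <- rev(seq_len(d))[1:(d - 1)]
    sk1 <- e1$skips; sk1[[d]] <- f5; sk1[[d - 1]] <- f4
    sk2 <- e2$skips; sk2[[d]] <- f5; sk2[[d - 1]] <- f4
    h1 <- run_decoder(m$dec1, b, sk1, levels)
    h2 <- run_decoder(m$dec2, b, sk2, levels)
    h <- op_up2(tape, op_concat(tape, h1, h2))
    h <- m$head_dc$fwd(tape, h, training)
    m$head$fwd(tape, h)
  }
}

#' Predict a gland probability map
#'
#' Runs the network in inference mode. Inputs whose dimensions are not
#' divisible by `2^depth` are reflect-padded and the output cropped back, so
#' any frame size is accepted (e.g. 892 x 892).
#'
#' @param net A trained [build_network()] object.
#' @param frame H x W grayscale matrix with values in \[0, 1\].
#' @return H x W matrix of foreground probabilities in (0, 1).
#' @export
predict_prob <- function(net, frame) {
  stopifnot(is.matrix(frame))
  pd <- pad_to_multiple(frame, 2^net$cfg$depth)
  z <- network_forward(net, NULL, as_tensor(pd$img), training = FALSE)$value
  p <- 1 / (1 + exp(-tensor_to_matrix(z)))
  p[seq_len(pd$h), seq_len(pd$w), drop = FALSE]
}

#' Predict a binary segmentation mask
#'
#' @inheritParams predict_prob
#' @param threshold Probability cut in \[0, 1\]; the mask is
#'   `probability >= threshold`.
#' @return H x W binary matrix (1 = glandular foreground).
#' @export
predict_mask <- function(net, frame, threshold = 0.5) {
  p <- predict_prob(net, frame)
  (p >= threshold) * 1
}

#' Training configuration
#'
#' Defaults follow the reference protocol: binary cross-entropy loss, Adam,
#' learning rate 5e-5, 100 epochs, batch size 2, 80/20 train/validation split
#' with a fixed seed.
#'
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param split_fraction Training share of the dataset, in (0, 1\].
#' @param split_seed Seed for the random split and shuffling.
#' @param loss Loss identifier; `"bce"` (binary cross-entropy) is supported.
#' @param max_steps Optional cap on total optimization steps.
#' @export
train_config <- function(learning_rate = 5e-5, epochs = 100L, batch_size = 2L,
                         split_fraction = 0.8, split_seed = 1L, loss = "bce",
                         max_steps = Inf) {
  stopifnot(learning_rate > 0, split_fraction > 0, split_fraction <= 1,
            identical(loss, "bce"))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed), loss = loss,
                 max_steps = max_steps),
            class = "train_config")
}

#' Train a segmentation network
#'
#' Splits the dataset deterministically, optimizes binary cross-entropy with
#' Adam, records the per-epoch mean training loss, and returns the weights
#' with the best validation Dice (final weights when no validation images
#' exist).
#'
#' @param net A [build_network()] object.
#' @param dataset List of `list(image = , mask = )` pairs of H x W matrices;
#'   masks binary.
#' @param tc A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A list with elements `net` (trained network), `loss_history`
#'   (per-epoch mean training BCE), `val_dice` (per-epoch validation Dice or
#'   `NA`), `train_idx`, `val_idx`.
#' @export
train_network <- function(net, dataset, tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "cle_network"), inherits(tc, "train_config"),
            length(dataset) >= 1)
  for (d in dataset) stopifnot_binary(d$mask)

  n <- length(dataset)
  n_train <- max(1L, round(tc$split_fraction * n))
  idx <- with_seed(tc$split_seed, sample.int(n))
  train_idx <- sort(idx[seq_len(n_train)])
  val_idx <- sort(setdiff(idx, train_idx))
  if (length(train_idx) == 0) stop("empty training split", call. = FALSE)

  params <- network_params(net)
  ast <- adam_state(params)
  step <- 0L
  loss_hist <- numeric(0)
  val_hist <- numeric(0)
  best_dice <- -Inf
  best_w <- NULL

  batch_tensor <- function(items, field) {
    h <- nrow(items[[1]][[field]]); w <- ncol(items[[1]][[field]])
    array(unlist(lapply(items, `[[`, field), use.names = FALSE),
          dim = c(h, w, 1L, length(items)))
  }

  for (ep in seq_len(tc$epochs)) {
    if (step >= tc$max_steps) break
    ord <- with_seed(derive_seed(tc$split_seed, ep), sample(train_idx))
    ep_losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = tc$batch_size)) {
      if (step >= tc$max_steps) break
      bi <- ord[b0:min(b0 + tc$batch_size - 1L, length(ord))]
      items <- dataset[bi]
      x <- batch_tensor(items, "image")
      y <- batch_tensor(items, "mask")
      tape <- ag_tape()
      z <- network_forward(net, tape, x, training = TRUE)
      loss <- op_bce_logits(tape, z, y)
      ag_backprop(tape, loss)
      step <- step + 1L
      ast <- adam_step(params, ast, tc$learning_rate, step)
      ep_losses <- c(ep_losses, loss$value)
    }
    loss_hist <- c(loss_hist, mean(ep_losses))
    vd <- NA_real_
    if (length(val_idx) > 0) {
      vd <- mean(vapply(val_idx, function(i) {
        segmentation_metrics(predict_mask(net, dataset[[i]]$image),
                             dataset[[i]]$mask)$dice
      }, 0))
      if (vd > best_dice) {
        best_dice <- vd
        best_w <- lapply(params, function(p) p$value)
      }
    }
    val_hist <- c(val_hist, vd)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  val dice %s", ep,
                      mean(ep_losses),
                      if (is.na(vd)) "-" else sprintf("%.2f", vd)))
    }
  }
  if (!is.null(best_w)) {
    for (i in seq_along(params)) params[[i]]$value <- best_w[[i]]
  }
  list(net = net, loss_history = loss_hist, val_dice = val_hist,
       train_idx = train_idx, val_idx = val_idx)
}

#' Segmentation quality metrics
#'
#' Accuracy, Dice coefficient, Jaccard index, sensitivity and specificity as
#' percentages from the confusion counts of a predicted vs. reference binary
#' mask. Ratios with a zero denominator are reported as 100 when both masks
#' are empty for that class and 0 otherwise.
#'
#' @param pred,truth Binary H x W matrices of identical dimensions.
#' @return A list with elements `ac`, `dice`, `ja`, `se`, `sp` in \[0, 100\].
#' @export
segmentation_metrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  stopifnot_binary(pred, "pred")
  stopifnot_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  ratio <- function(num, den, empty_ok) {
    if (den == 0) return(if (empty_ok) 100 else 0)
    100 * num / den
  }
  list(
    ac = 100 * (tp + tn) / (tp + tn + fp + fn),
    dice = ratio(2 * tp, 2 * tp + fp + fn, fp == 0 && fn == 0),
    ja = ratio(tp, tp + fp + fn, fp == 0 && fn == 0),
    se = ratio(tp, tp + fn, fp == 0),
    sp = ratio(tn, tn + fp, fn == 0)
  )
}

#' Evaluate a network on a dataset
#'
#' @param net Trained network.
#' @param dataset List of `list(image = , mask = )` pairs.
#' @param threshold Binarization threshold.
#' @param pooled If `TRUE`, pool confusion counts over all images before
#'   computing metrics; otherwise (default) report the mean of per-image
#'   metrics.
#' @return A list with `ac`, `dice`, `ja`, `se`, `sp`.
#' @export
evaluate_segmentation <- function(net, dataset, threshold = 0.5,
                                  pooled = FALSE) {
  preds <- lapply(dataset, function(d) predict_mask(net, d$image, threshold))
  if (pooled) {
    bigp <- do.call(rbind, preds)
    bigt <- do.call(rbind, lapply(dataset, `[[`, "mask"))
    segmentation_metrics(bigp, bigt)
  } else {
    ms <- Map(function(p, d) segmentation_metrics(p, d$mask), preds, dataset)
    as.list(colMeans(do.call(rbind, lapply(ms, unlist))))
  }
}
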