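# Minimal reverse-mode autodiff tape for the segmentation network.
#
# Nodes are environments holding $value and (after backprop) $grad. Recording
# happens only when a tape is supplied; with tape = NULL the same ops run in
# pure inference mode and keep no caches. All dense kernels live in src/ops.cpp.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (!is.null(tape) && !is.null(backward)) {
    nd$parents <- parents
    nd$backward <- backward
    tp_n <- tape$n + 1L
    if (tp_n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tp_n]] <- nd
    tape$n <- tp_n
  }
  nd
}

ag_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$is_param <- TRUE
  class(nd) <- "ag_param"
  nd
}

ag_backprop <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL # free memory as we go
  }
  invisible(NULL)
}

# ---- tensor ops -----------------------------------------------------------

op_conv <- function(tape, x, w, b) {
  xv <- x$value
  y <- conv2d_fwd_cpp(xv, w$value, b$value)
  if (is.null(tape)) return(ag_node(NULL, y))
  wv <- w$value
  ag_node(tape, y, parents = list(x, w, b), backward = function(dy) {
    g <- conv2d_bwd_cpp(xv, wv, dy)
    list(g$dx, g$dw, g$db)
  })
}

op_gauss <- function(tape, x, kernel) {
  y <- dwconv_fwd_cpp(x$value, kernel)
  if (is.null(tape)) return(ag_node(NULL, y))
  ag_node(tape, y, parents = list(x), backward = function(dy) {
    list(dwconv_bwd_cpp(dy, kernel))
  })
}

# Separable Gaussian smoothing layer: two 1-D depthwise passes, exactly
# equal to convolving with outer(g1, g1) but ~k/2 times cheaper.
op_gauss_sep <- function(tape, x, g1) {
  kc <- matrix(g1, ncol = 1)
  kr <- matrix(g1, nrow = 1)
  y <- dwconv_fwd_cpp(dwconv_fwd_cpp(x$value, kc), kr)
  if (is.null(tape)) return(ag_node(NULL, y))
  ag_node(tape, y, parents = list(x), backward = function(dy) {
    list(dwconv_bwd_cpp(dwconv_bwd_cpp(dy, kr), kc))
  })
}

op_relu <- function(tape, x) {
  xv <- x$value
  y <- xv
  y[y < 0] <- 0
  if (is.null(tape)) return(ag_node(NULL, y))
  ag_node(tape, y, parents = list(x), backward = function(dy) {
    dy[xv <= 0] <- 0
    list(dy)
  })
}

op_maxpool <- function(tape, x) {
  d <- dim(x$value)
  mp <- maxpool2_fwd_cpp(x$value)
  if (is.null(tape)) return(ag_node(NULL, mp$y))
  idx <- mp$idx
  ag_node(tape, mp$y, parents = list(x), backward = function(dy) {
    list(maxpool2_bwd_cpp(dy, idx, d[1L], d[2L]))
  })
}

op_up2 <- function(tape, x) {
  d <- dim(x$value)
  y <- up2_fwd_cpp(x$value)
  if (is.null(tape)) return(ag_node(NULL, y))
  ag_node(tape, y, parents = list(x), backward = function(dy) {
    list(up2_bwd_cpp(dy, d[1L], d[2L]))
  })
}

op_concat <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L], da[4L] == db[4L])
  y <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  y[, , seq_len(da[3L]), ] <- a$value
  y[, , da[3L] + seq_len(db[3L]), ] <- b$value
  if (is.null(tape)) return(ag_node(NULL, y))
  ag_node(tape, y, parents = list(a, b), backward = function(dy) {
    list(dy[, , seq_len(da[3L]), , drop = FALSE],
         dy[, , da[3L] + seq_len(db[3L]), , drop = FALSE])
  })
}

# Batch normalization over (H, W, N) per channel. `bn` carries the learnable
# gamma/beta and an environment with running statistics.
op_bn <- function(tape, x, bn, training, momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  if (training) {
    st0 <- bn_stats_cpp(xv)
    m <- st0$mean
    v <- st0$var
    st <- bn$state
    st$r_mean <- (1 - momentum) * st$r_mean + momentum * m
    st$r_var <- (1 - momentum) * st$r_var + momentum * v
  } else {
    m <- bn$state$r_mean
    v <- bn$state$r_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  fw <- bn_fwd_cpp(xv, m, inv_sd, bn$gamma$value, bn$beta$value)
  if (is.null(tape)) return(ag_node(NULL, fw$y))
  xhat <- fw$xhat
  ag_node(tape, fw$y, parents = list(x, bn$gamma, bn$beta),
          backward = function(dy) {
    g <- bn_bwd_cpp(dy, xhat, bn$gamma$value, inv_sd, training)
    list(g$dx, g$dgamma, g$dbeta)
  })
}

# Numerically stable binary cross-entropy on logits; returns a scalar node.
op_bce_logits <- function(tape, z, target) {
  zv <- z$value
  n <- length(zv)
  loss <- sum(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))) / n
  if (is.null(tape)) return(ag_node(NULL, loss))
  ag_node(tape, loss, parents = list(z), backward = function(dy) {
    p <- 1 / (1 + exp(-zv))
    list(dy * (p - target) / n)
  })
}

collect_params <- function(x) {
  if (inherits(x, "ag_param")) return(list(x))
  if (is.list(x)) return(unlist(lapply(x, collect_params), recursive = FALSE))
  list()
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(params) {
  lapply(params, function(p) list(m = 0 * p$value, v = 0 * p$value))
}

adam_step <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
    state[[i]] <- st
  }
  state
}
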