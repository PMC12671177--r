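#' @useDynLib clemosaic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif var sd median quantile
#' @importFrom utils modifyList
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Fan a base seed out to a per-item stream, kept within 32-bit integer range.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(counter) * 104729) %% 2147483647)
}

stopifnot_binary <- function(m, arg = "mask") {
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (values in {0, 1})", arg), call. = FALSE)
  }
  invisible(TRUE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Promote an H x W matrix (or H x W x C x N array) to the (H, W, C, N) layout
# used by the tensor kernels.
as_tensor <- function(x) {
  if (is.matrix(x)) {
    array(x, dim = c(nrow(x), ncol(x), 1L, 1L))
  } else if (length(dim(x)) == 4L) {
    x
  } else {
    stop("expected a matrix or a 4-d (H, W, C, N) array", call. = FALSE)
  }
}

tensor_to_matrix <- function(x) matrix(x[, , 1L, 1L], dim(x)[1L], dim(x)[2L])

# Reflect-pad a matrix so both dims are multiples of `m`; returns padded matrix
# plus the original dims for cropping back.
pad_to_multiple <- function(img, m) {
  h <- nrow(img); w <- ncol(img)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  if (ph == 0 && pw == 0) {
    return(list(img = img, h = h, w = w))
  }
  ridx <- c(seq_len(h), rev(seq_len(h))[seq_len(ph)])
  cidx <- c(seq_len(w), rev(seq_len(w))[seq_len(pw)])
  list(img = img[ridx, cidx, drop = FALSE], h = h, w = w)
}

is_odd <- function(k) k %% 2 == 1
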