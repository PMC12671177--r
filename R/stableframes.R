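# Mask-projection stability scoring and stable-frame selection.
#
# A frame's gland layout is summarized by the row and column projections of
# its binary segmentation mask; the squared difference of consecutive
# profiles (the D metric) spikes when rolling-shutter shear or large probe
# motion deforms the layout, giving a bimodal score distribution from which
# stable frames are selected.

#' Row/column projection profiles of a segmentation mask
#'
#' The raw row profile is `R(y) = sum_x M(x, y)` (foreground count per row)
#' and the column profile `C(x) = sum_y M(x, y)`. In `"fraction"` mode
#' (default) the row profile is divided by the image width and the column
#' profile by the height, giving per-line foreground fractions in \[0, 1\]
#' that are comparable across frame sizes; `"raw"` keeps plain counts.
#'
#' @param mask Binary H x W matrix.
#' @param normalization `"fraction"` or `"raw"`.
#' @return A `projection_profile` list with `row` (length H), `col`
#'   (length W), `normalization`.
#' @export
projection_profiles <- function(mask, normalization = c("fraction", "raw")) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(mask))
  stopifnot_binary(mask)
  row <- rowSums(mask)
  col <- colSums(mask)
  if (normalization == "fraction") {
    row <- row / ncol(mask)
    col <- col / nrow(mask)
  }
  structure(list(row = row, col = col, normalization = normalization),
            class = "projection_profile")
}

#' Projection difference metric between two profiles
#'
#' `D = sum_y (R_i(y) - R_j(y))^2 + sum_x (C_i(x) - C_j(x))^2`: the summed
#' squared differences of the row profiles plus those of the column profiles.
#'
#' @param a,b `projection_profile` objects of equal lengths and matching
#'   normalization mode.
#' @return Non-negative scalar; 0 iff the profiles are identical.
#' @export
projection_difference <- function(a, b) {
  stopifnot(inherits(a, "projection_profile"),
            inherits(b, "projection_profile"))
  if (length(a$row) != length(b$row) || length(a$col) != length(b$col)) {
    stop("profile lengths differ", call. = FALSE)
  }
  if (!identical(a$normalization, b$normalization)) {
    stop("profiles use different normalization modes", call. = FALSE)
  }
  sum((a$row - b$row)^2) + sum((a$col - b$col)^2)
}

#' Select stable frames from a mask sequence
#'
#' Scores every consecutive mask pair with the projection difference metric.
#' A frame is kept as stable iff at least one pair score adjacent to it is
#' below the threshold — i.e. the frame's gland layout is corroborated by a
#' neighbouring frame (boundary frames have a single adjacent pair). Frames
#' failing this are discarded as motion-corrupted: a moving frame disagrees
#' with both of its neighbours, while the stable frames flanking a motion
#' burst still agree with their stable side.
#'
#' @param masks List of binary H x W matrices (length >= 2).
#' @param threshold Stability threshold on D (default 0.8, on the
#'   `"fraction"` scale).
#' @param normalization Profile normalization mode.
#' @return `list(stable_indices = , scores = )`; `scores` is a data.frame
#'   with columns `i`, `j`, `d`, `below` for each consecutive pair.
#' @export
select_stable_frames <- function(masks, threshold = 0.8,
                                 normalization = c("fraction", "raw")) {
  normalization <- match.arg(normalization)
  if (length(masks) == 0) stop("empty mask list", call. = FALSE)
  if (length(masks) < 2) stop("need at least 2 masks", call. = FALSE)
  profs <- lapply(masks, projection_profiles, normalization = normalization)
  n <- length(masks)
  d <- vapply(seq_len(n - 1),
              function(i) projection_difference(profs[[i]], profs[[i + 1]]),
              0)
  below <- d < threshold
  stable <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) below[i - 1] else NA
    right <- if (i < n) below[i] else NA
    isTRUE(left) || isTRUE(right)
  }, TRUE)
  if (any(vapply(masks, sum, 0) == 0)) {
    warning("sequence contains empty masks; their pair scores carry no ",
            "gland information", call. = FALSE)
  }
  list(stable_indices = which(stable),
       scores = data.frame(i = seq_len(n - 1), j = 2:n, d = d,
                           below = below),
       threshold = threshold, normalization = normalization)
}

#' Suggest a stability threshold from observed scores
#'
#' Finds the split that maximizes the between-class variance of the score
#' distribution (the optimal separation point between the low-score stable
#' cluster and the high-score motion-corrupted cluster of the characteristic
#' bimodal distribution). Because the scores are ratio-scale quantities whose
#' motion cluster spans orders of magnitude, the variance criterion is
#' evaluated on `log(d + eps)` with `eps = max(d) / 100 + 1e-12` (a scale-aware noise floor
#' that compresses the near-zero stable cluster); on the raw
#' scale the spread-out motion cluster drags the split into its own interior,
#' which keeps sheared frames. Candidate splits are the midpoints of
#' consecutive sorted unique log-scores (geometric means on the raw scale).
#' When the distribution shows no usable bimodality — no empty gap of at
#' least 10% of the log-range at the split — the returned value carries
#' attribute `degenerate = TRUE`.
#'
#' @param d Numeric vector of projection-difference scores (length >= 4), or
#'   the `scores` data.frame from [select_stable_frames()].
#' @return The suggested threshold, with attributes `degenerate` (logical)
#'   and `separation` (between-class share of total variance).
#' @export
suggest_threshold <- function(d) {
  if (is.data.frame(d)) d <- d$d
  stopifnot(is.numeric(d))
  if (length(d) < 4) stop("need at least 4 scores", call. = FALSE)
  u <- sort(unique(d))
  if (length(u) == 1) {
    return(structure(u, degenerate = TRUE, separation = 0))
  }
  eps <- max(d) / 100 + 1e-12
  s <- sort(log(d + eps))
  n <- length(s)
  cs <- cumsum(s)
  tot <- cs[n]
  k <- seq_len(n - 1) # class 1 = s[1..k]
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  between <- (k / n) * ((n - k) / n) * (m1 - m2)^2
  # only cuts between distinct values are realizable thresholds
  valid <- s[k] < s[k + 1]
  between[!valid] <- -Inf
  kbest <- which.max(between)
  thr <- exp((s[kbest] + s[kbest + 1]) / 2) - eps
  total_var <- mean((s - mean(s))^2)
  sep <- if (total_var > 0) between[kbest] / total_var else 0
  # bimodality shows as a wide empty gap at the chosen split; a unimodal
  # spread has near-uniform spacings there
  gap <- (s[kbest + 1] - s[kbest]) / (s[n] - s[1])
  structure(thr, degenerate = gap < 0.1, separation = sep)
}
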