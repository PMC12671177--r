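# Sequence/mask I/O, checkpoints, and the top-level pipeline tying
# segmentation -> stable-frame selection -> stitching -> evaluation together.

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required for TIFF input")
      }
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e) {
    stop(sprintf("unreadable image file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(dim(img)) == 3) {
    # luminance conversion for multi-channel input
    ch <- dim(img)[3]
    if (ch >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}

#' Load an image sequence from a directory
#'
#' Frames are sorted lexicographically by filename, converted to grayscale by
#' luminance if multi-channel, and scaled to \[0, 1\] (8-bit 255 maps to
#' 1.0).
#'
#' @param dir Directory containing the frames.
#' @param pattern Filename regular expression (default: PNG/TIFF files).
#' @return List of H x W matrices.
#' @export
load_sequence <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  if (!dir.exists(dir)) stop(sprintf("directory '%s' not found", dir),
                             call. = FALSE)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) {
    stop(sprintf("no image files matching '%s' in '%s'", pattern, dir),
         call. = FALSE)
  }
  frames <- lapply(files, read_gray)
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(dims)) != 1) {
    stop("inconsistent frame dimensions across the sequence: ",
         paste(unique(dims), collapse = ", "), call. = FALSE)
  }
  names(frames) <- basename(files)
  frames
}

#' Write a frame as an 8-bit grayscale PNG
#'
#' Values are clamped to \[0, 1\] and quantized with round-half-up.
#'
#' @param img H x W matrix.
#' @param path Output file path.
#' @export
write_frame <- function(img, path) {
  q <- floor(clamp01(img) * 255 + 0.5) / 255
  png::writePNG(q, path)
  invisible(path)
}

#' Write a synthetic sequence to disk
#'
#' Writes zero-padded `frame_0000.png` / `mask_0000.png` files plus
#' `labels.json` (stability booleans) and `transforms.json` (row-major 3 x 3
#' consecutive-pair transforms).
#'
#' @param seq A [generate_sequence()] result.
#' @param dir Output directory (created if missing).
#' @export
write_sequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(seq$frames)
  for (i in seq_len(n)) {
    write_frame(seq$frames[[i]], file.path(dir, sprintf("frame_%04d.png", i - 1)))
    write_frame(seq$masks[[i]], file.path(dir, sprintf("mask_%04d.png", i - 1)))
  }
  jsonlite::write_json(seq$stability_labels,
                       file.path(dir, "labels.json"))
  jsonlite::write_json(lapply(seq$true_pair_transforms,
                              function(h) as.vector(t(h))),
                       file.path(dir, "transforms.json"), digits = NA)
  invisible(dir)
}

#' Save / load a trained network checkpoint
#'
#' The checkpoint stores the network configuration, all weights and the batch
#' normalization running statistics.
#'
#' @param net A `cle_network`.
#' @param path Checkpoint file path.
#' @export
save_network <- function(net, path) {
  params <- network_params(net)
  bns <- collect_bn_states(net$mods)
  saveRDS(list(cfg = unclass(net$cfg),
               weights = lapply(params, function(p) p$value),
               bn = lapply(bns, function(st) list(r_mean = st$r_mean,
                                                  r_var = st$r_var))),
          path)
  invisible(path)
}

collect_bn_states <- function(x) {
  if (is.environment(x) && !is.null(x$r_mean)) return(list(x))
  if (is.list(x) && !inherits(x, "ag_param")) {
    return(unlist(lapply(x, collect_bn_states), recursive = FALSE))
  }
  list()
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$cfg[c("variant", "in_channels",
                                          "base_channels", "depth",
                                          "gauss_size", "gauss_sigma",
                                          "seed")])
  net <- build_network(cfg)
  params <- network_params(net)
  stopifnot(length(params) == length(ck$weights))
  for (i in seq_along(params)) params[[i]]$value <- ck$weights[[i]]
  bns <- collect_bn_states(net$mods)
  stopifnot(length(bns) == length(ck$bn))
  for (i in seq_along(bns)) {
    bns[[i]]$r_mean <- ck$bn[[i]]$r_mean
    bns[[i]]$r_var <- ck$bn[[i]]$r_var
  }
  net
}

#' Pipeline configuration
#'
#' @param frames_dir Directory of input frames.
#' @param masks_dir Directory of binary masks aligned to the frames, or
#'   `NULL` to segment with `model`.
#' @param model Path to a [save_network()] checkpoint (used when `masks_dir`
#'   is `NULL`).
#' @param out_dir Output directory for the panorama and report.
#' @param threshold,normalization Stable-frame selection settings
#'   (`threshold = NULL` asks [suggest_threshold()] for one).
#' @param mask_threshold Binarization threshold for network masks.
#' @param stitch A [stitch_config()].
#' @param block_sizes Sharpness evaluation block sizes.
#' @param seed Global seed propagated to every stochastic stage.
#' @export
pipeline_config <- function(frames_dir, masks_dir = NULL, model = NULL,
                            out_dir = "clemosaic_out", threshold = 0.8,
                            normalization = "fraction", mask_threshold = 0.5,
                            stitch = stitch_config(),
                            block_sizes = c(64L, 128L, 256L), seed = 1L) {
  if (is.null(masks_dir) && is.null(model)) {
    stop("configuration error: either `masks_dir` or `model` is required",
         call. = FALSE)
  }
  structure(list(frames_dir = frames_dir, masks_dir = masks_dir,
                 model = model, out_dir = out_dir, threshold = threshold,
                 normalization = normalization,
                 mask_threshold = mask_threshold, stitch = stitch,
                 block_sizes = as.integer(block_sizes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full mosaicking pipeline
#'
#' Segmentation (network inference, or supplied masks), stable-frame
#' selection, mask-constrained stitching of the stable subset, and the
#' evaluation battery (jitter variance of the original vs. the
#' selected-then-interpolated sequence; block sharpness variance of the
#' panorama; SSIM/RMSE over registered consecutive overlaps). Writes
#' `panorama.png` and `report.json` under `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, `list(panorama_path = , report_path = , report = )`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  say("[1/5] loading frames from %s", cfg$frames_dir)
  frames <- load_sequence(cfg$frames_dir)
  if (!is.null(cfg$masks_dir)) {
    say("[2/5] loading masks from %s", cfg$masks_dir)
    masks <- lapply(load_sequence(cfg$masks_dir), function(m) (m >= 0.5) * 1)
    if (length(masks) != length(frames)) {
      stop("frame/mask counts differ", call. = FALSE)
    }
  } else {
    say("[2/5] segmenting %d frames with %s", length(frames), cfg$model)
    net <- load_network(cfg$model)
    masks <- lapply(frames, predict_mask, net = net,
                    threshold = cfg$mask_threshold)
  }

  say("[3/5] selecting stable frames (threshold %s, %s mode)",
      format(cfg$threshold), cfg$normalization)
  sel <- select_stable_frames(unname(masks),
                              threshold = if (is.null(cfg$threshold)) Inf else cfg$threshold,
                              normalization = cfg$normalization)
  if (is.null(cfg$threshold)) {
    thr <- suggest_threshold(sel$scores)
    say("      suggested threshold: %.4g", as.numeric(thr))
    sel <- select_stable_frames(unname(masks), threshold = as.numeric(thr),
                                normalization = cfg$normalization)
  }
  idx <- sel$stable_indices
  say("      %d / %d frames stable", length(idx), length(frames))

  say("[4/5] stitching %d stable frames", length(idx))
  st <- stitch_sequence(unname(frames)[idx], unname(masks)[idx],
                        cfg = cfg$stitch, verbose = verbose)

  say("[5/5] evaluating")
  orig_path <- estimate_camera_path(unname(frames), seed = cfg$seed)
  stab_frames <- align_frame_count(unname(frames)[idx], idx, length(frames))
  stab_path <- estimate_camera_path(stab_frames, seed = cfg$seed)
  jit <- list(original = as.list(jitter_variance(orig_path)),
              stabilized = as.list(jitter_variance(stab_path)))
  sharp <- lapply(cfg$block_sizes, function(bs) {
    vals <- lapply(c("laplacian", "sobel", "brenner"), function(met) {
      g <- tryCatch(block_sharpness(st$panorama, bs, met),
                    error = function(e) NULL)
      if (is.null(g)) return(NA_real_)
      tryCatch(sharpness_uniformity(g), error = function(e) NA_real_)
    })
    names(vals) <- c("laplacian", "sobel", "brenner")
    vals
  })
  names(sharp) <- paste0("block_", cfg$block_sizes)
  ret_global <- idx[st$retained]
  rel_homs <- lapply(seq_len(length(st$retained) - 1), function(t) {
    solve(st$homographies[[t]]) %*% st$homographies[[t + 1]]
  })
  sq <- sequence_quality(unname(frames)[ret_global], rel_homs)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pano_path <- file.path(cfg$out_dir, "panorama.png")
  write_frame(st$panorama, pano_path)
  report <- list(
    n_frames = length(frames),
    selection = list(stable_indices = idx, threshold = sel$threshold,
                     normalization = sel$normalization,
                     scores = sel$scores$d),
    stitching = list(retained = ret_global, dropped = idx[st$dropped],
                     gains = st$gains,
                     homographies = lapply(st$homographies,
                                           function(h) as.vector(t(h)))),
    evaluation = list(jitter_variance = jit, sharpness_variance = sharp,
                      sequence_quality = list(ssim_mean = sq$ssim_mean,
                                              ssim_sd = sq$ssim_sd,
                                              rmse_mean = sq$rmse_mean,
                                              rmse_sd = sq$rmse_sd)),
    seed = cfg$seed
  )
  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  say("done in %.1f s: %s", as.numeric(difftime(Sys.time(), t_start,
                                                units = "secs")),
      report_path)
  invisible(list(panorama_path = pano_path, report_path = report_path,
                 report = report))
}
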