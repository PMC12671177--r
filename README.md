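# clemosaic

Rolling-shutter-resistant mosaicking of probe-based confocal laser
endomicroscopy (CLE) sequences.

CLE visualizes gastrointestinal mucosa at micron scale through a fiber
probe, but one frame spans only a few hundred microns, so consecutive
frames are stitched into a panorama to widen the examination field. Because
CLE acquires frames by progressive line scanning, probe motion shears each
frame row-by-row (the rolling shutter effect); these inconsistent
distortions break feature matching and corrupt naive mosaics. `clemosaic`
implements a segmentation-guided pipeline that suppresses them:

1. **Gland segmentation** — a dual-path Gaussian U-Net (two parallel
   encoders, one preceded by fixed 9×9 Gaussian convolutions of the form
   `G(x,y) ∝ exp(−((x−μ)² + (y−μ)²)/2σ²)`, fused at the two deepest
   downsampling levels, with mirrored dual decoders) produces a binary
   gland mask `M(x,y)` per frame. The ablation variants (plain U-Net,
   Gaussian-only, dual-path-only) are included, along with the training
   loop (binary cross-entropy, Adam, lr 5e-5, batch 2, fixed-seed 80/20
   split) and the AC/Dice/JA/SE/SP metric battery.
2. **Stable-frame selection** — masks are summarized by their row and
   column projections `R(y) = Σₓ M(x,y)`, `C(x) = Σ_y M(x,y)`, and
   consecutive frames scored with
   `D(i,i+1) = Σ_y (R_i − R_{i+1})² + Σ_x (C_i − C_{i+1})²`
   (per-line-fraction normalization by default). Frames acquired during
   probe pauses form a low-`D` cluster; an Otsu-style split (or the
   conventional threshold 0.8) separates them from motion-corrupted
   frames, which are discarded.
3. **Mask-constrained stitching** — SIFT-style keypoints (DoG scale-space,
   128-d gradient-histogram descriptors) are kept only on mask foreground,
   matched with Lowe's ratio test (0.75), registered by RANSAC
   homographies, composed to the middle reference frame, gain-compensated
   and multi-band blended into the panorama.
4. **Evaluation** — dense polynomial-expansion optical flow restores the
   original frame count by temporal interpolation
   (`I = (1−α)·I₁(x′) + α·I₂(x′)`); accumulated affine camera paths give
   frame-to-frame jitter variance; block-wise Laplacian/Sobel/Brenner
   sharpness variance measures mosaic uniformity; SSIM/RMSE score
   registered consecutive overlaps.

A seeded synthetic generator (`simgen`) renders CLE-like glandular scenes —
bright elliptical/tubular glands on a darker speckled background, a
"slow translation – brief pause" probe motion model, row-progressive shear
on moving frames — with exact ground-truth masks, transforms and stability
labels, and is the substrate for the whole test suite.

## Worked example

```r
library(clemosaic)

scene  <- gland_scene_params(image_size = c(192L, 192L), n_glands = 25L,
                             gland_axis_range = c(6, 12), seed = 7)
script <- motion_script(40, unstable_fraction = 0.25, move_px = c(6, 11),
                        seed = 3)
seq <- generate_sequence(scene, script)

scores <- select_stable_frames(seq$masks, threshold = Inf)$scores
thr <- suggest_threshold(scores)
sel <- select_stable_frames(seq$masks, threshold = as.numeric(thr))

st <- stitch_sequence(seq$frames[sel$stable_indices],
                      seq$masks[sel$stable_indices])

jv_orig <- jitter_variance(estimate_camera_path(seq$frames))
stab <- align_frame_count(seq$frames[sel$stable_indices],
                          sel$stable_indices, length(seq$frames))
jv_stab <- jitter_variance(estimate_camera_path(stab))
```

This run prints:

```
frames: 40  truly unstable: 6
suggested threshold: 0.458
stable frames: 34
panorama: 223 x 201 px from 34 frames
jitter variance (px^2)  original: 0.543 9.592   stabilized: 0.046 0.524
```

The data-driven threshold (0.458, the same order as the conventional 0.8 on
the fraction scale) removes exactly the six script-labelled moving frames; the
34 stable frames stitch into a 223×201 panorama, and after frame-count
restoration the camera-path jitter variance drops by an order of magnitude
on both axes — the rolling-shutter shake is gone while the intended probe
translation is preserved.

For real data, train the segmenter first (`build_network()`,
`train_network()`, `predict_mask()`) or supply masks directly, then call
`run_pipeline()` — or use the command-line front end in `inst/cli/clemosaic`
(subcommands `simulate`, `segment train/predict`, `select`, `stitch`,
`evaluate`, `run`).

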