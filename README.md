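# flowinterp

Frame interpolation for microscopy time-lapses, with the downstream
evaluation built in.

Live-cell imaging has to ration light: sampling a dynamic process densely
in time bleaches the fluorophores and damages the cells.  A tempting
alternative is to acquire sparsely and synthesize the in-between frames —
but an interpolated movie is only as good as the analyses it feeds.
`flowinterp` is for researchers and method developers who want to *measure*
that: it couples classical and motion-compensated frame interpolators to a
seeded particle-motion simulator, pixel-based quality metrics, a
spot-tracking pipeline, the five particle-tracking-challenge criteria and
segmentation overlap scores, wired into reproducible benchmark protocols.

## The core method

Between two frames `A` and `B`, the content-aware interpolator (`"cafi"`)
estimates dense optical flow in both directions (pyramidal iterative
Lucas–Kanade with confidence-weighted regularization), backward-warps both
neighbours to the intermediate time `t`, and blends them:

    I_t = [(1-t) wA warp(A, -t F_AB) + t wB warp(B, -(1-t) F_BA)]
          / [(1-t) wA + t wB]

where the weights `wA`, `wB` down-weight pixels with inconsistent
forward/backward flows (occlusions) or correspondences outside the field of
view.  Baselines for comparison: frame duplication (`"none"`), temporal
linear blending (`"bil"`), and a Catmull–Rom temporal cubic (`"bic"`).
Applying 2x interpolation iteratively gives 4x/8x/16x upsampling
(`icafi()`), along time or along z.

The evaluation side implements scale-normalized Laplacian-of-Gaussian spot
detection with subpixel refinement, exact linear-assignment track linking
with gap closing, the five tracking criteria (alpha, beta, point and track
Jaccard, localization RMSE — oracle-tested against exhaustive enumeration),
SSIM/RMSE/PSNR with error maps, and matched-object mean IoU.

## A worked example

Simulate a dense particle movie, build a "velocity 4" ground truth (every
4th frame), remove every second frame, re-interpolate, and score both the
images and the tracking:

```r
library(flowinterp)

cfg <- simulation_config(width = 128, height = 128, n_frames = 81,
                         n_particles = 6, seed = 42)
sim <- simulate_particles(cfg)

gt        <- make_velocity_series(sim$sequence, v = 4, max_frames = 17)
gt_tracks <- downsample_tracks(sim$tracks, stride = 4, max_frames = 17)
sparse    <- downsample_axis(gt, 2)

held <- held_out_frames(gt, 2)$indices
for (method in c("none", "bil", "cafi")) {
  pred <- interpolate_sequence(sparse, method)
  print(quality_report(gt, pred, frames = held))
}
#> <quality_report> 8 frames: SSIM 0.9138, RMSE 0.0480, PSNR 26.6 dB
#> <quality_report> 8 frames: SSIM 0.9647, RMSE 0.0262, PSNR 31.78 dB
#> <quality_report> 8 frames: SSIM 0.9686, RMSE 0.0255, PSNR 32.17 dB

pred  <- interpolate_sequence(sparse, "cafi")
est   <- track_particles(normalize_sequence(pred, "minmax_global"),
                         diameter = 10, threshold = 0.1)
print(score_tracks(gt_tracks, est, epsilon = 5))
#> <tracking_score> alpha 0.8074, beta 0.8074, JSC 0.9519, JSC_theta 1.0000, RMSE 1.154 px
```

Reading the output: the three quality reports score the eight held-out
frames for duplication, blending and motion compensation — motion
compensation recovers the missing frames with the highest structural
similarity (0.969) and lowest error.  The tracking score says all six
trajectories were recovered (track Jaccard 1.0), 95% of individual
detections matched the ground truth within the 5-px gate, and the paired
detections sit 1.15 px from the true positions on average — the residual
is dominated by the Brownian motion component, which no interpolator can
predict at held-out times.

The same pipeline is scriptable from a shell via the bundled CLI
(`exec/flowinterp`): `simulate`, `interpolate`, `track`, `score-tracks`,
`evaluate-quality`, `evaluate-segmentation` and
`benchmark velocity|icafi|noise`, each writing a manifest with parameters,
seed and artifact checksums next to its outputs.

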