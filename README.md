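# mofex

Motion feature extraction, tracking and injury classification from image
sequences.

`mofex` implements a complete, testable batch pipeline for analysing human
motion in video-like image sequences, of the kind used to monitor posture
and injury risk during physical activity:

- **Foreground extraction** with a per-pixel Gaussian-mixture background
  model: each pixel's gray-level history is modelled as
  `p(x) = Σ_k w_k N(x; μ_k, σ_k²)` with `Σ_k w_k = 1`, updated online
  (Stauffer–Grimson style: match within 2.5 σ, learning rate α, replace the
  weakest component on no match). Foreground is the thresholded difference
  against the reconstructed background, cleaned by a 3×3 morphological
  opening.
- **Moment features**: central moments
  `E_pq = Σ (x − x̄)^p (y − ȳ)^q D(x, y)` of a mask or gray image and their
  normalized counterparts `η_pq = E_pq / E_00^γ`, `γ = (p+q)/2 + 1` for
  `p+q ∈ {2, 3, 4}`, plus a separable low-pass prefilter.
- **CAMSHIFT colour tracking** from a kernel-weighted hue histogram target
  model `p_u = I_h Σ_i k(‖(y − x_i)/h‖²) δ(b(x_i) − u)` (Epanechnikov
  profile), histogram back-projection, mean-shift recentring with
  mass-proportional window resizing, and **red-marker feedback**: when the
  back-projection confidence collapses, the window re-initializes on the
  nearest detected saturated-red marker region.
- **Injury-region localization and classification**: greedy snake descent
  on `E = a·E_in + β·E_es` (membrane + curvature internal energy, negative
  gradient-magnitude external energy), and an eigen-subspace classifier —
  eigendecomposition of the training covariance, components retained up to
  60 % cumulative eigenvalue mass by default, nearest neighbour by
  Euclidean distance in coefficient space.
- **Graph-convolutional feature management**: detections become nodes of a
  temporal/spatial graph; features propagate by
  `h^l = σ(D^{-1/2}(A + I)D^{-1/2} h^{l-1} W^{l-1})`, with the equivalent
  spectral view `U g(Λ) Uᵀ x` on the normalized Laplacian.
- A **seeded synthetic-scene generator** (moving elliptical blobs with red
  marker patches over a static textured background) with exact ground-truth
  masks, trajectories, marker centroids and labelled feature galleries, so
  every stage is tested against known truth.

## Worked example

```r
library(mofex)

# a 64x64, 40-frame scene: one moving blob carrying a red marker
scene <- make_scene(default_scene_config(seed = 1))

# track it from its starting window
tk <- track(scene, search_window(c(32, 14), c(12, 9)))
track_rmse(tk, scene$truth$trajectories[[1]])
#> [1] 0.3658852

# background model and foreground quality after 30 warm-up frames
grays <- lapply(scene$frames, to_gray)
gmm <- init_gmm(grays[[1]])
for (t in 2:31) gmm <- update_gmm(gmm, grays[[t]])
mask_iou(foreground_mask(gmm, grays[[32]]), scene$truth$masks[[32]])
#> [1] 0.8858447

# or run everything at once
report <- run_pipeline(list(out_dir = "mofex_out", seed = 2))
report
#> Pipeline run (mofex 0.1.0): 5 stage(s), 1.15 s
#>   background frames=40 warmup_frames=30 foreground_pixels=7905 seconds=0.749
#>   moments    frames_with_mass=40 seconds=0.208
#>   tracking   frames=40 reinit_events=0 rmse_px=0.3660529 seconds=0.079
#>   damage     queries=15 accuracy=1 retained_components=6 seconds=0.016
#>   graph      nodes=40 edges=39 layers=2 seconds=0.007
```

The track RMSE is the root-mean-square distance in pixels between the
tracked window centre and the blob's true trajectory; the IoU is the
intersection-over-union between the extracted foreground mask and the
ground-truth mask; the pipeline report echoes per-stage record counts and
the held-out classification accuracy of the synthetic injury gallery.

A thin command-line front end with `simulate`, `track`, `moments`,
`classify`, `graph` and `run` subcommands is installed at
`system.file("cli", "mofex.R", package = "mofex")`.

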