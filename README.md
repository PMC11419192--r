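# cherenkovseg

Transfer learning for segmenting vascular bio-morphological features in
low-SNR Cherenkov images from radiotherapy.

During external-beam radiotherapy, Cherenkov imaging shows superficial,
patient-specific dark structures — mainly subcutaneous veins — that could
anchor positioning verification and motion management, if only they could
be segmented quickly and reliably from noisy, low-contrast cumulative
images. Annotated Cherenkov vasculature is scarce, so this package
implements the two-stage remedy: **pretrain** a residual encoder–decoder
segmentation network on abundant fundus-photograph-like vessel patches
(source domain), then **fine-tune** all parameters on a small Cherenkov-like
set (target domain), selecting the checkpoint with minimum validation loss.
Writing `f_T` for the target predictor, fine-tuning learns the correction
`f_T(x) = f_S(x) + Δf(x)` by continuing the same risk minimisation from the
pretrained weights.

The training objective is the weighted compound loss

```
L_seg = λ1 · L_Dice(y_t, y_p) + λ2 · L_CE(y_t, y_p),   λ1 = 1, λ2 = 0.1
```

on sigmoid probabilities, optimised with RMSProp (batch 24, lr 1e-5, L2
decay 1e-8 during pretraining; 400 + 100 epochs at full scale). Data flows
through a patch-based protocol: centered N·224 ROIs (N ≤ 4 for
beam-limited Cherenkov images), non-overlapping 224×224 tiling, retention
of patches whose labeled area strictly exceeds 5%, a seeded 90/10
train/validation split, and on-the-fly augmentation (33% horizontal flip,
33% right-angle rotation, 50% Gaussian noise up to 25% of the dynamic
range).

Because the clinical data behind this design is IRB-restricted, the package
ships a synthetic vascular phantom generator covering both domains —
branching dark vessel trees on bright backgrounds; a noisy, beam-limited
target domain; 19.6 fps video streams with optional sinusoidal breathing
motion — so the entire pipeline, including the robustness and
sub-cumulative video protocols, runs and is tested end to end without any
external data. Everything is implemented in R, with the network's forward
and backward passes written against Rcpp/RcppArmadillo im2col convolution
kernels.

## Worked example

Generate a source-domain phantom, patchify it, and sweep time gates on a
noisy 120-frame target-domain video with a threshold segmenter:

```r
library(cherenkovseg)

spec <- phantom_spec("source", image_size = 448, seed = 1)
tree <- sample_vessel_tree(spec)
ann  <- render_annotated(tree, spec)
ann
#> <annotated_image 'phantom': 448 x 448 px, source domain, 7.2% labeled>

patchify_image(ann, n_grid = 2, seed = 1)
#> <patch_set: 3 patches of 224 x 224 px (3 train / 0 val)>
#> # A tibble: 3 × 7
#>   parent  origin_row origin_col labeled_fraction image    mask     split
#>   <chr>        <int>      <int>            <dbl> <list>   <list>   <chr>
#> 1 phantom          0          0           0.0510 <dbl[…]> <int[…]> train
#> 2 phantom        224          0           0.143  <dbl[…]> <int[…]> train
#> 3 phantom        224        224           0.0743 <dbl[…]> <int[…]> train
```

Only three of the four tiles survive the 5% retention filter — the fourth
carries too little vessel. The video protocol aggregates frames into
sub-cumulative images and scores each window against the full cumulation:

```r
vspec <- phantom_spec("target", image_size = 256, noise_sigma = 0.25, seed = 2)
fs <- render_video(sample_vessel_tree(vspec), vspec, n_frames = 120, seed = 3)
fs
#> <frame_stack: 120 frames of 256 x 256 px at 19.6 fps (6.1 s)>

subcumulative_analysis(threshold_segmenter(), fs, gates = c(10, 30, 60, 120))
#> # A tibble: 4 × 5
#>   gate_frames gate_seconds n_windows mean_dice  se_dice
#>         <int>        <dbl>     <int>     <dbl>    <dbl>
#> 1          10          0.5        12     0.889  0.00249
#> 2          30          1.5         4     0.939  0.00122
#> 3          60          3.1         2     0.953  0.00646
#> 4         120          6.1         1     1     NA
```

Half a second of frames already gives Dice ≈ 0.89 against the 6.1 s
cumulation, and the agreement rises monotonically with the gate — the
temporal-resolution/SNR trade the protocol quantifies. The transfer
experiment itself is one call (`phantom_transfer_benchmark()`); at the
package's scaled settings (200 source / 20 target patches of 64×64,
2-level network, 30 + 30 epochs) fine-tuning beats identically-seeded
scratch training by a wide margin, e.g.

```r
phantom_transfer_benchmark(n_seeds = 2, seed = 1)
#> # A tibble: 2 × 4
#>    seed finetuned_dice scratch_dice transfer_wins
#>   <dbl>          <dbl>        <dbl> <lgl>
#> 1     1          0.763        0.548 TRUE
#> 2  1001          0.771        0.639 TRUE
```

where the Dice columns are the selected (minimum-validation-loss)
checkpoints' validation Dice. Fitted stages are tidyverse-friendly:
`tidy()` returns the per-epoch history, `glance()` the selection summary,
and `autoplot()` the loss curves or gate sweeps.

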