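# savannaseg

Semantic segmentation of savanna tree species from very-high-resolution RGB
orthomosaics, as a desk-scale, fully testable R pipeline.

## The problem

Savanna tree layers are species-rich, morphologically heterogeneous and
strongly class-imbalanced: a bare-ground/herb background dominates the area,
and most tree species cover only small, patchy fractions of it.
Convolutional encoder-decoder networks (U-Net, FC-DenseNet, DeepLabv3+) can
map such canopies from centimetre-scale UAV imagery, but the surrounding
machinery — class weighting against imbalance, tiled inference over rasters
far larger than a network input, model selection on noisy validation curves,
and landscape-ecology covariates of per-class accuracy — is rarely available
as tested, reusable code. `savannaseg` implements that machinery end to end
and ships a seeded synthetic-scene generator so every stage can be exercised
and verified without field data or a GPU.

## What it computes

- **Class weighting.** For class shares `p_i` of the training pixels, loss
  weights are `w_i = 1 / p_i^x` with a tunable exponent `x >= 0` (`x = 0`
  disables weighting; absent classes get weight 0). The per-architecture
  defaults are `x = 0.1` (U-Net), `0.005` (FC-DenseNet), `0.2` (DeepLabv3+).
- **Weighted categorical cross-entropy** over pixels,
  `mean( w_c * -log p_hat_c )`, and **mIoU**
  `mean_i( O_i / U_i )` with `O_i` the true positives of class `i` and
  `U_i = TP + FP + FN`, classes absent from both masks excluded.
- **Training** with Adam (`alpha = 1e-4`, `beta1 = 0.9`, `beta2 = 0.999`),
  at most 300 epochs, early stopping after 40 epochs without validation-mIoU
  improvement, batch size scaled inversely with tile area, and per-epoch
  checkpoints. The best epoch is chosen on a degree-2 LOESS smoothing of the
  validation curve.
- **Inference** writes 16 prediction layers — tile grids offset by 0, 25, 50
  and 75% of the tile size in each axis — and fuses them by per-pixel
  majority vote (ties to the lowest class id).
- **Evaluation**: confusion matrix, per-class precision/recall/F1
  (`F1 = 2PR/(P+R)`), mean F1, overall accuracy, Cohen's kappa, mIoU, paired
  t-tests between model configurations.
- **Landscape metrics** per class — mean patch area, total class area, and
  smallest-circumscribing-circle compactness (`1 - a_patch / a_circle`) —
  with OLS regressions of per-class F1 on each metric (df = n - 2).

The three architectures are implemented natively at configurable scale on a
small compiled CNN engine (im2col convolution with dilation, max-pooling,
nearest-neighbour upsampling, backpropagation, Adam), so the whole pipeline
runs on one CPU.

## Worked example

```r
library(savannaseg)

cfg <- preset_separable_config(out_dir = "run", seed = 1)
run <- run_experiment(cfg)
run$summary
#>   architecture tile_size best_epoch epochs_run  mean_f1 overall_accuracy
#> 1         unet        64         25         25 0.978213        0.9858398
#>       kappa      miou
#> 1 0.9704384 0.9577657

temporal_transfer_eval(run, c(0, 0.5, 1), seed = 2)
#>   strength   mean_f1      miou
#> 1      0.0 0.9782130 0.9577657
#> 2      0.5 0.9472031 0.9029874
#> 3      1.0 0.5235239 0.4343906
```

The preset simulates three spectrally separable classes (70% bare ground,
18% and 12% vegetation), trains a depth-2 U-Net with inverse-power class
weighting for up to 25 epochs, picks the best epoch from the smoothed
validation curve, and predicts a held-out scene with the 16-layer majority
vote: mean F1 0.98 and kappa 0.97 on the held-out scene. The transfer table
re-evaluates that model on increasingly perturbed copies of the test scene
(a stand-in for imagery recorded in a later phenological phase): accuracy
decays monotonically, halving the mean F1 at full perturbation strength.

Individual stages are plain functions — `generate_scene()`, `tile_scene()`,
`augment_pair()`, `compute_class_weights()`, `build_model()`, `train()`,
`select_best_epoch()`, `predict_offset_stack()`, `majority_vote()`,
`summary_metrics()`, `class_landscape_metrics()` — and configurations can be
read from YAML via `read_pipeline_config()`.

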