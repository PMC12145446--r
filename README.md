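# organoidvit

Drug-induced liver injury (DILI) drives a large share of post-market drug
withdrawals. 3-D liver models — patient-derived liver organoids and HepG2
spheroids — show characteristic morphological responses to hepatotoxic
compounds within days, visible in plain brightfield microscopy: untreated
organoids grow into translucent hollow spheres, mildly affected cultures
arrest but stay intact, and severely affected cultures disintegrate around
Day 2. `organoidvit` turns those four-day brightfield z-stack series into a
three-class DILI-severity prediction (`vNo-` / `vLess-` / `vMost-DILI-
Concern`, the DILIrank classes retained after excluding ambiguous-concern
compounds).

The classifier factorizes time × depth × space into three encoders and a
head:

- a **ViT image encoder** per frame: N = HW/P² patches (196 of 16×16 at
  224 px), linear patch embedding + learnable 2-D positions + CLS token,
  L pre-LN transformer blocks `z' = MSA(LN(z)) + z; z = MLP(LN(z')) + z'`
  with `SA(x) = softmax(qkᵀ/√D_h)v`, final LayerNorm, CLS state out;
- a **two-block spatial encoder** over each day's Z frame-CLS tokens (own
  CLS token, no positional encoding — output is z-permutation invariant);
- a **Bi-LSTM temporal encoder** over the T per-day tokens, pooled as the
  concatenation of final forward/backward hidden states;
- an **MLP head** to 3 logits and softmax.

Training is cross-entropy + AdamW (lr 2e-4, batch 6, 100 epochs by
default) under stratified 5-fold cross-validation, with an optional
BEiT-style masked-image-modeling warm start (`mim_pretrain()`): ~40% of
patches are replaced by a learnable mask embedding and a linear head
regresses the masked patches' pixels. Because the original organoid image
datasets are available only on request, the package ships a synthetic
organoid simulator (`generate_sample()`, `generate_dataset()`) that
reproduces the three phenotypes — hollow-sphere growth, arrest,
Day-2 disintegration — with z-dependent defocus, so the whole method is
buildable and testable from nothing. All forward/backward passes are
implemented in R with Rcpp/Armadillo kernels and verified against
numerical gradients.

Evaluation utilities cover one-vs-rest confusion-matrix metrics (recall,
specificity, precision, F1, accuracy), ROC/AUC by threshold sweep,
Laplacian-variance focus stacking (`fuse_zstack()`), the two ablation
experiments (`run_ablation()`: Day 0–1 truncation; spatial-encoder removal
on fused images), and attention-rollout heatmaps (`attention_map()`,
`overlay_heatmap()`).

## A worked example

```r
library(organoidvit)

cfg <- sim_config(image_size = 48, z_planes_range = c(2, 3),
                  organoids_per_field = c(1, 2))
gen <- generate_stacks(5, cfg, seed = 11)

feats <- dataset_features(gen$stacks)
head(feats, 3)
#> # A tibble: 3 × 5
#>   sample_id label            area_ratio comp_ratio n_comp_last
#>   <chr>     <chr>                 <dbl>      <dbl>       <int>
#> 1 S001      vNo-DILI-Concern       6           1             1
#> 2 S002      vNo-DILI-Concern       6.06        0.5           1
#> 3 S003      vNo-DILI-Concern       6.37        1             1
```

`area_ratio` is the Day-3/Day-0 foreground area on focus-fused frames
(~6 for growing `vNo` organoids, ~1 under arrest, far below 1 after
disintegration) and `comp_ratio` the matching connected-component ratio
(> 1 once a sphere fragments). A two-threshold rule on these features
separates the synthetic classes, certifying the learning task is solvable;
the transformer then has to rediscover the morphology from pixels:

```r
cv <- run_synthetic_benchmark(seed = 1, n_per_class = 30)
cv
#> <stvit_cv> 5 folds | fold accuracies: 0.833 0.722 0.889 1.000 0.944 | mean 0.8778
```

Across seeds 1-3 the cross-validated accuracy averages 0.93 (0.878 /
0.944 / 0.978).

`tidy(cv)` / `glance(cv)` expose per-fold and averaged metrics as tibbles;
`autoplot(cv$mean_report)` draws the pooled confusion matrix.

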