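# soyemerge

Field-management decisions at the soybean seedling stage hinge on three
numbers that are tedious to collect by hand: how many seedlings have
emerged, what early growth stage each has reached — emergence (VE),
cotyledon (VC), first node (V1) — and whether the stand is emerging
uniformly. `soyemerge` computes all three from nadir RGB photographs of
row-planted fields, the kind captured by a camera drone a few metres above
the canopy, and ships a synthetic scene generator with exact ground truth so
the entire chain is testable without any field imagery.

The pipeline is an ensemble of four stages:

1. **Detection and counting.** The image is converted to the excess-green
   index $2G - R - B$, thresholded at the grey level $k$ maximising the
   between-class variance
   $\sigma^2(k) = w_0(\mu-\mu_0)^2 + w_1(\mu-\mu_1)^2$ (Otsu's method,
   exhaustive over all 256 candidates), re-masked to colour, and analysed
   into 8-connected components; components passing an area filter are each
   counted as one seedling and marked with their minimum bounding
   rectangle.
2. **Automatic cutting.** Every detection is expanded by a margin, clamped,
   and resized to a 255×255×3 crop; datasets are built from crops with the
   five augmentation operators (brightness, horizontal flip, saturation,
   random crop, scale), class balancing, and a stratified 3:1 train/test
   split.
3. **Growth-stage classification.** A compact AlexNet-style CNN — five
   stride-1 convolutions with kernels 7/5/3/3/3, LRN after the first two,
   overlapping 3×3/stride-2 max pooling at layers 1, 2 and 5, FC
   1024 → 256 → 3 with dropout 0.6 — trained with Adam (lr $10^{-4}$, batch
   32) on categorical cross-entropy. The conv/pool/FC engine is implemented
   in the package (RcppArmadillo); no external deep-learning framework is
   required.
4. **Emergence reporting.** Per-stage proportions $EP_i = TP_i / ST$, a
   configurable uniformity verdict, and count-agreement statistics against
   manual counts: $R^2$, RMSE, MAE and per-site average accuracy.

## A worked example

```r
library(soyemerge)

# a synthetic field scene with known ground truth: 24 plants in 4 rows
sc  <- generate_scene(scene_config(seed = 7))
det <- detect_seedlings(sc$image)
det
#> 24 seedling(s) detected (Otsu k = 98, min area = 25 px)
scene_to_count_truth(sc)
#> stage counts: VE 6, VC 10, V1 8 (total 24)

# cut each detection into a classifier-ready crop
crops <- lapply(seq_len(det$count), function(i)
  cut_crop(sc$image, det$detections[i, ]))

# train the reduced-channel stage classifier on synthetic crops
train <- synthetic_crop_set(150, seed = 2001)
man   <- build_dataset(train$crop, n_aug = 0, seed = 1)
fit   <- train_stagenet(build_model(net_config(conv_channels = c(4, 6, 8, 8, 6))),
                        man, train$crop, train_config(epochs = 10, seed = 1))
glance(fit)
#> # A tibble: 1 x 5
#>   epochs    AL    AA final_accuracy n_params
#>    <int> <dbl> <dbl>          <dbl>    <dbl>
#> 1     10 0.852  62.6          0.829  6171239

# classify the cut crops and report emergence
stages <- classify_crops(fit, crops)
report <- uniformity_verdict(
  emergence_proportion(stage_counts(sum(stages == 0), sum(stages == 1),
                                    sum(stages == 2))))
report
#> emergence report: EP(VE) = 0.7500, EP(VC) = 0.2500, EP(V1) = 0.0000 (ST = 24)
#>   emergence non-uniform (no dominant stage)
```

The count says 24 seedlings were detected, matching the scene's ground
truth exactly. The stage proportions are only as good as this deliberately
small training run (AL is the average per-epoch test loss, AA the average
accuracy over epochs; final test accuracy here is 0.83): the report leans
towards VE relative to the true 6/10/8 stage split, and the stand is
correctly judged non-uniform because no stage dominates. Training at the
scale used in the test suite (300 crops per class, 20 epochs, about ten
minutes on one CPU) reaches 0.956 test accuracy.

Comparing predicted against real per-stage proportions uses the bundled
six-date observation series:

```r
pe <- proportion_error_table(example_emergence_observations())
c(pe$max_error, pe$min_error)
#> [1] 0.0775 0.0060
```

## Command line

A thin CLI over the same functions lives at `inst/cli/soyemerge`:

```sh
Rscript inst/cli/soyemerge synth  --n-images 5 --seed 1 --out scenes/
Rscript inst/cli/soyemerge detect --input scenes/ --min-area 25 --out det/
Rscript inst/cli/soyemerge report --labels labels.csv --out report.json
```
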