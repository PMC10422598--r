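---
title: "Counting and staging seedling emergence from nadir RGB imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and staging seedling emergence from nadir RGB imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soyemerge)
```

## The problem

Judging how well a soybean stand has emerged requires three pieces of
information at once: how many seedlings are up, which early growth stage each
one has reached — emergence (VE), cotyledon (VC), or first node (V1) — and
whether the stand is developing uniformly. Collecting this by hand is slow
and error-prone; low-altitude nadir RGB photography over the rows makes it a
tractable image-analysis task. `soyemerge` implements that task as a chain of
four modules — seedling detection and counting, automatic cutting of each
detection into a classifier-ready crop, growth-stage classification with a
compact convolutional network, and emergence-proportion reporting — plus a
synthetic scene generator that makes the whole chain testable without field
imagery.

## Detection and counting

Counting rests on classical segmentation rather than a learned detector.

**Grayscale conversion.** Seedlings are green on brown soil, so the default
conversion is the excess-green index $2G - R - B$, clipped to $[0, 255]$.
Luminance and the raw green channel are available alternatives
(`to_gray(rule=)`). Excess green is what makes bright but green-poor
distractors — dry corn stalks are the canonical example — separable from
vegetation by a single threshold.

**Otsu thresholding.** The threshold $k$ maximises the between-class
variance, written in the weighted-deviation form

$$\sigma^2(k) = w_0\,(\mu - \mu_0)^2 + w_1\,(\mu - \mu_1)^2,$$

where class 0 is the target (grey value strictly above $k$), class 1 the
background, $w_i$ their probabilities and $\mu, \mu_0, \mu_1$ the overall and
class means. The implementation scans all 256 candidates exhaustively; the
tests assert both equality with the algebraically equivalent product form
$w_0 w_1 (\mu_0 - \mu_1)^2$ and exact agreement with an independent
brute-force scan. Two conventions the formula leaves open are pinned
explicitly and tested: ties break towards the smallest maximising $k$, and
binarisation is *strictly* greater-than ($\text{mask} = \{p : g(p) > k\}$). A
constant image has zero variance everywhere and is returned with a
`degenerate` flag, $k$ set at the constant value.

**Colour re-masking and components.** The binary mask is applied back to the
RGB image (original colour where vegetation, black elsewhere), and connected
components are taken over the non-black pixels of that masked colour image.
Adjacency is 8-connectivity by default — the four axial neighbours plus the
four diagonals — with 4-connectivity available for comparison; a diagonal
pair of pixels is one component under the former and two under the latter,
and the 8-connected component count can never exceed the 4-connected count.
Components are labelled in raster-scan order of their first pixel, which
makes detection indices reproducible. Labelling is a two-pass union-find in
C++.

**Area filtering and rectangles.** Components outside `[min_area, max_area]`
are dropped. The default `min_area` of 25 px corresponds to a 1 cm² footprint
at the default 2 mm/px ground sampling — small enough to keep every VE
seedling, large enough to reject noise speckle and weed fragments; it is
deliberately configurable because the right value depends on flight height.
Each surviving component is reported with its minimum axis-aligned bounding
rectangle (0-based, closed on both ends, `width = x_max - x_min + 1`) and
counted as exactly one seedling; overlapping plants that merge into one
component are therefore *undercounted, never split*, which the tests assert
on scenes with forced overlap. No morphological cleanup is applied before
labelling — with the excess-green default none is needed, and keeping the
chain minimal makes each stage auditable.

`annotate_detections()` draws the rectangles in red and the seedling indices
in blue (a built-in 3×5 digit font, no graphics device), recording the text
positions so tests can audit the overlay without OCR.

## Cutting and dataset construction

Each detection is expanded by a margin (default 10% of the larger rectangle
side — enough context to show the whole plant without pulling in
neighbours), clamped to the image, extracted, and resized to exactly
255×255×3 with bilinear interpolation; a window already at 255×255 passes
through pixel-identical. Labels use the stage coding 0 = VE, 1 = VC,
2 = V1.

Five augmentation operators enlarge the dataset: brightness gain (0.7–1.3),
horizontal flip, saturation adjustment (blend towards per-pixel luminance,
gain 0.7–1.3), random cropping retaining at least 80% of the area, and
scaling by 0.8–1.2 (centre-crop when zooming in, edge-replicating pad when
zooming out). All preserve the label and shape and are deterministic under a
seed; the parameter ranges are package defaults, chosen to perturb
appearance without destroying the morphological stage signal.

`build_dataset()` gives every original a configured number of augmented
copies (default 2, so 1000 originals per class become 3000) and balances
classes to equal counts by granting under-represented classes extra copies —
balancing by augmentation multiplicity rather than by discarding data.
The train/test split is stratified within each class at 3:1, with the test
share rounded *down* (3000 per class → 2250 train / 750 test). Augmented
entries are planned, not materialised: each manifest row records its source,
operator and seed, and `realise_crop()` regenerates pixels on demand, so the
manifest for thousands of crops costs kilobytes and is byte-reproducible
under its seed.

## The growth-stage classifier

The classifier is an AlexNet-style network adapted for this task: five
stride-1 "same"-padded convolutions with kernels shrinking 7 → 5 → 3 → 3 →
3, ReLU activations, local response normalisation after layers 1 and 2
(classic constants: neighbourhood 5, $\alpha = 10^{-4}$, $\beta = 0.75$,
$k = 2$), and overlapping max pooling — window 3, stride 2, so windows
overlap — halving the feature maps after layers 1, 2 and 5
(255 → 127 → 63 → 31). The head is the reduced fully connected stack
1024 → 256 → 3 with softmax, and dropout 0.6 on both hidden FC layers.
Training uses Adam at learning rate $10^{-4}$, batch size 32, categorical
cross-entropy (the natural loss for a 3-class softmax). The reference
training schedule is 150 epochs; the package's desk-scale default is 20.

Two sizing choices are the package's own. The per-layer channel counts are
not fixed by the architecture description, so they are configurable:
`net_config()` defaults to (32, 64, 96, 96, 64), and the reduced variants
used throughout the tests — (8, 12, 16, 16, 12) via `desk_net_config()`, and
(4, 6, 8, 8, 6) for the training runs — were sized by single-CPU wall-clock
measurements of the dominant matrix products so that a full training run
fits in minutes. Dropout is applied to both hidden FC layers (its placement
is otherwise unspecified).

There is no deep-learning framework in the package's dependency set, so the
numerical engine is part of the package: im2col convolution forward and
backward, pooling with cached argmax, LRN with its exact derivative, and a
fused Adam update, written against Armadillo and templated on the floating
type. Training runs in single precision for speed; the test suite
instantiates the same code in double precision and checks every layer's
backpropagated gradient against central differences. All stochastic pieces —
He-normal initialisation, epoch shuffles, dropout masks — derive from the
single training seed, so a fixed seed reproduces a run exactly. Inference
disables dropout and is deterministic; argmax ties break towards the lowest
class index.

Reported metrics follow the epoch-sum definitions: with per-epoch test loss
$L_e$ and accuracy $A_e$ over $e$ epochs, the average loss is
$AL = e_L / e$ and the average accuracy $AA = (e_A / e) \times 100\%$, where
$e_L$ and $e_A$ are the sums of loss and accuracy; model accuracy is
$A = N_C / N_T$, correctly classified over total. The per-epoch history
rows are the test-split evaluations after each epoch, alongside the mean
training loss.

## Emergence reporting

With per-stage counts $TP_i$ and total $ST = \sum_i TP_i$, the emergence
proportion of stage $i$ is $EP_i = TP_i / ST$; the three proportions sum to
one whenever anything emerged, and an empty field returns a defined report
without proportions. Proportion errors against reference observations are
absolute differences per stage, with table-wide maximum and minimum
summaries; the package bundles a six-date observation series from a
row-planted soybean trial (`example_emergence_observations()`) whose error
table reproduces exactly in the acceptance suite.

Count agreement against manual counts uses

$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad RMSE = \sqrt{\tfrac{1}{N}\sum_i (\hat y_i - y_i)^2}, \qquad
MAE = \tfrac{1}{N}\sum_i |\hat y_i - y_i|,$$

the standard coefficient of determination being the only sensible reading of
the fit-quality role it plays (a ratio of plain deviations is not
scale-invariant). "Average accuracy" has no standard formula, so the package
defines and documents it as the per-site mean of
$(1 - |\hat y_i - y_i| / y_i) \times 100\%$, excluding (and counting) sites
with $y_i = 0$. $R^2$ is flagged undefined when the real counts have no
variance.

Emergence uniformity is qualitative in the field; the package codifies it as
three configurable rules so it can be tested: a stand is uniform when the
dominant stage holds at least `theta_dom` (default 0.90) of the seedlings
and nothing flags a problem; it is non-uniform with reasons when all three
stages each exceed `theta_coexist` (default 0.05, "multi-stage
coexistence"), when no stage dominates, or when the emerged total falls
below `theta_density` (default 0.5) of an expected count ("low emergence").
The verdict is monotone in `theta_dom`: raising the bar never turns a
non-uniform stand uniform.

## The synthetic scene generator

The generator emulates the acquisition conditions the pipeline is built
for: parallel rows 225 mm apart, plants about 71 mm apart along the row
(jitter truncated at 80% of the mean so disjoint stays disjoint), green
plants on brown soil at 2 mm/px ground sampling — a 640×520 px default frame
standing in for a low-altitude nadir photograph. Plants are procedural
ellipse composites, not photorealistic renderings: a VE seedling is one
compact blob, VC two opposed cotyledon lobes joined by a hypocotyl stem, V1
larger cotyledons plus a node/leaf cluster attached to the stem. Stage is
thus encoded by lobe count and footprint area, which is a learnable,
documented signal. Per-plant and per-pixel colour jitter, a multiplicative
illumination gain with a random linear gradient, and i.i.d. Gaussian sensor
noise (default sd 6 grey levels) perturb the rendering. Distractors are
elongated stalk-like rectangles, brighter than the scene median but with
excess green far below the vegetation threshold — reproducing the classic
false-positive source so the detector's rejection of it is testable.

Ground truth records every plant's centre, stage and exact footprint pixel
set. The layout, stage assignment, plant rendering, distractors,
illumination and noise draw from independent sub-seeded streams, so
switching distractors on leaves the plants bit-identical — paired
distractor/no-distractor experiments compare like with like — and an
identical config reproduces the scene byte for byte.

`synthetic_crop_set()` renders single plants with the same morphologies but
zoomed the way cut-and-resized detections are (each plant spans 55–80% of
the 255×255 frame), which is the geometry the classifier actually sees in
the pipeline.

What the generator does *not* emulate — leaf texture, specular highlights,
cast shadows, soil cracking, weeds with plant-like spectra, perspective
distortion — bounds what passing tests mean: they verify the algorithmic
contracts (thresholding, connectivity, counting, shape learning, proportion
arithmetic) under controlled conditions, not field-grade accuracy on real
imagery, whose headline numbers depend on the acquisition campaign.

## Numerical choices and problem sizes

Images are numeric arrays on the 0..255 scale, coordinates are 0-based
(x, y) = (column, row), and rectangles are closed on both ends; crops cross
into the engine as integer arrays and are scaled to 0..1 there. The engine's
LRN exponent uses a square-root fast path for the classic $\beta = 0.75$.
Reports contain no timestamps, so pipeline reruns with the same config and
seed are byte-identical (wall-clock logging goes to the run log only).

The test and acceptance runs use sizes chosen to exercise every contract at
desk scale: 50 seeded scenes for count recovery, 200 random images for the
Otsu oracle, 100 random masks for the connectivity inequality, 300 synthetic
crops per class for 20 epochs for the classifier check (reduced channels
(4, 6, 8, 8, 6)), and a 200-per-class, 15-epoch training demonstration
inside the acceptance script.

## Limitations

Adaptive thresholding needs a genuine vegetation class to anchor on: below
roughly half a percent vegetation cover the between-class variance of the
soil noise rivals that of the soil/plant split, and the chosen threshold can
land inside the noise. `detect_seedlings()` therefore treats a vegetation
mask covering more than `max_veg_fraction` (default 0.25) of the frame as a
degenerate segmentation and reports zero detections with a flag, so an
all-soil image counts zero instead of speckle; frames with only a handful of
seedlings remain outside the method's operating regime.

Overlapping plants are counted as one (instance segmentation is out of
scope); the classifier is trained and validated on procedural crops, so its
synthetic accuracy does not transfer to field imagery without retraining on
real cut crops; the uniformity rules are a codification of a qualitative
judgement and their thresholds should be tuned to agronomic practice; and
the bundled observation series serves as worked input data, not as evidence
about any particular field.
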