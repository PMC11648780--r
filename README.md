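# cytoshift

Few-shot domain adaptation for the classification of nucleated blood cell
images.

## The problem

Morphological classification of white blood cells and erythroblasts from
stained smear images is a cornerstone of haematological diagnosis, and
convolutional classifiers do it well — until the images come from a
different laboratory. Stain palette, illumination, camera, magnification,
and resolution shift the pixel distribution ("domain shift") and accuracy
collapses. `cytoshift` implements a deliberately lightweight adaptation
workflow for this setting, aimed at a clinical centre that can afford to
annotate **at most 100 images** of its local data:

1. **Colour standardization** — every image is moved into a common colour
   style by matching per-channel means and standard deviations in the
   decorrelated log-opponent lαβ space (Reinhard statistics transfer):
   `x' = (x − μ_src)·σ_ref/σ_src + μ_ref` per channel, computed against a
   reference style pooled from the source training images.
2. **Source training** — an encoder + 128-d embedding + (512, 6) head
   classifier with batch normalization, dropout, ReLU, and a
   label-smoothing cross-entropy loss is trained on mixed-domain batches
   from the source datasets (batch 16, Adam, 15 epochs).
3. **Few-shot fine-tuning** — for each target domain, a stratified split
   selects `min(100, floor(n/10))` tuning images; hyperparameters come
   from a random search scored by stratified 3-fold cross-validation on
   that tuning set; the model is fine-tuned (full-model by default,
   head-only as an ablation) and evaluated on every remaining image.
4. **Quantification** — accuracy with percentile-bootstrap confidence
   intervals, per-class and macro precision/recall, class-averaged
   precision-recall curves, embedding exports for 2-D visualization, a
   wrong-prediction analysis (including the rank of the true class in the
   output probability vector), and a six-condition ablation harness with
   exact paired Wilcoxon signed-rank tests.

A synthetic blood-smear generator with controllable class morphology
(nucleus lobation, granule hue, cytoplasm colour) and domain style (stain
hue, brightness, background, blur, zoom, noise) makes the entire pipeline
testable and reproducible without any external image data. See the
methods vignette (`vignettes/cytoshift-methods.Rmd`) for the model,
parameter choices, and limitations.

## Worked example

A reduced version of the package's reference benchmark: two mildly
differing source styles, one strongly shifted target style (shift
magnitude 0.7), and two of the six ablation conditions. Runs in a couple
of minutes on one CPU:

```r
library(cytoshift)

bm <- run_synthetic_benchmark(seed = 1, n_seeds = 1,
                              n_per_class_source = 25,
                              n_per_class_target = 40, budget = 60,
                              conditions = ablation_conditions()[c(2, 6), ])
bm$source_accuracy
#>   seed  accuracy
#> 1    1 0.9666667
bm$summary[, c("condition", "accuracy")]
#>            condition  accuracy
#> 1 without_finetuning 0.4611111
#> 2  proposed_workflow 0.8500000
```

Reading: the source model reaches 0.97 held-out accuracy within its own
domains; applied to the shifted target without adaptation (but with the
colour transform) it drops to 0.46; colour standardization plus
fine-tuning on 60 labelled target images recovers 0.85 — a few
annotations buy back most of the gap. The full benchmark
(`run_synthetic_benchmark()` with its defaults: 600 source and 600 target
images, budget 100, three seeds) sharpens these numbers to 0.99 / 0.47 /
0.92.

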