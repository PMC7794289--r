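# retvasc

Classification of Alzheimer's disease (AD) from retinal vasculature images,
as an R package. The retina is the only directly photographable extension of
the central nervous system, and retinal microvascular degeneration — thinning
and loss of small vessels — accompanies AD. `retvasc` implements the full
screening pipeline needed to test whether segmented retinal vessel maps
separate AD patients from exactly matched healthy controls:

1. **Quality gating** — an ensemble of five identically configured quality
   classifiers, differing only in random initialization, applied as a cascade;
   an image is retained only on a *unanimous* "sufficient" vote.
2. **Vessel segmentation** — a multiscale Hessian vesselness filter with
   hysteresis linking (a trained segmentation model can be swapped in via a
   backend function).
3. **Matched cohort construction** — five redundant control groups, each
   matching the AD group *exactly* on age, sex, and eye side.
4. **Classification** — per-pixel feature selection by a two-sample Welch
   t-test, then an RBF-kernel SVM under nested stratified 5-fold
   cross-validation (inner folds tune cost and kernel width; feature
   selection is refit inside every training split, so no information leaks
   from held-out data).
5. **Saliency** — multiscale occlusion sensitivity maps explaining the
   fitted classifier's decisions.

No clinical data ship with the package. A synthetic generator produces
branching vascular trees with a controllable small-vessel group effect,
fundus-like renderings with four quality-fault operators, matched subject
tables, and planted-signal calibration cohorts, so every stage is exercised
and validated end to end on data with known ground truth.

## Core model

For each pixel $(x, y)$ and groups AD and CN with $n_{AD}$, $n_{CN}$ training
images, the selection statistic is the unequal-variance (Welch) t:

$$ t_{(x,y)} = \frac{\bar I_{(x,y,AD)} - \bar I_{(x,y,CN)}}
   {\sqrt{\sigma^2_{(x,y,AD)}/n_{AD} + \sigma^2_{(x,y,CN)}/n_{CN}}} $$

where $\bar I$ and $\sigma^2$ are the per-pixel sample mean and variance. A
pixel enters the feature vector when $|t|$ exceeds the two-sided critical
value at significance level $\alpha$ (default $0.01$) with
Welch–Satterthwaite degrees of freedom. Selected intensities feed a
C-classification SVM with RBF kernel
$K(u, v) = \exp(-\gamma \lVert u - v \rVert^2)$; $(C, \gamma)$ are chosen by
inner-fold grid search and performance is reported as the mean and standard
deviation over outer folds of accuracy, PPV, NPV, specificity, sensitivity
and F1. See the vignette
(`vignettes/retinal-vasculature-classification.Rmd`) for the segmentation,
quality-gate, matching and saliency models.

## Worked example

The numbered scripts under `analysis/` run the study end to end; each is a
thin driver over package functions and writes its artifacts under
`results/`. Run them in order from the package root:

```sh
Rscript analysis/01_simulate.R     # synthetic cohort + subject table
Rscript analysis/02_quality_gate.R # unanimity gate on clean vs faulty images
Rscript analysis/03_segment.R      # render -> segment round trip, Dice
Rscript analysis/04_match.R        # five exact-matched control groups
Rscript analysis/05_classify.R     # nested-CV SVM per control group
Rscript analysis/06_saliency.R     # occlusion saliency on a planted cohort
```

Actual output (seeds are fixed in the scripts, so these reproduce exactly):

```
== analysis/01_simulate.R ==
cohort: 20 AD and 100 NC images; AD thin-vessel pixels average 76 vs 336 in NC

== analysis/02_quality_gate.R ==
 stage member entering surviving
     1      1       20        10
     2      2       10        10
     ...
final unanimous-pass count: 10
focus-fault pass rates by severity: 1.00 0.00 0.00 0.00 0.00 0.00

== analysis/03_segment.R ==
render/segment round trip over 20 trees: mean Dice 0.914 (min 0.886)

== analysis/04_match.R ==
AD group: 20 images, age 67.35 (5.28)
control group 1: 20 images, age 67.35 (5.28) -- identical multiset
... (all five groups identical, no NC image reused)

== analysis/05_classify.R ==
group 1 with selection accuracy 0.850 (0.163)
...
average accuracy: 0.750 with selection vs 0.865 without

== analysis/06_saliency.R ==
mean saliency: 0.579 inside the planted region vs 0.053 outside (rank-sum p = 8.7e-18)
```

The quality gate passes all 10 clean images and rejects all 10 faulty
distractors; the matched control groups replicate the AD demographic multiset
exactly. On this particular synthetic study the planted small-vessel effect
is spatially *dense* (it touches most thin-vessel pixels), so t-test
selection at $\alpha = 0.05$ discards usable pixels and the all-pixel SVM is
slightly better (0.865 vs 0.750). Selection earns its keep in the sparse
regime: with a planted signal confined to 0.4 % of pixels, the acceptance
run below measures a selection gain of about +0.08 accuracy. Both regimes
are reported as observed; no parameters were tuned to favor either.

A minimal in-session example:

```r
library(retvasc)
cfg <- simulation_config(image_size = 64, n_ad = 20, small_vessel_effect = 0.5)
co  <- generate_cohort(cfg, seed = 1)
asg <- match_controls(co$table, n_groups = 5, seed = 11)
ids <- c(co$table$image_id[co$table$diagnosis == "AD"], control_group_ids(asg, 1))
res <- nested_cv(co$maps[ids], rep(c("AD", "NC"), each = 20),
                 svm_config(seed = 2), alpha = 0.05, resize_to = 32)
res$mean["accuracy"]
```

Alternatively, `run_pipeline(default_pipeline_config(seed = 1, output_dir = "out"))`
executes every stage (quality gate, segmentation, matching, per-group
nested CV, saliency) in one call and writes `cv_results.json` plus a report.

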