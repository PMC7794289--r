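---
title: "Classifying Alzheimer's disease from retinal vasculature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Alzheimer's disease from retinal vasculature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retvasc)
```

## The problem

The retina is the only part of the central nervous system that can be
photographed directly in vivo, and retinal microvascular changes — narrowing
vessel diameters, venular degeneration — accompany Alzheimer's disease. This
package implements a modular screening pipeline that asks whether the
geometry of the retinal vasculature, as captured in a segmented vessel map,
carries enough signal to separate AD patients from demographically identical
healthy controls with a conventional, interpretable classifier.

The pipeline has five analysis stages, each usable on its own:

1. **Quality gating.** Clinical fundus databases contain many images
   degraded by over- or under-exposure, defocus, faulty composition or
   artifacts. Five identically configured binary quality classifiers are
   trained with different random initializations — an in-silico
   multi-reviewer panel — and an image enters the study only if all five
   accept it. Unanimity is deliberately stricter than majority vote: a
   degraded image that slips through contributes non-pathological features
   downstream, which is costlier than discarding a usable image.
2. **Vessel segmentation.** Fundus photographs are reduced to vessel maps.
   The default is a classical multiscale vesselness filter (below); a
   trained segmentation network can be swapped in through the external
   backend because each stage only depends on its predecessor's output
   contract.
3. **Matched cohort construction.** For each AD image, controls are drawn
   with the *identical* integer age, sex, and eye side — exact matching, not
   a caliper — and partitioned into five redundant control groups, so any
   conclusion can be checked for dependence on one particular control draw.
4. **Classification.** A per-pixel two-sample Welch t-test on the training
   images selects discriminative pixels at p = 0.01; the selected
   intensities feed an RBF-kernel SVM evaluated under nested five-fold
   cross-validation.
5. **Saliency.** Occlusion tests at several window scales attribute the
   fitted model's decisions back to image regions.

## The classification model

For class $c \in \{\mathrm{AD}, \mathrm{CN}\}$ with $n_c$ images, let
$\bar I_{(x,y,c)}$ and $\sigma^2_{(x,y,c)}$ be the per-pixel sample mean and
variance. The per-pixel statistic is the unequal-variance (Welch) two-sample
t:

$$ t_{(x,y)} \;=\; \frac{\bar I_{(x,y,AD)} - \bar I_{(x,y,CN)}}
   {\sqrt{\sigma^2_{(x,y,AD)}/n_{AD} + \sigma^2_{(x,y,CN)}/n_{CN}}} $$

A pixel is selected when $|t|$ exceeds the two-sided critical value at
$\alpha$ (default 0.01) with Welch–Satterthwaite degrees of freedom. Because
the statistic is the unequal-variance form, the matching Welch–Satterthwaite
df is the only consistent choice for the threshold; a pooled df would
contradict the statistic itself. The test is two-sided — both vessel loss
and vessel gain are admissible signal — which makes the selected set
invariant under swapping the group labels. No multiplicity correction is
applied: the threshold is a raw per-pixel p-value cut, used as a feature
*filter* whose downstream utility is judged by cross-validated accuracy, not
as an inferential family of tests. Degenerate pixels where both group
variances vanish give $t = 0$ (equal means, never selected) or signed
infinity (unequal means, always selected).

Selected pixels, flattened row-major, feed a C-classification SVM with RBF
kernel. Performance is estimated by **nested** five-fold cross-validation:
stratified outer folds estimate accuracy; inside each outer training set an
inner five-fold grid search picks cost $C$ and kernel width $\gamma$
(log-spaced $6 \times 6$ grid, $C \in 10^{-2..3}$, $\gamma \in 10^{-4..1}$,
by default). The feature mask is refitted inside *every* inner training
split as well as on each outer training set, so neither the hyper-parameter
choice nor the final model ever sees held-out data through the selection —
the no-leakage property the chance-level null test verifies. Ties in the
inner grid search go to the first grid point (smallest cost). Each outer
fold contributes a confusion table from which accuracy, PPV, NPV,
specificity, sensitivity and F1 are derived; fold means and standard
deviations are reported, and metrics with zero denominators are NaN with a
warning rather than silently zero.

Classification itself uses the SVM decision rule; Platt-scaled class
probabilities are fitted only where a probability is needed — the occlusion
test — since a margin classifier has no native likelihood.

## Occlusion saliency

For window sizes 1, 2, 4 and 8 pixels (configurable; larger windows such as
32 may be added), a blackout patch slides with stride 1 over every position
fully inside the image. The raw importance of a position is the drop in the
model's probability for its predicted label when the patch is zeroed, stored
at the window's central pixel (offset $\lfloor (k-1)/2 \rfloor$ from the
top-left corner for even sizes). Per scale, raw values are min-max
normalized to $[0, 1]$; a constant raw map normalizes to zeros, and border
positions never covered by a window center contribute 0. The final map is
the per-pixel average across scales. Signed raw differences are kept before
normalization, so a window whose occlusion *increases* confidence is mapped
below the scale's midpoint; the most confidence-destroying window maps
to 1. Occluding an already-black region is exactly a no-op and yields raw
saliency identically zero — a useful invariant, because vessel maps are
mostly dark background.

## The synthetic data generator

No clinical images ship with the package; every stage is exercised on
synthetic data whose construction mirrors what the analysis assumes about
real data.

* **Vessel maps** are recursive branching trees rasterized on a square
  grid: four thick major branches (caliber ≈ 3 px) arc from an
  optic-disc-like origin, spawning thinner child branches whose caliber
  tapers with depth, all confined to the camera disc. The planted group
  difference multiplies thin-branch caliber and spawn probability by
  `small_vessel_effect` in the AD group only, so the discriminative signal
  lives in small vessels while major-branch morphology is identically
  distributed — matching the clinical observation that small vessels are the
  more vulnerable compartment. Setting the effect to 1 gives an exact null:
  AD and NC maps are then pixel-identical under the same seed.
* **Fundus renderings** composite dark vessels on a bright vignetted disc
  and apply one of four fault operators (exposure shift with clipping,
  Gaussian defocus, disc translation out of frame, bright blobs/streaks),
  mirroring the standard quality-fault taxonomy.
* **Subject tables** draw AD ages as uniform integers 55–75 (bracketing a
  cohort mean near 65), sexes Bernoulli(1/2), one image per subject with a
  random eye side, and generate five dedicated NC subjects with identical
  age and sex and the same eye side per AD subject — so exact matching is
  feasible by construction and its failure modes can be tested by deleting
  candidates.
* **Planted-signal cohorts** are i.i.d. Gaussian images with a mean shift of
  `effect_size` standard deviations confined to a known square region. They
  calibrate the feature-selection rate (effect 0 is an exact null) and make
  saliency localization scorable, since the discriminative region is known
  exactly.

What the generator does *not* emulate: photometric realism, optic disc and
macula anatomy, inter-eye correlation, age-dependent vascular change, or
spatially correlated acquisition noise. Passing tests therefore demonstrate
that the *machinery* is correct and leak-free under the stated statistical
structure, not that any particular accuracy transfers to clinical images.

## Study conditions used by the tests

Problem sizes are chosen so each check is statistically informative at desk
scale. Null-calibration uses 60 images per group on 64×64 grids (4096
pixels), where the binomial 3σ band around a 1% selection rate is
[0.004, 0.016]. Chance-level runs use 60-vs-60 null vessel cohorts. The
selection-benefit study plants a 2×2-pixel region (0.4% of a 32×32 grid) at
standardized effect 1.2 with 30 images per group: the total planted signal
caps Bayes accuracy near $\Phi(\sqrt{4}\cdot 1.2/2) \approx 0.88$, i.e. an
operating point comparable to the published regime this pipeline targets,
and sparse enough that a full-pixel kernel dilutes it — the regime where
selection should, and does, help. The separable sanity check raises the
effect to 5 SD over 5% of pixels, where near-perfect accuracy is expected.

## Numerical and design choices

* **Segmentation.** Frangi-style vesselness: Hessian of the Gaussian-smoothed
  image at scales {1, 2, 4} px (spanning the generator's caliber range),
  scale-normalized by $\sigma^2$, eigenvalues ordered by magnitude, response
  $\exp(-R_b^2/2\beta^2)(1 - \exp(-S^2/2c^2))$ with $\beta = 0.5$ and $c$
  set to half the maximal Hessian norm, gated to dark-on-bright ridges.
  Because the ridge response peaks on centerlines, full vessel caliber is
  recovered by a background-subtraction darkness map (the image minus its
  large-σ blur) merged into the hysteresis weak mask; components survive
  only if they touch a strong vesselness pixel. The camera disc is detected
  with a range-relative threshold (shift-equivariant by construction), dark
  vessel pixels inside it recovered by hole filling, and the rim eroded away
  since the aperture edge is itself a ridge. Accepted pixels carry graded
  confidence in [0.5, 1], so binarizing at 0.5 recovers the mask while
  consumers that want the continuous response still get one.
* **Quality members.** The panel members are small single-hidden-layer
  neural networks over eight image-quality features (intensity moments,
  clipped-pixel fractions, log gradient energy, disc coverage, bright-mass
  centroid offset, bright-outlier fraction), trained identically and
  differing only in initialization seed. The ensemble logic is the
  contribution; the member architecture is a pluggable interface, and a
  convolutional member can be substituted without touching the gate.
* **Matching.** Exact equality on (integer age, sex, eye); candidate ties
  are broken by a seeded random draw without replacement. Insufficient
  candidates is an error naming the deficient rows — no silent relaxation —
  because the generator guarantees feasibility and real deployments should
  surface, not paper over, a thin control pool. A `same_subject_blocks`
  option forces all images of one case to draw controls from a single
  control subject.
* **Resolution.** Maps are reduced by exact area averaging (block means) to
  a configurable classification resolution before pixel statistics; 32–64 px
  sides are used throughout the synthetic studies.
* **Determinism.** Every stochastic operation takes an explicit integer
  seed; child streams are derived by hashing a parent seed with a stream
  label. Identical configuration and seed reproduce byte-identical
  cross-validation JSON, which the test suite asserts.
* **Five control groups** are evaluated as five independent AD-vs-NC runs
  and averaged, so no conclusion hinges on one control draw.

## Limitations

The classifier treats pixels as features after rigid rasterization; no
registration, vessel graph extraction, or geometric normalization is
performed, so spatial misalignment across subjects would dilute the per-pixel
statistics on real data. The unanimity gate's member model is a
feature-based stand-in for the deep reviewers a production system would
train. Vesselness segmentation is tuned to the generator's rendering
contract (dark vessels, bright disc) and is not a benchmarked clinical
segmenter. All reported numbers in this package are computed on synthetic
cohorts by the test suite and the acceptance script; none are claims about
clinical data.
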