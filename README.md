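# cardiotexture

Texture-based discrimination of cardiac tissue types in 2-D confocal
microscopy images.

## The problem

During surgical repair of congenital heart disease, cutting through
specialized conduction tissue (the sinoatrial and atrioventricular nodes)
causes lasting conduction disturbances — but nodal tissue looks like
ordinary atrial working myocardium (AWM) on the operating field. Confocal
imaging of extracellularly labeled tissue exposes a microstructural
difference: AWM has a **regularly striated** extracellular-space texture
(aligned myocyte rows), nodal tissue an **irregular reticular** one. This
package quantifies that difference and automates the classification, for
researchers evaluating intraoperative confocal imaging and for anyone who
needs a transparent, fully tested spatial-regularity classifier for
two-phenotype texture discrimination.

## The method

Each image is reduced to one regularity score **I15 ∈ [0, 1]** by either
of two spectral methods (image windowed with a 2-D Hann taper,
zero-meaned, DFT power spectrum in physical cycles/µm):

- **Fourier** — the fraction of non-DC spectral energy in the *striation
  band*: spatial periods 10–20 µm within ±15° of the dominant
  orientation. A striated image concentrates its energy in one spectral
  line inside the band (I15 → 1); a reticular image spreads it over all
  frequencies (I15 → 0).
- **Moments** — the anisotropy `1 − λ₂/λ₁` of the 2 × 2 second-order
  central moment matrix of the normalized power spectrum: collinear
  (grating-like) spectra give 1, isotropic spectra 0.

Labeled scores feed an exact ROC analysis; the decision cutoff minimizes
the cost-weighted corner distance `√(fn_cost·(1−TPR)² + fp_cost·FPR²)`
with **false positives (nodal called AWM) costed twice as much as false
negatives**, because misidentifying conduction tissue as workaday
myocardium is the surgically dangerous error. Classification at the
cutoff is summarized as sensitivity = 100·TP/(TP+FN) and specificity =
100·TN/(TN+FP), with multi-examiner panels aggregated as mean ± SE.

A seeded synthetic generator produces striated and reticular images at
the imaging scales of fiber-optics confocal microscopy (1.8 µm/px,
169 × 120 µm; 1.4 µm/px, 186 × 130 µm), so the whole pipeline runs and is
tested without instrument data.

## Worked example

```r
library(cardiotexture)

train <- generate_dataset(81, 81, seed = 101)   # 81 AWM + 81 nodal images
fit <- i15_classifier(train, method = "fourier")
fit
#> I15 texture classifier (AWM vs NODAL)
#>   method: fourier, band [10, 20] um, sector +/- 15 deg
#>   trained on 81 AWM + 81 NODAL images, AUC 1.0000
#>   cutoff 0.4384 (weighted_corner_distance, fp_cost 2): sensitivity 100.0%, specificity 100.0%

eval_set <- generate_dataset(81, 81, seed = 202)  # independent evaluation set
cm <- confusion(predict(fit, eval_set), eval_set$labels)
cm
#>        predicted
#> truth   AWM NODAL
#>   AWM    81     0
#>   NODAL   0    81
c(sensitivity = sensitivity(cm), specificity = specificity(cm))
#> sensitivity specificity
#>         100         100
```

The fitted cutoff (0.4384) falls in the gap between the reticular scores
(≈ 0.05–0.10) and the striated scores (≈ 0.78–0.97): the synthetic
classes are fully separated, so an independent evaluation set classifies
perfectly. The same arithmetic applied to published confusion counts from
real tissue reproduces the reported figures, e.g. 2 misclassified AWM
images out of 81:

```r
round_half_up(sensitivity(confusion_counts(tp = 79, fp = 4, tn = 77, fn = 2)))
#> [1] 97.5
```

`plot(fit)` draws the class-wise I15 histograms with the cutoff and the
ROC curve with the selected operating point. A command-line wrapper with
verbs `simulate | score | roc | classify | report | run` is installed at
`inst/cli/cardiotexture.R`.

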