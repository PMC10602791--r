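---
title: "Staging zebrafish embryos from brightfield images: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging zebrafish embryos from brightfield images: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(embryostage)
```

This vignette documents the models implemented in `embryostage`, the
assumptions behind them, the parameters a user may want to touch, and the
places where the design was genuinely open and a choice had to be made.

## The staging problem

A zebrafish embryo's true developmental stage is defined morphologically,
but experiments label images with hours post fertilisation (hpf), which is
only a proxy: fertilisation time is known to ~30 min at best, embryos
within a clutch develop at slightly different rates, and incubation
temperature rescales the whole timeline. The package treats staging as a
regression problem — one brightfield image in, one hpf estimate out — and
treats *population-level* rate comparisons, not individual staging, as the
scientifically reliable output.

## The temperature-rate model

`rate_model()` implements the standard relation between developmental time
at temperature $T$ and the 28.5 °C reference,

$$H_T = \frac{h}{0.055\,T - c}, \qquad c = 0.57\ °\mathrm{C},$$

so the *relative rate* $0.055\,T - c$ is the expected slope of a
stage-versus-clock-time line. Two numerical consequences are worth noting.
First, at 25.0 °C the rate is exactly $0.055 \times 25 - 0.57 = 0.805$.
Second, at the reference temperature itself the formula gives $0.9975$,
not 1; the package evaluates the formula as printed rather than
renormalising, and all expectations in the tests use $0.9975$ for
28.5 °C. Temperatures at or below $c/0.055 \approx 10.36$ °C make the rate
nonpositive and are rejected.

## The synthetic plate simulator

No image data ship with the package; `simulate_plate()` generates them.
The generator is *not* photorealistic and does not try to be. It encodes
stage in a handful of morphological features chosen to mimic the logic of
staging guides while remaining resolvable at 64–256 px:

* an elliptical yolk (shrinking slightly with stage);
* a circular-arc body axis that wraps further around the yolk as
  development proceeds (6°/hpf, capped at 300°);
* a tapering tail extending the arc;
* somite-like stripes, one per 1.5 h capped at 30, echoing somite-count
  staging;
* pigmentation darkening linearly towards stage 55;
* an eye disc appearing at 24 hpf-equivalent;
* a chorion ring, a mild linear illumination gradient of random
  orientation, and additive Gaussian noise (default SD 0.02).

Body arc, tail length, stripe count and pigment level are nondecreasing in
stage by construction, which guarantees the signal is monotone and
learnable — the test suite checks that even mean image intensity has rank
correlation above 0.9 with stage. Stage progression across temperature
uses the rate model, so a plate simulated at 25.0 °C carries labels that
grow at 80.5 % of the reference rate. Per-well fertilisation-time jitter
is uniform on [0, 0.5] h, mirroring a clutch laid within half an hour; the
magnitude is a stand-in, since no per-embryo stage-uncertainty model is
available to calibrate it. Every image is bit-reproducible from the plate
seed.

What passing tests on these images show is that the *pipeline* —
architecture, optimisation, statistics — can recover known rate ratios
from images whose stage signal is monotone and moderately noisy. They do
not show robustness to the things the simulator omits: chorion hatching,
death and deformity phenotypes, debris, focus drift, or embryos
overlapping the well edge.

## Network architecture and training

The regressor is a deliberately small AlexNet-descendant
(`build_stage_model()`): repeated units of 3×3 convolution (zero-padded,
stride 1), ReLU and 2×2 max pooling; then flatten, a fully connected ReLU
layer, dropout, and a single linear output neuron. Input images are
cropped in x only (the acquisition aspect ratio is wider than tall, and
the crop removes x-translation artefacts introduced by augmentation) and
rescaled from [0, 1] to [−1, 1].

The full-scale default — 5 units with (16, 32, 64, 128, 256) filters,
dense width 512, dropout 0.5, 224×320 inputs cropped to 224×224 — follows
the architecture's lineage; the original tuned values were never
published, so these are explicit, overridable defaults rather than a
reproduction. The desk-scale preset (`scaled_stage_config()`: 3 units,
(8, 16, 32) filters, dense width 64, dropout 0.2, 64×96 cropped to 64×64)
preserves the layer structure at roughly 137k parameters and trains on a
few hundred images in about a minute on one CPU core.

Training minimises plain MSE in hpf² with Adam at learning rate 5e-4
(default 500 epochs at full scale). Loss is unweighted and unscaled, so a
training loss of ~8.5 hpf² reads as a ~2.9 h RMSE. The engine's backward
pass is verified against numerical differentiation in the development
history and its parameter-count arithmetic against hand-derived formulas
in the tests. Training is deterministic given the config seed:
initialisation, shuffling, dropout and augmentation all draw from one
seeded stream.

Augmentation defaults deserve a note: only the translation bound (20 % of
width) and zoom bound (30 %) are fixed by convention; the application
probabilities (0.5 for equalisation, saturation and each flip) and the
noise SD (0.02) are conventional choices. Saturation on replicated
grayscale channels is a no-op by design — it is defined so that true RGB
input is also handled, and documented as such. Zoom and translation fill
exposed pixels by edge replication rather than zeros, so saliency maps do
not latch onto synthetic black borders.

## Statistics: origin fits, bands, verdicts

`fit_through_origin()` uses the closed form $m = \sum x_i y_i / \sum
x_i^2$. $R^2$ is reported as the conventional $1 - SS_{res}/SS_{tot}$ with
$SS_{tot}$ about the mean of $y$; for through-origin fits this statistic
can be negative, and it is reported as `NA` when $SS_{tot} = 0$. Residual
summaries follow the divisor conventions of the numerical routines this
layer mirrors: SD with divisor $n$, SEM as the $n-1$-divisor SD over
$\sqrt n$; the two conventions are inconsistent with each other and are
replicated deliberately.

`bootstrap_slope_band()` draws subsets *without* replacement by default —
"randomly chosen sets of data points" reads as subsampling rather than a
classical bootstrap — with `replace = TRUE` available as a switch. The
band is the min/max of resampled slopes, exactly as stated, not a
percentile interval (a percentile mode can be layered on via the returned
`slopes` vector). With $k = n$ the band collapses to the full-data slope;
the expected band narrows as $k$ grows, which the tests check by Monte
Carlo. Two populations are distinguishable when their bands are disjoint;
since both cones pass through the origin, slope-interval disjointness
implies separation at every positive abscissa.

For two populations incubated at different temperatures the fits use
elapsed time (`x = "time_h"`) as the abscissa: manifest hpf labels are
temperature-scaled stages, so predicted-stage-versus-label slopes would be
~1 at any temperature, while predicted-stage-versus-time slopes recover
the rates (0.9975 vs 0.805) whose ratio the pipeline is designed to
detect.

## Transfer learning

`transfer_learn()` unfreezes whole layers from the output end backwards
until the requested fraction of parameters is trainable — the minimal
whole-layer set meeting the target, reported as the achieved fraction. In
dense-headed architectures like this one the achieved fraction can far
exceed the target (the first dense layer dominates the parameter count);
the report makes that explicit rather than silently splitting a layer.
Fine-tuning uses a learning rate five times lower than initial training
(1e-4) by default.

## Saliency

`saliency_map()` backpropagates the scalar output with the DeconvNet ReLU
rule: the backward signal through a ReLU keeps only its positive part,
regardless of the forward activation sign. Channels are reduced by the
maximum of absolute values, so maps are non-negative with the cropped
input's spatial shape. For a purely linear model the map reduces to
$|w|$, which the tests assert in closed form.

## Desk-scale validation experiments

The acceptance tests run the whole pipeline at sizes chosen once as
realistic desk-scale analogues of a 96-well experiment:

* *Rate recovery*: two 24-well plates at 28.5 and 25.0 °C, 40 frames per
  well at 1.0 h intervals from 3 hpf (coarser than the 15-min acquisition
  the simulator defaults to, trading frame density for stage-range
  coverage at a few hundred images), 64×96 frames; the scaled CNN trains
  30 epochs on half the reference wells without augmentation —
  at this data volume the regulariser is unnecessary and markedly slows
  convergence within the epoch budget. The recovered slope ratio must lie
  within 0.805 ± 0.08 and 100-point bootstrap bands must be disjoint.
* *Bootstrap structure*: 5,000 points on $y = 0.805x$ with Gaussian noise
  of SD 2.136 h (a realistic residual scale for this regressor); the
  $k=100$ band must contain 0.805 and the $k=200$ band must nest inside
  the $k=100$ band in at least 95 of 100 seeds.
* *Transfer direction*: a model pre-trained on one synthetic site is
  evaluated on a second site with shifted background (0.72 vs 0.88),
  stronger illumination gradient and 5× noise; fine-tuning on 12 wells
  with a 0.23 target retrained fraction must reduce mean absolute error.
  Only the direction of the improvement is claimed, not its magnitude.

## Known limitations

* Predictions are not clipped to non-negative hpf; nothing in the
  training objective forbids small negative outputs near stage zero.
* The simulator's morphology is invented; conclusions about real
  plate imagery require real data through the same manifest interface.
* The full-scale architecture's hyperparameters are plausible defaults,
  not tuned values.
* Whole-layer freezing cannot hit arbitrary retrained fractions in
  dense-dominated architectures, as discussed above.
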