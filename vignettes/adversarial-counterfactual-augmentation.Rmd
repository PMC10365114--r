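---
title: "Adversarial counterfactual augmentation: method, toy world, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial counterfactual augmentation: method, toy world, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfaug)
```

## The problem and the method

A binary image classifier `C` (here: Alzheimer's disease vs control normal,
from 2D brain slices) is given together with a *frozen* conditional
counterfactual generator `G(x, a)` that can re-render a subject's image `x`
at a different target age `a` while preserving identity and diagnosis.
The question the package answers is how to spend a small synthesis budget
so that the generated images actually help the classifier.

The method plays an adversarial game on the generator's *conditional
factor* rather than on its weights:

1. **Pre-train** `C` on the training split by minimising mean binary
   cross-entropy (BCE).
2. **Hard-sample selection.** Record the per-sample BCE of every training
   image under the pre-trained `C` and keep the `N` highest-loss samples
   (`N = 100` by default), the hard set.
3. **Adversarial classification training.** Initialise one target age per
   hard sample (uniformly between the sample's real age and 90 years, or
   at the real ages for the spurious-correlation experiment).  Then for
   `k = 5` outer iterations:
   * ascend each target age along the gradient of its own sample's loss,
     `a <- a + gamma_a * dL/da`, clipping into [60, 90] years after every
     step — the counterfactual `G(x, a)` keeps the source label, so the
     ascent drives each counterfactual toward what the *current*
     classifier finds hardest;
   * synthesize the counterfactual set at the updated ages;
   * retrain `C` for one epoch on the union of the training split and the
     current synthetic set.

The gradient `dL/da` exists because every stage of the conditioning is
smooth: the age is normalised affinely into [0, 1), lifted by a random
Fourier feature map
`gamma(v) = (p_j cos(2 pi b_j . v), p_j sin(2 pi b_j . v))_{j=1..m}`,
and the generator is differentiable in the encoded conditions.  The
discrete thermometer ("ordinal") encoding that Fourier features replace is
exactly what breaks this chain: adding a real-valued gradient step to a
thermometer vector no longer yields a thermometer vector
(`ordinal_encode()` demonstrates this).

Two variants complete the picture:

* **Continual learning.** When only `M%` of the training data is retained
  (a memory buffer `D_store`), selection, synthesis and replay all draw
  from the buffer.  Retraining on synthetic data alone is the ablation
  that exhibits catastrophic forgetting.
* **G-vs-C (cautionary).** Updating the *generator's weights* to maximise
  classifier loss — instead of the conditional factor — degrades the
  generator, because nothing constrains it toward realistic output.
  `train_generator_adversarially()` implements this mode and logs the
  generator's fidelity to the oracle per round.

## The synthetic world

No real MRI data can ship with a desk-scale package, so the simulator in
`render_config()` / `sample_dataset()` *is* the study system, and the same
renderer doubles as the oracle generator (`oracle_generator()` re-renders
a subject at any target age, noiselessly, with an analytic age
derivative).  A slice is an elliptic shell of bright tissue around dark
ventricles in normalized coordinates, plus a smooth per-subject texture
field and frozen Gaussian pixel noise; all edges are sigmoid-smoothed
(temperature `tau = 0.02`) so the map from age to image is differentiable
everywhere.

What the world must reproduce, and how each requirement fixed a parameter:

* **Ageing shows.** Ventricle semi-axes grow linearly in effective
  atrophy `t = (age - 60)/30 + beta_ad * diagnosis`, and the outer shell
  shrinks with age (12% over the range, against +/-2% subject jitter, so
  shell size is informative about age).  Dark interior area is
  monotonically non-decreasing in age by construction.
* **AD and old age are confusable, but not identical.**  `beta_ad = 0.3`
  gives an AD brain roughly nine extra years of ventricular atrophy; a
  subtle shape marker (the AD ventricle is elongated by a factor 1.3)
  keeps the diagnosis identifiable in principle.  If a single atrophy
  scalar drove everything, diagnosis would be unidentifiable beyond it
  and no classifier could pass 90% on an uncoupled cohort; if the marker
  were much weaker, a handful of counterfactuals could never outweigh
  hundreds of coupled training images in the spurious-correlation
  experiment.
* **The problem must sit off its accuracy ceiling.**  Pixel noise is
  0.3 (s.d., frozen per sample, applied after the geometry so the
  gradient path is noise-free) and training ages follow a young-heavy
  Beta(1.2, 2.5) law, under-representing the oldest subjects the way
  clinical cohorts do.  Both choices exist for the same reason: with
  near-noiseless images and uniform ages every strategy saturates at
  100% accuracy and neither catastrophic forgetting nor differences
  between augmentation strategies can be observed.  Test ages are drawn
  uniformly so each age-group cell is measured with adequate counts.
* **Spurious-correlation cohort.** `make_spurious_dataset()` couples
  diagnosis to age deterministically in train/val (AD below 75, CN above)
  while the test split stays uncoupled.  The outer-shell age cue is then
  a perfect shortcut, and the pre-trained classifier collapses on the
  broken-shortcut test groups (young CN, old AD) — which is the condition
  the adversarial loop is supposed to repair.

What the toy world does *not* model: anatomy beyond two ellipses, 3D
structure, MRI physics and artefacts, registration error, label noise,
and disease heterogeneity.  Passing tests therefore demonstrate the
mechanics and the direction of the method's effects, not clinical
performance.

## The two players

The classifier is a single-hidden-layer tanh network (16 units) over
centred pixels with a sigmoid output, trained with Adam (learning rate
1e-3, 100 epochs, mini-batches of 64).  A dense network is used instead
of a small convolutional stack because its input gradients are exact in a
few lines of algebra, it trains in seconds on one CPU core, and the toy
world is comfortably within its capacity.  Optimisation uses label
smoothing 0.05: without it the pre-trained network saturates and the loss
surface over the target age becomes a flat plateau ending in a cliff
(median |dL/da| around 1e-3), leaving gradient ascent no signal to move
along.  Reported losses and hard-sample selection always use the plain
0/1 labels.

The neural generator (`train_neural_generator()`) is a conditional
encoder–decoder: the source image is compressed to a 32-dimensional code,
fused with the 200-dimensional Fourier encoding of the target conditions
in a 96-unit hidden layer, and decoded into a residual added to the
source image.  It is trained by regression onto the oracle's
counterfactuals at random target ages.  Sources and targets are both
noiseless renders: a residual network cannot denoise, and the generator
is meant to model the clean image manifold; its fidelity to the oracle is
accordingly also measured from noiseless sources (`noiseless_samples()`),
which isolates the generator's own error from input noise.  The oracle
generator is the default player in all experiments; the neural generator
exists to satisfy the same contract with trainable weights, which the
G-vs-C mode requires.

## Numerical choices

* **Ascent step.** `gamma_a` operates on the year scale with `n_ascent
  = 10` inner steps per outer iteration.  The default 5 years per unit
  gradient was set from the measured gradient distribution: the loss
  surface is plateau-shaped away from the decision boundary, so
  year-scale steps are needed for ages to travel at all, while much
  larger steps overshoot every crossing sample to the clip bound and
  synthesize needlessly extreme counterfactuals that can hurt the
  classifier.  With 5, ages stop just past the decision boundary.
* **Per-sample gradients.** Each target age is updated with the gradient
  of its own sample's loss (equivalently, of the summed loss) — the
  closed-form reading of the update rule that makes the scripted
  surrogate in the tests move by exactly `gamma_a * 20`.
* **Clipping** to [60, 90] after *every* inner step, never only at the
  end.
* **Selection** ranks by continuous per-sample BCE (not 0/1 error), with
  ties broken by ascending sample id, so exactly `N` samples are chosen
  deterministically.  Selection happens once, before the loop; a
  `reselect_hard` flag exists but is off by default.
* **Degenerate inputs.** `n_hard` larger than the pool is an error in the
  full loop but clamps with a warning in the continual variant, where a
  1% buffer may simply be small.  A ventricle that would outgrow the
  shell is clamped with a warning and a zero gradient.  `k = 0` returns
  the classifier unchanged.
* **Seeds.** One master seed fans out to per-stage sub-seeds through
  `derive_seed(seed, label)`, so each stage is reproducible regardless of
  how much randomness other stages consume; this is also what makes the
  continual loop at `M = 100` bitwise-identical to the full loop.

## Problem sizes

Experiments in the tests and the acceptance script use cohorts of 240
subjects (uncoupled) and 500 subjects (spurious) at 64 x 64 pixels, with
100 hard samples, `k = 5`, and three fixed seeds where an average is
reported.  These sizes keep every experiment within minutes on one CPU
core while leaving all the phenomena of interest measurable.

## Known limitations

* Group accuracies on toy test splits move in steps of one image
  (about 2 percentage points), so small method orderings are at the edge
  of measurement resolution; the ordering checks treat differences below
  one test image as ties.
* The adversarial game's target-age dynamics are not monotone: as the
  classifier absorbs counterfactuals, the hard direction can reverse
  between iterations, and per-seed mean shifts occasionally change sign
  even though the seed-averaged shifts behave as expected.
* The oracle generator shares its renderer with the data simulator, so
  generator error is zero by construction; conclusions about generator
  quality transfer to the neural generator only through its measured
  fidelity.
* The spurious-correlation experiment uses balanced per-class hard
  selection (50 CN + 50 AD) and real-age initialisation; with unbalanced
  selection the hard set can collapse onto one class and the recovery
  weakens.
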