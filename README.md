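# cfaug — adversarial counterfactual augmentation

`cfaug` improves a binary image classifier with a *frozen* conditional
counterfactual generator by playing an adversarial game on the
generator's conditional factor.  The motivating application is
Alzheimer's disease (AD) classification from 2D brain slices, where a
pre-trained brain-ageing generator `G(x, a)` can re-render a subject's
image `x` at any target age `a` while preserving identity and diagnosis.

Instead of generating counterfactuals at random, the package finds the
classifier's *weakness*: it selects the `N` training samples with the
highest per-sample binary cross-entropy, then alternates for `k`
iterations between

```
a  <-  clip( a + gamma_a * dL_C/da ,  60, 90 )     # harden the counterfactuals
C  <-  one epoch of BCE on  D_train U G(x_hard, a) # absorb them
```

The ascent is possible because the conditional factor is encoded with a
differentiable random Fourier feature map,
`gamma(v) = (p_j cos(2*pi*b_j.v), p_j sin(2*pi*b_j.v))_{j=1..m}` with
`v = (age, diagnosis)` normalised into `[0,1)^2`, `m = 100`,
`b_j ~ N(0, mu_scale^2)`, `mu_scale = 10` — unlike the discrete
thermometer encoding it replaces, which no gradient step can preserve.

The package ships:

* a differentiable synthetic ageing-brain simulator (dataset source,
  spurious-correlation cohort builder, and oracle counterfactual
  generator with an analytic age derivative),
* reference classifier and conditional generator implementations with
  hand-written analytic backpropagation and Adam,
* the adversarial loop, its continual-learning memory-buffer variant
  (`D_store` of `M%` of training data), and the cautionary
  generator-vs-classifier mode,
* the comparison strategies RSRS, HSRS, RSAT and JTT under the same
  contracts,
* group-stratified evaluation (per diagnosis x age-bin accuracy,
  precision, recall, worst group) with `tidy()` / `glance()` /
  `autoplot()` methods,
* a config-driven pipeline (`cmd_simulate()` ... `cmd_experiment()`) and
  a thin shell driver at `inst/scripts/cfaug`.

## Worked example: breaking a spurious correlation

A cohort is built in which every training AD subject is younger than 75
and every training CN subject older — so "looks old" is a perfect
shortcut for "CN" during training, while the test split is uncoupled.

```r
library(cfaug)

cfg  <- render_config()
spur <- make_spurious_dataset(n = 500, age_split = 75, seed = 1, cfg = cfg)
fit  <- pretrain_classifier(spur, train_config(seed = 2))
test <- dataset_split(spur, "test")

glance(group_metrics(fit, test))
#>       n accuracy precision recall worst_group worst_group_accuracy
#>     150    0.893     0.833      1 CN 60-75                   0.429
```

The shortcut-trained classifier gets only 42.9% of young CN test
subjects right.  Running the adversarial loop with target ages
initialised at the subjects' real ages and 50 hard samples per class:

```r
G   <- oracle_generator(cfg)
res <- adversarial_augment(fit, G, spur,
         augment_config(init_mode = "real_age", balance_classes = TRUE,
                        seed = 3))

glance(group_metrics(res$classifier, test))
#>       n accuracy precision recall worst_group worst_group_accuracy
#>     150     0.92     0.870      1 CN 60-75                   0.571

tidy(res)[, 1:5]
#>   iteration loss_before loss_after mean_target_age mean_target_age_ad
#> 1         1      1.06        1.29             77.3               72.9
#> 2         2      0.0740      0.226            77.8               73.9
#> 3         3      0.105       0.124            77.8               74.1
#> 4         4      0.152       0.161            77.6               74.1
#> 5         5      0.0766      0.105            77.3               74.1
```

Each iteration the ascent raises the hard-set loss (`loss_before` →
`loss_after`) and the classifier update brings it back down; the AD
target ages drift upward (72.9 → 74.1 on average) — the game synthesizes
the old-AD images missing from the coupled training set — and overall
test accuracy rises from 89.3% to 92.0% with the worst group up from
42.9% to 57.1%.  `plot_target_age_shift(res)` draws the before/after
target-age histograms; seed-averaged experiments live in
`cmd_experiment()`.

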