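#' Configuration of the adversarial counterfactual augmentation loop
#'
#' Defaults follow the reference procedure: `n_hard = 100` hard samples
#' selected once, `k = 5` outer iterations, target ages clipped to
#' `[60, 90]` years after every update.  The ascent step `gamma_a` operates
#' on the year scale (the gradient is taken through the renderer or the
#' conditioning encoder, both parameterised in years); `n_ascent` gradient
#' steps on the target ages are taken per outer iteration.
#'
#' @param n_hard Number of hard samples to select (default 100).
#' @param k Outer iterations of ascend / synthesize / update (default 5).
#' @param gamma_a Ascent step size on the target ages, in years per unit
#'   gradient (default 5; the toy loss surface is plateau-shaped away from
#'   the decision boundary, so year-scale steps are needed for target ages
#'   to travel, while steps much larger overshoot to the clip bound and
#'   synthesize needlessly extreme counterfactuals).
#' @param n_ascent Inner ascent steps per outer iteration (default 10).
#' @param clip_range Permitted target-age interval, default `c(60, 90)`.
#' @param classifier_lr Adam rate for classifier updates during the loop
#'   (default `1e-3`).
#' @param memory_fraction M in `(0, 100]`: percentage of the training split
#'   retained in the memory buffer for the continual-learning variant.
#' @param init_mode Target-age initialisation: `"uniform_to_max"` draws
#'   uniformly between each sample's real age and the upper clip bound;
#'   `"real_age"` copies the real ages (used in the spurious-correlation
#'   experiment).
#' @param balance_classes If `TRUE`, hard samples are selected per class
#'   (n_hard/2 CN + n_hard/2 AD), as in the spurious-correlation experiment.
#' @param reselect_hard If `TRUE`, re-run hard selection at every outer
#'   iteration instead of once before the loop (off by default).
#' @param seed Master seed; stages derive sub-seeds via [derive_seed()].
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(n_hard = 100, k = 5, gamma_a = 5, n_ascent = 10,
                           clip_range = c(60, 90), classifier_lr = 1e-3,
                           memory_fraction = 100,
                           init_mode = c("uniform_to_max", "real_age"),
                           balance_classes = FALSE, reselect_hard = FALSE,
                           seed = 1) {
  check_scalar_number(gamma_a, "gamma_a", positive = TRUE)
  stopifnot(k >= 0, n_ascent >= 1, length(clip_range) == 2,
            clip_range[1] < clip_range[2],
            memory_fraction > 0, memory_fraction <= 100)
  structure(
    list(n_hard = as.integer(n_hard), k = as.integer(k), gamma_a = gamma_a,
         n_ascent = as.integer(n_ascent), clip_range = clip_range,
         classifier_lr = classifier_lr, memory_fraction = memory_fraction,
         init_mode = match.arg(init_mode),
         balance_classes = isTRUE(balance_classes),
         reselect_hard = isTRUE(reselect_hard), seed = as.integer(seed)),
    class = "augment_config"
  )
}

#' Select the hardest samples under a classifier
#'
#' Ranks samples by per-sample binary cross-entropy (descending) and returns
#' the top `n_hard`; ties are broken by ascending `sample_id`, so selection
#' is stable and deterministic.  With `balance_classes`, `n_hard / 2`
#' samples are taken per diagnosis.
#'
#' @param C A classifier (or fit).
#' @param samples A `toy_dataset` split.
#' @param n_hard Number of samples to select.
#' @param balance_classes Select per diagnosis class.
#' @return The selected rows, ordered by descending loss, with a `loss`
#'   column appended.
#' @export
select_hard_samples <- function(C, samples, n_hard, balance_classes = FALSE) {
  C <- as_classifier(C)
  if (n_hard > nrow(samples)) {
    abort(sprintf("`n_hard` (%d) exceeds the split size (%d).",
                  n_hard, nrow(samples)))
  }
  samples$loss <- per_sample_errors(C, samples)
  pick <- function(d, n) d[order(-d$loss, d$sample_id)[seq_len(n)], ]
  if (balance_classes) {
    per <- n_hard %/% 2
    cn <- pick(samples[samples$diagnosis == 0, ], per)
    ad <- pick(samples[samples$diagnosis == 1, ], n_hard - per)
    dplyr::bind_rows(ad, cn)
  } else {
    pick(samples, n_hard)
  }
}

#' Initialise the target ages of the hard set
#'
#' @param d_hard Hard-sample tibble from [select_hard_samples()].
#' @param mode `"uniform_to_max"`: uniform between each sample's real age
#'   and `clip_range[2]`; `"real_age"`: the real ages.
#' @param seed Integer seed.
#' @param clip_range Target-age interval.
#' @return Numeric vector of target ages aligned with `d_hard`.
#' @export
init_target_ages <- function(d_hard, mode = c("uniform_to_max", "real_age"),
                             seed = 1, clip_range = c(60, 90)) {
  mode <- match.arg(mode)
  if (mode == "real_age") return(d_hard$age)
  withr::with_seed(as.integer(seed),
                   runif(nrow(d_hard), d_hard$age, clip_range[2]))
}

# per-sample gradient of the classifier loss w.r.t. each target age:
# chain the classifier's input gradient through the generator's age gradient
target_age_gradient <- function(a, d_hard, G, C) {
  imgs <- cf_generate(G, d_hard, a)
  X <- stack_images(imgs)
  bw <- classifier_backward(C, X, d_hard$diagnosis)
  gmats <- cf_generate_grad(G, d_hard, a)
  grad <- vapply(seq_along(a),
                 function(i) sum(bw$gX[i, ] * as.vector(gmats[[i]])),
                 numeric(1))
  list(grad = grad, loss = bce(bw$p, d_hard$diagnosis))
}

#' Gradient-ascend the target ages toward maximal classifier loss
#'
#' Performs `n_ascent` steps of `a <- a + gamma_a * d loss / d a`, where the
#' loss is each sample's own binary cross-entropy on the counterfactual
#' `G(x, a)` against the *source* label, clipping into `clip_range` after
#' every step.  Neither the classifier nor the generator parameters are
#' touched.
#'
#' @param a Numeric target ages aligned with `d_hard`.
#' @param d_hard Hard-sample tibble.
#' @param G A generator satisfying the contract.
#' @param C A classifier (or fit).
#' @param cfg An [augment_config()].
#' @return Updated target ages, with attributes `loss_before` and
#'   `loss_after` (mean hard-set loss at the old and new ages).
#' @export
ascend_target_ages <- function(a, d_hard, G, C, cfg = augment_config()) {
  C <- as_classifier(C)
  stopifnot(length(a) == nrow(d_hard))
  loss_before <- NULL
  for (step in seq_len(cfg$n_ascent)) {
    ga <- target_age_gradient(a, d_hard, G, C)
    if (any(!is.finite(ga$grad))) {
      abort("Non-finite gradient in target-age ascent; aborting.")
    }
    if (is.null(loss_before)) loss_before <- mean(ga$loss)
    a <- clip(a + cfg$gamma_a * ga$grad, cfg$clip_range[1], cfg$clip_range[2])
  }
  after <- target_age_gradient(a, d_hard, G, C)
  structure(a, loss_before = loss_before, loss_after = mean(after$loss))
}

#' Synthesize the counterfactual set from the hard samples
#'
#' Generates one counterfactual per hard sample at its current target age.
#' Each synthetic sample inherits the source sample's diagnosis label
#' (changing the target age does not change the AD status) and records the
#' target age as its age.
#'
#' @param d_hard Hard-sample tibble.
#' @param a Target ages aligned with `d_hard`.
#' @param G Generator.
#' @return A tibble shaped like a dataset split, with `split = "synthetic"`
#'   and a `source_sample_id` column.
#' @export
synthesize_counterfactuals <- function(d_hard, a, G) {
  stopifnot(length(a) == nrow(d_hard))
  imgs <- cf_generate(G, d_hard, a)
  out <- d_hard
  out$source_sample_id <- out$sample_id
  out$age <- as.numeric(a)
  out$split <- "synthetic"
  out$image <- imgs
  out$loss <- NULL
  out
}

#' One combined epoch of classifier training on real plus synthetic data
#'
#' Runs one epoch of binary cross-entropy minimisation over the
#' concatenation of the provided real split and the synthetic set, at the
#' adversarial-phase learning rate.
#'
#' @param C Classifier (or fit).
#' @param real Real samples tibble (may be empty).
#' @param d_syn Synthetic samples tibble (may be empty).
#' @param cfg An [augment_config()].
#' @param seed Seed for the epoch's batch shuffle.
#' @param epochs Number of passes (default 1, one combined epoch).
#' @param opt_state Optional Adam state carried across calls.
#' @return List with updated `classifier` and `opt_state`.
#' @export
classifier_update <- function(C, real, d_syn, cfg = augment_config(),
                              seed = cfg$seed, epochs = 1, opt_state = NULL) {
  C <- as_classifier(C)
  combined <- dplyr::bind_rows(
    real[, c("sample_id", "diagnosis", "image")],
    if (!is.null(d_syn) && nrow(d_syn)) d_syn[, c("sample_id", "diagnosis", "image")]
  )
  if (nrow(combined) == 0) return(list(classifier = C, opt_state = opt_state))
  X <- stack_images(combined$image)
  fit <- train_classifier(C, X, combined$diagnosis, epochs = epochs,
                          lr = cfg$classifier_lr, batch_size = 64,
                          seed = seed, opt_state = opt_state)
  list(classifier = fit$classifier, opt_state = fit$opt_state)
}

new_run_history <- function(rows) {
  structure(dplyr::bind_rows(rows),
            class = c("run_history", class(tibble::tibble())))
}

# the engine behind Algorithms 1 and 2: `real` is the data pool used for
# selection and replay (full training split, or the memory buffer);
# `preselected` overrides the loss-ranked selection (RSAT)
run_adversarial <- function(C, G, real, test, cfg, memory = TRUE,
                            preselected = NULL) {
  C <- as_classifier(C)
  g_state0 <- generator_state(G)
  d_hard <- preselected %||%
    select_hard_samples(C, real, cfg$n_hard, cfg$balance_classes)
  a <- init_target_ages(d_hard, cfg$init_mode,
                        derive_seed(cfg$seed, "init-ages"), cfg$clip_range)
  a0 <- a
  rows <- vector("list", cfg$k)
  opt_state <- NULL
  for (i in seq_len(cfg$k)) {
    if (cfg$reselect_hard && i > 1 && is.null(preselected)) {
      d_hard <- select_hard_samples(C, real, cfg$n_hard, cfg$balance_classes)
      a <- init_target_ages(d_hard, cfg$init_mode,
                            derive_seed(cfg$seed, paste0("init-ages", i)),
                            cfg$clip_range)
    }
    a <- ascend_target_ages(a, d_hard, G, C, cfg)
    d_syn <- synthesize_counterfactuals(d_hard, a, G)
    upd <- classifier_update(C, if (memory) real else real[0, ], d_syn, cfg,
                             seed = derive_seed(cfg$seed, paste0("update", i)),
                             opt_state = opt_state)
    C <- upd$classifier; opt_state <- upd$opt_state
    rows[[i]] <- tibble::tibble(
      iteration = i,
      loss_before = attr(a, "loss_before"),
      loss_after = attr(a, "loss_after"),
      mean_target_age = mean(a),
      mean_target_age_ad = mean(a[d_syn$diagnosis == 1]),
      mean_target_age_cn = mean(a[d_syn$diagnosis == 0]),
      target_ages = list(as.numeric(a)),
      n_real = if (memory) nrow(real) else 0L,
      n_syn = nrow(d_syn),
      n_syn_ad = sum(d_syn$diagnosis)
    )
  }
  if (!identical(generator_state(G), g_state0)) {
    abort("Generator parameters changed during a frozen-generator loop.")
  }
  history <- new_run_history(rows)
  attr(history, "initial_target_ages") <- as.numeric(a0)
  attr(history, "hard_sample_ids") <- d_hard$sample_id
  structure(list(classifier = C, history = history, hard = d_hard, cfg = cfg),
            class = "cf_augment")
}

#' Adversarial counterfactual augmentation with a frozen generator
#'
#' The main training loop: select the `n_hard` highest-loss training
#' samples once, initialise their target ages, then for `k` iterations
#' ascend the target ages toward maximal classifier loss, synthesize the
#' counterfactual set at the updated ages, and retrain the classifier for
#' one epoch on the union of the training split and the synthetic set.  The
#' generator is frozen throughout; the run errors if its parameters change.
#'
#' @param C Pre-trained classifier (or [pretrain_classifier()] fit).
#' @param G Frozen generator satisfying the contract.
#' @param dataset A `toy_dataset`.
#' @param cfg An [augment_config()].
#' @return A `cf_augment` object: `$classifier` (updated), `$history` (a
#'   `run_history` tibble with one row per iteration, target-age snapshots
#'   in a list-column), `$hard`, `$cfg`.
#' @export
#' @examples
#' cfg <- render_config(size = 32)
#' ds <- sample_dataset(40, seed = 1, cfg = cfg)
#' fit <- pretrain_classifier(ds, train_config(epochs = 5, seed = 1))
#' res <- adversarial_augment(fit, oracle_generator(cfg), ds,
#'                            augment_config(n_hard = 8, k = 2, seed = 1))
#' res$history$mean_target_age
adversarial_augment <- function(C, G, dataset, cfg = augment_config()) {
  run_adversarial(C, G, dataset_split(dataset, "train"),
                  dataset_split(dataset, "test"), cfg)
}

#' Adversarial augmentation from a memory buffer (continual learning)
#'
#' Variant for the continual-learning setting: only a uniformly sampled
#' `memory_fraction` percent of the training split (the memory buffer
#' `D_store`) is available.  Hard-sample selection, counterfactual
#' synthesis, and classifier replay all draw from the buffer; with
#' `memory_fraction = 100` the trajectory is identical to
#' [adversarial_augment()] under the same seed.  If the buffer is smaller
#' than `n_hard`, `n_hard` is lowered with a warning.  With
#' `memory = "none"` the classifier retrains on the synthetic set alone --
#' the ablation that exhibits catastrophic forgetting.
#'
#' @inheritParams adversarial_augment
#' @param memory `"store"` replays the buffer alongside the synthetic set;
#'   `"none"` retrains on synthetic data only.
#' @return A `cf_augment` object (see [adversarial_augment()]); the buffer
#'   sample ids are attached as `$store_ids`.
#' @export
continual_adversarial_augment <- function(C, G, dataset,
                                          cfg = augment_config(),
                                          memory = c("store", "none")) {
  memory <- match.arg(memory)
  train <- dataset_split(dataset, "train")
  n_store <- round(cfg$memory_fraction / 100 * nrow(train))
  idx <- sort(withr::with_seed(derive_seed(cfg$seed, "store"),
                               sample.int(nrow(train), n_store)))
  store <- train[idx, ]
  if (cfg$n_hard > nrow(store)) {
    warn(sprintf("Memory buffer (%d) smaller than n_hard (%d); lowering n_hard.",
                 nrow(store), cfg$n_hard))
    cfg$n_hard <- nrow(store)
  }
  out <- run_adversarial(C, G, store, dataset_split(dataset, "test"), cfg,
                         memory = memory == "store")
  out$store_ids <- store$sample_id
  out
}

#' @export
print.cf_augment <- function(x, ...) {
  cat(sprintf("<cf_augment> k = %d iterations, %d hard samples\n",
              nrow(x$history), length(attr(x$history, "hard_sample_ids"))))
  print(tibble::as_tibble(x$history)[, c("iteration", "loss_before",
                                         "loss_after", "mean_target_age")])
  invisible(x)
}
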