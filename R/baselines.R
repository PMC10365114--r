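#' Configuration of the baseline augmentation strategies
#'
#' @param n_select Samples selected for synthesis (default 100).
#' @param n_synthesis_per_sample Random counterfactuals generated per
#'   selected sample (default 5, so the default synthetic budget is 500,
#'   matching the adversarial loop's k x n_hard).
#' @param k Retraining passes over the combined set (default 5).
#' @param lambda_up Oversampling factor for the error set in [jtt()]
#'   (default 2).
#' @param classifier_lr Adam rate for the retraining passes.
#' @param clip_range Target-age range for random synthesis.
#' @param seed Master seed.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(n_select = 100, n_synthesis_per_sample = 5,
                            k = 5, lambda_up = 2, classifier_lr = 1e-3,
                            clip_range = c(60, 90), seed = 1) {
  stopifnot(n_select >= 1, n_synthesis_per_sample >= 1, k >= 1, lambda_up >= 1)
  structure(list(n_select = as.integer(n_select),
                 n_synthesis_per_sample = as.integer(n_synthesis_per_sample),
                 k = as.integer(k), lambda_up = as.integer(lambda_up),
                 classifier_lr = classifier_lr, clip_range = clip_range,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

random_synthesis <- function(selected, G, cfg) {
  reps <- selected[rep(seq_len(nrow(selected)), each = cfg$n_synthesis_per_sample), ]
  ages <- withr::with_seed(
    derive_seed(cfg$seed, "rand-ages"),
    runif(nrow(reps), cfg$clip_range[1], cfg$clip_range[2]))
  synthesize_counterfactuals(reps, ages, G)
}

retrain_on <- function(C, real, d_syn, cfg) {
  acfg <- augment_config(classifier_lr = cfg$classifier_lr, seed = cfg$seed)
  classifier_update(C, real, d_syn, acfg,
                    seed = derive_seed(cfg$seed, "retrain"),
                    epochs = cfg$k)$classifier
}

#' RSRS baseline: random selection + random synthesis
#'
#' Randomly selects `n_select` training samples, generates
#' `n_synthesis_per_sample` counterfactuals each at target ages drawn
#' uniformly over the clip range, and retrains the classifier on the
#' combined real + synthetic set for `k` one-epoch passes.  This is the
#' conventional generate-and-merge augmentation recipe.
#'
#' @param C Pre-trained classifier (or fit).
#' @param G Generator.
#' @param dataset A `toy_dataset`.
#' @param cfg A [baseline_config()].
#' @return List with the updated `$classifier` and the synthetic set
#'   `$d_syn`.
#' @export
rsrs <- function(C, G, dataset, cfg = baseline_config()) {
  train <- dataset_split(dataset, "train")
  idx <- withr::with_seed(derive_seed(cfg$seed, "rand-select"),
                          sample.int(nrow(train), cfg$n_select))
  d_syn <- random_synthesis(train[idx, ], G, cfg)
  list(classifier = retrain_on(C, train, d_syn, cfg), d_syn = d_syn)
}

#' HSRS baseline: hard selection + random synthesis
#'
#' As [rsrs()], but the `n_select` samples are the hardest under the
#' pre-trained classifier ([select_hard_samples()]).
#'
#' @inheritParams rsrs
#' @param balance_classes Select hard samples per diagnosis class.
#' @return List with `$classifier` and `$d_syn`.
#' @export
hsrs <- function(C, G, dataset, cfg = baseline_config(),
                 balance_classes = FALSE) {
  train <- dataset_split(dataset, "train")
  hard <- select_hard_samples(C, train, cfg$n_select, balance_classes)
  d_syn <- random_synthesis(hard, G, cfg)
  list(classifier = retrain_on(C, train, d_syn, cfg), d_syn = d_syn)
}

#' RSAT baseline: random selection + adversarial training
#'
#' The full adversarial loop of [adversarial_augment()], except the
#' samples whose target ages are ascended are chosen uniformly at random
#' instead of by loss ranking.
#'
#' @inheritParams rsrs
#' @param acfg An [augment_config()] for the adversarial loop.
#' @return A `cf_augment` object.
#' @export
rsat <- function(C, G, dataset, acfg = augment_config()) {
  train <- dataset_split(dataset, "train")
  idx <- withr::with_seed(derive_seed(acfg$seed, "rsat-select"),
                          sample.int(nrow(train), acfg$n_hard))
  run_adversarial(C, G, train, dataset_split(dataset, "test"),
                  acfg, memory = TRUE, preselected = train[idx, ])
}

#' JTT baseline: just train twice
#'
#' Records the error set (samples misclassified at threshold 0.5 by the
#' pre-trained classifier), builds an oversampled dataset containing the
#' error set `lambda_up` times and every other sample once, and retrains
#' the classifier on it for `k` passes.  No generator is involved.
#'
#' @inheritParams rsrs
#' @return List with `$classifier` and the error-set sample ids
#'   `$error_ids`.
#' @export
jtt <- function(C, dataset, cfg = baseline_config()) {
  C0 <- as_classifier(C)
  train <- dataset_split(dataset, "train")
  wrong <- (predict_proba(C0, train) > 0.5) != (train$diagnosis == 1)
  if (!any(wrong)) {
    warn("Error set is empty; retraining on the unmodified training split.")
  }
  extra <- train[rep(which(wrong), each = cfg$lambda_up - 1), ]
  d_up <- dplyr::bind_rows(train, extra)
  list(classifier = retrain_on(C, d_up, NULL, cfg),
       error_ids = train$sample_id[wrong], n_retrain = nrow(d_up))
}
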