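#' Run a set of augmentation methods head-to-head
#'
#' From one pre-trained classifier and one frozen generator, runs any of
#' `naive`, `rsrs`, `hsrs`, `rsat`, `jtt`, `proposed` (and optionally the
#' cautionary `gvc` mode given a trainable generator) under a shared seed
#' and evaluates each on the test split with [group_metrics()].
#'
#' @param fit Pre-trained classifier fit ([pretrain_classifier()]).
#' @param G Frozen generator.
#' @param dataset A `toy_dataset`.
#' @param methods Character vector of method names.
#' @param acfg [augment_config()] for `proposed` / `rsat`.
#' @param bcfg [baseline_config()] for `rsrs` / `hsrs` / `jtt`.
#' @param neural_fit Optional trained neural generator fit, required for
#'   `gvc`.
#' @return A list with `$reports` (named `group_report`s), `$comparison`
#'   (the [compare_runs()] table) and `$results` (per-method raw results).
#' @export
run_methods <- function(fit, G, dataset,
                        methods = c("naive", "rsrs", "hsrs", "rsat", "jtt",
                                    "proposed"),
                        acfg = augment_config(), bcfg = baseline_config(),
                        neural_fit = NULL) {
  methods <- match.arg(methods,
                       c("naive", "rsrs", "hsrs", "rsat", "jtt", "proposed",
                         "gvc"), several.ok = TRUE)
  test <- dataset_split(dataset, "test")
  results <- list()
  classifiers <- list()
  for (m in methods) {
    res <- switch(
      m,
      naive = list(classifier = as_classifier(fit)),
      rsrs = rsrs(fit, G, dataset, bcfg),
      hsrs = hsrs(fit, G, dataset, bcfg),
      rsat = rsat(fit, G, dataset, acfg),
      jtt = jtt(fit, dataset, bcfg),
      proposed = adversarial_augment(fit, G, dataset, acfg),
      gvc = {
        if (is.null(neural_fit)) {
          abort("Method 'gvc' needs `neural_fit` (a trainable generator).")
        }
        train_generator_adversarially(neural_fit, fit, dataset, acfg)
      })
    results[[m]] <- res
    classifiers[[m]] <- res$classifier
  }
  reports <- purrr::map(classifiers, group_metrics, samples = test)
  list(reports = reports, comparison = compare_runs(reports),
       results = results)
}
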