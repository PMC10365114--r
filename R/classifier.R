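#' Training configuration for the reference classifier
#'
#' @param epochs Number of passes over the training split (default 100).
#' @param learning_rate Adam learning rate (pre-training default `1e-3`;
#'   adversarial-phase updates use the smaller rate in [augment_config()]).
#' @param batch_size Mini-batch size.
#' @param hidden Hidden-layer width of the classifier.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @param label_smoothing Targets are shrunk to
#'   `[label_smoothing, 1 - label_smoothing]` during optimisation (default
#'   0.05).  This keeps the classifier calibrated rather than saturated, so
#'   the loss surface seen by the target-age ascent retains usable
#'   gradients away from the decision boundary.  Reported losses and
#'   [per_sample_errors()] always use the hard 0/1 labels.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, learning_rate = 1e-3, batch_size = 64,
                         hidden = 16, seed = 1, label_smoothing = 0.05,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  check_scalar_number(epochs, "epochs", positive = TRUE)
  check_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  check_scalar_number(batch_size, "batch_size", positive = TRUE)
  stopifnot(label_smoothing >= 0, label_smoothing < 0.5)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), hidden = as.integer(hidden),
                 seed = as.integer(seed), label_smoothing = label_smoothing,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Initialise an untrained classifier
#'
#' A single-hidden-layer tanh network with a sigmoid output: small enough to
#' train on a CPU in seconds, smooth everywhere (so finite-difference checks
#' of the input gradient are exact to first order), and expressive enough to
#' learn the toy world.  `predict_proba()` returns the probability of AD and
#' `per_sample_errors()` the per-sample binary cross-entropy; gradients flow
#' to the image inputs, which is what the target-age ascent consumes.
#'
#' @param input_size Image side in pixels (input dimension is its square).
#' @param hidden Hidden width.
#' @param seed Seed for the Gaussian weight initialisation.
#' @return An object of class `cf_classifier`.
#' @export
new_classifier <- function(input_size, hidden = 16, seed = 1) {
  p <- as.integer(input_size)^2
  withr::with_seed(as.integer(seed), {
    params <- list(
      W1 = matrix(rnorm(hidden * p, 0, 1 / sqrt(p)), hidden, p),
      b1 = rep(0, hidden),
      w2 = matrix(rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1),
      b2 = 0
    )
  })
  structure(list(params = params, input_size = as.integer(input_size),
                 hidden = as.integer(hidden), center = rep(0, p)),
            class = "cf_classifier")
}

classifier_forward <- function(C, X) {
  X <- sweep(X, 2, C$center)  # train-mean centering; constant shift, so
                              # input gradients are unaffected
  Z1 <- sweep(X %*% t(C$params$W1), 2, C$params$b1, `+`)
  H <- tanh(Z1)
  logit <- c(H %*% C$params$w2 + C$params$b2)
  list(H = H, logit = logit, p = sigmoid(logit))
}

images_matrix <- function(samples) {
  if (is.data.frame(samples)) stack_images(samples$image) else stack_images(samples)
}

#' Predicted probability of AD
#'
#' @param C A `cf_classifier`.
#' @param samples A `toy_dataset`/tibble with an `image` list-column, a list
#'   of image matrices, or an `n x p` matrix of flattened images.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(C, samples) {
  X <- if (is.matrix(samples)) samples else images_matrix(samples)
  classifier_forward(C, X)$p
}

bce <- function(p, y) {
  p <- clip(p, 1e-12, 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Per-sample binary cross-entropy of a classifier
#'
#' Order-aligned with the input: entry `i` is the loss of sample `i`.  This
#' continuous error is what ranks samples for hard-sample selection.
#'
#' @inheritParams predict_proba
#' @param labels Optional labels; defaults to `samples$diagnosis`.
#' @return Numeric vector of non-negative losses.
#' @export
per_sample_errors <- function(C, samples, labels = NULL) {
  if (is.null(labels)) labels <- samples$diagnosis
  bce(predict_proba(C, samples), labels)
}

# per-sample gradient of BCE w.r.t. each input row, plus parameter
# gradients of the MEAN loss; one backward pass serves both uses
classifier_backward <- function(C, X, y, fwd = NULL) {
  if (is.null(fwd)) fwd <- classifier_forward(C, X)
  n <- nrow(X)
  dlogit <- fwd$p - y                              # per-sample
  gH <- outer(dlogit, c(C$params$w2))               # n x hidden
  gZ1 <- gH * (1 - fwd$H^2)
  list(
    gX = gZ1 %*% C$params$W1,                       # per-sample input grads
    grads = list(
      W1 = crossprod(gZ1, X) / n,
      b1 = colSums(gZ1) / n,
      w2 = crossprod(fwd$H, dlogit) / n,
      b2 = mean(dlogit)
    ),
    p = fwd$p
  )
}

# mini-batch Adam over (X, y); returns updated classifier + history tibble
train_classifier <- function(C, X, y, epochs, lr, batch_size, seed,
                             opt_state = NULL, cfg = train_config()) {
  n <- nrow(X)
  if (is.null(opt_state)) opt_state <- adam_init(C$params)
  y_soft <- y * (1 - 2 * cfg$label_smoothing) + cfg$label_smoothing
  history <- vector("list", epochs)
  withr::with_seed(as.integer(seed), {
    for (e in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        b <- idx[start:min(start + batch_size - 1, n)]
        bw <- classifier_backward(C, X[b, , drop = FALSE], y_soft[b])
        st <- adam_step(C$params, bw$grads, opt_state, lr,
                        cfg$beta1, cfg$beta2, cfg$eps)
        C$params <- st$params; opt_state <- st$state
      }
      p <- classifier_forward(C, X)$p
      history[[e]] <- tibble::tibble(
        epoch = e, loss = mean(bce(p, y)),
        accuracy = mean((p > 0.5) == (y == 1)))
    }
  })
  list(classifier = C, history = dplyr::bind_rows(history),
       opt_state = opt_state)
}

#' Pre-train the AD classifier on a dataset's training split
#'
#' Minimises mean binary cross-entropy with Adam; deterministic given the
#' config seed.  Errors if the training split is missing a class.
#'
#' @param dataset A `toy_dataset`.
#' @param cfg A [train_config()].
#' @return An object of class `classifier_fit`: list with `$classifier`,
#'   `$history` (per-epoch loss/accuracy tibble) and `$cfg`.
#'   [generics::tidy()] returns the history, [generics::glance()] the final
#'   epoch.
#' @export
pretrain_classifier <- function(dataset, cfg = train_config()) {
  train <- dataset_split(dataset, "train")
  if (nrow(train) == 0) abort("Training split is empty.")
  if (length(unique(train$diagnosis)) < 2) {
    abort("Training split contains a single class; cannot fit a classifier.")
  }
  size <- dataset_render_cfg(dataset)$size
  C <- new_classifier(size, hidden = cfg$hidden,
                      seed = derive_seed(cfg$seed, "clf-init"))
  X <- images_matrix(train)
  C$center <- colMeans(X)
  fit <- train_classifier(C, X, train$diagnosis, cfg$epochs,
                          cfg$learning_rate, cfg$batch_size,
                          derive_seed(cfg$seed, "clf-train"), cfg = cfg)
  structure(list(classifier = fit$classifier, history = fit$history, cfg = cfg),
            class = "classifier_fit")
}

#' Coerce to a bare classifier
#' @param x A `cf_classifier`, or any fit/result object carrying one
#'   (`classifier_fit`, `cf_augment`, `gvc_result`, baseline results).
#' @return The `cf_classifier`.
#' @export
as_classifier <- function(x) {
  if (inherits(x, "cf_classifier")) x
  else if (is.list(x) && inherits(x$classifier, "cf_classifier")) x$classifier
  else abort("Not a classifier or classifier fit.")
}

#' @export
print.classifier_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<classifier_fit> %d epochs; final train loss %.4f, accuracy %.3f\n",
              nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}
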