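#' Training configuration for the neural conditional generator
#'
#' @param epochs Adam epochs over the (sample, target age) pair set.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param code_dim Width of the image bottleneck code.
#' @param hidden Width of the fused (code, conditioning) hidden layer.
#' @param pairs_per_sample Random target ages drawn per training sample.
#' @param enc_m,enc_mu_scale Fourier conditioning: number of frequency
#'   pairs and frequency scale.
#' @param patience Epoch window for the divergence check: training errors
#'   out if the loss has not improved over this many epochs.
#' @param seed Seed for pair sampling, initialisation and shuffling.
#' @return A list of class `gen_train_config`.
#' @export
gen_train_config <- function(epochs = 150, learning_rate = 1e-3,
                             batch_size = 64, code_dim = 32, hidden = 96,
                             pairs_per_sample = 3, enc_m = 100,
                             enc_mu_scale = 10, patience = 50, seed = 1) {
  check_scalar_number(epochs, "epochs", positive = TRUE)
  check_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 code_dim = as.integer(code_dim), hidden = as.integer(hidden),
                 pairs_per_sample = as.integer(pairs_per_sample),
                 enc_m = as.integer(enc_m), enc_mu_scale = enc_mu_scale,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "gen_train_config")
}

new_neural_generator <- function(input_size, cfg, age_range, seed) {
  p <- as.integer(input_size)^2
  f <- 2L * cfg$enc_m
  withr::with_seed(as.integer(seed), {
    params <- list(
      We = matrix(rnorm(p * cfg$code_dim, 0, 1 / sqrt(p)), p, cfg$code_dim),
      be = rep(0, cfg$code_dim),
      Wz = matrix(rnorm(cfg$code_dim * cfg$hidden, 0, 1 / sqrt(cfg$code_dim)),
                  cfg$code_dim, cfg$hidden),
      Wg = matrix(rnorm(f * cfg$hidden, 0, 1 / sqrt(f)), f, cfg$hidden),
      bh = rep(0, cfg$hidden),
      Wd = matrix(rnorm(cfg$hidden * p, 0, 1e-3), cfg$hidden, p),
      bd = rep(0, p)
    )
  })
  structure(
    list(params = params, input_size = as.integer(input_size),
         enc_spec = make_encoding_spec(cfg$enc_m, cfg$enc_mu_scale,
                                       seed = derive_seed(seed, "enc"), d = 2),
         age_range = age_range, cfg = cfg),
    class = c("neural_generator", "cf_generator")
  )
}

# forward pass on flattened source images X (n x p) and normalized
# conditions V (n x 2); residual decoder: x_hat = x + delta
neural_forward <- function(G, X, V) {
  pr <- G$params
  Gam <- fourier_encode(V, G$enc_spec)
  Z <- tanh(sweep(X %*% pr$We, 2, pr$be, `+`))
  H <- tanh(sweep(Z %*% pr$Wz + Gam %*% pr$Wg, 2, pr$bh, `+`))
  Delta <- sweep(H %*% pr$Wd, 2, pr$bd, `+`)
  list(Gam = Gam, Z = Z, H = H, Xhat = X + Delta)
}

# parameter gradients given upstream dL/dXhat; the source image path is a
# constant input, so only the residual branch carries parameter gradients
neural_backward <- function(G, X, V, fwd, gXhat) {
  pr <- G$params
  gH <- gXhat %*% t(pr$Wd)
  gHpre <- gH * (1 - fwd$H^2)
  gZ <- gHpre %*% t(pr$Wz)
  gZpre <- gZ * (1 - fwd$Z^2)
  list(
    We = crossprod(X, gZpre), be = colSums(gZpre),
    Wz = crossprod(fwd$Z, gHpre), Wg = crossprod(fwd$Gam, gHpre),
    bh = colSums(gHpre),
    Wd = crossprod(fwd$H, gXhat), bd = colSums(gXhat)
  )
}

neural_conditions <- function(G, samples, target_ages) {
  normalize_conditions(clip(target_ages, G$age_range[1], G$age_range[2]),
                       samples$diagnosis, G$age_range) |>
    (\(v) if (is.null(dim(v))) matrix(v, nrow = 1) else v)()
}

#' Train the neural conditional counterfactual generator
#'
#' A conditional encoder--decoder: the source image is compressed to a
#' bottleneck code, fused with the Fourier encoding of the normalized
#' (target age, diagnosis) conditions, and decoded to a residual added to
#' the source image.  It is trained by supervised regression onto the
#' oracle generator's counterfactuals at random target ages (mean squared
#' pixel error).  Gradients with respect to the target age flow through the
#' Fourier conditioning analytically, so the trained generator satisfies
#' the same differentiable-generator contract as the oracle.
#'
#' @param dataset A `toy_dataset`; pairs are built from its training split.
#' @param oracle An [oracle_generator()] used as regression target.
#' @param cfg A [gen_train_config()].
#' @return A `generator_fit`: list with `$generator` (a `neural_generator`),
#'   `$history` (per-epoch loss tibble) and `$cfg`.
#' @export
train_neural_generator <- function(dataset, oracle, cfg = gen_train_config()) {
  train <- dataset_split(dataset, "train")
  if (nrow(train) == 0) abort("Training split is empty.")
  rcfg <- dataset_render_cfg(dataset)
  G <- new_neural_generator(rcfg$size, cfg, rcfg$age_range,
                            derive_seed(cfg$seed, "gen-init"))
  reps <- cfg$pairs_per_sample
  # regress clean manifold -> clean manifold: sources are noiseless
  # re-renders, as targets are; a residual network cannot denoise, and the
  # pre-trained generator is meant to model the image manifold itself
  train <- noiseless_samples(train, rcfg)
  pairs <- train[rep(seq_len(nrow(train)), each = reps), ]
  pairs$target_age <- withr::with_seed(
    derive_seed(cfg$seed, "gen-pairs"),
    runif(nrow(pairs), rcfg$age_range[1], rcfg$age_range[2]))
  X <- stack_images(pairs$image)
  Y <- stack_images(cf_generate(oracle, pairs, pairs$target_age))
  V <- neural_conditions(G, pairs, pairs$target_age)
  n <- nrow(X)
  opt <- adam_init(G$params)
  history <- vector("list", cfg$epochs)
  best <- Inf; stale <- 0L
  withr::with_seed(derive_seed(cfg$seed, "gen-train"), {
    for (e in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        b <- idx[start:min(start + cfg$batch_size - 1, n)]
        fwd <- neural_forward(G, X[b, , drop = FALSE], V[b, , drop = FALSE])
        gXhat <- 2 * (fwd$Xhat - Y[b, , drop = FALSE]) / length(b)
        grads <- neural_backward(G, X[b, , drop = FALSE], V[b, , drop = FALSE],
                                 fwd, gXhat)
        st <- adam_step(G$params, grads, opt, cfg$learning_rate)
        G$params <- st$params; opt <- st$state
      }
      fwd <- neural_forward(G, X, V)
      loss <- mean((fwd$Xhat - Y)^2)
      history[[e]] <- tibble::tibble(epoch = e, mse = loss)
      if (is.finite(loss) && loss < best - 1e-8) {
        best <- loss; stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= cfg$patience) {
        abort(sprintf(
          "Generator training diverged: no improvement over %d epochs (mse %.4g).",
          cfg$patience, loss))
      }
    }
  })
  structure(list(generator = G, history = dplyr::bind_rows(history), cfg = cfg),
            class = "generator_fit")
}

#' Coerce to a bare generator
#' @param x A `cf_generator` or `generator_fit`.
#' @return The `cf_generator`.
#' @export
as_generator <- function(x) {
  if (inherits(x, "generator_fit")) x$generator
  else if (inherits(x, "cf_generator")) x
  else abort("Not a generator or generator fit.")
}

#' @export
cf_generate.neural_generator <- function(G, samples, target_ages) {
  stopifnot(nrow(samples) == length(target_ages))
  X <- stack_images(samples$image)
  V <- neural_conditions(G, samples, target_ages)
  Xhat <- neural_forward(G, X, V)$Xhat
  purrr::map(seq_len(nrow(X)),
             function(i) unstack_image(Xhat[i, ], G$input_size))
}

#' @export
cf_generate_grad.neural_generator <- function(G, samples, target_ages) {
  stopifnot(nrow(samples) == length(target_ages))
  pr <- G$params
  X <- stack_images(samples$image)
  V <- neural_conditions(G, samples, target_ages)
  fwd <- neural_forward(G, X, V)
  dv_da <- 1 / (diff(G$age_range) + 1e-6)  # d age_norm / d age (years)
  purrr::map(seq_len(nrow(X)), function(i) {
    J <- fourier_jacobian(V[i, ], G$enc_spec)     # 2m x 2
    dGam <- J[, 1] * dv_da                        # d gamma / d age
    dH <- (1 - fwd$H[i, ]^2) * c(crossprod(pr$Wg, dGam))
    unstack_image(c(crossprod(pr$Wd, dH)), G$input_size)
  })
}

#' @export
is_trainable.neural_generator <- function(G) TRUE

#' @export
generator_state.neural_generator <- function(G) G$params

#' @export
print.generator_fit <- function(x, ...) {
  cat(sprintf("<generator_fit> %d epochs; final oracle-regression mse %.5f\n",
              nrow(x$history), x$history$mse[nrow(x$history)]))
  invisible(x)
}

#' Replace sample images by noiseless re-renders
#'
#' Rebuilds each sample's image at its own age and diagnosis with the pixel
#' noise turned off.  Used when evaluating generator fidelity: a residual
#' generator passes input noise through to its output, so measuring it from
#' noiseless sources isolates the generator's own error.
#'
#' @param samples A `toy_dataset` (or split).
#' @param cfg The [render_config()] the samples were rendered with.
#' @return The samples with clean images.
#' @export
noiseless_samples <- function(samples, cfg) {
  O <- oracle_generator(cfg)
  samples$image <- cf_generate(O, samples, samples$age)
  samples
}

#' Mean absolute pixel distance between a generator and the oracle
#'
#' Fidelity probe used to monitor generator degradation during adversarial
#' generator training: counterfactuals for a fixed probe set are produced by
#' both generators and compared pixelwise.
#'
#' @param G Generator under test.
#' @param oracle Reference [oracle_generator()].
#' @param samples Probe samples.
#' @param target_ages Probe target ages.
#' @return Mean absolute pixel difference.
#' @export
generator_fidelity <- function(G, oracle, samples, target_ages) {
  a <- stack_images(cf_generate(as_generator(G), samples, target_ages))
  b <- stack_images(cf_generate(oracle, samples, target_ages))
  mean(abs(a - b))
}

#' Adversarially train the generator against the classifier
#'
#' The cautionary alternative to updating the conditional factor: the
#' *generator's parameters* are updated by gradient ascent on the
#' classifier's loss over synthetic samples, alternating with one combined
#' classifier epoch per round.  Nothing constrains the generator toward
#' realistic output, so its fidelity to the oracle counterfactuals (logged
#' per epoch) typically degrades, and the classifier trained on its output
#' typically ends up worse than under the frozen-generator loop.
#'
#' @param G A *trainable* generator (fit or `neural_generator`); passing the
#'   oracle is a contract error.
#' @param C Classifier (or fit).
#' @param dataset A `toy_dataset`.
#' @param cfg An [augment_config()]; `k` is the number of adversarial
#'   epochs (10 in the reference setup) and `n_hard` the synthetic set size
#'   per round (100).
#' @param oracle Oracle generator used only for the fidelity log.
#' @param gen_lr Ascent learning rate on the generator parameters.
#' @return List of class `gvc_result`: updated `$generator`, `$classifier`,
#'   and `$history` (per-epoch fidelity and losses).
#' @export
train_generator_adversarially <- function(G, C, dataset,
                                          cfg = augment_config(k = 10),
                                          oracle = NULL, gen_lr = 3e-3) {
  G <- as_generator(G)
  if (!is_trainable(G)) {
    abort("`G` must be a trainable generator; the oracle cannot be trained against C.")
  }
  C <- as_classifier(C)
  train <- dataset_split(dataset, "train")
  if (is.null(oracle)) oracle <- oracle_generator(dataset_render_cfg(dataset))
  probe <- noiseless_samples(head(train, min(32, nrow(train))),
                             dataset_render_cfg(dataset))
  probe_ages <- withr::with_seed(
    derive_seed(cfg$seed, "gvc-probe"),
    runif(nrow(probe), cfg$clip_range[1], cfg$clip_range[2]))
  opt_g <- adam_init(G$params)
  opt_c <- NULL
  rows <- vector("list", cfg$k)
  for (e in seq_len(cfg$k)) {
    pick <- withr::with_seed(derive_seed(cfg$seed, paste0("gvc-pick", e)), {
      i <- sample.int(nrow(train), min(cfg$n_hard, nrow(train)))
      list(idx = i, ages = runif(length(i), cfg$clip_range[1], cfg$clip_range[2]))
    })
    batch <- train[pick$idx, ]
    X <- stack_images(batch$image)
    V <- neural_conditions(G, batch, pick$ages)
    fwd <- neural_forward(G, X, V)
    bw <- classifier_backward(C, fwd$Xhat, batch$diagnosis)
    # ascend: maximise classifier loss => descend on its negative
    grads <- neural_backward(G, X, V, fwd, -bw$gX / nrow(X))
    st <- adam_step(G$params, grads, opt_g, gen_lr)
    G$params <- st$params; opt_g <- st$state
    d_syn <- synthesize_counterfactuals(batch, pick$ages, G)
    upd <- classifier_update(C, train, d_syn, cfg,
                             seed = derive_seed(cfg$seed, paste0("gvc-upd", e)),
                             opt_state = opt_c)
    C <- upd$classifier; opt_c <- upd$opt_state
    rows[[e]] <- tibble::tibble(
      epoch = e,
      fidelity = generator_fidelity(G, oracle, probe, probe_ages),
      syn_loss = mean(bce(classifier_forward(C, fwd$Xhat)$p, batch$diagnosis))
    )
  }
  structure(list(generator = G, classifier = C,
                 history = new_run_history(rows), cfg = cfg),
            class = "gvc_result")
}
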