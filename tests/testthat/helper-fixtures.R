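# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_cfg <- function() render_config(size = 32)

small_dataset <- function() {
  fixture("small_dataset",
          function() sample_dataset(60, seed = 101, cfg = small_cfg()))
}

small_fit <- function() {
  fixture("small_fit", function() {
    pretrain_classifier(small_dataset(), train_config(epochs = 30, seed = 11))
  })
}

small_generator_fit <- function() {
  fixture("small_generator_fit", function() {
    train_neural_generator(small_dataset(), oracle_generator(small_cfg()),
                           gen_train_config(epochs = 120, seed = 21))
  })
}

# a hand-weighted classifier over 1x1 "images": logit = w2 * tanh(s * (v - center))
# lets tests dial per-sample probabilities exactly
scripted_classifier <- function(center = 0, s = 1, w2 = 1, b2 = 0) {
  C <- new_classifier(input_size = 1, hidden = 1, seed = 1)
  C$params$W1 <- matrix(s, 1, 1)
  C$params$b1 <- 0
  C$params$w2 <- matrix(w2, 1, 1)
  C$params$b2 <- b2
  C$center <- center
  C
}

# generator over 1x1 images whose output pixel IS the target age
linear_age_generator <- function() {
  structure(list(), class = c("linear_age_generator", "cf_generator"))
}

cf_generate.linear_age_generator <- function(G, samples, target_ages) {
  lapply(target_ages, function(a) matrix(a, 1, 1))
}

cf_generate_grad.linear_age_generator <- function(G, samples, target_ages) {
  lapply(target_ages, function(a) matrix(1, 1, 1))
}

is_trainable.linear_age_generator <- function(G) FALSE
generator_state.linear_age_generator <- function(G) NULL

registerS3method("cf_generate", "linear_age_generator",
                 cf_generate.linear_age_generator,
                 envir = asNamespace("cfaug"))
registerS3method("cf_generate_grad", "linear_age_generator",
                 cf_generate_grad.linear_age_generator,
                 envir = asNamespace("cfaug"))
registerS3method("is_trainable", "linear_age_generator",
                 is_trainable.linear_age_generator,
                 envir = asNamespace("cfaug"))
registerS3method("generator_state", "linear_age_generator",
                 generator_state.linear_age_generator,
                 envir = asNamespace("cfaug"))

# independent BCE, written longhand on purpose
bce_oracle <- function(p, y) {
  vapply(seq_along(p), function(i) {
    pi <- min(max(p[i], 1e-12), 1 - 1e-12)
    if (y[i] == 1) -log(pi) else -log(1 - pi)
  }, numeric(1))
}

test_accuracy <- function(C, samples) {
  mean((predict_proba(as_classifier(C), samples) > 0.5) ==
         (samples$diagnosis == 1))
}
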