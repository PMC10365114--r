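#' Generator contract
#'
#' A counterfactual generator `G` takes samples and per-sample target ages
#' and returns images of the same shape; it must be differentiable with
#' respect to the target ages.  Two implementations satisfy the contract:
#' the simulator-backed [oracle_generator()] (exact re-render, analytic
#' age gradient, no trainable parameters) and the trained
#' [train_neural_generator()] network.  Diagnosis labels are never part of
#' the generator output -- label preservation is the caller's contract.
#'
#' @param G A generator object.
#' @param samples A `toy_dataset` (or compatible tibble with `image`,
#'   `diagnosis` and subject columns).
#' @param target_ages Numeric vector, one target age (years) per sample.
#' @return `cf_generate()`: a list of image matrices.
#'   `cf_generate_grad()`: a list of `d image / d target_age` matrices.
#' @name generator-contract
NULL

#' @rdname generator-contract
#' @export
cf_generate <- function(G, samples, target_ages) UseMethod("cf_generate")

#' @rdname generator-contract
#' @export
cf_generate_grad <- function(G, samples, target_ages) UseMethod("cf_generate_grad")

#' @rdname generator-contract
#' @export
is_trainable <- function(G) UseMethod("is_trainable")

#' Snapshot of a generator's trainable state
#'
#' Used to assert the frozen-generator guarantee of the Algorithm-1 loop;
#' the oracle generator has no trainable state and returns `NULL`.
#'
#' @param G A generator object.
#' @return A serializable object, compared with `identical()`.
#' @export
generator_state <- function(G) UseMethod("generator_state")

#' Simulator-backed oracle counterfactual generator
#'
#' Re-renders each sample's subject at the requested target age with the
#' sample's own diagnosis and no pixel noise.  Target ages above the
#' sample's age simulate ageing, below it rejuvenation, so one mechanism
#' covers both generator directions.  The age gradient is the renderer's
#' analytic derivative.
#'
#' @param cfg A [render_config()]; must match the dataset the samples come
#'   from.
#' @return An object of classes `oracle_generator`, `cf_generator`.
#' @export
#' @examples
#' cfg <- render_config(size = 32)
#' ds <- sample_dataset(8, seed = 1, cfg = cfg)
#' G <- oracle_generator(cfg)
#' aged <- cf_generate(G, ds[1, ], 88)
oracle_generator <- function(cfg = render_config()) {
  structure(list(cfg = cfg), class = c("oracle_generator", "cf_generator"))
}

oracle_cfg_noiseless <- function(G) {
  cfg <- G$cfg
  cfg$sigma_noise <- 0
  cfg
}

subject_of <- function(samples, i) {
  list(outer_a = samples$outer_a[i], outer_b = samples$outer_b[i],
       vent_a = samples$vent_a[i], vent_b = samples$vent_b[i],
       texture_seed = samples$texture_seed[i])
}

#' @export
cf_generate.oracle_generator <- function(G, samples, target_ages) {
  stopifnot(nrow(samples) == length(target_ages), all(is.finite(target_ages)))
  cfg <- oracle_cfg_noiseless(G)
  purrr::map(seq_len(nrow(samples)), function(i) {
    render_brain(subject_of(samples, i), target_ages[i],
                 samples$diagnosis[i], cfg)
  })
}

#' @export
cf_generate_grad.oracle_generator <- function(G, samples, target_ages) {
  stopifnot(nrow(samples) == length(target_ages))
  cfg <- oracle_cfg_noiseless(G)
  purrr::map(seq_len(nrow(samples)), function(i) {
    render_brain(subject_of(samples, i), target_ages[i],
                 samples$diagnosis[i], cfg, grad = TRUE)$grad_age
  })
}

#' @export
is_trainable.oracle_generator <- function(G) FALSE

#' @export
generator_state.oracle_generator <- function(G) NULL
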