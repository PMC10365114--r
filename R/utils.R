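#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rbinom predict
#' @importFrom utils head
NULL

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of a run (subject sampling, weight initialisation,
#' batch shuffling, memory-buffer selection, ...) draws its own seed from the
#' master seed and a stage label, so that stages are reproducible
#' independently of how much randomness earlier stages consumed.
#'
#' @param seed Master integer seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "pretrain")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 1048573
  as.integer((abs(seed) %% 1048573) * 2047 + h * 31 + 17) %% 2147483647L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# flatten a list of equally sized image matrices into an n x p matrix
# (column-major per image, the package-wide convention)
stack_images <- function(images) {
  stopifnot(length(images) >= 1)
  do.call(rbind, lapply(images, as.vector))
}

unstack_image <- function(x, size) matrix(x, nrow = size, ncol = size)

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}
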