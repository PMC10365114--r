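#' Normalize conditional factors into the unit interval
#'
#' The conditional vector fed to a counterfactual generator holds the target
#' age and the diagnosis.  Both are mapped into `[0, 1)`: age affinely over
#' the configured range (with a small `eps` in the denominator so the upper
#' bound stays strictly below 1), diagnosis to `0` (CN) or `c_ad` (AD).  The
#' map is affine in age, hence differentiable with derivative
#' `1 / (hi - lo + eps)`, and invertible via [denormalize_age()].
#'
#' @param age Numeric vector of ages in years.
#' @param diagnosis Integer/logical vector, 0 = CN, 1 = AD (recycled).
#' @param age_range Closed age range `c(lo, hi)`, default `c(60, 90)`.
#' @param c_ad Constant in `[0, 1)` encoding an AD diagnosis; default 0.5.
#' @param eps Guard added to the range width; default `1e-6`.
#' @return For scalar input a length-2 numeric vector `(age_norm, dx_norm)`;
#'   for vector input an `n x 2` matrix with one row per sample.
#' @export
#' @examples
#' normalize_conditions(75, 0)
#' normalize_conditions(c(60, 90), c(0, 1))
normalize_conditions <- function(age, diagnosis, age_range = c(60, 90),
                                 c_ad = 0.5, eps = 1e-6) {
  stopifnot(length(age_range) == 2, age_range[2] > age_range[1])
  diagnosis <- rep_len(as.numeric(diagnosis), length(age))
  if (any(!is.finite(age)) || any(age < age_range[1]) || any(age > age_range[2])) {
    abort(sprintf("`age` must lie within [%g, %g]; clip before calling.",
                  age_range[1], age_range[2]))
  }
  if (!all(diagnosis %in% c(0, 1))) abort("`diagnosis` must be 0 (CN) or 1 (AD).")
  a <- (age - age_range[1]) / (diff(age_range) + eps)
  out <- cbind(age_norm = a, dx_norm = diagnosis * c_ad)
  if (length(age) == 1) stats::setNames(c(out), colnames(out)) else out
}

#' Invert the age normalization
#'
#' @param age_norm Normalized age component in `[0, 1)`.
#' @inheritParams normalize_conditions
#' @return Ages in years.
#' @export
denormalize_age <- function(age_norm, age_range = c(60, 90), eps = 1e-6) {
  age_norm * (diff(age_range) + eps) + age_range[1]
}

#' Construct a Fourier feature encoding specification
#'
#' Fixes the random Fourier basis used to lift the d-dimensional normalized
#' condition vector into a 2m-dimensional sinusoidal feature vector.  The
#' frequency matrix `b` (`d x m`) is drawn i.i.d. from a zero-mean Gaussian
#' with standard deviation `mu_scale` and is fully determined by `seed`; the
#' coefficients satisfy `p_j^2 = 1`.  The basis is regenerated from the seed
#' on deserialization and never stored.
#'
#' @param m Number of frequency pairs (default 100, giving a 200-dim encoding).
#' @param mu_scale Frequency scale (Gaussian s.d. of the entries of `b`),
#'   default 10.
#' @param seed Integer seed fixing `b`.
#' @param d Dimension of the condition vector (default 2: age + diagnosis).
#' @return An object of class `encoding_spec`.
#' @export
#' @examples
#' spec <- make_encoding_spec(m = 100, mu_scale = 10, seed = 1)
#' length(fourier_encode(c(0.5, 0), spec))
make_encoding_spec <- function(m = 100, mu_scale = 10, seed = 1, d = 2) {
  check_scalar_number(m, "m", positive = TRUE)
  check_scalar_number(d, "d", positive = TRUE)
  check_scalar_number(mu_scale, "mu_scale", positive = TRUE)
  m <- as.integer(m); d <- as.integer(d)
  b <- withr::with_seed(as.integer(seed),
                        matrix(rnorm(d * m, mean = 0, sd = mu_scale), nrow = d))
  structure(
    list(m = m, d = d, mu_scale = mu_scale, seed = as.integer(seed),
         p = rep(1, m), b = b),
    class = "encoding_spec"
  )
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat(sprintf("<encoding_spec> d = %d, m = %d (encoded length %d), mu_scale = %g, seed = %d\n",
              x$d, x$m, 2L * x$m, x$mu_scale, x$seed))
  invisible(x)
}

#' Serialize / restore an encoding spec
#'
#' Only `{m, mu_scale, seed, d}` are stored; the frequency matrix is
#' regenerated from the seed.
#'
#' @param spec,config An `encoding_spec` / a named list.
#' @return A named list / an `encoding_spec`.
#' @export
encoding_spec_config <- function(spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  list(m = spec$m, mu_scale = spec$mu_scale, seed = spec$seed, d = spec$d)
}

#' @rdname encoding_spec_config
#' @export
encoding_spec_from_config <- function(config) {
  make_encoding_spec(m = config$m, mu_scale = config$mu_scale,
                     seed = config$seed, d = config$d)
}

#' Fourier-encode a normalized condition vector
#'
#' Maps `v` in `[0,1)^d` to
#' `(p_1 cos(2 pi b_1 . v), p_1 sin(2 pi b_1 . v), ..., p_m cos(...), p_m sin(...))`,
#' an interleaved cos/sin pair per frequency.  The map is smooth in `v`
#' (see [fourier_jacobian()]) and 1-periodic in every component, which is
#' what lets gradient ascent reach the conditional factor through the
#' generator.
#'
#' @param v Numeric vector of length `d`, or an `n x d` matrix of rows.
#' @param spec An [make_encoding_spec()] object.
#' @return A length-`2m` vector (or `n x 2m` matrix).
#' @export
fourier_encode <- function(v, spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  single <- is.null(dim(v))
  V <- if (single) matrix(v, nrow = 1) else as.matrix(v)
  if (ncol(V) != spec$d) {
    abort(sprintf("`v` has %d components but the spec expects d = %d.",
                  ncol(V), spec$d))
  }
  phase <- 2 * pi * (V %*% spec$b)          # n x m
  out <- matrix(0, nrow(V), 2L * spec$m)
  out[, seq(1, 2 * spec$m, by = 2)] <- sweep(cos(phase), 2, spec$p, `*`)
  out[, seq(2, 2 * spec$m, by = 2)] <- sweep(sin(phase), 2, spec$p, `*`)
  if (single) c(out) else out
}

#' Analytic Jacobian of the Fourier encoding
#'
#' Row `2j-1` is `-2 pi p_j sin(2 pi b_j . v) b_j`, row `2j` is
#' `2 pi p_j cos(2 pi b_j . v) b_j`.
#'
#' @inheritParams fourier_encode
#' @return A `2m x d` matrix.
#' @export
fourier_jacobian <- function(v, spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (length(v) != spec$d) {
    abort(sprintf("`v` has %d components but the spec expects d = %d.",
                  length(v), spec$d))
  }
  phase <- 2 * pi * c(crossprod(spec$b, v))  # length m
  J <- matrix(0, 2L * spec$m, spec$d)
  J[seq(1, 2 * spec$m, by = 2), ] <- t(spec$b) * (-2 * pi * spec$p * sin(phase))
  J[seq(2, 2 * spec$m, by = 2), ] <- t(spec$b) * (2 * pi * spec$p * cos(phase))
  J
}

#' Ordinal (thermometer) encoding of an integer
#'
#' The discrete encoding that Fourier features replace: the first `value`
#' entries are 1, the rest 0.  Kept to demonstrate why gradient updates break
#' it -- adding a real-valued gradient step to a thermometer vector yields a
#' vector that is no longer ordinal, and projecting back (quantize, then
#' re-sort the ones) is not differentiable.
#'
#' @param value Integer in `[0, n_bins]`.
#' @param n_bins Vector length.
#' @return A 0/1 numeric vector of length `n_bins`.
#' @export
#' @examples
#' ordinal_encode(3, 5)
ordinal_encode <- function(value, n_bins) {
  check_scalar_number(value, "value")
  check_scalar_number(n_bins, "n_bins", positive = TRUE)
  if (value < 0 || value > n_bins || value != round(value)) {
    abort("`value` must be an integer in [0, n_bins].")
  }
  c(rep(1, value), rep(0, n_bins - value))
}

#' Check the thermometer property of a vector
#'
#' TRUE when the vector is a valid ordinal encoding (all entries 0/1 and
#' non-increasing).
#'
#' @param x Numeric vector.
#' @return Logical scalar.
#' @export
is_ordinal_vector <- function(x) {
  all(x %in% c(0, 1)) && !is.unsorted(rev(x))
}
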