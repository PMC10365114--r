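test_that("condition normalization maps the age range onto [0, 1) and inverts", {
  expect_equal(normalize_conditions(60, 0, c(60, 90)), c(age_norm = 0, dx_norm = 0))
  v90 <- normalize_conditions(90, 1, c(60, 90))
  expect_lt(v90[["age_norm"]], 1)
  expect_gt(v90[["age_norm"]], 0.999)
  expect_equal(v90[["dx_norm"]], 0.5)
  v75 <- normalize_conditions(75, 0, c(60, 90))
  expect_equal(v75[["age_norm"]], (75 - 60) / (30 + 1e-6))
  # invertible round trip to < 1e-9 years across the range
  ages <- seq(60, 90, length.out = 31)
  back <- denormalize_age(normalize_conditions(ages, 0)[, "age_norm"])
  expect_lt(max(abs(back - ages)), 1e-9)
  expect_error(normalize_conditions(59, 0), "within")
  expect_error(normalize_conditions(75, 2), "diagnosis")
})

test_that("encoding spec is seed-deterministic with Gaussian frequencies", {
  s1 <- make_encoding_spec(m = 50, mu_scale = 10, seed = 42)
  s2 <- make_encoding_spec(m = 50, mu_scale = 10, seed = 42)
  expect_identical(s1$b, s2$b)
  expect_equal(dim(s1$b), c(2L, 50L))
  expect_true(all(s1$p^2 == 1))
  # empirical spread of b matches mu_scale within 2% at m = 10000
  big <- make_encoding_spec(m = 10000, mu_scale = 10, seed = 7)
  expect_equal(sd(big$b), 10, tolerance = 0.02)
  expect_error(make_encoding_spec(m = 0), "positive")
  expect_error(make_encoding_spec(mu_scale = -1), "positive")
})

test_that("spec config block regenerates the same basis without storing it", {
  s <- make_encoding_spec(m = 25, mu_scale = 3, seed = 5, d = 2)
  cfgblock <- encoding_spec_config(s)
  expect_named(cfgblock, c("m", "mu_scale", "seed", "d"))
  expect_identical(encoding_spec_from_config(cfgblock)$b, s$b)
})

test_that("fourier encoding has length 2m and matches a scalar-loop evaluation", {
  for (m in c(1, 10, 100)) {
    spec <- make_encoding_spec(m = m, seed = m)
    expect_length(fourier_encode(c(0.3, 0.7), spec), 2 * m)
  }
  spec <- make_encoding_spec(m = 100, mu_scale = 10, seed = 3)
  expect_length(fourier_encode(c(0.1, 0.5), spec), 200)

  # brute-force oracle: literal per-frequency loop
  withr::with_seed(9, {
    for (rep in 1:5) {
      v <- runif(2)
      enc <- fourier_encode(v, spec)
      ref <- numeric(2 * spec$m)
      for (j in seq_len(spec$m)) {
        phase <- 2 * pi * sum(spec$b[, j] * v)
        ref[2 * j - 1] <- spec$p[j] * cos(phase)
        ref[2 * j] <- spec$p[j] * sin(phase)
      }
      expect_lt(max(abs(enc - ref)), 1e-12)
      expect_true(all(abs(enc) <= max(spec$p)))
    }
  })

  # zero frequencies: cos rows are p, sin rows are 0
  z <- make_encoding_spec(m = 4, seed = 1)
  z$b[] <- 0
  enc0 <- fourier_encode(c(0.2, 0.9), z)
  expect_equal(enc0[seq(1, 8, 2)], rep(1, 4))
  expect_equal(enc0[seq(2, 8, 2)], rep(0, 4))
  expect_error(fourier_encode(c(0.1, 0.2, 0.3), spec), "d = 2")
})

test_that("encoding is 1-periodic in each component of v", {
  spec <- make_encoding_spec(m = 20, mu_scale = 4, seed = 13)
  # integer frequencies make shifts by 1 exact periods
  spec$b[] <- matrix(sample(-5:5, 40, replace = TRUE), 2, 20)
  v <- c(0.37, 0.81)
  for (shift in list(c(1, 0), c(0, 1), c(2, -1))) {
    expect_equal(fourier_encode(v + shift, spec), fourier_encode(v, spec),
                 tolerance = 1e-9)
  }
})

test_that("analytic jacobian matches closed forms and finite differences", {
  # closed form at d = 1, m = 1, b = 1, v = 0: rows (0, 2*pi)
  s1 <- make_encoding_spec(m = 1, mu_scale = 1, seed = 1, d = 1)
  s1$b[] <- 1
  expect_equal(fourier_jacobian(0, s1), matrix(c(0, 2 * pi), 2, 1))
  sz <- make_encoding_spec(m = 3, seed = 2)
  sz$b[] <- 0
  expect_equal(fourier_jacobian(c(0.4, 0.2), sz), matrix(0, 6, 2))

  # 100 random (v, spec) draws against central differences
  h <- 1e-6
  worst <- 0
  withr::with_seed(31, {
    for (i in 1:100) {
      spec <- make_encoding_spec(m = sample(1:20, 1),
                                 mu_scale = runif(1, 0.5, 10),
                                 seed = sample.int(1e6, 1))
      v <- runif(2)
      J <- fourier_jacobian(v, spec)
      for (k in 1:2) {
        e <- c(0, 0); e[k] <- h
        fd <- (fourier_encode(v + e, spec) - fourier_encode(v - e, spec)) / (2 * h)
        worst <- max(worst, max(abs(J[, k] - fd)))
      }
    }
  })
  expect_lt(worst, 1e-5)
})

test_that("normalize -> encode composition is differentiable in age", {
  spec <- make_encoding_spec(m = 30, mu_scale = 10, seed = 17)
  age <- 72.3
  v <- normalize_conditions(age, 1)
  # chain rule: d gamma / d age = J[, 1] * d age_norm / d age
  analytic <- fourier_jacobian(v, spec)[, 1] / (30 + 1e-6)
  h <- 1e-5
  fd <- (fourier_encode(normalize_conditions(age + h, 1), spec) -
           fourier_encode(normalize_conditions(age - h, 1), spec)) / (2 * h)
  expect_lt(max(abs(analytic - fd)), 1e-5)
})

test_that("ordinal encoding reproduces the thermometer layout and its breakage", {
  expect_equal(ordinal_encode(3, 5), c(1, 1, 1, 0, 0))
  expect_equal(ordinal_encode(0, 5), rep(0, 5))
  expect_equal(ordinal_encode(5, 5), rep(1, 5))
  expect_error(ordinal_encode(6, 5), "in \\[0, n_bins\\]")
  expect_error(ordinal_encode(-1, 5), "in \\[0, n_bins\\]")

  # a gradient-style additive update destroys the ordinal structure
  grad_step <- c(-0.3, -0.1, 0.1, 0.2, -0.3)
  updated <- ordinal_encode(3, 5) + grad_step
  expect_equal(updated, c(0.7, 0.9, 1.1, 0.2, -0.3))
  expect_true(is_ordinal_vector(ordinal_encode(3, 5)))
  expect_false(is_ordinal_vector(updated))
})
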