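#' Rendering configuration for the synthetic ageing-brain simulator
#'
#' The simulator draws an axial-slice cartoon of a brain in normalized
#' `[-1, 1]^2` coordinates: an elliptic outer shell of bright tissue around
#' dark elliptic ventricles, plus a smooth per-subject texture field.  Ageing
#' shrinks the outer shell and enlarges the ventricles; an AD diagnosis adds
#' `beta_ad` of extra effective ventricular atrophy (about nine "years") and
#' subtly elongates the ventricles, so advanced age and AD are visually
#' confusable through ventricle size while diagnosis stays identifiable
#' through shape.  All region edges are sigmoid-smoothed with temperature
#' `tau`, making the map from age to image smooth -- the property the
#' adversarial target-age ascent relies on.
#'
#' @param size Image side in pixels (resolution knob only; geometry lives in
#'   normalized coordinates).
#' @param tau Edge temperature of the sigmoid-smoothed region boundaries.
#' @param sigma_noise S.d. of additive Gaussian pixel noise, applied last and
#'   frozen per sample; the gradient path is noise-free.  The default 0.3 is
#'   what keeps the toy classification problem off its accuracy ceiling:
#'   with near-noiseless images every strategy saturates and neither
#'   forgetting nor method orderings are observable.
#' @param beta_ad Extra effective ventricular atrophy for AD, in units of the
#'   full age range (0.3 = nine years over a 30-year range).
#' @param ad_elong Multiplicative elongation of the ventricle x-semi-axis for
#'   AD -- the subtle diagnosis-specific shape marker.
#' @param base_outer,base_vent Default outer / ventricle semi-axes.
#' @param vent_growth Ventricle semi-axis growth per unit effective atrophy.
#' @param shell_shrink Outer-shell shrink per unit *age* (the clean age cue;
#'   larger than the outer-axis subject jitter so the shell is informative
#'   about age).
#' @param jitter_outer,jitter_vent Relative subject jitter of the outer /
#'   ventricle semi-axes (both within the +/- 5% envelope).
#' @param tissue Brightness of tissue over the -1 background.
#' @param texture_amp Amplitude of the per-subject texture field.
#' @param age_range Age range in years; atrophy is linear over it.
#' @return A list of class `render_config`.
#' @export
render_config <- function(size = 64, tau = 0.02, sigma_noise = 0.3,
                          beta_ad = 0.3, ad_elong = 1.3,
                          base_outer = c(0.72, 0.88),
                          base_vent = c(0.16, 0.22),
                          vent_growth = c(0.10, 0.13),
                          shell_shrink = 0.12, jitter_outer = 0.02,
                          jitter_vent = 0.05, tissue = 1.6,
                          texture_amp = 0.12, age_range = c(60, 90)) {
  stopifnot(size >= 32, tau > 0, sigma_noise >= 0, length(age_range) == 2)
  structure(
    list(size = as.integer(size), tau = tau, sigma_noise = sigma_noise,
         beta_ad = beta_ad, ad_elong = ad_elong, base_outer = base_outer,
         base_vent = base_vent, vent_growth = vent_growth,
         shell_shrink = shell_shrink, jitter_outer = jitter_outer,
         jitter_vent = jitter_vent, tissue = tissue,
         texture_amp = texture_amp, age_range = age_range),
    class = "render_config"
  )
}

#' Sample per-subject anatomy parameters
#'
#' Each subject jitters the default outer and ventricle semi-axes within
#' +/- 5% and carries a texture seed; identical `subject_id` under the same
#' seed always yields identical parameters.  Subject identity is what the
#' counterfactual generator preserves when it re-ages an image.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param cfg A [render_config()].
#' @return A tibble with one row per subject.
#' @export
make_subjects <- function(n, seed = 1, cfg = render_config()) {
  stopifnot(n >= 1)
  withr::with_seed(as.integer(seed), {
    jit <- function(base, rel) {
      m <- matrix(runif(2 * n, 1 - rel, 1 + rel), ncol = 2, byrow = TRUE)
      sweep(m, 2, base, `*`)
    }
    ja <- jit(cfg$base_outer, cfg$jitter_outer)
    jv <- jit(cfg$base_vent, cfg$jitter_vent)
    tibble::tibble(
      subject_id = seq_len(n),
      outer_a = ja[, 1], outer_b = ja[, 2],
      vent_a = jv[, 1], vent_b = jv[, 2],
      texture_seed = sample.int(2^30, n)
    )
  })
}

subject_texture <- function(subject, cfg) {
  s <- cfg$size
  u <- seq(-1, 1, length.out = s)
  withr::with_seed(as.integer(subject$texture_seed), {
    k <- 4L
    fx <- runif(k, 0.5, 2.5); fy <- runif(k, 0.5, 2.5)
    ph <- runif(k, 0, 2 * pi); cc <- rnorm(k)
    cc <- cc / sqrt(sum(cc^2))
    tex <- matrix(0, s, s)
    for (j in seq_len(k)) {
      tex <- tex + cc[j] * sin(outer(2 * pi * fx[j] * u, 2 * pi * fy[j] * u, `+`) + ph[j])
    }
    cfg$texture_amp * tex
  })
}

# geometry shared by value and gradient paths; clamps degenerate ventricles
render_geometry <- function(subject, age, diagnosis, cfg) {
  rng <- cfg$age_range
  age_n <- (age - rng[1]) / diff(rng)       # clean age signal
  t_eff <- age_n + cfg$beta_ad * diagnosis  # effective ventricular atrophy
  A <- c(subject$outer_a, subject$outer_b) * (1 - cfg$shell_shrink * age_n)
  elong <- c(if (diagnosis > 0) cfg$ad_elong else 1, 1)
  R <- (c(subject$vent_a, subject$vent_b) + cfg$vent_growth * t_eff) * elong
  dR_dt <- cfg$vent_growth * elong
  cap <- 0.85 * A
  clamped <- R > cap
  if (any(clamped)) {
    warn("Ventricle exceeded brain shell; axes clamped.")
    R[clamped] <- cap[clamped]
    dR_dt[clamped] <- 0
  }
  list(A = A, R = R, age_n = age_n, t_eff = t_eff,
       dA_dage = -cfg$shell_shrink * c(subject$outer_a, subject$outer_b) / diff(rng),
       dR_dage = dR_dt / diff(rng))
}

#' Render a synthetic brain slice
#'
#' Deterministic given `(subject, age, diagnosis, cfg, noise_seed)`.
#' Intensities lie in `[-1, 1]`.  With `grad = TRUE` the analytic derivative
#' of every pixel with respect to age (in years) is returned alongside; the
#' derivative ignores the frozen additive noise, which is applied after the
#' geometry.
#'
#' @param subject One-row tibble (or list) of subject parameters from
#'   [make_subjects()].
#' @param age Age in years within `cfg$age_range`.
#' @param diagnosis 0 (CN) or 1 (AD).
#' @param cfg A [render_config()].
#' @param noise_seed Integer seed for the additive pixel noise, or `NULL`
#'   for a noiseless render.
#' @param grad If `TRUE`, also return `d image / d age`.
#' @return An image matrix, or (with `grad`) a list `(image, grad_age)`.
#' @export
render_brain <- function(subject, age, diagnosis, cfg = render_config(),
                         noise_seed = NULL, grad = FALSE) {
  rng <- cfg$age_range
  if (age < rng[1] || age > rng[2]) {
    abort(sprintf("`age` %g outside configured range [%g, %g].", age, rng[1], rng[2]))
  }
  g <- render_geometry(subject, age, diagnosis, cfg)
  s <- cfg$size
  u <- seq(-1, 1, length.out = s)
  u2 <- u^2
  q_out <- outer(u2 / g$A[1]^2, u2 / g$A[2]^2, `+`)
  q_vent <- outer(u2 / g$R[1]^2, u2 / g$R[2]^2, `+`)
  m_out <- sigmoid((1 - q_out) / cfg$tau)
  m_vent <- sigmoid((1 - q_vent) / cfg$tau)
  tex <- subject_texture(subject, cfg)
  shade <- cfg$tissue + tex
  img <- -1 + shade * m_out * (1 - m_vent)
  out <- img
  if (!is.null(noise_seed) && cfg$sigma_noise > 0) {
    noise <- withr::with_seed(as.integer(noise_seed),
                              matrix(rnorm(s * s, 0, cfg$sigma_noise), s, s))
    out <- clip(img + noise, -1, 1)
  }
  if (!grad) return(out)
  dq_out <- outer(-2 * u2 / g$A[1]^3 * g$dA_dage[1],
                  -2 * u2 / g$A[2]^3 * g$dA_dage[2], `+`)
  dq_vent <- outer(-2 * u2 / g$R[1]^3 * g$dR_dage[1],
                   -2 * u2 / g$R[2]^3 * g$dR_dage[2], `+`)
  dm_out <- m_out * (1 - m_out) * (-dq_out) / cfg$tau
  dm_vent <- m_vent * (1 - m_vent) * (-dq_vent) / cfg$tau
  grad_age <- shade * (dm_out * (1 - m_vent) - m_out * dm_vent)
  list(image = out, grad_age = grad_age)
}

#' Dark-interior area of a rendered slice
#'
#' Counts pixels darker than `threshold` inside the brain (outer-shell) mask,
#' i.e. the ventricular/CSF area that grows with atrophy.  The mask is
#' recomputed from the sample's subject parameters and age, so background
#' pixels (also dark) are excluded.
#'
#' @param image Image matrix.
#' @param subject,age,diagnosis Geometry of the rendered sample.
#' @param cfg The [render_config()] used to render it.
#' @param threshold Intensity below which a pixel counts as dark.
#' @return Number of dark interior pixels.
#' @export
dark_interior_area <- function(image, subject, age, diagnosis,
                               cfg = render_config(), threshold = -0.5) {
  g <- render_geometry(subject, age, diagnosis, cfg)
  u <- seq(-1, 1, length.out = cfg$size)
  q_out <- outer(u^2 / g$A[1]^2, u^2 / g$A[2]^2, `+`)
  sum(image[q_out < 1] < threshold)
}

new_toy_dataset <- function(samples, cfg, provenance,
                            age_bins = c(60, 70, 80, 90)) {
  structure(samples,
            class = c("toy_dataset", class(tibble::tibble()))) |>
    (\(x) { attr(x, "render_cfg") <- cfg
            attr(x, "provenance") <- provenance
            attr(x, "age_bins") <- age_bins
            x })()
}

#' Render configuration attached to a dataset
#' @param dataset A `toy_dataset`.
#' @return The [render_config()] it was rendered with.
#' @export
dataset_render_cfg <- function(dataset) attr(dataset, "render_cfg")

render_samples <- function(meta, subjects, cfg, seed) {
  meta <- dplyr::left_join(meta, subjects, by = "subject_id")
  meta$image <- purrr::pmap(
    list(meta$sample_id, meta$subject_id, meta$age, meta$diagnosis),
    function(sid, sub, age, dx) {
      subject <- subjects[subjects$subject_id == sub, ]
      render_brain(subject, age, dx, cfg,
                   noise_seed = derive_seed(seed, paste0("noise", sid)))
    }
  )
  meta
}

split_counts <- function(n, fracs) {
  stopifnot(abs(sum(fracs) - 1) < 1e-8)
  counts <- diff(c(0, round(cumsum(fracs) * n)))
  if (any(counts <= 0)) abort("Split fractions leave an empty split.")
  counts
}

#' Simulate an uncoupled ageing-brain cohort
#'
#' One slice per subject; training and validation ages are drawn from
#' `age_law`, diagnosis Bernoulli(`ad_fraction`) independent of age (no
#' spurious coupling).  Splits partition *subjects*, so no subject leaks
#' across train/val/test.
#'
#' The default `"young_heavy"` law (a Beta(1.2, 2.5) over the age range)
#' under-represents the oldest subjects, the way clinical cohorts do; the
#' sparse old-CN corner is then both data-poor and visually confusable
#' with AD, which is what gives targeted counterfactual augmentation
#' something to balance.  Test ages are always drawn uniformly so every
#' age-group cell is measured with adequate counts.
#'
#' @param n_subjects Number of subjects (= samples).
#' @param age_law `"young_heavy"` (default) or `"uniform"`, for the
#'   train/val ages.
#' @param ad_fraction Probability of an AD diagnosis.
#' @param seed Master seed; all stages derive sub-seeds from it.
#' @param split_fracs Named fractions `(train, val, test)` summing to 1.
#' @param cfg A [render_config()].
#' @return A `toy_dataset` tibble with columns `sample_id`, `subject_id`,
#'   `age`, `diagnosis`, `split`, subject parameters, and an `image`
#'   list-column.
#' @export
#' @examples
#' ds <- sample_dataset(n_subjects = 12, seed = 1,
#'                      cfg = render_config(size = 32))
#' dplyr::count(ds, split, diagnosis)
sample_dataset <- function(n_subjects = 300,
                           age_law = c("young_heavy", "uniform"),
                           ad_fraction = 0.5, seed = 1,
                           split_fracs = c(train = 0.7, val = 0.1, test = 0.2),
                           cfg = render_config()) {
  age_law <- match.arg(age_law)
  subjects <- make_subjects(n_subjects, derive_seed(seed, "subjects"), cfg)
  rng <- cfg$age_range
  counts <- split_counts(n_subjects, split_fracs)
  perm <- withr::with_seed(derive_seed(seed, "splits"),
                           sample.int(n_subjects))
  split <- character(n_subjects)
  split[perm] <- rep(c("train", "val", "test"), counts)
  meta <- withr::with_seed(derive_seed(seed, "cohort"), {
    age <- if (age_law == "young_heavy") {
      rng[1] + diff(rng) * stats::rbeta(n_subjects, 1.2, 2.5)
    } else {
      runif(n_subjects, rng[1], rng[2])
    }
    age[split == "test"] <- runif(sum(split == "test"), rng[1], rng[2])
    tibble::tibble(
      sample_id = seq_len(n_subjects),
      subject_id = seq_len(n_subjects),
      age = age,
      diagnosis = rbinom(n_subjects, 1, ad_fraction),
      split = split
    )
  })
  meta <- render_samples(meta, subjects, cfg, seed)
  new_toy_dataset(meta, cfg,
                  provenance = list(kind = "uncoupled", n_subjects = n_subjects,
                                    ad_fraction = ad_fraction, seed = seed,
                                    split_fracs = split_fracs))
}

#' Simulate a spuriously coupled cohort (young AD, old CN)
#'
#' Training and validation samples couple diagnosis to age deterministically:
#' every AD subject is younger than `age_split`, every CN subject at least
#' `age_split` -- the shortcut a classifier can exploit.  The test split is
#' *not* coupled: ages and diagnoses are independent, so all four
#' age-group x diagnosis cells are populated and the broken-shortcut groups
#' (young CN, old AD) are measurable.
#'
#' @param n Total number of subjects.
#' @param age_split Coupling boundary in years (default 75).
#' @param seed Master seed.
#' @param split_fracs Named fractions `(train, val, test)`.
#' @param cfg A [render_config()].
#' @return A `toy_dataset`; its age bins are `c(60, age_split, 90)`.
#' @export
make_spurious_dataset <- function(n = 500, age_split = 75, seed = 1,
                                  split_fracs = c(train = 0.6, val = 0.1, test = 0.3),
                                  cfg = render_config()) {
  rng <- cfg$age_range
  stopifnot(age_split > rng[1], age_split < rng[2])
  subjects <- make_subjects(n, derive_seed(seed, "subjects"), cfg)
  counts <- split_counts(n, split_fracs)
  meta <- withr::with_seed(derive_seed(seed, "cohort"), {
    split <- rep(c("train", "val", "test"), counts)[sample.int(n)]
    age <- runif(n, rng[1], rng[2])
    diagnosis <- ifelse(split == "test",
                        rbinom(n, 1, 0.5),
                        as.integer(age < age_split))
    tibble::tibble(sample_id = seq_len(n), subject_id = seq_len(n),
                   age = age, diagnosis = diagnosis, split = split)
  })
  test <- meta[meta$split == "test", ]
  cells <- table(test$diagnosis, test$age < age_split)
  if (length(cells) < 4 || any(cells == 0)) {
    abort("`n` too small to populate all four test age x diagnosis groups.")
  }
  meta <- render_samples(meta, subjects, cfg, seed)
  new_toy_dataset(meta, cfg,
                  provenance = list(kind = "spurious", n = n,
                                    age_split = age_split, seed = seed,
                                    split_fracs = split_fracs),
                  age_bins = c(rng[1], age_split, rng[2]))
}

#' Filter a dataset to one split
#' @param dataset A `toy_dataset`.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return The matching rows, attributes preserved.
#' @export
dataset_split <- function(dataset, split = c("train", "val", "test")) {
  split <- match.arg(split)
  out <- dataset[dataset$split == split, ]
  for (a in c("render_cfg", "provenance", "age_bins")) {
    attr(out, a) <- attr(dataset, a)
  }
  out
}
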