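test_that("rendering is deterministic and bounded in [-1, 1]", {
  cfg <- small_cfg()
  sub <- make_subjects(2, seed = 3, cfg = cfg)[1, ]
  a <- render_brain(sub, 72, 0, cfg, noise_seed = 5)
  b <- render_brain(sub, 72, 0, cfg, noise_seed = 5)
  expect_identical(a, b)
  expect_true(all(a >= -1 & a <= 1))
  # noiseless render is also deterministic and noise-free
  expect_identical(render_brain(sub, 72, 0, cfg), render_brain(sub, 72, 0, cfg))
  expect_error(render_brain(sub, 95, 0, cfg), "outside")
})

test_that("subject parameters are reproducible and jittered within 5%", {
  cfg <- small_cfg()
  s1 <- make_subjects(20, seed = 9, cfg = cfg)
  s2 <- make_subjects(20, seed = 9, cfg = cfg)
  expect_identical(s1, s2)
  expect_true(all(abs(s1$vent_a / cfg$base_vent[1] - 1) <= 0.05))
  expect_true(all(abs(s1$outer_a / cfg$base_outer[1] - 1) <= 0.05))
})

test_that("dark interior area grows with age and with an AD diagnosis", {
  cfg <- small_cfg()
  subs <- make_subjects(10, seed = 4, cfg = cfg)
  ages <- seq(60, 90, length.out = 7)
  for (i in seq_len(nrow(subs))) {
    sub <- subs[i, ]
    areas <- vapply(ages, function(a) {
      dark_interior_area(render_brain(sub, a, 0, cfg), sub, a, 0, cfg)
    }, numeric(1))
    expect_true(all(diff(areas) >= 0))
    expect_gt(areas[7], areas[1])
  }
  sub <- subs[1, ]
  area_cn <- dark_interior_area(render_brain(sub, 70, 0, cfg), sub, 70, 0, cfg)
  area_ad <- dark_interior_area(render_brain(sub, 70, 1, cfg), sub, 70, 1, cfg)
  expect_gt(area_ad, area_cn)
})

test_that("renderer age gradient matches central finite differences", {
  cfg <- small_cfg()
  subs <- make_subjects(5, seed = 6, cfg = cfg)
  h <- 1e-4
  withr::with_seed(8, {
    for (i in 1:5) {
      sub <- subs[i, ]
      age <- runif(1, 61, 89); dx <- rbinom(1, 1, 0.5)
      g <- render_brain(sub, age, dx, cfg, grad = TRUE)
      fd <- (render_brain(sub, age + h, dx, cfg) -
               render_brain(sub, age - h, dx, cfg)) / (2 * h)
      expect_lt(max(abs(g$grad_age - fd)), 1e-5)
    }
  })
})

test_that("degenerate ventricle geometry is clamped with a warning", {
  cfg <- small_cfg()
  cfg$base_vent <- c(0.7, 0.8)  # near the shell already
  sub <- make_subjects(1, seed = 2, cfg = cfg)[1, ]
  expect_warning(render_brain(sub, 90, 1, cfg), "clamped")
})

test_that("uncoupled cohorts have exact splits, binomial balance, and no leakage", {
  cfg <- small_cfg()
  ds <- sample_dataset(100, ad_fraction = 0.5, seed = 31, cfg = cfg)
  expect_equal(unname(table(ds$split)[c("train", "val", "test")]),
               c(70L, 10L, 20L), ignore_attr = TRUE)
  # AD count within binomial 99% bounds of n/2
  expect_true(abs(sum(ds$diagnosis) - 50) < qnorm(0.995) * sqrt(100 * 0.25) + 1)
  # seed reproducibility: identical order, ages, images
  ds2 <- sample_dataset(100, ad_fraction = 0.5, seed = 31, cfg = cfg)
  expect_identical(ds$age, ds2$age)
  expect_identical(ds$image[[17]], ds2$image[[17]])
  # diagnosis independent of age: correlation near zero at n = 100
  expect_lt(abs(cor(ds$age, ds$diagnosis)), 0.3)
  # no subject appears in two splits
  expect_equal(anyDuplicated(unique(ds[, c("subject_id", "split")])$subject_id), 0)
  expect_error(sample_dataset(5, split_fracs = c(train = 0.99, val = 0.005,
                                                 test = 0.005), cfg = cfg),
               "empty split")
})

test_that("spurious cohorts couple train ages to diagnosis but not test", {
  cfg <- small_cfg()
  ds <- make_spurious_dataset(160, age_split = 75, seed = 41, cfg = cfg)
  tr <- dplyr::filter(ds, split %in% c("train", "val"))
  expect_true(all(tr$age[tr$diagnosis == 1] < 75))
  expect_true(all(tr$age[tr$diagnosis == 0] >= 75))
  te <- dplyr::filter(ds, split == "test")
  counts <- table(te$diagnosis, te$age >= 75)
  expect_true(all(counts > 0))   # all four groups populated
  expect_equal(attr(ds, "age_bins"), c(60, 75, 90))
  expect_error(make_spurious_dataset(8, seed = 1, cfg = cfg))
})

test_that("oracle generator re-renders the subject: identity, ageing, rejuvenation", {
  cfg <- small_cfg()
  ds <- small_dataset()
  G <- oracle_generator(cfg)
  s <- ds[3, ]
  # identity counterfactual equals the noiseless re-render
  cfg0 <- cfg; cfg0$sigma_noise <- 0
  expect_equal(cf_generate(G, s, s$age)[[1]],
               render_brain(s, s$age, s$diagnosis, cfg0))
  # rejuvenation shrinks the dark interior (85 -> 65 on a CN subject)
  cn <- dplyr::filter(ds, diagnosis == 0)[1, ]
  img85 <- cf_generate(G, cn, 85)[[1]]
  img65 <- cf_generate(G, cn, 65)[[1]]
  expect_lt(dark_interior_area(img65, cn, 65, 0, cfg),
            dark_interior_area(img85, cn, 85, 0, cfg))
  # analytic d(image)/d(target age) matches finite differences
  g <- cf_generate_grad(G, s, 77)[[1]]
  h <- 1e-3
  fd <- (cf_generate(G, s, 77 + h)[[1]] - cf_generate(G, s, 77 - h)[[1]]) / (2 * h)
  expect_lt(max(abs(g - fd)), 1e-4)
  expect_false(is_trainable(G))
  expect_null(generator_state(G))
})

test_that("a classifier learns the uncoupled world but inherits the spurious shortcut", {
  # learnable: balanced cohort reaches high train and > 90% test accuracy
  cfg <- render_config()  # full-size world
  ds <- fixture("learn_ds", function() sample_dataset(200, seed = 1, cfg = cfg))
  fit <- fixture("learn_fit", function() {
    pretrain_classifier(ds, train_config(epochs = 30, seed = 2))
  })
  expect_gt(fit$history$accuracy[nrow(fit$history)], 0.95)
  expect_gt(test_accuracy(fit, dataset_split(ds, "test")), 0.9)

  # the same classifier trained on the coupled cohort collapses on the
  # groups where the coupling breaks
  sp <- fixture("spur_ds_small", function() {
    make_spurious_dataset(300, seed = 1, cfg = cfg)
  })
  fit_sp <- fixture("spur_fit_small", function() {
    pretrain_classifier(sp, train_config(epochs = 30, seed = 2))
  })
  te <- dataset_split(sp, "test")
  p <- predict_proba(as_classifier(fit_sp), te)
  ok <- (p > 0.5) == (te$diagnosis == 1)
  broken <- (te$diagnosis == 1 & te$age >= 75) | (te$diagnosis == 0 & te$age < 75)
  expect_lt(mean(ok[broken]), mean(ok[!broken]) - 0.2)
})

test_that("datasets round-trip through the on-disk artifact format", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_toy_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  back <- read_toy_dataset(dir)
  expect_equal(back$age, ds$age)
  expect_identical(back$image[[5]], ds$image[[5]])
  expect_equal(dataset_render_cfg(back)$size, dataset_render_cfg(ds)$size)
  expect_equal(attr(back, "age_bins"), attr(ds, "age_bins"))
})

test_that("NIfTI slices ingest with metadata when RNifti is available", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  vol <- array(runif(16 * 16 * 5, 0, 100), dim = c(16, 16, 5))
  RNifti::writeNifti(RNifti::asNifti(vol), file.path(dir, "v1.nii.gz"))
  meta <- tibble::tibble(sample_id = 1, subject_id = 1, age = 70,
                         diagnosis = 1, split = "train", file = "v1.nii.gz")
  readr::write_csv(meta, file.path(dir, "meta.csv"))
  out <- read_nifti_slices(file.path(dir, "meta.csv"), size = 16)
  expect_equal(nrow(out), 1)
  expect_equal(dim(out$image[[1]]), c(16L, 16L))
  expect_true(all(out$image[[1]] >= -1 & out$image[[1]] <= 1))
})
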