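test_that("noiseless homogeneous phantom is exactly flat inside the lesion", {
  spec <- phantom_spec(heterogeneity = 0, noise_sigma = 0)
  ph <- make_lesion_phantom(spec, seed = 1)
  inside <- ph$volume$values[ph$mask$values]
  expect_true(all(inside == spec$lesion_level))
  expect_equal(stats::var(inside), 0)
  expect_gt(mask_size(ph$mask), 0)
})

test_that("phantom rendering is deterministic and heterogeneity raises variance", {
  spec <- phantom_spec(heterogeneity = 0.7)
  a <- make_lesion_phantom(spec, seed = 7)
  b <- make_lesion_phantom(spec, seed = 7)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, b$mask$values)

  for (s in 1:20) {
    hi <- make_lesion_phantom(phantom_spec(heterogeneity = 50), seed = s)
    lo <- make_lesion_phantom(phantom_spec(heterogeneity = 0), seed = s)
    expect_gt(stats::var(hi$volume$values[hi$mask$values]),
              stats::var(lo$volume$values[lo$mask$values]))
  }

  expect_error(phantom_spec(lesion_radius = 60), "does not fit")
  expect_error(phantom_spec(heterogeneity = -1), ">= 0")
})

test_that("contour perturbation moves the boundary by the requested amount", {
  sph10 <- sphere_mask(10, 2, 16)
  expect_identical(perturb_mask(sph10, 0, seed = 1)$values, sph10$values)
  pert <- perturb_mask(sph10, 2, seed = 1)
  expect_lt(dice(sph10, pert), 1)
  expect_gt(mask_size(pert), 0)

  sph20 <- sphere_mask(20, 2.5, 20)
  mean_dice <- vapply(c(1, 2, 4), function(mag) {
    mean(vapply(1:50, function(s)
      dice(sph20, perturb_mask(sph20, mag, seed = s)), 0))
  }, 0)
  expect_true(all(diff(mean_dice) < 0))
})

test_that("survival simulator matches its exponential model", {
  s0 <- simulate_survival(rep(0, 200), baseline_scale = 16,
                          censor_rate = 0, seed = 3)
  expect_true(all(s0$event == 1L))
  expect_true(all(s0$time > 0))

  s1 <- simulate_survival(rep(0, 1000), baseline_scale = 16,
                          censor_rate = 0, seed = 5)
  expect_lt(abs(km_median(s1$time, s1$event) - 16 * log(2)) / (16 * log(2)),
            0.10)

  s2 <- simulate_survival(rnorm(2000), baseline_scale = 16,
                          censor_rate = 0.4, seed = 6)
  expect_lt(abs(mean(1 - s2$event) - 0.4), 0.05)
  expect_error(simulate_survival(0, censor_rate = 1), "censor_rate")
})

test_that("cohorts plant the intended association between texture and outcome", {
  null_c <- simulate_cohort(500, 0, seed = 11, render = FALSE)
  c0 <- harrell_c(null_c$h, null_c$outcomes$time_months,
                  null_c$outcomes$event)
  expect_gt(c0, 0.45); expect_lt(c0, 0.55)

  eff <- simulate_cohort(500, 1, seed = 12, render = FALSE)
  expect_gt(harrell_c(eff$h, eff$outcomes$time_months, eff$outcomes$event),
            0.65)

  a <- simulate_cohort(50, 0.5, seed = 1, render = FALSE)
  b <- simulate_cohort(50, 0.5, seed = 2, render = FALSE)
  expect_false(identical(a$h, b$h))
  expect_lt(abs(mean(a$h) - mean(b$h)), 0.25)
  # realized censoring within 0.15 of target at n >= 50
  expect_lt(abs(mean(1 - a$outcomes$event) - a$censor_rate_target), 0.15)

  cc <- simulate_cohort(50, 0.5, seed = 1, render = FALSE)
  expect_identical(a$outcomes, cc$outcomes)
})

test_that("cohorts round-trip through NIfTI + CSV on disk", {
  co <- simulate_cohort(3, 1, seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "case_001_img.nii.gz")))
  expect_true(file.exists(file.path(dir, "case_001_mask.nii.gz")))
  outc <- utils::read.csv(file.path(dir, "outcomes.csv"))
  expect_identical(names(outc), c("case_id", "time_months", "event"))
  back <- read_volume(file.path(dir, "case_002_img.nii.gz"), "PET")
  expect_equal(back$values, co$cases[[2]]$volume$values, tolerance = 1e-6)
  mback <- read_mask(file.path(dir, "case_003_mask.nii.gz"))
  expect_identical(mback$values, co$cases[[3]]$mask$values)
})
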