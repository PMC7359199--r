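test_that("consistency ICC handles identical, offset and noise observers", {
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(icc_consistency(cbind(m[, 1], m[, 1], m[, 1])), 1)
  # constant observer offsets are ignored by the consistency variant
  expect_equal(icc_consistency(cbind(c(1, 2, 3), c(2, 3, 4))), 1)
  expect_equal(icc_consistency(matrix(5, 4, 3)), 1)

  set.seed(10)
  noise <- matrix(rnorm(2000), 1000, 2)
  expect_lt(abs(icc_consistency(noise)), 0.1)

  # agreement variant penalizes the offset
  expect_lt(icc_consistency(cbind(c(1, 2, 3), c(2, 3, 4)), "agreement"), 1)
  expect_error(icc_consistency(matrix(1:3, 3, 1)), ">= 2")
})

test_that("ICC is affine-invariant and matches the ANOVA oracle", {
  set.seed(11)
  for (r in 1:100) {
    m <- matrix(rnorm(33), 11, 3)
    icc <- icc_consistency(m)
    expect_equal(icc, oracle_icc31(m), tolerance = 1e-10)
    expect_equal(icc_consistency(2.5 * m + 7), icc, tolerance = 1e-10)
  }
})

test_that("the stability filter keeps reproducible features and drops noise", {
  set.seed(12)
  base <- matrix(rnorm(33), 11, 3)
  arr <- array(NA_real_, c(11, 3, 3),
               dimnames = list(NULL, NULL, c("stable", "noisy", "gappy")))
  arr[, , "stable"] <- base[, 1]          # identical across observers
  arr[, , "noisy"] <- rnorm(33)           # pure per-observer noise
  arr[, , "gappy"] <- base; arr[5, 2, "gappy"] <- NA
  res <- stability_filter(observer_feature_table(arr), threshold = 0.8)
  expect_true("stable" %in% res$stable)
  expect_false("gappy" %in% res$stable)   # missing cell => unstable
  expect_true(res$report$retained[res$report$feature == "stable"])

  # pure observer noise at 11 cases is excluded essentially always
  excl <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    icc_consistency(matrix(rnorm(33), 11, 3)) <= 0.8
  }, TRUE)
  expect_gte(sum(excl), 97)
})

test_that("long-format observer tables round-trip into the filter", {
  long <- expand.grid(case_id = sprintf("c%02d", 1:5),
                      observer_id = c("o1", "o2", "o3"),
                      feature = c("f1", "f2"), stringsAsFactors = FALSE)
  set.seed(13)
  per_case <- rnorm(5)
  long$value <- ifelse(long$feature == "f1",
                       per_case[match(long$case_id, sprintf("c%02d", 1:5))],
                       rnorm(nrow(long)))
  res <- stability_filter(long)
  expect_identical(res$stable, "f1")
})

test_that("interior intensity features are more observer-robust than boundary shape", {
  icc_med <- numeric(20); icc_area <- numeric(20)
  for (s in 1:20) {
    meds <- matrix(0, 12, 3); areas <- matrix(0, 12, 3)
    for (cs in 1:12) {
      ph <- make_lesion_phantom(
        phantom_spec(heterogeneity = 0.2, noise_sigma = 0.1,
                     lesion_radius = 18 + cs / 4), seed = s * 100 + cs)
      for (ob in 1:3) {
        mk <- if (ob == 1) ph$mask else
          perturb_mask(ph$mask, 4, seed = s * 1000 + cs * 10 + ob)
        meds[cs, ob] <- stats::median(ph$volume$values[mk$values])
        areas[cs, ob] <- shape_features(mk)[["shape surface area"]]
      }
    }
    icc_med[s] <- icc_consistency(meds)
    icc_area[s] <- icc_consistency(areas)
  }
  expect_gt(mean(icc_med), mean(icc_area))
})
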