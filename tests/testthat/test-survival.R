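test_that("prefilter applies the missingness and variability rules", {
  set.seed(20)
  X <- data.frame(a = rnorm(36), b = rnorm(36), flat = rep(2, 36),
                  check.names = FALSE)
  X$a[1:8] <- NA                       # 8/36 = 22.2% missing -> dropped
  X$b[1:7] <- NA                       # 7/36 = 19.4% -> kept, imputed
  pf <- prefilter(X)
  expect_false("a" %in% pf$kept)
  expect_false("flat" %in% pf$kept)
  expect_true("b" %in% pf$kept)
  expect_false(anyNA(pf$features$b))
  expect_equal(pf$features$b[1], stats::median(X$b, na.rm = TRUE))

  # exactly 20% missing is retained (strict inequality)
  Y <- data.frame(c = c(rep(NA, 4), rnorm(16)))
  expect_true("c" %in% prefilter(Y)$kept)
  expect_error(prefilter(data.frame(flat = rep(1, 10))), "every feature")
})

test_that("parallel analysis and PCA grouping recover planted factors", {
  set.seed(21)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(sapply(1:5, function(i) 0.9 * f1 + sqrt(1 - 0.81) * rnorm(n)),
             sapply(1:5, function(i) 0.9 * f2 + sqrt(1 - 0.81) * rnorm(n)))
  colnames(X) <- sprintf("v%d", 1:10)
  k <- horn_parallel(X, seed = 1)
  expect_identical(k, 2L)
  expect_identical(horn_parallel(X, seed = 1), k)   # same seed, same k

  grp <- pca_group(X, k)
  expect_length(unique(grp$groups[1:5]), 1L)
  expect_length(unique(grp$groups[6:10]), 1L)
  expect_false(grp$groups[1] == grp$groups[6])

  # duplicated column lands in the same group
  Xd <- cbind(X, v11 = X[, 1])
  gd <- pca_group(Xd, 2)
  expect_equal(unname(gd$groups["v11"]), unname(gd$groups["v1"]))

  one <- pca_group(X, 1)
  expect_true(all(one$groups == 1L))
  expect_error(pca_group(X[, 1:2], 5), "rank")
})

test_that("iid-noise eigenvalues retain no component under the p95 criterion", {
  keep0 <- vapply(1:50, function(s) {
    set.seed(3000 + s)
    horn_parallel(matrix(rnorm(1000), 100, 10), seed = s,
                  criterion = "p95")
  }, 0L)
  expect_gte(mean(keep0 == 0L), 0.9)
})

test_that("Cox fitting flags degenerate inputs and estimates the null near zero", {
  set.seed(22)
  x <- rnorm(500)
  s <- simulate_survival(rep(0, 500), censor_rate = 0.2, seed = 9)
  f <- cox_fit(matrix(x, ncol = 1), s$time, s$event)
  expect_true(f$ok)
  expect_lt(abs(f$coef[1]), 0.2)
  expect_error(cox_fit(matrix(x, ncol = 1), s$time, rep(0, 500)), "no events")
  expect_error(cox_fit(matrix(1, 500, 1), s$time, s$event), "zero-variance")
})

test_that("Harrell's c matches enumeration, symmetry and survival::concordance", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  # permissible pairs: (1,2)+, (1,3)+, (2,3)-
  expect_equal(harrell_c(c(3, 1, 2), c(1, 2, 3), c(1, 1, 0)), 2 / 3)
  expect_true(is.na(harrell_c(c(1, 2), c(5, 5), c(0, 0))))

  set.seed(23)
  lp <- rnorm(150)
  s <- simulate_survival(lp, censor_rate = 0.3, seed = 10)
  mine <- harrell_c(lp, s$time, s$event)
  ref <- survival::concordance(survival::Surv(s$time, s$event) ~ lp,
                               reverse = TRUE)$concordance
  expect_equal(mine, ref, tolerance = 1e-12)
  # event-complete data: reversing the predictor mirrors c around 1/2
  s2 <- simulate_survival(lp, censor_rate = 0, seed = 11)
  expect_equal(harrell_c(-lp, s2$time, s2$event),
               1 - harrell_c(lp, s2$time, s2$event))

  lp_null <- rnorm(1000)
  s3 <- simulate_survival(rep(0, 1000), censor_rate = 0.2, seed = 12)
  c0 <- harrell_c(lp_null, s3$time, s3$event)
  expect_gt(c0, 0.45); expect_lt(c0, 0.55)
})

test_that("the univariable screen reports BH q-values matching brute force", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04, 0.8), "BH"),
               c(0.04, 0.04, 0.0533333333333333, 0.8))
  set.seed(24)
  for (r in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }

  s <- simulate_survival(rnorm(60), censor_rate = 0.2, seed = 13)
  X <- data.frame(f1 = rnorm(60), check.names = FALSE)
  X$f2 <- X$f1
  sc <- univariable_screen(X, s$time, s$event)
  expect_equal(sc$p[1], sc$p[2])
  expect_equal(sc$cindex[1], sc$cindex[2])
})

test_that("per-group selection applies the FDR gate before the c-index race", {
  screen <- data.frame(feature = c("good", "lucky"),
                       coef = c(1, 1), cindex = c(0.70, 0.75),
                       p = c(0.001, 0.2), q = c(0.01, 0.40))
  groups <- c(good = 1L, lucky = 1L)
  expect_identical(select_per_group(screen, groups, 0.25), "good")

  screen$q <- c(0.9, 0.9)
  expect_length(select_per_group(screen, groups, 0.25), 0)

  screen3 <- data.frame(feature = c("a", "b", "c"), coef = 1,
                        cindex = c(0.7, 0.68, 0.66), p = 0.001, q = 0.01)
  groups3 <- c(a = 1L, b = 2L, c = 3L)
  expect_identical(sort(select_per_group(screen3, groups3, 0.25)),
                   c("a", "b", "c"))
})

test_that("backward AIC selection drops redundant and noise covariates", {
  set.seed(25)
  n <- 300
  signal <- rnorm(n)
  s <- simulate_survival(1.2 * signal, censor_rate = 0.2, seed = 14)
  one <- backward_aic(data.frame(signal = signal), s$time, s$event)
  expect_identical(one$selected, "signal")

  dup <- backward_aic(data.frame(signal = signal, copy = signal),
                      s$time, s$event)
  expect_length(dup$selected, 1L)

  dropped <- vapply(1:50, function(r) {
    set.seed(4000 + r)
    sig <- rnorm(n)
    ss <- simulate_survival(1.2 * sig, censor_rate = 0.2, seed = 4000 + r)
    fit <- backward_aic(data.frame(signal = sig, noise = rnorm(n)),
                        ss$time, ss$event)
    !("noise" %in% fit$selected)
  }, TRUE)
  expect_gte(mean(dropped), 0.8)
})

test_that("cross-validated concordance is seeded and calibrated", {
  set.seed(26)
  n <- 200
  x <- rnorm(n)
  s <- simulate_survival(3 * x, censor_rate = 0.1, seed = 15)
  cv1 <- cv_cindex(data.frame(x = x), s$time, s$event, "x", seed = 5,
                   n_boot = 200)
  cv2 <- cv_cindex(data.frame(x = x), s$time, s$event, "x", seed = 5,
                   n_boot = 200)
  expect_identical(cv1, cv2)
  expect_gt(cv1$mean_c, 0.8)
  expect_true(cv1$ci[1] <= cv1$mean_c && cv1$mean_c <= cv1$ci[2])

  s0 <- simulate_survival(rep(0, n), censor_rate = 0.1, seed = 16)
  cv0 <- cv_cindex(data.frame(x = rnorm(n)), s0$time, s0$event, "x",
                   seed = 6, n_boot = 200)
  expect_gt(cv0$mean_c, 0.45); expect_lt(cv0$mean_c, 0.55)
})

test_that("risk splitting freezes the training threshold", {
  rs <- risk_split(1:10, percentile = 80)
  expect_equal(rs$threshold, 8.2)
  expect_identical(sum(rs$group == "high"), 2L)

  set.seed(27)
  lp36 <- rnorm(36)
  rs36 <- risk_split(lp36, percentile = 80)
  expect_identical(sum(rs36$group == "high"), 7L)

  shifted <- risk_split(lp36 + 2, threshold = rs36$threshold)
  expect_gt(sum(shifted$group == "high"), 7L)  # frozen threshold, new mix

  deg <- risk_split(rep(1, 5), percentile = 80)
  expect_true(deg$degenerate)
})

test_that("the G-rho test matches a textbook log-rank computation and has power", {
  t6 <- c(1, 3, 4, 5, 7, 9); e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- c(1, 2, 1, 2, 1, 2)
  mine <- grho_test(t6, e6, g6, rho = 0)
  ref <- oracle_logrank(t6, e6, g6)
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-10)
  expect_equal(mine$p, ref$p, tolerance = 1e-10)
  expect_error(grho_test(t6, e6, rep(1, 6)), "two non-empty")

  sig <- vapply(1:50, function(r) {
    grp <- rep(c(0, 1), each = 50)
    s <- simulate_survival(log(3) * grp, censor_rate = 0.2, seed = 5000 + r)
    grho_test(s$time, s$event, grp)$p < 0.05
  }, TRUE)
  expect_gte(mean(sig), 0.8)
})

test_that("KM medians follow the step function and the exponential closed form", {
  expect_equal(km_median(1:5, rep(1, 5)), 3)
  expect_true(is.na(km_median(1:5, rep(0, 5))))
  set.seed(28)
  t <- rexp(1000, rate = 0.1)
  expect_lt(abs(km_median(t, rep(1, 1000)) - log(2) / 0.1) / (log(2) / 0.1),
            0.1)
})

test_that("scalar baselines recover the design effect and stay null otherwise", {
  co <- simulate_cohort(400, 1, seed = 31, render = FALSE)
  half <- 1:200
  bs <- baseline_scalar_model(co$h[half], co$outcomes$time_months[half],
                              co$outcomes$event[half],
                              co$h[-half], co$outcomes$time_months[-half],
                              co$outcomes$event[-half], n_boot = 200,
                              seed = 2)
  expect_gt(bs$train$c, 0.65)
  expect_gt(bs$valid$c, 0.6)

  set.seed(29)
  null_bs <- baseline_scalar_model(rnorm(400), co$outcomes$time_months,
                                   co$outcomes$event, n_boot = 200, seed = 3)
  expect_gt(null_bs$train$c, 0.45); expect_lt(null_bs$train$c, 0.55)
})
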