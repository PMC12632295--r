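test_that("the days-gained fold change is a plain survival ratio", {
  expect_equal(dgfc(400, 400), 1)
  expect_equal(dgfc(800, 400), 2)
  expect_lt(dgfc(300, 400), 1)
  expect_equal(dgfc(c(100, 300), c(50, 100)), c(2, 3))
  expect_error(dgfc(0, 100))
  expect_error(dgfc(100, -1))
})

test_that("the product-limit curve matches a hand calculation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_surv_at(km, c(0.5, 1, 1.9, 2.5, 10)),
               c(1, 2 / 3, 2 / 3, 1 / 3, 0))

  # all censored: the curve never drops
  km0 <- kaplan_meier(c(4, 7, 9), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # without censoring the estimator is the empirical survival function
  set.seed(3)
  x <- sample(1:20, 12, replace = TRUE)
  km1 <- kaplan_meier(x, rep(1, 12))
  for (t in km1$time)
    expect_equal(km_surv_at(km1, t), mean(x > t))

  # randomised censored samples against the independent implementation
  for (k in 1:10) {
    time <- sample(1:15, 20, replace = TRUE)
    event <- runif(20) < 0.7
    if (!any(event)) event[1] <- TRUE
    km <- kaplan_meier(time, event)
    hk <- hand_km(time, event)
    expect_equal(km_surv_at(km, hk$time), hk$surv)
  }
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("median survival reads off the curve", {
  expect_equal(km_median(kaplan_meier(c(1, 2, 3, 4), rep(1, 4))), 2)
  expect_equal(km_median(kaplan_meier(c(5, 6), c(0, 0))), Inf)
})

test_that("the log-rank test handles degenerate and identical arms", {
  lr <- logrank_test(c(5, 8, 10), c(1, 1, 0), c(5, 8, 10), c(1, 1, 0))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # no events anywhere
  lr0 <- logrank_test(c(5, 8), c(0, 0), c(7, 9), c(0, 0))
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "empty")
})

test_that("the log-rank test is calibrated and powerful", {
  set.seed(8)
  # type I error under a shared survival law
  p_null <- replicate(800, {
    a <- rexp(20, 1 / 200); b <- rexp(20, 1 / 200)
    logrank_test(a, rep(1, 20), b, rep(1, 20))$p
  })
  expect_gt(mean(p_null < 0.05), 0.03)
  expect_lt(mean(p_null < 0.05), 0.075)
  # power against a fourfold difference in mean survival
  p_alt <- replicate(300, {
    a <- rexp(20, 1 / 100); b <- rexp(20, 1 / 400)
    logrank_test(a, rep(1, 20), b, rep(1, 20))$p
  })
  expect_gt(mean(p_alt < 0.05), 0.9)
})

test_that("trials are reproducible and honest at zero dose", {
  rng <- parameter_ranges()
  a <- run_virtual_trial(rng, n_patients = 6, seed = 12, t_max = 1500)
  b <- run_virtual_trial(rng, n_patients = 6, seed = 12, t_max = 1500)
  expect_equal(a$outcomes, b$outcomes)
  expect_equal(a$p, b$p)
  z <- run_virtual_trial(rng, n_patients = 6, dose_m0 = 0, seed = 12,
                         t_max = 1500)
  # identical parameters in both arms: only death noise differs
  expect_false(z$success)
  expect_true(z$p > 0.05 || z$medians["continuous"] < z$medians["ctrl"])
})

test_that("trial series checkpoint and resume deterministically", {
  rng <- parameter_ranges()
  dir <- file.path(tempdir(), "ckpt-test")
  unlink(dir, recursive = TRUE)
  s1 <- run_trial_series(rng, n_trials = 2, n_patients = 4, seed = 7,
                         t_max = 1200, checkpoint_dir = dir)
  expect_equal(nrow(s1), 2)
  expect_true(file.exists(file.path(dir, "trial_001.csv")))
  # drop one checkpoint and resume: identical table
  unlink(file.path(dir, "trial_002.csv"))
  s2 <- run_trial_series(rng, n_trials = 2, n_patients = 4, seed = 7,
                         t_max = 1200, checkpoint_dir = dir)
  expect_equal(s2$p, s1$p)
  expect_equal(s2$success, s1$success)
})

test_that("cohort stratification splits ranges at their midpoints", {
  rng <- parameter_ranges()
  co <- stratify_cohorts(rng)
  expect_named(co, c("insensitive_slow", "insensitive_fast",
                     "sensitive_slow", "sensitive_fast", "unstratified"))
  get <- function(tab, p) unlist(tab[tab$parameter == p,
                                     c("lower", "upper")])
  expect_equal(unname(get(co$insensitive_slow, "ms")), c(10, 50))
  expect_equal(unname(get(co$sensitive_fast, "ms")), c(50, 90))
  expect_equal(unname(get(co$insensitive_slow, "psi")), c(0, 0.1))
  expect_equal(unname(get(co$sensitive_fast, "psi")), c(0.1, 0.2))
  # halves cover the full range
  expect_equal(get(co$insensitive_slow, "ms")[["upper"]],
               get(co$insensitive_fast, "ms")[["lower"]])
  # other parameters untouched
  expect_equal(get(co$sensitive_fast, "eta"), get(rng, "eta"))
})

test_that("standardised regression recovers constructed coefficients", {
  set.seed(15)
  X <- as.data.frame(matrix(runif(200 * 5), 200, 5))
  names(X) <- paste0("x", 1:5)
  # a constant response carries no sensitivity signal (perfect-fit
  # warnings from the underlying lm summary are expected)
  g0 <- suppressWarnings(gsa_regression(X, rep(2, 200)))
  expect_true(all(abs(g0$slope) < 1e-10))
  expect_false(any(g0$significant))
  # an exact linear dependence: standardised slope = 3 sd(x3)
  y <- 3 * X$x3
  g <- suppressWarnings(gsa_regression(X, y))
  expect_equal(g$slope[1], 3 * sd(X$x3), tolerance = 1e-10)
  expect_equal(g$parameter[1], "x3")
  expect_true(g$significant[1])
  expect_error(gsa_regression(X[1:4, ], y[1:4]), "more observations")
})

test_that("partial regression obeys the Frisch-Waugh-Lovell identity", {
  set.seed(19)
  X <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
  names(X) <- paste0("x", 1:5)
  y <- 2 * X$x1 - 1.5 * X$x4 + rnorm(200, sd = 0.3)
  for (j in list(1, 4, "x2")) {
    pr <- partial_regression(X, y, j)
    expect_equal(pr$slope, pr$full_coef, tolerance = 1e-10)
  }
  # a predictor unrelated to the response has a near-zero residual slope
  expect_lt(abs(partial_regression(X, y, "x3")$slope), 0.1)
  # exact dependence gives residual slope one
  expect_equal(partial_regression(X, X$x2, "x2")$slope, 1,
               tolerance = 1e-10)
})

test_that("responder groups split on the stated thresholds", {
  pts <- data.frame(psi = c(0.2, 0.01), ms = c(80, 20))
  rs <- responder_split(pts, c(1.3, 1.05))
  expect_equal(length(rs$good), 1)
  expect_equal(length(rs$poor), 1)
  expect_warning(responder_split(pts, c(1.0, 1.0))$skipped,
                 "empty responder group")
  # the in-between band is excluded
  pts3 <- data.frame(psi = 1:3 / 10, ms = 1:3)
  rs3 <- responder_split(pts3, c(1.15, 1.3, 1.05))
  expect_equal(rs3$good, 2L)
  expect_equal(rs3$poor, 3L)
})
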