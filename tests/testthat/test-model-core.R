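test_that("hierarchy rates reduce to known limits", {
  hp <- hierarchy_params(ms = 0.3, mis = 2, n = 10, psmax = 1, psmin = 0)
  r1 <- c(1, rep(0, 9))
  st <- tumor_state(s = 0.2, v = rep(0, 10))

  # pure self-renewal with no death: logistic growth of the stem pool
  d <- hierarchy_rhs(st, hp, Ps = 1, r = r1)
  expect_equal(d$ds, 0.3 * 0.2 * (1 - 0.2))
  expect_equal(d$dv, rep(0, 10))

  # balanced self-renewal: the stem pool neither grows nor shrinks
  d <- hierarchy_rhs(st, hp, Ps = 0.5, r = r1)
  expect_equal(d$ds, 0)

  # at carrying capacity all proliferation stops; only death remains
  hp2 <- hierarchy_params(ms = 0.3, mis = 2, delta_s = 0.01, delta_is = 2,
                          delta_ns = 3, n = 10, psmax = 1, psmin = 0)
  stK <- tumor_state(s = 0.4, v = c(rep(0.05, 9), 0.15))
  expect_equal(total_density(stK), 1)
  d <- hierarchy_rhs(stK, hp2, Ps = 0.7, r = r1)
  expect_equal(d$ds, -0.01 * 0.4)
  expect_equal(d$dv[1:9], rep(-0.02 * 0.05, 9))
  expect_equal(d$dv[10], -0.06 * 0.15)
})

test_that("hierarchy rates validate their inputs", {
  hp <- hierarchy_params(ms = 0.3, n = 10)
  st <- tumor_state(s = 0.1, v = rep(0, 10))
  expect_error(hierarchy_rhs(st, hp, Ps = 1, r = rep(0.2, 10)), "sum 1")
  expect_error(hierarchy_rhs(st, hp, Ps = 1.2, r = c(1, rep(0, 9))),
               "Ps")
  expect_error(hierarchy_rhs(st, hp, Ps = 1, r = c(1, rep(0, 8))),
               "length")
})

test_that("the reference rates and the compiled integrator agree", {
  # one implicit Euler step of the compiled system must match the R rates;
  # checked through a very short integration with tiny step
  set.seed(11)
  for (k in 1:20) {
    hp <- hierarchy_params(ms = runif(1, 0.05, 0.5), mis = runif(1, 0, 4),
                           delta_s = runif(1, 0, 0.01),
                           delta_is = runif(1, 0, 10),
                           delta_ns = runif(1, 0, 5), n = 10,
                           psmax = runif(1, 0.5, 1),
                           psmin = runif(1, 0, 0.4))
    rp <- response_params(runif(1, 0, 0.2), runif(1, 0, 0.1))
    B <- runif(1, 0, 50)
    st <- tumor_state(s = runif(1, 0, 0.2), v = runif(10, 0, 0.05),
                      B = B, m = 0)
    Ps <- self_renewal_probability(B, rp, hp$psmin, hp$psmax)
    r <- compartment_distribution(B, rp$phi, hp$n)
    ref <- hierarchy_rhs(st, hp, Ps, r)
    h <- 1e-6
    tr <- simulate_tumor(st, hp, times = c(0, h), rp = rp, hold_b = TRUE)
    num_ds <- (tr$s[2] - tr$s[1]) / h
    num_dv <- (as.numeric(tr[2, paste0("v", 1:10)]) -
                 as.numeric(tr[1, paste0("v", 1:10)])) / h
    expect_equal(num_ds, ref$ds, tolerance = 1e-4)
    expect_equal(num_dv, ref$dv, tolerance = 1e-4)
  }
})

test_that("single-population growth matches the logistic closed form", {
  hp <- hierarchy_params(ms = 0.3, n = 10, psmax = 1, psmin = 1)
  st <- tumor_state(s = 1e-4, v = rep(0, 10))
  tr <- simulate_tumor(st, hp, times = seq(0, 60, 1), ps_fixed = 1,
                       hold_b = TRUE, rtol = 1e-10, atol = 1e-12)
  expected <- logistic_n(tr$t, 1e-4, 0.3)
  expect_lt(max(abs(tr$N - expected) / expected), 1e-6)
})

test_that("the all-zero state is a fixed point", {
  hp <- hierarchy_params(ms = 0.4, mis = 2, n = 10)
  st <- tumor_state(s = 0, v = rep(0, 10))
  tr <- simulate_tumor(st, hp, times = seq(0, 50, 5))
  expect_true(all(tr$N == 0))
  expect_true(all(tr$s == 0))
})

test_that("splitting an integration at an event time is consistent", {
  hp <- hierarchy_params(ms = 0.2, mis = 2, n = 10, psmax = 0.55,
                         psmin = 0.2)
  dp <- delivery_params()
  rp <- response_params(0.05, 0.05)
  st <- tumor_state(s = 1e-4, v = rep(0, 10), B = 5, m = 2)
  whole <- simulate_tumor(st, hp, 0:100, dp = dp, rp = rp)
  first <- simulate_tumor(st, hp, 0:37, dp = dp, rp = rp)
  second <- simulate_tumor(state_at(first, 37), hp, 37:100, dp = dp,
                           rp = rp)
  i <- whole$t >= 37
  expect_lt(max(abs(whole$N[i] - second$N) / pmax(second$N, 1e-12)), 1e-8)
})

test_that("densities stay non-negative and bounded from random draws", {
  set.seed(202)
  for (k in 1:100) {
    hp <- hierarchy_params(ms = runif(1, 0.02, 0.6), mis = runif(1, 0, 5),
                           delta_s = 0, n = 10,
                           psmax = runif(1, 0.5, 1),
                           psmin = runif(1, 0.1, 0.4))
    rp <- response_params(runif(1, 0, 0.2), runif(1, 0, 0.1))
    st <- tumor_state(s = runif(1, 1e-5, 0.3), v = runif(10, 0, 0.05),
                      B = runif(1, 0, 100), m = 0)
    tr <- simulate_tumor(st, hp, times = seq(st$t, st$t + 150, 10),
                         rp = rp, hold_b = TRUE)
    expect_true(all(as.matrix(tr[, -1]) >= 0))
    # with no death, total density cannot overshoot capacity
    expect_lte(max(tr$N), max(total_density(st), hp$K) + 1e-6)
  }
})

test_that("total density sums stem and progenitor compartments", {
  st <- tumor_state(s = 0.1, v = c(0.05, rep(0, 9)))
  expect_equal(total_density(st), 0.15)
  expect_equal(total_density(tumor_state(s = 0, v = rep(0, 10))), 0)
})

test_that("states and trajectories validate and export", {
  expect_error(tumor_state(s = -0.1, v = rep(0, 10)), "negative")
  expect_error(tumor_state(s = Inf, v = rep(0, 10)), "finite")
  hp <- hierarchy_params(ms = 0.3, n = 10)
  tr <- simulate_tumor(tumor_state(s = 0.01, v = rep(0, 10)), hp, 0:5)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("t", "s", paste0("v", 1:10), "B", "m", "N"))
  expect_equal(back$N, tr$N)
})
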