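test_that("delivery kinetics follow the stated linear system", {
  dp <- delivery_params(delta_m = 0.5, delta_b = 0.5, c_rel = 0.3,
                        u_b = 0.2)
  d <- bmp4_rhs(m = 2, B = 10, s = 0.1, dp, infusion = 1)
  expect_equal(d$dm, 1 - 0.5 * 2)
  expect_equal(d$dB, 0.3 * 2 - 0.2 * 10 * 0.1 - 0.5 * 10)

  # pure decay without source or uptake
  hp <- hierarchy_params(ms = 0.1, n = 10)
  st <- tumor_state(s = 0, v = rep(0, 10), B = 8, m = 0)
  tr <- simulate_tumor(st, hp, times = 0:6, dp = dp)
  expect_equal(tr$B, 8 * exp(-0.5 * tr$t), tolerance = 1e-6)

  # bolus of carriers: release peaks at 48 h when both decay rates are
  # 0.5/day (the equal-rate limit of ln(db/dm)/(db - dm))
  st <- tumor_state(s = 0, v = rep(0, 10), B = 0, m = 1)
  tr <- simulate_tumor(st, hp, times = seq(0, 10, 0.05),
                       dp = delivery_params())
  expect_equal(tr$t[which.max(tr$B)], 2, tolerance = 0.03)

  # constant infusion equilibrates carriers at rate / decay
  sched <- data.frame(time = 0, kind = "infusion_start", magnitude = 3)
  tr <- simulate_tumor(tumor_state(s = 0, v = rep(0, 10)), hp,
                       times = seq(0, 60, 5), dp = dp, schedule = sched)
  expect_equal(tr$m[nrow(tr)], 3 / 0.5, tolerance = 1e-4)
})

test_that("self-renewal probability responds to BMP4 as specified", {
  rp <- response_params(0.01, 0)
  expect_equal(self_renewal_probability(0, rp, 0.2, 0.6), 0.6)
  expect_equal(self_renewal_probability(100, response_params(0, 0),
                                        0.2, 0.6), 0.6)
  # psi * B = 1 halves the responsive span
  expect_equal(self_renewal_probability(100, rp, 0.2, 0.6), 0.4)

  # non-increasing in concentration and in sensitivity, bounded
  B <- seq(0, 500, 25)
  for (psi in c(0, 0.01, 0.1, 0.3)) {
    ps <- self_renewal_probability(B, response_params(psi, 0), 0.2, 0.6)
    expect_true(all(diff(ps) <= 1e-12))
    expect_true(all(ps >= 0.2 - 1e-12 & ps <= 0.6 + 1e-12))
  }
  for (b in c(10, 100)) {
    ps <- vapply(c(0, 0.01, 0.1, 0.3), function(psi)
      self_renewal_probability(b, response_params(psi, 0), 0.2, 0.6),
      numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("the triangle weight follows its piecewise definition", {
  expect_equal(triangle_weight(0), 1)
  expect_equal(triangle_weight(-1), 0)
  expect_equal(triangle_weight(1), 0)
  expect_equal(triangle_weight(0.5), 0.5)
  expect_equal(triangle_weight(-0.25), 0.75)
  expect_equal(triangle_weight(c(-2, 2)), c(0, 0))
})

test_that("differentiation distribution reproduces the worked peaks", {
  # no BMP4: perfectly hierarchical differentiation into compartment 1
  expect_equal(compartment_distribution(0, 0.05, 10),
               c(1, rep(0, 9)))
  # in-text worked examples at 100 ng/mL
  expect_equal(which.max(compartment_distribution(100, 0.0494, 10)), 6)
  expect_equal(which.max(compartment_distribution(100, 0.0787, 10)), 9)
  expect_error(compartment_distribution(10, 0.05, 0), "n must")
})

test_that("differentiation distribution is a two-point probability vector", {
  set.seed(5)
  for (k in 1:50) {
    B <- runif(1, 0, 300)
    phi <- runif(1, 0, 0.12)
    r <- compartment_distribution(B, phi, 10)
    expect_equal(sum(r), 1)
    expect_true(all(r >= 0))
    theta <- 1 + phi * B
    if (theta <= 10) expect_lte(sum(r > 1e-12), 2)
  }
  # centre beyond the terminal compartment: everything goes to TDCs
  expect_equal(compartment_distribution(300, 0.1, 10),
               c(rep(0, 9), 1))
})

test_that("linear-quadratic survival matches its closed form", {
  expect_equal(rt_survival_fraction(0, 0.3), 1)
  expect_equal(rt_survival_fraction(2, 0.3, 1), exp(-0.72))
  # radioprotection strictly increases survival
  expect_gt(rt_survival_fraction(2, 0.3, 0.1376),
            rt_survival_fraction(2, 0.3, 1))
  expect_error(rt_survival_fraction(-1, 0.3), "negative dose")
})

test_that("a radiotherapy fraction acts per compartment", {
  rtp <- rt_params(0.2, eta = 0.1376, mu = 0.5)
  st <- tumor_state(s = 0.1, v = c(1, rep(0.02, 8), 0.3), B = 3, m = 1)

  expect_equal(apply_rt_fraction(st, rtp, 0)$v, st$v)

  post <- apply_rt_fraction(st, rtp, 2)
  expect_equal(post$v[1], exp(-0.48), tolerance = 1e-12)
  expect_equal(post$s, 0.1 * exp(-0.1376 * 0.48))
  expect_equal(post$v[10], 0.3 * exp(-0.5 * 0.48))
  expect_equal(post$B, 3)
  expect_equal(post$m, 1)

  # protected stem cells enrich after irradiation
  expect_gt(post$s / total_density(post), st$s / total_density(st))

  # linearity: the operator commutes with uniform scaling
  half <- tumor_state(s = st$s / 2, v = st$v / 2, B = st$B, m = st$m)
  post_half <- apply_rt_fraction(half, rtp, 2)
  expect_equal(post_half$s * 2, post$s)
  expect_equal(post_half$v * 2, post$v)

  # two fractions multiply: gamma(d)^2 per compartment
  twice <- apply_rt_fraction(post, rtp, 2)
  expect_equal(twice$v[1], exp(-0.48)^2, tolerance = 1e-12)
  expect_equal(twice$s, 0.1 * exp(-0.1376 * 0.48)^2)
})

test_that("resection removes a fixed fraction of every compartment", {
  st <- tumor_state(s = 0.3, v = c(0.4, rep(0.02, 8), 0.14), B = 2, m = 5)
  post <- apply_resection(st)
  expect_equal(total_density(post), total_density(st) * (1 - 0.917))
  expect_equal(post$s / total_density(post), st$s / total_density(st))
  expect_equal(post$B, 2)
  expect_equal(post$m, 5)
  zero <- tumor_state(s = 0, v = rep(0, 10))
  expect_equal(total_density(apply_resection(zero)), 0)
  expect_error(apply_resection(st, extent = 1), "extent")
  expect_error(apply_resection(st, extent = -0.1), "extent")
})

test_that("standard of care delivers 60 Gy in 30 fractions over six weeks", {
  for (td in c(0, 57, 400)) {
    sch <- standard_of_care_schedule(td, "ctrl")
    rt <- sch[sch$kind == "rt_fraction", ]
    expect_equal(nrow(rt), 30)
    expect_equal(sum(rt$magnitude), 60)
    expect_equal(min(rt$time), td + 30)
    expect_equal(max(rt$time), td + 69)
    # five on, two off: no weekend fractions
    expect_true(all(((rt$time - td - 30) %% 7) <= 4))
    expect_equal(sch$time[sch$kind == "resection"], td)
  }
  expect_error(standard_of_care_schedule(10, "weekly"), "arg")
})

test_that("both delivery arms administer the same total carrier amount", {
  single <- standard_of_care_schedule(50, "single", dose_m0 = 120)
  expect_equal(single$magnitude[single$kind == "bmp4_bolus"], 120)
  cont <- standard_of_care_schedule(50, "continuous", dose_m0 = 120)
  rate <- cont$magnitude[cont$kind == "infusion_start"]
  dur <- cont$time[cont$kind == "infusion_stop"] -
    cont$time[cont$kind == "infusion_start"]
  expect_equal(rate * dur, 120)
})

test_that("schedules round-trip through JSON", {
  sch <- standard_of_care_schedule(30, "continuous", dose_m0 = 10)
  path <- tempfile(fileext = ".json")
  schedule_to_json(sch, path)
  back <- schedule_from_json(path)
  expect_equal(back$time, sch$time)
  expect_equal(back$kind, sch$kind)
  expect_equal(back$magnitude, sch$magnitude)
})
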