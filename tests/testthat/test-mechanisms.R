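test_that("one-step closed form matches direct ODE integration", {
  set.seed(101)
  for (i in 1:6) {
    kapp <- 10^runif(1, 3, 6)
    p0 <- 10^runif(1, -7.5, -5.5)
    s0 <- 10^runif(1, -7.5, -5.5)
    t_scale <- 1 / (kapp * max(p0, s0))
    times <- seq(0, 5 * t_scale, length.out = 100)
    tr <- simulate_model1(rate_parameters_model1(kapp), p0, s0, times)
    ps_oracle <- ode_oracle_model1(kapp, p0, s0, times)
    expect_lt(max(abs(tr$species[, "PS"] - ps_oracle)) / min(p0, s0), 1e-6)
  }
})

test_that("one-step trajectory starts at the initial condition", {
  tr <- simulate_model1(rate_parameters_model1(1e5), 2e-6, 1e-6, c(0, 1))
  expect_equal(unname(tr$species[1, ]), c(2e-6, 1e-6, 0))
})

test_that("equal-concentration branch agrees with the ODE oracle", {
  times <- seq(0, 10, length.out = 50)
  tr <- simulate_model1(rate_parameters_model1(1e5), 1e-6, 1e-6, times)
  # second-order equal-concentration law at t = 10 s: k t C^2/(1 + k t C)
  expect_equal(tr$species[times == 10, "PS"], 0.5e-6, tolerance = 1e-9,
               ignore_attr = TRUE)
  ps_oracle <- ode_oracle_model1(1e5, 1e-6, 1e-6, times, dt = 1e-3)
  expect_lt(max(abs(tr$species[, "PS"] - ps_oracle)) / 1e-6, 1e-6)
})

test_that("half-labeling time under substrate excess follows ln2/(kapp S)", {
  # 1 uM substrate in excess, kapp = 1e5: protein half-labeled near 6.93 s
  times <- seq(0, 30, length.out = 3001)
  tr <- simulate_model1(rate_parameters_model1(1e5), 1e-8, 1e-6, times)
  frac <- tr$species[, "PS"] / 1e-8
  t_half <- stats::approx(frac, times, xout = 0.5)$y
  expect_equal(t_half, log(2) / (1e5 * 1e-6), tolerance = 0.01)
})

test_that("invalid one-step inputs are rejected", {
  expect_error(simulate_model1(rate_parameters_model1(1e5), 0, 1e-6, 0:1),
               class = "slpkin_config_error")
  expect_error(rate_parameters_model1(-1), class = "slpkin_config_error")
  expect_error(rate_parameters_model1(Inf), class = "slpkin_config_error")
})

test_that("two-step mechanism conserves mass and accumulates product", {
  set.seed(202)
  for (i in 1:5) {
    k1 <- 10^runif(1, 5, 8)
    km1 <- 10^runif(1, -1, 2)
    k2 <- 10^runif(1, -1, 1.5)
    p0 <- 10^runif(1, -7, -6)
    s0 <- 10^runif(1, -7, -6)
    times <- log_spaced_times(1e-4, 50, 80)
    tr <- simulate_model2(rate_parameters_model2(k1, km1, k2), p0, s0, times)
    sp <- tr$species
    expect_true(all(sp >= 0))
    expect_lt(max(abs(sp[, "P"] + sp[, "PSi"] + sp[, "PS"] - p0)) / p0, 1e-9)
    expect_lt(max(abs(sp[, "S"] + sp[, "PSi"] + sp[, "PS"] - s0)) / s0, 1e-9)
    expect_true(all(diff(sp[, "PS"]) >= 0))
  }
})

test_that("two-step limits: no covalent step and no association", {
  # k2 -> 0 is outside the constructor's domain, so take k2 tiny instead:
  # the complex relaxes to the reversible binding equilibrium set by Kd
  k1 <- 1e6; km1 <- 100; kd <- km1 / k1
  p0 <- s0 <- 1e-6
  tr <- simulate_model2(rate_parameters_model2(k1, km1, 1e-12), p0, s0,
                        c(0, 0.5, 5))
  # analytic equilibrium complex for P0 = S0: quadratic in [PS*]
  b <- 2 * p0 + kd
  c_eq <- (b - sqrt(b^2 - 4 * p0^2)) / 2
  expect_equal(tr$species[3, "PSi"], c_eq, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(tr$species[3, "PS"], 1e-9 * s0)

  # k1 -> 0: nothing happens on any accessible timescale
  tr0 <- simulate_model2(rate_parameters_model2(1e-12, km1, 10), p0, s0,
                         c(0, 10))
  expect_equal(unname(tr0$species[2, c("P", "S")]), c(p0, s0),
               tolerance = 1e-9)
})

test_that("two-step mechanism at low concentration reduces to one step", {
  params <- rate_parameters_model2(1e6, 100, 10)  # Kd = 100 uM
  kapp <- kapp_from_rates(params)
  expect_equal(kapp, 1e6 * 10 / 110)
  p0 <- s0 <- 1e-9  # Kd / 1e5
  times <- log_spaced_times(0.1, 2e4, 60)
  t2 <- simulate_model2(params, p0, s0, times, atol = 1e-18)
  t1 <- simulate_model1(rate_parameters_model1(kapp), p0, s0, times)
  ps2 <- t2$species[, "PS"] + t2$species[, "PSi"]
  ps1 <- t1$species[, "PS"]
  sel <- ps1 > 1e-3 * s0
  expect_lt(max(abs(ps2[sel] - ps1[sel]) / ps1[sel]), 0.01)
})

test_that("derived Kd and kapp behave as required", {
  expect_equal(kd_from_rates(rate_parameters_model2(1e6, 1, 10)), 1e-6)
  expect_equal(kd_from_rates(rate_parameters_model2(50, 50, 1)), 1)
  rl <- live580_rates()
  expect_equal(kd_from_rates(do.call(rate_parameters_model2, rl)), 9.99e-9)
  expect_equal(kapp_from_rates(do.call(rate_parameters_model2, rl)), 1.39e8)

  # symmetric case k_minus1 = k2 gives k1/2; k2 >> k_minus1 approaches k1
  expect_equal(kapp_from_rates(rate_parameters_model2(1e8, 100, 100)), 5e7)
  expect_equal(kapp_from_rates(rate_parameters_model2(1e8, 1e-5, 100)), 1e8,
               tolerance = 1e-6)
  # kapp <= k1, increasing in k2, decreasing in k_minus1
  set.seed(33)
  for (i in 1:10) {
    k1 <- 10^runif(1, 4, 8); km1 <- 10^runif(1, -2, 3); k2 <- 10^runif(1, -2, 3)
    ka <- kapp_from_rates(rate_parameters_model2(k1, km1, k2))
    expect_lte(ka, k1)
    expect_gt(kapp_from_rates(rate_parameters_model2(k1, km1, k2 * 2)), ka)
    expect_lt(kapp_from_rates(rate_parameters_model2(k1, km1 * 2, k2)), ka)
  }
})

test_that("aging mechanism matches its ODE oracle and degenerate limits", {
  kapp <- 1e5; k3 <- 1e-2; p0 <- 900e-9; s0 <- 20e-9
  times <- seq(0, 600, length.out = 61)
  tr <- simulate_aging(rate_parameters_aging(kapp, k3), p0, s0, times,
                       atol = 1e-16)
  oracle <- ode_oracle_aging(kapp, k3, p0, s0, times, dt = 0.05)
  expect_lt(max(abs(tr$species[, "PSa"] - oracle[, "psa"])) / s0, 1e-5)
  expect_lt(max(abs(tr$species[, "PSb"] - oracle[, "psb"])) / s0, 1e-5)
  # labeled pool nondecreasing; mass conserved
  lab <- tr$species[, "PSa"] + tr$species[, "PSb"]
  expect_true(all(diff(lab) >= 0))
  expect_lt(max(abs(tr$species[, "S"] + lab - s0)) / s0, 1e-9)

  # near-zero aging reproduces the one-step product in state A only
  tr0 <- simulate_aging(rate_parameters_aging(kapp, 1e-15), p0, s0, times,
                        atol = 1e-16)
  m1 <- simulate_model1(rate_parameters_model1(kapp), p0, s0, times)
  expect_equal(tr0$species[, "PSa"], m1$species[, "PS"], tolerance = 1e-6)
  expect_lt(max(tr0$species[, "PSb"]), 1e-9 * s0)

  # the aged state absorbs everything at long times
  tr_inf <- simulate_aging(rate_parameters_aging(kapp, 1e-2), p0, s0,
                           c(0, 5e4))
  expect_equal(tr_inf$species[2, "PSb"], s0, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_lt(tr_inf$species[2, "PSa"], 1e-4 * s0)
})

test_that("competition mechanism reduces, is symmetric, and matches oracle", {
  ks <- 2.57e4; ki <- 1.53e3
  p0 <- 200e-9; s0 <- 50e-9; i0 <- 1e-6
  times <- seq(0, 1200, length.out = 25)

  # no competitor: identical to the one-step mechanism
  tr0 <- simulate_competition(rate_parameters_competition(ks, ki), p0, s0,
                              0, times)
  m1 <- simulate_model1(rate_parameters_model1(ks), p0, s0, times)
  expect_equal(tr0$species[, "PS"], m1$species[, "PS"])
  expect_true(all(tr0$species[, "PI"] == 0))

  # equal rates and totals: PS(t) = PI(t)
  tr_sym <- simulate_competition(rate_parameters_competition(ks, ks), p0,
                                 s0, s0, times)
  expect_equal(tr_sym$species[, "PS"], tr_sym$species[, "PI"],
               tolerance = 1e-9)

  # fine-step oracle agreement on the final product split
  tr <- simulate_competition(rate_parameters_competition(ks, ki), p0, s0,
                             i0, times)
  oracle <- ode_oracle_competition(ks, ki, p0, s0, i0, times, dt = 0.02)
  n <- length(times)
  expect_lt(abs(tr$species[n, "PS"] - oracle[n, "ps"]) / oracle[n, "ps"], 1e-3)
  expect_lt(abs(tr$species[n, "PI"] - oracle[n, "pi"]) / oracle[n, "pi"], 1e-3)
  # the protein pool is never oversubscribed
  expect_true(all(tr$species[, "PS"] + tr$species[, "PI"] <= p0 * (1 + 1e-9)))
})

test_that("mass conservation holds across mechanisms and random inputs", {
  set.seed(404)
  for (i in 1:5) {
    p0 <- 10^runif(1, -7, -5); s0 <- 10^runif(1, -8, -6)
    times <- seq(0, 10^runif(1, 1, 3), length.out = 40)
    ka <- 10^runif(1, 3, 5)
    tr <- simulate_competition(
      rate_parameters_competition(ka, 10^runif(1, 3, 5)), p0, s0,
      10^runif(1, -7, -6), times)
    sp <- tr$species
    expect_lt(max(abs(sp[, "P"] + sp[, "PS"] + sp[, "PI"] - p0)) / p0, 1e-9)
    expect_lt(max(abs(sp[, "S"] + sp[, "PS"] - s0)) / s0, 1e-9)
    expect_true(all(diff(sp[, "PS"]) >= 0))
  }
})
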