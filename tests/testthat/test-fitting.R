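make_model1_traces <- function(kapp = 2.5e4, noise_sd = 0,
                               proteins = c(0.5e-6, 2e-6, 10e-6),
                               s0 = 50e-9, seed = 1, n_points = 61,
                               t_end = 1200) {
  des <- experiment_design(
    "model1", list(kapp = kapp), proteins, s0,
    response = signal_response(r_free = 0.05, r_bound = 0.30),
    time_grid = list(from = 0, to = t_end, n = n_points, spacing = "linear"),
    replicates = 1, noise_sd = noise_sd, signal_type = "fp", seed = seed)
  generate_kinetic_dataset(des)$traces
}

test_that("noiseless one-step traces are recovered to tight tolerance", {
  traces <- make_model1_traces(kapp = 2.5e4, noise_sd = 0)
  fit <- fit_global(traces, "model1", fixed = list(r_free = 0.05),
                    n_starts = 2)
  expect_lt(abs(fit$estimates["kapp"] - 2.5e4) / 2.5e4, 1e-4)
  expect_lt(abs(fit$estimates["r_bound"] - 0.30) / 0.30, 1e-4)
  expect_lt(fit$rss, 1e-12)
})

test_that("global fits are invariant to trace order and signal scaling", {
  traces <- make_model1_traces(noise_sd = 0.004, seed = 8)
  fit_fwd <- fit_global(traces, "model1", fixed = list(r_free = 0.05),
                        n_starts = 1)
  fit_rev <- fit_global(rev(traces), "model1", fixed = list(r_free = 0.05),
                        n_starts = 1)
  expect_equal(fit_fwd$estimates["kapp"], fit_rev$estimates["kapp"],
               tolerance = 1e-8)
  # mP-vs-fraction scaling: scale signals and responses by 1000
  scaled <- lapply(traces, function(tr) { tr$signal <- tr$signal * 1000; tr })
  fit_mp <- fit_global(scaled, "model1", fixed = list(r_free = 50),
                       n_starts = 1)
  expect_equal(fit_mp$estimates["kapp"], fit_fwd$estimates["kapp"],
               tolerance = 1e-6)
  expect_equal(fit_mp$estimates["r_bound"],
               1000 * fit_fwd$estimates["r_bound"], tolerance = 1e-6)
})

test_that("fitting the substrate scale absorbs quantification error", {
  # traces generated with 20% less substrate than the nominal 50 nM;
  # protein-limited conditions make the scale identifiable
  des <- experiment_design(
    "model1", list(kapp = 4.29e5),
    protein_totals = c(15e-9, 60e-9, 250e-9, 900e-9),
    substrate_totals = 40e-9,
    response = signal_response(r_free = 0.05, r_bound = 0.30),
    time_grid = list(from = 0, to = 1800, n = 81, spacing = "linear"),
    replicates = 1, noise_sd = 0, signal_type = "fp", seed = 3)
  traces <- generate_kinetic_dataset(des)$traces
  mislabeled <- lapply(traces, function(tr) {
    tr$substrate_total <- 50e-9
    tr
  })
  fit <- fit_global(mislabeled, "model1", fixed = list(r_free = 0.05),
                    fit_substrate_scale = TRUE, n_starts = 2)
  expect_equal(unname(fit$estimates["s_scale"]), 0.8, tolerance = 1e-3)
  expect_lt(abs(fit$estimates["kapp"] - 4.29e5) / 4.29e5, 1e-3)
})

test_that("competition fits recover the competitor rate constant", {
  des <- experiment_design(
    "competition", list(kapp_S = 2.57e4, kapp_I = 2.57e4),
    protein_totals = rep(200e-9, 4), substrate_totals = 50e-9,
    competitor_totals = c(0, 0.1e-6, 0.4e-6, 1e-6),
    response = signal_response(r_free = 0.05, r_bound = 0.30),
    time_grid = list(from = 0, to = 2400, n = 81, spacing = "linear"),
    replicates = 1, noise_sd = 0.002, signal_type = "fp", seed = 12)
  traces <- generate_kinetic_dataset(des)$traces
  fit <- fit_competition(traces, kapp_S = 2.57e4,
                         fixed = list(r_free = 0.05), n_starts = 2)
  # identical substrate and competitor chemistry: ratio comes back ~1
  expect_lt(abs(fit$estimates["kapp_I"] / 2.57e4 - 1), 0.05)

  # the zero-competitor trace is explained exactly as a one-step fit
  zero_idx <- which(vapply(traces, function(tr) tr$competitor_total == 0,
                           logical(1)))
  m1 <- fit_global(traces[zero_idx], "model1",
                   free = list(kapp = 2.57e4),
                   fixed = list(r_free = 0.05), n_starts = 1)
  expect_equal(sum(fit$residuals[[zero_idx]]^2), sum(m1$residuals[[1]]^2),
               tolerance = 0.05)
})

test_that("Monte Carlo intervals are deterministic and ordered", {
  traces <- make_model1_traces(noise_sd = 0.004, seed = 21, n_points = 41)
  fit <- fit_global(traces, "model1", fixed = list(r_free = 0.05),
                    n_starts = 1)
  mc1 <- monte_carlo_ci(fit, n_iterations = 60, seed = 99)
  mc2 <- monte_carlo_ci(fit, n_iterations = 60, seed = 99)
  expect_identical(mc1$ci, mc2$ci)
  expect_true(all(mc1$ci[, "lower"] < mc1$ci[, "upper"]))
  # point estimates inside their intervals
  expect_true(all(mc1$ci[, "lower"] <= fit$estimates &
                  fit$estimates <= mc1$ci[, "upper"]))
  # samples honor the discard rule
  expect_equal(mc1$mc$n_kept, 60 - floor(0.05 * 60))
})

test_that("Monte Carlo intervals collapse on noise-free data", {
  traces <- make_model1_traces(noise_sd = 0, n_points = 31)
  fit <- fit_global(traces, "model1", fixed = list(r_free = 0.05),
                    n_starts = 1)
  mc <- monte_carlo_ci(fit, n_iterations = 30, seed = 5)
  expect_lt(diff(mc$ci["kapp", ]) / fit$estimates["kapp"], 1e-6)
})

test_that("dead-time estimation recovers a truncated exponential", {
  k <- 100; dead_true <- 3e-3
  t_obs <- seq(0, 0.05, length.out = 200)
  set.seed(31)
  amp0 <- 1
  y <- amp0 * exp(-k * (t_obs + dead_true)) + rnorm(200, sd = 0.01)
  tr <- kinetic_trace(t_obs + dead_true, pmax(y, 1e-6), 1e-6, 1e-6)
  est <- estimate_dead_time(tr, expected_amplitude = amp0)
  expect_lt(abs(est - dead_true) / dead_true, 0.10)

  # full-amplitude trace: dead time zero
  y0 <- amp0 * exp(-k * t_obs)
  tr0 <- kinetic_trace(t_obs, pmax(y0, 1e-9), 1e-6, 1e-6)
  expect_lt(estimate_dead_time(tr0, expected_amplitude = amp0), 1e-4)

  # without the expected amplitude the offset is unidentifiable
  expect_error(estimate_dead_time(tr), class = "slpkin_config_error")
  # a non-exponential trace fails the fit-quality gate
  y_bad <- exp(-60 * t_obs) + 0.35 * sin(300 * t_obs) * exp(-10 * t_obs)
  bad <- kinetic_trace(t_obs, y_bad, 1e-6, 1e-6)
  expect_error(estimate_dead_time(bad, expected_amplitude = 1),
               class = "slpkin_numeric_error")
})

test_that("log-log correlation handles exact and degenerate input", {
  ka <- 10^seq(4, 8, length.out = 6)
  kapp <- 10^(1.042 * log10(ka) + 1.544)
  # noiseless input: lm warns about the exact fit, which is the point here
  res <- suppressWarnings(loglog_correlation(kapp, ka))
  expect_equal(res$slope, 1.042, tolerance = 1e-10)
  expect_equal(res$intercept, 1.544, tolerance = 1e-10)
  expect_true(all(res$bands$lower <= res$bands$fit &
                  res$bands$fit <= res$bands$upper))
  expect_error(loglog_correlation(c(1, 2), c(1, 2)),
               class = "slpkin_config_error")
  expect_error(loglog_correlation(c(1, -2, 3), c(1, 2, 3)),
               class = "slpkin_config_error")
})

test_that("log-log confidence bands cover the true line at nominal rate", {
  set.seed(77)
  slope <- 1.0; intercept <- -0.74
  n_rep <- 200
  x <- seq(3, 7, length.out = 8)
  x_test <- 5
  covered <- vapply(seq_len(n_rep), function(i) {
    y <- intercept + slope * x + rnorm(8, sd = 0.3)
    res <- loglog_correlation(10^y, 10^x)
    truth <- intercept + slope * x_test
    idx <- which.min(abs(res$bands$log_ka - x_test))
    res$bands$lower[idx] <= truth && truth <= res$bands$upper[idx]
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("model comparison flags the biphasic misfit of the one-step model", {
  # Kd = 1 uM, slow covalent step: saturating traces are clearly biphasic
  rl <- list(k1 = 1e6, k_minus1 = 1, k2 = 0.05)
  des <- stopped_flow_design(rl, concs = c(2e-6, 5e-6, 10e-6),
                             seed = 61, noise_sd = 0.002, n_points = 200,
                             t_end = 200, dead_time = 0)
  traces <- generate_kinetic_dataset(des)$traces
  f1 <- fit_global(traces, "model1", fixed = list(r_free = 0.05), n_starts = 2)
  f2 <- fit_global(traces, "model2",
                   free = c("k1", "k_minus1", "r_bound"),
                   fixed = list(k2 = 0.05, r_free = 0.05), n_starts = 2)
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$preferred, "b")
  expect_gt(cmp$rss_ratio, 1)
  expect_lt(cmp$runs_test$p_value, 0.01)

  # data genuinely generated by the one-step mechanism: model 1 keeps up
  traces1 <- make_model1_traces(noise_sd = 0.003, seed = 62)
  g1 <- fit_global(traces1, "model1", fixed = list(r_free = 0.05), n_starts = 1)
  g2 <- fit_global(traces1, "model2",
                   free = c("k1", "k_minus1", "r_bound"),
                   fixed = list(k2 = 10, r_free = 0.05), n_starts = 1)
  cmp1 <- compare_models(g1, g2)
  expect_true(cmp1$preferred %in% c("a", "either"))

  # identical fits give a zero criterion difference
  cmp_same <- compare_models(g1, g1)
  expect_equal(cmp_same$delta_aicc, 0)
  expect_error(compare_models(f1, g1), class = "slpkin_config_error")
})

test_that("one-step fits of saturating two-step data overestimate the rate", {
  rl <- rate_parameters_model2(1e6, 1, 0.02)  # Kd = 1 uM, kapp ~ 1.96e4
  kapp_true <- kapp_from_rates(rl)
  times <- log_spaced_times(0.01, 400, 80)
  n_over <- 0L
  n_sim <- 20L
  for (s in seq_len(n_sim)) {
    set.seed(600 + s)
    traces <- lapply(c(20e-6, 50e-6), function(c0) {
      traj <- simulate_model2(rl, c0, c0, times)
      tr <- project_signal(traj, signal_response(0.05, 0.25),
                           signal_type = "anisotropy")
      tr$signal <- tr$signal + rnorm(length(tr$signal), sd = 0.002)
      tr
    })
    f1 <- fit_global(traces, "model1", fixed = list(r_free = 0.05),
                     n_starts = 1)
    if (f1$estimates["kapp"] > kapp_true) n_over <- n_over + 1L
  }
  expect_gte(n_over / n_sim, 0.95)
})

test_that("ill-identified two-step fits raise the conditioning flag", {
  # concentrations far below Kd: k1 and k_minus1 only enter through their
  # ratio, so the covariance conditioning explodes
  rl <- rate_parameters_model2(1e6, 100, 10)  # Kd = 100 uM
  times <- log_spaced_times(1, 2e4, 60)
  traces <- lapply(c(0.5e-9, 1e-9), function(c0) {
    traj <- simulate_model2(rl, c0, c0, times, atol = 1e-18)
    project_signal(traj, signal_response(0.05, 0.25),
                   signal_type = "anisotropy")
  })
  fit <- fit_global(traces, "model2", free = c("k1", "k_minus1", "r_bound"),
                    fixed = list(k2 = 10, r_free = 0.05), n_starts = 1,
                    condition_threshold = 1e5)
  expect_true(fit$identifiability$flag)
  expect_gt(fit$identifiability$condition_number, 1e5)
  # a well-posed design at comparable scale stays below the same threshold
  well <- make_model1_traces(noise_sd = 0.002, seed = 63)
  fit_ok <- fit_global(well, "model1", fixed = list(r_free = 0.05),
                       n_starts = 1, condition_threshold = 1e5)
  expect_false(fit_ok$identifiability$flag)
})
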