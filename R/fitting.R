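# Global nonlinear least-squares estimation of labeling kinetics across
# multi-concentration trace sets. Rate constants are optimized on the
# log10 scale (positivity by construction); signal-response parameters on
# the linear scale. Levenberg-Marquardt via minpack.lm::nls.lm with
# log-uniform multi-start.

mechanism_rate_names <- function(mechanism) {
  switch(mechanism,
    model1      = "kapp",
    model2      = c("k1", "k_minus1", "k2"),
    aging       = c("kapp", "k3"),
    competition = c("kapp_S", "kapp_I"),
    stop_config("unknown mechanism: ", mechanism))
}

response_param_names <- c("r_free", "r_bound", "r_bound_b", "offset")
log_scale_params <- c("k1", "k_minus1", "k2", "kapp", "kapp_S", "kapp_I",
                      "k3", "s_scale")

# Model signal for one trace under a full named parameter vector.
predict_trace_signal <- function(mechanism, pars, trace,
                                 rtol = 1e-8, atol = 1e-12) {
  t_rxn <- trace$times - pars[["delay"]]
  if (any(t_rxn < 0)) stop_config("trace contains points before the delay")
  s_tot <- trace$substrate_total * pars[["s_scale"]]
  p0 <- trace$protein_total
  r_free <- pars[["r_free"]]; r_bound <- pars[["r_bound"]]
  off <- pars[["offset"]]
  if (mechanism == "model1") {
    ps <- bimolecular_product(pars[["kapp"]], p0, s_tot, t_rxn)
    return(off + (r_free * (s_tot - ps) + r_bound * ps) / s_tot)
  }
  if (mechanism == "competition" && trace$competitor_total == 0) {
    ps <- bimolecular_product(pars[["kapp_S"]], p0, s_tot, t_rxn)
    return(off + (r_free * (s_tot - ps) + r_bound * ps) / s_tot)
  }
  traj <- switch(mechanism,
    model2 = simulate_model2(
      rate_parameters_model2(pars[["k1"]], pars[["k_minus1"]], pars[["k2"]]),
      p0, s_tot, t_rxn, rtol = rtol, atol = atol),
    aging = simulate_aging(
      rate_parameters_aging(pars[["kapp"]], pars[["k3"]]),
      p0, s_tot, t_rxn, rtol = rtol, atol = atol),
    competition = simulate_competition(
      rate_parameters_competition(pars[["kapp_S"]], pars[["kapp_I"]]),
      p0, s_tot, trace$competitor_total, t_rxn, rtol = rtol, atol = atol))
  sp <- traj$species
  bound <- switch(mechanism,
    model2 = r_bound * (sp[, "PSi"] + sp[, "PS"]),
    aging = r_bound * sp[, "PSa"] + pars[["r_bound_b"]] * sp[, "PSb"],
    competition = r_bound * sp[, "PS"])
  off + (r_free * sp[, "S"] + bound) / s_tot
}

# Half-rise heuristic for an apparent bimolecular rate constant.
guess_kapp <- function(traces) {
  est <- vapply(traces, function(tr) {
    sig <- tr$signal
    half <- (sig[1] + sig[length(sig)]) / 2
    rising <- sig[length(sig)] >= sig[1]
    idx <- if (rising) which(sig >= half) else which(sig <= half)
    t_half <- if (length(idx)) tr$times[idx[1]] else max(tr$times)
    excess <- max(tr$protein_total, tr$substrate_total)
    log(2) / (max(t_half, min(diff(tr$times))) * excess)
  }, numeric(1))
  stats::median(est)
}

default_param_setup <- function(mechanism, traces, free, fixed,
                                fit_substrate_scale) {
  rates <- mechanism_rate_names(mechanism)
  init <- list()
  kapp0 <- guess_kapp(traces)
  init$kapp <- kapp0
  init$kapp_S <- kapp0
  init$kapp_I <- kapp0
  init$k2 <- fixed$k2 %||% 10
  init$k_minus1 <- init$k2
  init$k1 <- 2 * kapp0
  init$k3 <- 3e-3
  init$r_bound <- max(vapply(traces, function(tr) max(tr$signal), numeric(1)))
  init$r_free <- min(vapply(traces, function(tr) tr$signal[1], numeric(1)))
  init$r_bound_b <- init$r_bound
  init$offset <- 0
  init$s_scale <- 1
  # default free set: mechanism rates plus the bound-state response
  if (is.null(free)) {
    free <- c(setdiff(rates, names(fixed)), "r_bound")
  }
  if (is.character(free)) {
    free <- stats::setNames(vector("list", length(free)), free)
  }
  free_names <- names(free)
  if (!length(free_names)) stop_config("at least one free parameter required")
  if (fit_substrate_scale && !("s_scale" %in% c(free_names, names(fixed)))) {
    free$s_scale <- 1
    free_names <- names(free)
  }
  bad <- intersect(free_names, c("dead_time", "delay"))
  if (length(bad)) stop_config("dead_time/delay are fixed instrument parameters")
  # fill unspecified inits
  for (nm in free_names) {
    if (is.null(free[[nm]])) free[[nm]] <- init[[nm]]
    if (is.null(free[[nm]])) stop_config("no initial value for parameter ", nm)
  }
  fixed_full <- fixed
  for (nm in c(rates, response_param_names, "s_scale")) {
    if (!nm %in% free_names && is.null(fixed_full[[nm]])) {
      if (nm == "r_free") stop_config("r_free must be free or fixed explicitly")
      if (nm %in% rates) stop_config("rate parameter ", nm, " must be free or fixed")
      fixed_full[[nm]] <- if (nm == "r_bound_b") NA_real_ else init[[nm]]
    }
  }
  fixed_full$dead_time <- fixed$dead_time %||% 0
  fixed_full$delay <- fixed$delay %||% 0
  list(free = free, fixed = fixed_full)
}

assemble_pars <- function(theta, free_names, fixed) {
  pars <- fixed
  for (i in seq_along(free_names)) {
    nm <- free_names[i]
    pars[[nm]] <- if (nm %in% log_scale_params) 10^theta[i] else theta[i]
  }
  if (is.null(pars$s_scale)) pars$s_scale <- 1
  if (is.na(pars$r_bound_b %||% NA_real_)) pars$r_bound_b <- pars$r_bound
  pars
}

to_theta <- function(values, free_names) {
  vapply(seq_along(free_names), function(i) {
    v <- values[[free_names[i]]]
    if (free_names[i] %in% log_scale_params) log10(v) else v
  }, numeric(1))
}

#' Global fit of a labeling mechanism to a set of kinetic traces
#'
#' Minimizes the summed squared difference between projected model signals
#' and every trace simultaneously, sharing the kinetic constants and the
#' bound-state signal response across traces (the noncovalent complex and
#' covalent product share one response). Rate constants are optimized on
#' the log10 scale so positivity is structural; fits are restarted from
#' `n_starts` log-uniform perturbations of the data-driven initial guess
#' and the lowest-RSS converged solution wins.
#'
#' @param traces List of [kinetic_trace()] objects sharing a signal type.
#' @param mechanism One of `"model1"`, `"model2"`, `"aging"`,
#'   `"competition"`.
#' @param free Free parameters: a character vector of names (initial
#'   values chosen from the data) or a named list of initial values.
#'   Defaults to the mechanism's rate constants plus `r_bound`.
#' @param fixed Named list of fixed parameters. `r_free` (free-dye
#'   baseline) must appear here or in `free`; `offset`, `dead_time`,
#'   `delay` default to 0. For `"competition"`, fix `kapp_S` from a prior
#'   direct fit. Fixing `k2` is the usual remedy when two-step parameters
#'   are not separable.
#' @param fit_substrate_scale If `TRUE`, one shared substrate-concentration
#'   scale factor (`s_scale`) is fitted across traces to absorb probe
#'   quantification error; identifiable only when some traces are
#'   protein-limited.
#' @param n_starts Number of multi-start optimizations (default 5).
#' @param seed Seed for the multi-start perturbations (default 1).
#' @param rtol,atol ODE solver tolerances for mechanisms without closed
#'   forms.
#' @param condition_threshold Condition number of the parameter covariance
#'   above which the fit is flagged structurally ill-identified.
#' @return An object of class `slp_fit`: `estimates` (natural scale),
#'   `sd`, `ci` (95%, linearized until [monte_carlo_ci()] replaces them),
#'   `rss`, `residuals` (per trace), `convergence`, `identifiability`,
#'   plus the data and configuration needed to resume (for Monte Carlo).
#' @export
fit_global <- function(traces, mechanism = c("model1", "model2", "aging",
                                             "competition"),
                       free = NULL, fixed = list(),
                       fit_substrate_scale = FALSE, n_starts = 5, seed = 1,
                       rtol = 1e-8, atol = 1e-12,
                       condition_threshold = 1e6) {
  mechanism <- match.arg(mechanism)
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  if (!length(traces) || !all(vapply(traces, inherits, logical(1), "kinetic_trace"))) {
    stop_config("traces must be a list of kinetic_trace objects")
  }
  st <- unique(vapply(traces, function(tr) tr$signal_type, character(1)))
  if (length(st) != 1L) stop_config("all traces must share one signal_type")
  setup <- default_param_setup(mechanism, traces, free, fixed,
                               fit_substrate_scale)
  free_names <- names(setup$free)
  fixed_full <- setup$fixed
  theta0 <- to_theta(setup$free, free_names)

  residual_fun <- function(theta) {
    pars <- assemble_pars(theta, free_names, fixed_full)
    unlist(lapply(traces, function(tr) {
      predict_trace_signal(mechanism, pars, tr, rtol, atol) - tr$signal
    }), use.names = FALSE)
  }

  starts <- list(theta0)
  if (n_starts > 1) {
    seeds <- child_seeds(seed, n_starts - 1)
    amp <- diff(range(unlist(lapply(traces, `[[`, "signal"))))
    for (i in seq_len(n_starts - 1)) {
      set.seed(seeds[i])
      th <- theta0
      for (j in seq_along(free_names)) {
        th[j] <- if (free_names[j] %in% log_scale_params) {
          th[j] + stats::runif(1, -1, 1)
        } else {
          th[j] + stats::runif(1, -0.2, 0.2) * max(amp, abs(th[j]))
        }
      }
      starts[[i + 1]] <- th
    }
  }

  best <- NULL
  n_fail <- 0L
  for (th in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = th, fn = residual_fun,
      control = minpack.lm::nls.lm.control(maxiter = 150)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$deviance)) {
      n_fail <- n_fail + 1L
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop_numeric("fit did not converge from any start (", n_fail, " failures)")
  }

  pars_hat <- assemble_pars(best$par, free_names, fixed_full)
  estimates <- stats::setNames(
    vapply(free_names, function(nm) pars_hat[[nm]], numeric(1)), free_names)

  n_obs <- sum(vapply(traces, function(tr) length(tr$signal), integer(1)))
  p <- length(free_names)
  sigma2 <- best$deviance / max(n_obs - p, 1L)
  cov_theta <- try(sigma2 * chol2inv(chol(best$hessian)), silent = TRUE)
  ident <- list(condition_number = NA_real_, flag = FALSE)
  if (inherits(cov_theta, "try-error")) {
    sd_theta <- rep(NA_real_, p)
    ident$flag <- TRUE
  } else {
    sd_theta <- sqrt(pmax(diag(cov_theta), 0))
    ev <- eigen(best$hessian, symmetric = TRUE, only.values = TRUE)$values
    ident$condition_number <- max(ev) / max(min(ev), .Machine$double.eps)
    ident$flag <- ident$condition_number > condition_threshold
  }
  # delta method back to natural scale for log-parameters
  sd_nat <- vapply(seq_len(p), function(i) {
    if (free_names[i] %in% log_scale_params) {
      estimates[i] * log(10) * sd_theta[i]
    } else sd_theta[i]
  }, numeric(1))
  names(sd_nat) <- free_names
  ci <- cbind(lower = estimates - 1.96 * sd_nat,
              upper = estimates + 1.96 * sd_nat)

  res_by_trace <- split(
    best$fvec,
    rep(seq_along(traces), vapply(traces, function(tr) length(tr$signal), integer(1))))

  structure(
    list(mechanism = mechanism, estimates = estimates, sd = sd_nat, ci = ci,
         rss = best$deviance, convergence = list(info = best$info,
                                                 message = best$message,
                                                 n_failed_starts = n_fail),
         residuals = res_by_trace, identifiability = ident,
         free_names = free_names, fixed = fixed_full, traces = traces,
         fitted = lapply(seq_along(traces), function(i) {
           traces[[i]]$signal + res_by_trace[[i]]
         }),
         options = list(n_starts = n_starts, seed = seed, rtol = rtol,
                        atol = atol,
                        condition_threshold = condition_threshold),
         mc = NULL),
    class = "slp_fit")
}

#' @export
coef.slp_fit <- function(object, ...) object$estimates

#' @export
print.slp_fit <- function(x, ...) {
  cat(sprintf("<slp_fit> mechanism %s, %d traces, RSS = %.4g\n",
              x$mechanism, length(x$traces), x$rss))
  tab <- data.frame(estimate = x$estimates, sd = x$sd,
                    ci_lower = x$ci[, "lower"], ci_upper = x$ci[, "upper"])
  print(signif(tab, 4))
  if (!is.null(x$mc)) cat(sprintf("  (uncertainty from %d Monte Carlo refits)\n", x$mc$n_kept))
  if (isTRUE(x$identifiability$flag)) {
    cat("  warning: parameters ill-identified (covariance condition number ",
        format(x$identifiability$condition_number, digits = 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Derived quantities of a fitted two-step mechanism
#'
#' For a `"model2"` fit, returns `kd = k_minus1 / k1` and
#' `kapp = k1 k2 / (k_minus1 + k2)` at the point estimates.
#'
#' @param fit An `slp_fit`.
#' @return Named numeric vector with `kd` (molar) and `kapp` (M^-1 s^-1),
#'   or an empty vector for other mechanisms.
#' @export
derived_rates <- function(fit) {
  stopifnot(inherits(fit, "slp_fit"))
  if (fit$mechanism != "model2") return(stats::setNames(numeric(0), character(0)))
  pars <- assemble_pars(to_theta(as.list(fit$estimates), fit$free_names),
                        fit$free_names, fit$fixed)
  rp <- rate_parameters_model2(pars$k1, pars$k_minus1, pars$k2)
  c(kd = kd_from_rates(rp), kapp = kapp_from_rates(rp))
}

#' Fit competitor labeling kinetics against a fixed probe rate
#'
#' Convenience wrapper for the kinetic competition mechanism: the probe's
#' rate constant `kapp_S` is fixed from a prior direct fit, and the
#' competitor's `kapp_I` is estimated globally across the competitor
#' concentration series (including any zero-competitor traces).
#'
#' @param traces List of [kinetic_trace()] objects with varying
#'   `competitor_total`.
#' @param kapp_S Fixed probe rate constant, M^-1 s^-1.
#' @param ... Passed to [fit_global()] (e.g. `fixed`, `free`, `n_starts`).
#' @return An `slp_fit` for the competition mechanism.
#' @export
fit_competition <- function(traces, kapp_S, ...) {
  check_scalar_positive(kapp_S, "kapp_S")
  args <- list(...)
  args$fixed <- c(list(kapp_S = kapp_S), args$fixed)
  do.call(fit_global, c(list(traces = traces, mechanism = "competition"), args))
}

#' Monte Carlo confidence intervals by parametric bootstrap
#'
#' DynaFit-style Monte Carlo uncertainty: `n_iterations` synthetic
#' datasets are simulated from the fitted model plus homoscedastic
#' Gaussian noise at each trace's residual standard deviation, each is
#' refit (single start from the point estimates), the `discard_fraction`
#' of refits with the highest RSS is discarded, and per-parameter
#' standard deviations and percentile 95% intervals are computed from the
#' kept parameter samples. Fully deterministic for a given `seed`.
#'
#' @param fit A converged [fit_global()] result.
#' @param n_iterations Number of bootstrap replicates (default 1000).
#' @param discard_fraction Fraction of worst refits (by RSS) to discard
#'   (default 0.05).
#' @param seed Integer seed; one seed fans out deterministically into
#'   per-iteration child seeds.
#' @return The `slp_fit` with `sd` and `ci` replaced by Monte Carlo
#'   estimates and an `mc` element holding the kept parameter samples.
#'   A warning is raised when more than 20% of refits fail.
#' @export
monte_carlo_ci <- function(fit, n_iterations = 1000, discard_fraction = 0.05,
                           seed = 1) {
  stopifnot(inherits(fit, "slp_fit"))
  if (n_iterations < 10) stop_config("n_iterations must be at least 10")
  traces <- fit$traces
  noise_sd <- vapply(fit$residuals, function(r) {
    sqrt(mean(r^2))
  }, numeric(1))
  theta_hat <- to_theta(as.list(fit$estimates), fit$free_names)
  seeds <- child_seeds(seed, n_iterations)
  p <- length(fit$free_names)
  samples <- matrix(NA_real_, n_iterations, p,
                    dimnames = list(NULL, fit$free_names))
  rss <- rep(NA_real_, n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(seeds[it])
    sim_traces <- lapply(seq_along(traces), function(i) {
      tr <- traces[[i]]
      tr$signal <- fit$fitted[[i]] + stats::rnorm(length(tr$signal),
                                                  sd = noise_sd[i])
      tr
    })
    residual_fun <- function(theta) {
      pars <- assemble_pars(theta, fit$free_names, fit$fixed)
      unlist(lapply(sim_traces, function(tr) {
        predict_trace_signal(fit$mechanism, pars, tr,
                             fit$options$rtol, fit$options$atol) - tr$signal
      }), use.names = FALSE)
    }
    refit <- try(minpack.lm::nls.lm(
      par = theta_hat, fn = residual_fun,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(refit, "try-error") || !is.finite(refit$deviance)) next
    pars <- assemble_pars(refit$par, fit$free_names, fit$fixed)
    samples[it, ] <- vapply(fit$free_names, function(nm) pars[[nm]], numeric(1))
    rss[it] <- refit$deviance
  }
  ok <- is.finite(rss)
  fail_rate <- 1 - mean(ok)
  if (fail_rate > 0.2) {
    warning(sprintf("Monte Carlo reliability warning: %.0f%% of refits failed",
                    100 * fail_rate))
  }
  samples <- samples[ok, , drop = FALSE]
  rss <- rss[ok]
  n_keep <- max(1L, nrow(samples) - floor(discard_fraction * nrow(samples)))
  keep <- order(rss)[seq_len(n_keep)]
  kept <- samples[keep, , drop = FALSE]
  mc_sd <- apply(kept, 2, stats::sd)
  mc_ci <- t(apply(kept, 2, stats::quantile, probs = c(0.025, 0.975),
                   names = FALSE))
  colnames(mc_ci) <- c("lower", "upper")
  fit$sd <- mc_sd
  fit$ci <- mc_ci
  fit$mc <- list(samples = kept, rss = rss[keep], n_requested = n_iterations,
                 n_kept = n_keep, fail_rate = fail_rate,
                 discard_fraction = discard_fraction, seed = seed,
                 noise_sd = noise_sd)
  fit
}

#' Estimate the stopped-flow dead time from a calibration decay
#'
#' Fits the first-order rate law `A exp(-k t)` to a pseudo-first-order
#' calibration decay recorded from the first observed point (t = 0 at the
#' first sample), then returns the time the reaction must already have
#' been running for the extrapolated amplitude to have decayed from the
#' known initial amplitude to the observed one:
#' `dead_time = log(expected_amplitude / A_fit) / k`.
#'
#' @param trace A [kinetic_trace()] holding the calibration decay.
#' @param expected_amplitude The true initial amplitude of the decay
#'   (e.g. from a premixed control). Without it the offset is structurally
#'   unidentifiable and an error is raised.
#' @param baseline Fixed signal floor of the decay (default 0).
#' @param min_r_squared Fit-quality gate; below it the trace is rejected
#'   as non-exponential (default 0.95).
#' @return Estimated dead time in seconds (>= 0), with attributes
#'   `rate` and `amplitude` of the fitted exponential.
#' @export
estimate_dead_time <- function(trace, expected_amplitude = NULL, baseline = 0,
                               min_r_squared = 0.95) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (is.null(expected_amplitude)) {
    stop_config("dead time is unidentifiable without the expected initial ",
                "amplitude of the calibration decay")
  }
  check_scalar_positive(expected_amplitude, "expected_amplitude")
  t_obs <- trace$times - trace$times[1]
  y <- trace$signal - baseline
  if (y[1] <= 0 || stats::cor(t_obs, y) > 0) {
    stop_numeric("trace is not a decaying signal")
  }
  pos <- y > 0
  k0 <- -stats::coef(stats::lm(log(y[pos]) ~ t_obs[pos]))[[2]]
  k0 <- max(k0, 1e-6)
  fit <- minpack.lm::nls.lm(
    par = c(log_a = log(max(y[1], 1e-12)), log_k = log(k0)),
    fn = function(th) exp(th[1]) * exp(-exp(th[2]) * t_obs) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  a <- exp(fit$par[[1]]); k <- exp(fit$par[[2]])
  r2 <- 1 - fit$deviance / sum((y - mean(y))^2)
  if (!is.finite(r2) || r2 < min_r_squared) {
    stop_numeric("calibration trace is not well described by a single ",
                 "exponential (R^2 = ", signif(r2, 3), ")")
  }
  if (a > expected_amplitude) {
    dead <- 0
  } else {
    dead <- log(expected_amplitude / a) / k
  }
  structure(dead, rate = k, amplitude = a)
}

#' Log-log regression of labeling rate against association constant
#'
#' Ordinary least squares of `log10(kapp)` on `log10(Ka)` with pointwise
#' 95% confidence bands for the regression line, quantifying how strongly
#' apparent labeling rate constants track equilibrium affinity across a
#' substrate panel.
#'
#' @param kapp_values Apparent rate constants, M^-1 s^-1, > 0.
#' @param ka_values Association constants (1/Kd), M^-1, > 0, same length.
#' @param conf_level Confidence level for the bands (default 0.95).
#' @param n_grid Number of grid points for the band evaluation.
#' @return A list with `slope`, `intercept`, `ci` (rows slope/intercept),
#'   `bands` (data frame `log_ka`, `fit`, `lower`, `upper`), `r_squared`,
#'   and the underlying `lm` fit.
#' @export
loglog_correlation <- function(kapp_values, ka_values, conf_level = 0.95,
                               n_grid = 100) {
  if (length(kapp_values) != length(ka_values)) stop_config("lengths differ")
  if (length(kapp_values) < 3L) stop_config("need at least 3 pairs")
  if (any(kapp_values <= 0) || any(ka_values <= 0)) {
    stop_config("values must be strictly positive")
  }
  d <- data.frame(x = log10(ka_values), y = log10(kapp_values))
  m <- stats::lm(y ~ x, data = d)
  grid <- data.frame(x = seq(min(d$x), max(d$x), length.out = n_grid))
  pred <- stats::predict(m, newdata = grid, interval = "confidence",
                         level = conf_level)
  ci <- stats::confint(m, level = conf_level)[c("x", "(Intercept)"), ]
  rownames(ci) <- c("slope", "intercept")
  list(slope = unname(stats::coef(m)["x"]),
       intercept = unname(stats::coef(m)["(Intercept)"]),
       ci = ci,
       bands = data.frame(log_ka = grid$x, fit = pred[, "fit"],
                          lower = pred[, "lwr"], upper = pred[, "upr"]),
       r_squared = summary(m)$r.squared,
       model = m)
}

# Wald-Wolfowitz runs test on residual signs, pooled across traces
# (runs never span trace boundaries). One-sided: few runs = systematic
# (e.g. biphasic) misfit.
residual_runs_test <- function(residual_list) {
  total_runs <- 0; e_runs <- 0; v_runs <- 0
  for (r in residual_list) {
    s <- sign(r); s <- s[s != 0]
    if (length(s) < 2) next
    n_pos <- sum(s > 0); n_neg <- sum(s < 0); n <- n_pos + n_neg
    if (n_pos == 0 || n_neg == 0) {
      total_runs <- total_runs + 1
      e_runs <- e_runs + 1
      next
    }
    total_runs <- total_runs + 1 + sum(diff(s) != 0)
    e_runs <- e_runs + 1 + 2 * n_pos * n_neg / n
    v_runs <- v_runs + (2 * n_pos * n_neg * (2 * n_pos * n_neg - n)) /
      (n^2 * (n - 1))
  }
  if (v_runs <= 0) return(list(z = NA_real_, p_value = NA_real_))
  z <- (total_runs - e_runs) / sqrt(v_runs)
  list(z = z, p_value = stats::pnorm(z), runs = total_runs,
       expected = e_runs)
}

#' Compare two mechanism fits on the same traces
#'
#' Advisory model comparison between nested labeling mechanisms fitted to
#' identical data: reports the RSS ratio, the small-sample-corrected
#' information criterion (AICc) difference, and a runs test on the
#' simpler model's residuals that is sensitive to the biphasic misfit
#' signature of a missing binding step.
#'
#' @param fit_a,fit_b Two `slp_fit` objects on the same traces;
#'   conventionally `fit_a` the simpler mechanism.
#' @param delta_threshold AICc difference below which the models are
#'   considered equivalent (default 2).
#' @return A list with `rss` (named pair), `rss_ratio` (a/b), `aicc`
#'   (named pair), `delta_aicc` (a - b), `runs_test` (on `fit_a`
#'   residuals), and `preferred` (`"a"`, `"b"`, or `"either"`).
#' @export
compare_models <- function(fit_a, fit_b, delta_threshold = 2) {
  stopifnot(inherits(fit_a, "slp_fit"), inherits(fit_b, "slp_fit"))
  same <- length(fit_a$traces) == length(fit_b$traces) &&
    all(vapply(seq_along(fit_a$traces), function(i) {
      identical(fit_a$traces[[i]]$times, fit_b$traces[[i]]$times) &&
        identical(fit_a$traces[[i]]$signal, fit_b$traces[[i]]$signal)
    }, logical(1)))
  if (!same) stop_config("fits must be on identical traces")
  n <- sum(vapply(fit_a$traces, function(tr) length(tr$signal), integer(1)))
  aicc <- function(fit) {
    k <- length(fit$free_names) + 1  # + residual variance
    n * log(fit$rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  a <- aicc(fit_a); b <- aicc(fit_b)
  delta <- a - b
  preferred <- if (abs(delta) <= delta_threshold) "either"
               else if (delta > 0) "b" else "a"
  list(rss = c(a = fit_a$rss, b = fit_b$rss),
       rss_ratio = fit_a$rss / fit_b$rss,
       aicc = c(a = a, b = b), delta_aicc = delta,
       runs_test = residual_runs_test(fit_a$residuals),
       preferred = preferred)
}
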