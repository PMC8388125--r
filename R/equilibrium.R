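# Equilibrium FP analysis: direct binding isotherms, competition curves,
# and the exact two-ligand/one-site mass-action equilibrium used to turn
# an I50 into a competitor Kd under ligand and protein depletion.

GAS_CONSTANT <- 8.31446261815324  # J mol^-1 K^-1

#' Single-site binding isotherm
#'
#' Hyperbolic one-site model for an FP titration of a fixed trace probe
#' against protein: `FP([P]) = FP_min + (FP_max - FP_min) [P] / (Kd + [P])`.
#' At zero protein the signal is `fp_min`, at saturation `fp_max`, and at
#' `[P] = Kd` exactly the midpoint.
#'
#' @param kd Dissociation constant, molar.
#' @param fp_min FP of the free fluorophore (lower plateau).
#' @param fp_max FP of the fully bound fluorophore (upper plateau).
#' @param protein_concentration Protein concentration(s), molar.
#' @return Predicted FP value(s).
#' @export
isotherm_predict <- function(kd, fp_min, fp_max, protein_concentration) {
  check_scalar_positive(kd, "kd")
  if (any(protein_concentration < 0)) stop_config("protein concentrations must be >= 0")
  fp_min + (fp_max - fp_min) * protein_concentration / (kd + protein_concentration)
}

#' Titration data for a direct binding isotherm
#'
#' @param protein_concentrations Molar, >= 0; at least 4 distinct values.
#' @param fp_values FP per observation (fractional units), same length as
#'   `protein_concentrations` (replicates appear as repeated
#'   concentrations).
#' @param probe_total Probe concentration, molar.
#' @param anchor_point Optional `list(concentration =, fp =)` pseudo-point
#'   pinning the upper plateau; typically the FP of the fully reacted dye
#'   assigned to a huge nominal protein concentration.
#' @return Object of class `isotherm_data`.
#' @export
isotherm_data <- function(protein_concentrations, fp_values, probe_total,
                          anchor_point = NULL) {
  if (length(protein_concentrations) != length(fp_values)) {
    stop_config("concentrations and fp_values must have equal length")
  }
  if (length(unique(protein_concentrations)) < 4L) {
    stop_config("need at least 4 distinct protein concentrations")
  }
  if (any(protein_concentrations < 0) || any(!is.finite(fp_values))) {
    stop_config("concentrations must be >= 0 and fp finite")
  }
  check_scalar_positive(probe_total, "probe_total")
  if (!is.null(anchor_point)) {
    stopifnot(is.list(anchor_point),
              all(c("concentration", "fp") %in% names(anchor_point)))
  }
  structure(list(protein_concentrations = as.numeric(protein_concentrations),
                 fp_values = as.numeric(fp_values),
                 probe_total = probe_total, anchor_point = anchor_point),
            class = "isotherm_data")
}

#' Fit the single-site isotherm to titration data
#'
#' Least-squares fit of [isotherm_predict()] with `Kd` optimized on the
#' log scale. Replicate FP values at the same concentration are averaged
#' before fitting; the optional anchor pseudo-point is appended as one
#' extra equally weighted observation to pin the upper plateau when the
#' titration cannot reach saturation.
#'
#' @param data An [isotherm_data()].
#' @param average_replicates Average replicate wells per concentration
#'   before fitting (default TRUE).
#' @return Object of class `isotherm_fit` with elements `kd`, `fp_min`,
#'   `fp_max`, `sd`, `ci` (95%, linearized), `rss`, `flags` (may contain
#'   `"flat_curve"` or `"upper_plateau_unidentifiable"`), `fitted`,
#'   `residuals`.
#' @export
fit_isotherm <- function(data, average_replicates = TRUE) {
  stopifnot(inherits(data, "isotherm_data"))
  conc <- data$protein_concentrations
  fp <- data$fp_values
  if (average_replicates) {
    agg <- tapply(fp, conc, mean)
    conc <- as.numeric(names(agg))
    fp <- as.numeric(agg)
    o <- order(conc); conc <- conc[o]; fp <- fp[o]
  }
  anchored <- !is.null(data$anchor_point)
  if (anchored) {
    conc <- c(conc, data$anchor_point$concentration)
    fp <- c(fp, data$anchor_point$fp)
  }
  flags <- character()
  amp <- diff(range(fp))
  noise_guess <- stats::mad(diff(fp)) / sqrt(2)
  if (amp < 4 * max(noise_guess, 1e-12) || amp == 0) {
    flags <- c(flags, "flat_curve")
  }
  # starting values: plateaus from the extremes, Kd from the half-rise
  fp_min0 <- fp[which.min(conc)]
  fp_max0 <- max(fp)
  half <- (fp_min0 + fp_max0) / 2
  pos <- conc[conc > 0]
  kd0 <- if (length(pos) && any(fp >= half)) {
    max(min(pos[fp[conc > 0] >= half], na.rm = TRUE), min(pos))
  } else stats::median(pos)
  resid_fun <- function(theta) {
    isotherm_predict(10^theta[1], theta[2], theta[3], conc) - fp
  }
  fit <- minpack.lm::nls.lm(
    par = c(log_kd = log10(kd0), fp_min = fp_min0, fp_max = fp_max0),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- fit$par
  kd <- 10^est[[1]]
  n <- length(fp); p <- 3L
  sigma2 <- fit$deviance / max(n - p, 1L)
  cov <- try(sigma2 * solve(fit$hessian / 2), silent = TRUE)
  if (inherits(cov, "try-error")) {
    sd_theta <- rep(NA_real_, 3)
    flags <- c(flags, "singular_covariance")
  } else {
    sd_theta <- sqrt(pmax(diag(cov), 0))
  }
  # delta method for Kd on the natural scale
  sd_nat <- c(kd * log(10) * sd_theta[1], sd_theta[2], sd_theta[3])
  estimates <- c(kd = kd, fp_min = est[[2]], fp_max = est[[3]])
  ci <- cbind(lower = estimates - 1.96 * sd_nat,
              upper = estimates + 1.96 * sd_nat)
  rownames(ci) <- names(estimates)
  # plateau identifiability: without an anchor, a Kd beyond the titration
  # range means the upper plateau was never approached
  if (!anchored && kd > max(conc) / 2) {
    flags <- c(flags, "upper_plateau_unidentifiable")
  }
  structure(list(kd = kd, fp_min = est[[2]], fp_max = est[[3]],
                 sd = stats::setNames(sd_nat, names(estimates)), ci = ci,
                 rss = fit$deviance, flags = flags,
                 fitted = fp - fit$fvec, residuals = fit$fvec,
                 concentrations = conc, convergence = fit$info),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> Kd = %.4g M [%.4g, %.4g], FPmin = %.4g, FPmax = %.4g, RSS = %.3g\n",
              x$kd, x$ci["kd", 1], x$ci["kd", 2], x$fp_min, x$fp_max, x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Standard free energy of binding from a dissociation constant
#'
#' `dG = R T ln(Kd / 1 M)` in kJ/mol, relative to the 1 M standard state:
#' negative for sub-molar affinities, exactly zero at `Kd` = 1 M, and
#' strictly increasing in `Kd`.
#'
#' @param kd Dissociation constant(s), molar, > 0.
#' @param temperature Kelvin; default 310.15 K (37 degrees C, the assay
#'   temperature).
#' @return Free energy in kJ mol^-1.
#' @examples
#' binding_energy(2.62e-3)  # about -15.3 kJ/mol
#' @export
binding_energy <- function(kd, temperature = 310.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop_config("kd must be > 0")
  check_scalar_positive(temperature, "temperature")
  GAS_CONSTANT * temperature * log(kd) / 1000
}

#' Fit a four-parameter logistic competition curve
#'
#' Decreasing 4PL in competitor concentration x:
#' `FP(x) = FP_min + (FP_max - FP_min) / (1 + (x / I50)^h)`, so the fitted
#' curve equals the plateau midpoint exactly at `x = I50`. The lower
#' plateau can be fixed to the measured FP of the free dye, which
#' stabilizes the fit when the titration cannot reach full displacement.
#'
#' @param competitor_concentrations Molar, > 0; at least 5 distinct values
#'   spanning the transition.
#' @param fp_values FP per observation (replicates as repeated
#'   concentrations).
#' @param fix_lower Optional fixed value for the lower plateau `FP_min`.
#' @param average_replicates Average replicates per concentration first.
#' @return Object of class `fourpl_fit` with `fp_min`, `fp_max`, `i50`,
#'   `hill_slope`, `sd`, `ci`, `rss`, `flags` (may contain
#'   `"i50_outside_range"`).
#' @export
fit_4pl <- function(competitor_concentrations, fp_values, fix_lower = NULL,
                    average_replicates = TRUE) {
  x <- competitor_concentrations; y <- fp_values
  if (length(x) != length(y)) stop_config("lengths differ")
  if (any(x <= 0)) stop_config("competitor concentrations must be > 0")
  if (length(unique(x)) < 5L) stop_config("need at least 5 distinct concentrations")
  if (average_replicates) {
    agg <- tapply(y, x, mean)
    x <- as.numeric(names(agg)); y <- as.numeric(agg)
    o <- order(x); x <- x[o]; y <- y[o]
  }
  fixed_lower <- !is.null(fix_lower)
  fp_max0 <- max(y)
  fp_min0 <- if (fixed_lower) fix_lower else min(y)
  half <- (fp_max0 + fp_min0) / 2
  below <- x[y <= half]
  i50_0 <- if (length(below)) min(below) else stats::median(x)
  model <- function(theta) {
    i50 <- 10^theta[["log_i50"]]; h <- exp(theta[["log_h"]])
    fmin <- if (fixed_lower) fix_lower else theta[["fp_min"]]
    fmin + (theta[["fp_max"]] - fmin) / (1 + (x / i50)^h)
  }
  par0 <- c(log_i50 = log10(i50_0), log_h = 0, fp_max = fp_max0)
  if (!fixed_lower) par0 <- c(par0, fp_min = fp_min0)
  fit <- minpack.lm::nls.lm(par = par0, fn = function(th) model(th) - y,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- fit$par
  i50 <- 10^est[["log_i50"]]; h <- exp(est[["log_h"]])
  fp_min <- if (fixed_lower) fix_lower else est[["fp_min"]]
  n <- length(y); p <- length(par0)
  sigma2 <- fit$deviance / max(n - p, 1L)
  cov <- try(sigma2 * solve(fit$hessian / 2), silent = TRUE)
  sd_theta <- if (inherits(cov, "try-error")) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
  names(sd_theta) <- names(par0)
  sd_nat <- c(i50 = unname(i50 * log(10) * sd_theta["log_i50"]),
              hill_slope = unname(h * sd_theta["log_h"]),
              fp_max = unname(sd_theta["fp_max"]),
              fp_min = if (fixed_lower) 0 else unname(sd_theta["fp_min"]))
  estimates <- c(i50 = i50, hill_slope = h, fp_max = est[["fp_max"]],
                 fp_min = fp_min)
  ci <- cbind(lower = estimates - 1.96 * sd_nat[names(estimates)],
              upper = estimates + 1.96 * sd_nat[names(estimates)])
  flags <- character()
  if (i50 < min(x) || i50 > max(x)) flags <- c(flags, "i50_outside_range")
  structure(list(fp_min = fp_min, fp_max = est[["fp_max"]], i50 = i50,
                 hill_slope = h, sd = sd_nat, ci = ci, rss = fit$deviance,
                 flags = flags, residuals = fit$fvec,
                 concentrations = x, convergence = fit$info),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit> I50 = %.4g M, hill = %.3g, FPmax = %.4g, FPmin = %.4g%s\n",
              x$i50, x$hill_slope, x$fp_max, x$fp_min,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Two-ligand, one-site competitive binding system
#'
#' @param protein_total Total protein, molar, > 0.
#' @param probe_total Total fluorescent probe, molar, > 0.
#' @param probe_kd Probe dissociation constant, molar, > 0.
#' @param competitor_total Total competitor, molar, >= 0.
#' @param competitor_kd Competitor dissociation constant, molar, > 0
#'   (may be `Inf` for a non-binder).
#' @return Object of class `competitive_system`.
#' @export
competitive_system <- function(protein_total, probe_total, probe_kd,
                               competitor_total, competitor_kd) {
  check_scalar_positive(protein_total, "protein_total")
  check_scalar_positive(probe_total, "probe_total")
  check_scalar_positive(probe_kd, "probe_kd")
  check_scalar_nonneg(competitor_total, "competitor_total")
  if (!(is.numeric(competitor_kd) && length(competitor_kd) == 1L &&
        competitor_kd > 0)) {
    stop_config("competitor_kd must be > 0 (Inf allowed)")
  }
  structure(list(protein_total = protein_total, probe_total = probe_total,
                 probe_kd = probe_kd, competitor_total = competitor_total,
                 competitor_kd = competitor_kd),
            class = "competitive_system")
}

# Free-protein root for two ligands competing for one site; exact
# mass-action equilibrium with full depletion of protein and both
# ligands. f is strictly increasing in pf, so the root on
# [0, protein_total] is unique; solved by uniroot to 1e-12 relative.
free_protein_root <- function(ptot, stot, kds, itot, kdi) {
  f <- function(pf) {
    bound_s <- stot * pf / (kds + pf)
    bound_i <- if (itot > 0 && is.finite(kdi)) itot * pf / (kdi + pf) else 0
    pf + bound_s + bound_i - ptot
  }
  stats::uniroot(f, c(0, ptot), tol = max(1e-12 * ptot, 1e-30))$root
}

#' Exact competitive binding equilibrium
#'
#' Solves the coupled mass-action equilibrium of a fluorescent probe and a
#' nonfluorescent competitor binding the same protein site, accounting for
#' depletion of the protein and of both ligands (no Cheng-Prusoff-style
#' approximation). The free-protein concentration is found by a bracketed
#' root solve; all three totals are conserved exactly. With
#' `competitor_total = 0` (or infinite competitor Kd) the result equals
#' the one-ligand quadratic solution.
#'
#' @param system A [competitive_system()].
#' @return A list with `free_protein`, `probe_bound`, `competitor_bound`
#'   (molar), and `probe_bound_fraction`, `competitor_bound_fraction`.
#' @export
competitive_equilibrium <- function(system) {
  stopifnot(inherits(system, "competitive_system"))
  pf <- free_protein_root(system$protein_total, system$probe_total,
                          system$probe_kd, system$competitor_total,
                          system$competitor_kd)
  probe_bound <- system$probe_total * pf / (system$probe_kd + pf)
  comp_bound <- if (system$competitor_total > 0 && is.finite(system$competitor_kd)) {
    system$competitor_total * pf / (system$competitor_kd + pf)
  } else 0
  list(free_protein = pf,
       probe_bound = probe_bound,
       competitor_bound = comp_bound,
       probe_bound_fraction = probe_bound / system$probe_total,
       competitor_bound_fraction = if (system$competitor_total > 0)
         comp_bound / system$competitor_total else 0)
}

probe_bound_fraction_at <- function(protein_total, probe_total, probe_kd,
                                    competitor_total, competitor_kd) {
  competitive_equilibrium(competitive_system(
    protein_total, probe_total, probe_kd, competitor_total, competitor_kd
  ))$probe_bound_fraction
}

#' Competitor concentration halving the probe-specific signal
#'
#' Inverse of [i50_to_kd()]: for a known competitor Kd, finds the
#' competitor concentration at which the equilibrium probe-bound fraction
#' is half its no-competitor value.
#'
#' @param competitor_kd Competitor dissociation constant, molar.
#' @param protein_total,probe_total,probe_kd Assay concentrations, molar.
#' @return The I50 concentration in molar.
#' @export
kd_to_i50 <- function(competitor_kd, protein_total, probe_total, probe_kd) {
  b0 <- probe_bound_fraction_at(protein_total, probe_total, probe_kd, 0, Inf)
  g <- function(log_i) {
    probe_bound_fraction_at(protein_total, probe_total, probe_kd,
                            10^log_i, competitor_kd) - b0 / 2
  }
  # bound fraction decreases in competitor, so g is decreasing in log_i
  lo <- -12; hi <- 3
  if (g(lo) < 0 || g(hi) > 0) {
    stop_numeric("no I50 bracket found for the given system")
  }
  10^stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Competitor dissociation constant from a measured I50
#'
#' Exact depletion-corrected conversion of a half-inhibition concentration
#' into a competitor Kd: finds the `competitor_kd` for which the
#' two-ligand equilibrium predicts a 50% reduction of the probe-bound
#' fraction at `competitor_total = i50`, given the assay's protein and
#' probe concentrations and the probe's own Kd. This is the exact
#' mass-action counterpart of approximate I50-to-Ki corrections and
#' reduces to Cheng-Prusoff when depletion is negligible. Round trip with
#' [kd_to_i50()] is the identity.
#'
#' @param i50 Measured half-inhibition concentration, molar.
#' @param protein_total,probe_total,probe_kd Assay concentrations, molar.
#' @return The competitor Kd in molar.
#' @export
i50_to_kd <- function(i50, protein_total, probe_total, probe_kd) {
  check_scalar_positive(i50, "i50")
  b0 <- probe_bound_fraction_at(protein_total, probe_total, probe_kd, 0, Inf)
  g <- function(log_kd) {
    probe_bound_fraction_at(protein_total, probe_total, probe_kd,
                            i50, 10^log_kd) - b0 / 2
  }
  # weaker competitor (larger Kd) leaves more probe bound: g increasing
  lo <- -15; hi <- 6
  if (g(lo) > 0 || g(hi) < 0) {
    stop_numeric("i50 = ", signif(i50, 4),
                 " M is inconsistent with any positive competitor Kd at ",
                 "these assay concentrations (depletion bound violated)")
  }
  10^stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Cheng-Prusoff approximation for competitive binding
#'
#' Classical no-depletion conversion `Ki = I50 / (1 + [probe]/Kd_probe)`,
#' provided as a cross-check for [i50_to_kd()]; valid only when protein
#' and probe depletion are negligible (protein well below both Kds).
#'
#' @inheritParams i50_to_kd
#' @return Approximate competitor Kd in molar.
#' @export
cheng_prusoff_kd <- function(i50, probe_total, probe_kd) {
  check_scalar_positive(i50, "i50")
  i50 / (1 + probe_total / probe_kd)
}
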