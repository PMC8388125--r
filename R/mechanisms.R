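# Mass-action mechanisms of self-labeling tag chemistry.
#
# Mechanism "model1":      P + S -> PS                 (kapp, M^-1 s^-1)
# Mechanism "model2":      P + S <-> PS* -> PS         (k1, k_minus1, k2)
# Mechanism "aging":       P + S -> PSa -> PSb         (kapp, k3)
# Mechanism "competition": P + S -> PS ; P + I -> PI   (kapp_S, kapp_I)
#
# Units are molar and seconds throughout; mP and other I/O units are
# converted at the boundary.

#' Rate parameters for the one-step labeling mechanism
#'
#' The simplest description of tag labeling: a single irreversible
#' bimolecular step with apparent second-order rate constant `kapp`,
#' valid when reactant concentrations are well below the binding Kd.
#'
#' @param kapp Apparent second-order rate constant, M^-1 s^-1.
#' @return Object of class `rate_parameters_model1`.
#' @export
rate_parameters_model1 <- function(kapp) {
  check_scalar_positive(kapp, "kapp")
  structure(list(kapp = kapp), class = "rate_parameters_model1")
}

#' Rate parameters for the two-step labeling mechanism
#'
#' Reversible substrate binding (`k1` association, `k_minus1`
#' dissociation) followed by an irreversible covalent reaction (`k2`).
#' Derived quantities: `Kd = k_minus1 / k1` ([kd_from_rates()]) and the
#' low-concentration apparent rate constant
#' `kapp = k1 k2 / (k_minus1 + k2)` ([kapp_from_rates()]).
#'
#' @param k1 Association rate constant, M^-1 s^-1.
#' @param k_minus1 Dissociation rate constant, s^-1.
#' @param k2 Covalent-reaction rate constant, s^-1.
#' @return Object of class `rate_parameters_model2`.
#' @export
rate_parameters_model2 <- function(k1, k_minus1, k2) {
  check_scalar_positive(k1, "k1")
  check_scalar_positive(k_minus1, "k_minus1")
  check_scalar_positive(k2, "k2")
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2),
            class = "rate_parameters_model2")
}

#' Rate parameters for labeling followed by slow product aging
#'
#' One-step labeling (`kapp`) producing state A of the conjugate, which
#' converts first-order (`k3`) into state B. Describes traces with a slow
#' second signal phase, e.g. a conformational change of the labeled
#' protein; `k3` is typically 1e-3 to 1e-2 s^-1.
#'
#' @param kapp Apparent second-order labeling rate constant, M^-1 s^-1.
#' @param k3 First-order A -> B conversion rate, s^-1.
#' @return Object of class `rate_parameters_aging`.
#' @export
rate_parameters_aging <- function(kapp, k3) {
  check_scalar_positive(kapp, "kapp")
  check_scalar_positive(k3, "k3")
  structure(list(kapp = kapp, k3 = k3), class = "rate_parameters_aging")
}

#' Rate parameters for kinetic competition labeling
#'
#' Two parallel irreversible bimolecular labeling reactions sharing the
#' protein: a fluorescent substrate S (`kapp_S`) and a nonfluorescent
#' competitor I (`kapp_I`).
#'
#' @param kapp_S Rate constant for the fluorescent substrate, M^-1 s^-1.
#' @param kapp_I Rate constant for the competitor, M^-1 s^-1.
#' @return Object of class `rate_parameters_competition`.
#' @export
rate_parameters_competition <- function(kapp_S, kapp_I) {
  check_scalar_positive(kapp_S, "kapp_S")
  check_scalar_positive(kapp_I, "kapp_I")
  structure(list(kapp_S = kapp_S, kapp_I = kapp_I),
            class = "rate_parameters_competition")
}

#' Dissociation constant from two-step rate constants
#'
#' @param params A [rate_parameters_model2()].
#' @return `k_minus1 / k1` in molar.
#' @export
kd_from_rates <- function(params) {
  stopifnot(inherits(params, "rate_parameters_model2"))
  params$k_minus1 / params$k1
}

#' Apparent second-order rate constant from two-step rate constants
#'
#' The low-concentration limit of the two-step mechanism behaves as a
#' single bimolecular step with `kapp = k1 k2 / (k_minus1 + k2)`
#' (M^-1 s^-1). `kapp` never exceeds `k1`, grows with `k2` and falls
#' with `k_minus1`.
#'
#' @param params A [rate_parameters_model2()].
#' @return Apparent rate constant in M^-1 s^-1.
#' @export
kapp_from_rates <- function(params) {
  stopifnot(inherits(params, "rate_parameters_model2"))
  params$k1 * params$k2 / (params$k_minus1 + params$k2)
}

new_trajectory <- function(mechanism, times, species, protein_total,
                           substrate_total, competitor_total = 0) {
  structure(
    list(mechanism = mechanism, times = as.numeric(times),
         species = species, protein_total = protein_total,
         substrate_total = substrate_total,
         competitor_total = competitor_total),
    class = "species_trajectory"
  )
}

#' @export
print.species_trajectory <- function(x, ...) {
  cat(sprintf("<species_trajectory> mechanism %s, %d time points, species: %s\n",
              x$mechanism, length(x$times),
              paste(colnames(x$species), collapse = ", ")))
  invisible(x)
}

#' Convert a species trajectory to a data frame
#' @param x A `species_trajectory`.
#' @param ... Unused.
#' @export
as.data.frame.species_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$species, check.names = FALSE)
}

# Closed-form product concentration of the irreversible bimolecular
# reaction P + S -> PS. Uses expm1 and asymptotic guards to stay stable
# when (P0 - S0) k t is large, and the equal-concentration solution when
# the totals are indistinguishable (relative gap < 1e-9), where the
# general form suffers catastrophic cancellation.
bimolecular_product <- function(kapp, p0, s0, times) {
  if (max(p0, s0) == 0) return(rep(0, length(times)))
  delta <- p0 - s0
  if (abs(delta) / max(p0, s0) < 1e-9) {
    c0 <- (p0 + s0) / 2
    return(kapp * times * c0^2 / (1 + kapp * times * c0))
  }
  d <- delta * kapp * times
  ps <- numeric(length(times))
  big <- d > 500
  neg_big <- d < -500
  mid <- !big & !neg_big
  ps[big] <- s0       # P in excess, substrate exhausted
  ps[neg_big] <- p0   # S in excess, protein exhausted
  e <- expm1(d[mid])
  ps[mid] <- p0 * s0 * e / (p0 * e + delta)
  ps
}

#' Simulate the one-step labeling mechanism
#'
#' Irreversible bimolecular labeling `P + S -> PS`, evaluated from the
#' closed-form integrated rate law (with a numerically stable
#' equal-concentration branch), which agrees with direct ODE integration.
#'
#' @param params A [rate_parameters_model1()] (or a bare positive number
#'   taken as `kapp`).
#' @param protein_total,substrate_total Initial totals in molar, > 0.
#' @param times Seconds, >= 0.
#' @return A `species_trajectory` with species P, S, PS.
#' @examples
#' tr <- simulate_model1(rate_parameters_model1(1e5), 1e-6, 1e-6,
#'                       seq(0, 60, by = 1))
#' tail(as.data.frame(tr), 2)
#' @export
simulate_model1 <- function(params, protein_total, substrate_total, times) {
  if (is.numeric(params)) params <- rate_parameters_model1(params)
  stopifnot(inherits(params, "rate_parameters_model1"))
  check_scalar_positive(protein_total, "protein_total")
  check_scalar_positive(substrate_total, "substrate_total")
  check_times(times)
  ps <- bimolecular_product(params$kapp, protein_total, substrate_total, times)
  species <- cbind(P = protein_total - ps, S = substrate_total - ps, PS = ps)
  new_trajectory("model1", times, species, protein_total, substrate_total)
}

#' Simulate the two-step labeling mechanism
#'
#' Integrates `P + S <-> PS* -> PS` by stiff-capable adaptive ODE
#' integration (deSolve::lsoda) on the reduced state (PS*, PS); free P and
#' S are recovered from conservation, so mass balance holds to rounding.
#' The covalent product PS is nondecreasing and approaches
#' `min(P0, S0)` as t grows.
#'
#' @param params A [rate_parameters_model2()].
#' @param protein_total,substrate_total Initial totals in molar, > 0.
#' @param times Seconds, >= 0.
#' @param rtol,atol Solver tolerances (relative; absolute in molar). The
#'   defaults (1e-8, 1e-12) resolve nM-to-uM concentrations across the
#'   stiff regimes reached when `k1` approaches diffusion control.
#' @return A `species_trajectory` with species P, S, PSi (the noncovalent
#'   complex PS*), PS.
#' @export
simulate_model2 <- function(params, protein_total, substrate_total, times,
                            rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "rate_parameters_model2"))
  check_scalar_positive(protein_total, "protein_total")
  check_scalar_positive(substrate_total, "substrate_total")
  check_times(times)
  p0 <- protein_total; s0 <- substrate_total
  deriv <- function(t, y, parms) {
    p <- p0 - y[1] - y[2]
    s <- s0 - y[1] - y[2]
    v_on <- parms$k1 * p * s
    v_off <- parms$k_minus1 * y[1]
    v_cov <- parms$k2 * y[1]
    list(c(v_on - v_off - v_cov, v_cov))
  }
  out <- integrate_ode(c(psi = 0, ps = 0), times, deriv, params, rtol, atol)
  cap <- min(p0, s0)
  ps <- cummax(pmin(pmax(out[, "ps"], 0), cap))
  psi <- pmin(pmax(out[, "psi"], 0), cap - ps)
  species <- cbind(P = p0 - psi - ps, S = s0 - psi - ps, PSi = psi, PS = ps)
  new_trajectory("model2", times, species, p0, s0)
}

#' Simulate labeling with slow product aging
#'
#' Integrates `P + S -> PSa -> PSb`: one-step labeling into conjugate
#' state A followed by first-order conversion to state B. The labeled
#' pool PSa + PSb is nondecreasing, and PSb absorbs everything as t
#' grows.
#'
#' @inheritParams simulate_model2
#' @param params A [rate_parameters_aging()].
#' @return A `species_trajectory` with species P, S, PSa, PSb.
#' @export
simulate_aging <- function(params, protein_total, substrate_total, times,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "rate_parameters_aging"))
  check_scalar_positive(protein_total, "protein_total")
  check_scalar_positive(substrate_total, "substrate_total")
  check_times(times)
  p0 <- protein_total; s0 <- substrate_total
  deriv <- function(t, y, parms) {
    lab <- y[1] + y[2]
    v_lab <- parms$kapp * (p0 - lab) * (s0 - lab)
    v_age <- parms$k3 * y[1]
    list(c(v_lab - v_age, v_age))
  }
  out <- integrate_ode(c(psa = 0, psb = 0), times, deriv, params, rtol, atol)
  cap <- min(p0, s0)
  psb <- cummax(pmin(pmax(out[, "psb"], 0), cap))
  lab <- pmax(cummax(pmin(pmax(out[, "psa"] + out[, "psb"], 0), cap)), psb)
  psa <- lab - psb
  species <- cbind(P = p0 - lab, S = s0 - lab, PSa = psa, PSb = psb)
  new_trajectory("aging", times, species, p0, s0)
}

#' Simulate kinetic competition labeling
#'
#' Two parallel irreversible bimolecular labeling reactions sharing the
#' protein pool: fluorescent substrate S (`kapp_S`) and nonfluorescent
#' competitor I (`kapp_I`). With no competitor the output reduces exactly
#' to [simulate_model1()] (and is computed by its closed form).
#'
#' @inheritParams simulate_model2
#' @param params A [rate_parameters_competition()].
#' @param competitor_total Competitor total in molar, >= 0.
#' @return A `species_trajectory` with species P, S, I, PS, PI.
#' @export
simulate_competition <- function(params, protein_total, substrate_total,
                                 competitor_total, times,
                                 rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "rate_parameters_competition"))
  check_scalar_positive(protein_total, "protein_total")
  check_scalar_positive(substrate_total, "substrate_total")
  check_scalar_nonneg(competitor_total, "competitor_total")
  check_times(times)
  p0 <- protein_total; s0 <- substrate_total; i0 <- competitor_total
  if (i0 == 0) {
    m1 <- simulate_model1(rate_parameters_model1(params$kapp_S), p0, s0, times)
    species <- cbind(m1$species[, c("P", "S"), drop = FALSE],
                     I = rep(0, length(times)),
                     PS = m1$species[, "PS"], PI = rep(0, length(times)))
    return(new_trajectory("competition", times, species, p0, s0, 0))
  }
  deriv <- function(t, y, parms) {
    p <- p0 - y[1] - y[2]
    list(c(parms$kapp_S * p * (s0 - y[1]),
           parms$kapp_I * p * (i0 - y[2])))
  }
  out <- integrate_ode(c(ps = 0, pi = 0), times, deriv, params, rtol, atol)
  ps <- cummax(pmin(pmax(out[, "ps"], 0), min(p0, s0)))
  pi_ <- cummax(pmin(pmax(out[, "pi"], 0), min(p0, i0)))
  # integration error can overshoot the shared protein pool by ~atol;
  # free protein is floored at zero, leaving a sub-tolerance mass defect
  species <- cbind(P = pmax(p0 - ps - pi_, 0), S = s0 - ps, I = i0 - pi_,
                   PS = ps, PI = pi_)
  new_trajectory("competition", times, species, p0, s0, i0)
}

# Shared lsoda wrapper: prepends t = 0 when absent so integration always
# starts from the true initial condition, and converts solver failures
# into a typed error carrying the diagnostic.
integrate_ode <- function(y0, times, deriv, parms, rtol, atol) {
  t_solver <- times
  prepend <- times[1] > 0
  if (prepend) t_solver <- c(0, times)
  # collapse duplicated time points (lsoda requires strict monotonicity)
  tu <- unique(t_solver)
  if (length(tu) == 1L) {
    out <- matrix(rep(y0, each = length(times)), nrow = length(times),
                  dimnames = list(NULL, names(y0)))
    return(out)
  }
  out <- try(deSolve::lsoda(y0, tu, deriv, parms, rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(out))) {
    stop_numeric("ODE integration failed: ",
                 if (inherits(out, "try-error")) attr(out, "condition")$message
                 else "non-finite state reached")
  }
  idx <- match(times, tu)
  out[idx, , drop = FALSE]
}
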