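# Independent numerical oracles used to check the package's simulators.
# These deliberately avoid the package's own integration code paths.

# Fixed-step RK4 integration of dy/dt = f(t, y); returns states at `times`.
rk4_integrate <- function(f, y0, times, dt) {
  t_now <- times[1]
  y <- y0
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  for (i in seq_along(times)[-1]) {
    while (t_now < times[i] - 1e-15) {
      h <- min(dt, times[i] - t_now)
      k1 <- f(t_now, y)
      k2 <- f(t_now + h / 2, y + h / 2 * k1)
      k3 <- f(t_now + h / 2, y + h / 2 * k2)
      k4 <- f(t_now + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_now <- t_now + h
    }
    out[i, ] <- y
  }
  colnames(out) <- names(y0)
  out
}

# Direct ODE oracle for the irreversible bimolecular reaction P + S -> PS.
ode_oracle_model1 <- function(kapp, p0, s0, times, dt = NULL) {
  if (is.null(dt)) dt <- 1 / (kapp * max(p0, s0)) / 200
  f <- function(t, y) {
    v <- kapp * (p0 - y[["ps"]]) * (s0 - y[["ps"]])
    c(ps = v)
  }
  rk4_integrate(f, c(ps = 0), times, dt)[, "ps"]
}

# Full-species oracle for the aging mechanism P + S -> PSa -> PSb.
ode_oracle_aging <- function(kapp, k3, p0, s0, times, dt) {
  f <- function(t, y) {
    lab <- y[["psa"]] + y[["psb"]]
    v1 <- kapp * (p0 - lab) * (s0 - lab)
    v2 <- k3 * y[["psa"]]
    c(psa = v1 - v2, psb = v2)
  }
  rk4_integrate(f, c(psa = 0, psb = 0), times, dt)
}

# Competition oracle: two parallel irreversible reactions sharing P.
ode_oracle_competition <- function(ks, ki, p0, s0, i0, times, dt) {
  f <- function(t, y) {
    p <- p0 - y[["ps"]] - y[["pi"]]
    c(ps = ks * p * (s0 - y[["ps"]]), pi = ki * p * (i0 - y[["pi"]]))
  }
  rk4_integrate(f, c(ps = 0, pi = 0), times, dt)
}

# Brute-force competitive equilibrium: grid search + refinement over the
# free-protein concentration, independent of the package's root solve.
grid_competitive_equilibrium <- function(ptot, stot, kds, itot, kdi) {
  obj <- function(pf) {
    abs(pf + stot * pf / (kds + pf) + itot * pf / (kdi + pf) - ptot)
  }
  lo <- 0; hi <- ptot
  for (pass in 1:12) {
    grid <- seq(lo, hi, length.out = 201)
    v <- vapply(grid, obj, numeric(1))
    i <- which.min(v)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  }
  pf <- (lo + hi) / 2
  list(free_protein = pf,
       probe_bound_fraction = pf / (kds + pf))
}
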