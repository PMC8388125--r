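---
title: "Models and methods behind slpkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slpkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slpkin)
```

# The measurement and the models

Self-labeling protein tags (HaloTag7, SNAP-tag, CLIP-tag) form a
covalent bond with a small synthetic substrate. When the substrate
carries a fluorophore, its rotational mobility drops on binding, so
fluorescence polarization (FP) or anisotropy rises as the reaction
proceeds. `slpkin` models that time course with mass-action kinetics and
estimates rate and binding constants from it.

Internally every concentration is molar and every time is in seconds;
polarization and anisotropy are dimensionless fractions (millipolarization
is converted by 1000 at the file boundary). FP and anisotropy are
related exactly by `r = 2P/(3 - P)` (`fp_anisotropy_convert`), and FP is
computed from channel intensities as
`(I_par - G I_perp)/(I_par + G I_perp)`, where `G` is the conventional
instrument calibration factor for the two detection channels.

Four mechanisms are implemented:

* **One-step** (`model1`): `P + S -> PS`, rate constant `kapp`
  (M^-1 s^-1). This is the integrated-rate-law workhorse for
  plate-reader kinetics at concentrations well below the binding Kd.
  The closed form is used, not numerical integration:
  for unequal totals `PS(t) = P0 S0 (e^d - 1)/(P0 e^d - S0)` with
  `d = (P0 - S0) k t`, and `PS(t) = k t C^2/(1 + k t C)` when the totals
  are equal.
* **Two-step** (`model2`): `P + S <-> PS* -> PS` with `k1`, `k_minus1`,
  `k2`. Derived quantities: `Kd = k_minus1/k1` and
  `kapp = k1 k2/(k_minus1 + k2)`, the low-concentration limit of the
  mechanism. Note that `kapp` has second-order units; it is the
  bimolecular constant an observer fitting the one-step model at low
  concentrations would measure.
* **Aging** (`aging`): `P + S -> PSa -> PSb`, for traces with a slow
  second phase (`k3`, typically 1e-3 to 1e-2 s^-1) attributed to a
  conformational change of the labeled protein. The two product states
  may be given distinct signal responses.
* **Competition** (`competition`): parallel irreversible labeling by a
  fluorescent probe (`kapp_S`) and a dark competitor (`kapp_I`) sharing
  the protein pool. This is how nonfluorescent substrates are measured:
  the competitor's only observable effect is the probe signal it
  suppresses.

## The observable

`project_signal` maps species to signal by mole-fraction weighting over
the substrate pool: free substrate contributes `r_free`, every
protein-associated substrate species contributes `r_bound` (the
noncovalent complex and the covalent product are assumed
indistinguishable in FP — the fluorophore is immobilized either way),
and competitor species contribute nothing. Intensity weighting is
available (`intensity_weights`) but defaults to none, appropriate when
fluorescence intensity changes on binding are small (of order 10% or
less); in that regime intensity-weighted and mole-fraction mixing are
indistinguishable at assay noise.

Instrument effects are limited to two fixed parameters: a **dead time**
(points with reaction time earlier than it are dropped, never
interpolated) and a **delay** (a constant offset between reaction time
and the recorded clock). Both are treated as known calibration
constants in fits. `estimate_dead_time` recovers the dead time from a
pseudo-first-order calibration decay by fitting `A exp(-k t)` and
comparing the extrapolated amplitude with the known initial amplitude;
without the known amplitude the offset is structurally unidentifiable
and the function refuses to guess.

# Global fitting

`fit_global` minimizes the summed squared residuals of all traces of a
concentration series simultaneously. Choices that matter:

* **Positivity by construction.** Rate constants (and the optional
  substrate-scale factor) are optimized as log10 values; response
  parameters stay linear. No penalty terms, no clipping.
* **Optimizer.** Levenberg–Marquardt (`minpack.lm::nls.lm`, up to 150
  iterations), restarted from `n_starts` (default 5) perturbations of a
  data-driven initial guess: log-rates are jittered log-uniformly by up
  to a decade, response parameters by up to 20% of the signal range.
  The lowest-RSS converged solution wins; ties cannot arise because
  strictly better deviance is required to replace the incumbent.
* **Initial guesses.** `kapp` from the half-rise heuristic
  `ln 2 / (t_half * excess concentration)` (median over traces); for the
  two-step mechanism `k2` starts at 10 s^-1, `k_minus1 = k2`, and
  `k1 = 2 kapp`; `r_bound` from the largest observed signal.
* **Shared response.** One `r_bound` is shared across all traces, as is
  every kinetic constant; this is what makes multi-concentration global
  fitting informative.
* **Substrate-scale option.** `fit_substrate_scale = TRUE` adds one
  shared multiplier on the nominal substrate concentration, absorbing
  probe quantification error. It is identifiable only when some traces
  are protein-limited (the plateau then reports the true substrate
  amount), which is exactly how such assays are designed.
* **Identifiability warning.** The condition number of the
  Jacobian-derived parameter covariance is compared against a threshold
  (default 1e6); fits above it carry a flag rather than an error,
  because an ill-conditioned two-step fit can still constrain the
  ratio `k_minus1/k1` usefully. For fits where only that ratio is
  constrained (all traces far below Kd) the conditioning lands within
  an order of magnitude of the default threshold, so studies that need
  a hard guarantee should set `condition_threshold` to their own
  tolerance.

## Uncertainty

`monte_carlo_ci` implements a parametric bootstrap: `n_iterations`
(default 1000) synthetic datasets are drawn from the fitted curves plus
homoscedastic Gaussian noise at each trace's own residual RMS, each is
refit from the point estimates, the fraction with the highest refit RSS
(default 5%) is discarded as failed/outlier refits, and per-parameter
standard deviations and percentile 95% intervals are taken from the
kept samples. "Worst" is defined by RSS — the only criterion available
without knowing the truth. One integer seed fans out into per-iteration
child seeds, so results are bit-reproducible; a refit failure rate
above 20% triggers a reliability warning. On noise-free data the
interval width collapses to numerical zero, which the test suite checks.

`compare_models` reports the RSS ratio, the small-sample-corrected AICc
difference, and a one-sided runs test on the simpler model's residual
signs (pooled across traces, runs never spanning trace boundaries) —
the signature of a missing binding step is long same-sign residual
stretches, i.e. too few runs. The preference is advisory, with a
configurable equivalence band (default ΔAICc of 2).

# Equilibrium analysis

* **Direct isotherms** (`fit_isotherm`): the hyperbolic single-site
  model in total protein concentration, unweighted least squares on
  replicate-averaged values (per-replicate fitting is available via
  `average_replicates = FALSE`). When the titration cannot reach
  saturation, an **anchor pseudo-point** — the measured FP of fully
  reacted probe assigned to a huge nominal concentration — is appended
  as one ordinary observation (equal weight, the simplest defensible
  choice) to pin the upper plateau. Fits flag `flat_curve` degeneracy
  and `upper_plateau_unidentifiable` (fitted Kd beyond half the
  titration range without an anchor) instead of failing.
* **Competition titrations** (`fit_4pl`): a four-parameter logistic
  with free Hill slope, decreasing in competitor concentration, whose
  value at `i50` is exactly the plateau midpoint. The lower plateau can
  be fixed to the measured free-dye FP. Since the exact logistic
  parameterization used on any given instrument varies, the full 4PL
  with free slope is the safe superset; an `i50` outside the titrated
  range is flagged.
* **I50 to Kd** (`i50_to_kd`): rather than a closed-form correction,
  the package inverts the exact two-ligand, one-site mass-action
  equilibrium (free protein solved by bracketed root finding on
  `[0, protein_total]`, relative tolerance 1e-12; the objective is
  strictly monotone so the root is unique). The competitor Kd is the
  value at which the predicted probe-bound fraction at
  `competitor = I50` is half its no-competitor value. This accounts for
  depletion of protein and of both ligands — essential when the probe
  affinity (micromolar) is comparable to the protein concentration.
  The classical Cheng–Prusoff correction is provided
  (`cheng_prusoff_kd`) purely as a limiting-case cross-check; the two
  agree when the protein is far below both Kds, and the tests verify
  both that limit and the exact round trip `kd -> i50 -> kd` to 0.1%.
* **Free energy** (`binding_energy`): `RT ln(Kd / 1 M)`, default
  T = 310.15 K (37 °C, the labeling-assay temperature), configurable
  for room-temperature affinities. Note that a Kd rounded to three
  digits propagates to about ±0.01 kJ/mol, but disagreement between a
  published ΔG and one recomputed from the published rounded Kd can
  reach the half-unit of the last printed digit; the package computes
  from whatever Kd it is given and leaves rounding to the caller.

# The synthetic-data generator

`experiment_design` + the `generate_*` functions emulate the three
assay formats end to end:

* stopped-flow anisotropy: 1:1 protein:substrate mixing series
  (0.125–1 μM scale), log-spaced time grids (default rationale: the
  information is in the fast phase), instrument dead time of
  milliseconds, anisotropy noise SD 0.002;
* plate-reader FP kinetics: fixed trace-level substrate (20–50 nM),
  protein series spanning protein-limited to saturating, linear time
  grids, FP noise SD 5 mP (0.005);
* FP isotherms and competition titrations: log-spaced concentration
  grids with replicates, noise SD 2–3 mP.

Noise is additive i.i.d. Gaussian on the signal only — never on times
or concentrations — and every generator is a pure function of
(design, seed), which the tests check byte-for-byte. The noise SDs are
declared defaults chosen to sit in the scatter regime typical of these
instruments, not measured facts; they are configurable per design.
What the generator deliberately does **not** emulate: photobleaching,
drift, mixing artifacts, fluorogenicity equilibria, or heteroscedastic
detector noise. Recovery results on synthetic data therefore
demonstrate estimator correctness and precision under the stated noise
model, not robustness to instrument pathology.

Datasets round-trip losslessly through plain-text fixture bundles
(`write_fixture_bundle`/`read_fixture_bundle`: per-trace CSV plus JSON
sidecars, a design record, the generating truth, and a schema-versioned
manifest). Millipolarization files are converted to fractional units on
read with the original unit flag preserved.

# Numerical choices

* ODE integration: `deSolve::lsoda` (stiff-capable, adaptive), relative
  tolerance 1e-8 and absolute tolerance 1e-12 M by default; nM-scale
  problems in the tests pass tighter `atol` where the comparison
  demands it. The reduced state (product species only) is integrated
  and free species recovered from conservation, so mass balance is
  exact by construction.
* Solver output is sanitized so the physical invariants hold exactly,
  not just to solver tolerance: product concentrations are clamped to
  `[0, min(P0, S0)]` and monotonized (`cummax`) for irreversible steps;
  in the competition mechanism the shared protein pool is floored at
  zero, leaving at worst a ~1e-15 relative mass defect.
* The equal-concentration closed form is selected when
  `|P0 - S0|/max(P0, S0) < 1e-9`, where the general expression loses
  all significant digits; the general branch uses `expm1` and switches
  to the exact asymptote when `|d| > 500` to avoid overflow.
* Root solves (`competitive_equilibrium`, `i50_to_kd`, `kd_to_i50`)
  use bracketed `uniroot` on monotone objectives; `i50_to_kd` raises a
  domain error with an explanation when no positive Kd can produce the
  requested I50 (e.g. below the depletion bound).
* Degenerate inputs are flagged, not fatal: flat isotherms, missing
  transitions, unidentifiable dead time, ill-conditioned covariances.

# Problem sizes used in the shipped studies

The recovery studies run by the test suite and by
`scripts/acceptance.R` use: plate-reader designs of 4–5 protein
concentrations × 3 replicates × 121 time points over 1800 s;
stopped-flow designs of 4 concentrations × 3 replicates × 1000
log-spaced points over 10 ms–10 s; competition titrations of 12
log-spaced competitor concentrations × 3 replicates; isotherms of 12
protein concentrations × 3 replicates with an anchor point; 20 seeds
per study with the median reported. Monte Carlo coverage is assessed at
a reduced bootstrap depth (N = 150, 120 outer repetitions) on a
single-trace design — the package's own choice of a study small enough
to run routinely while keeping the binomial uncertainty of the coverage
estimate near one percentage point.

# Known limitations

* No Bayesian posterior sampling; multi-start Levenberg–Marquardt is
  the only global strategy, and pathological multimodality beyond a
  decade around the heuristic start is not explored.
* The two-step mechanism's `k2` is rarely separable from `k_minus1`
  when the observable cannot distinguish complex from product; fixing
  `k2` (as the fitting interface encourages) is a modeling commitment,
  and the derived `kapp` inherits it.
* Signal projection assumes the competitor and its conjugate are
  strictly dark, and that FP mixes linearly in mole fractions;
  strongly fluorogenic substrates violate both.
* The equilibrium module is strictly one site, no cooperativity.
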