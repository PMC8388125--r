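# slpkin

Kinetic and equilibrium analysis of self-labeling protein tags
(HaloTag7, SNAP-tag, CLIP-tag) from fluorescence polarization (FP) and
anisotropy measurements.

Self-labeling tags react covalently with a synthetic substrate
(chloroalkane for HaloTag, benzylguanine/benzylcytosine for SNAP/CLIP).
Labeling speed and substrate affinity vary over orders of magnitude with
the attached fluorophore, and the standard readout — polarization of a
fluorescent substrate rising as it binds and reacts — mixes binding and
chemistry in one signal. `slpkin` provides the mechanistic models and
estimators needed to turn such traces and titrations into rate and
binding constants, for anyone characterizing tag/substrate pairs or
engineering faster ones.

## Models

All concentrations are molar, time in seconds, signals dimensionless
(mP / 1000 at the I/O boundary).

* **One-step labeling** (`simulate_model1`): P + S → PS with apparent
  second-order rate constant *k*app (M⁻¹ s⁻¹), by the closed-form
  integrated rate law. Valid well below the binding *K*d.
* **Two-step labeling** (`simulate_model2`):
  P + S ⇌ PS\* → PS with association *k*₁, dissociation *k*₋₁ and
  covalent rate *k*₂; derived *K*d = *k*₋₁/*k*₁ and
  *k*app = *k*₁*k*₂/(*k*₋₁ + *k*₂).
* **Product aging** (`simulate_aging`): P + S → PSa → PSb, the slow
  second phase seen for some SNAP/CLIP substrates.
* **Kinetic competition** (`simulate_competition`): a fluorescent probe
  and a dark competitor racing for the same protein, for measuring rate
  constants of nonfluorescent substrates.

Species trajectories are projected onto the observable by mole-fraction
mixing (`project_signal`; complex and product share one response), and
fitted globally across concentration series by bounded
Levenberg–Marquardt on log-scaled rates (`fit_global`), with parametric
bootstrap uncertainty (`monte_carlo_ci`, N = 1000, worst 5% of refits
discarded).

Equilibrium tools: single-site isotherm fits with an optional
upper-plateau anchor point (`fit_isotherm`), four-parameter logistic
competition curves (`fit_4pl`), exact depletion-corrected conversion of
an I₅₀ into a competitor *K*d by inverting the two-ligand mass-action
equilibrium (`i50_to_kd`; Cheng–Prusoff provided as a cross-check), and
ΔG = *RT* ln *K*d (`binding_energy`).

A synthetic-data module (`experiment_design`,
`generate_kinetic_dataset`, `generate_isotherm_dataset`,
`generate_competition_dataset`) emulates stopped-flow and plate-reader
assays — concentration grids, dead time, triplicates, Gaussian noise —
so the whole pipeline is testable end to end without instrument data.

## Worked example

Simulate a stopped-flow anisotropy series (1:1 protein:substrate at
0.125–1 μM, 2 ms dead time, triplicate, noise SD 0.002) for a fast
substrate with *k*₁ = 1.61×10⁸ M⁻¹s⁻¹, *k*₋₁ = 1.61 s⁻¹, *k*₂ = 10 s⁻¹,
then fit the two-step model globally:

```r
library(slpkin)
design <- experiment_design(
  mechanism = "model2",
  params = list(k1 = 1.61e8, k_minus1 = 1.61, k2 = 10),
  protein_totals   = c(0.125, 0.25, 0.5, 1) * 1e-6,
  substrate_totals = c(0.125, 0.25, 0.5, 1) * 1e-6,
  response = signal_response(r_free = 0.05, r_bound = 0.25, dead_time = 2e-3),
  time_grid = list(from = 1e-3, to = 10, n = 400, spacing = "log"),
  replicates = 3, noise_sd = 0.002, signal_type = "anisotropy", seed = 101)
dataset <- generate_kinetic_dataset(design)

fit <- fit_global(dataset$traces, mechanism = "model2",
                  free = c("k1", "k_minus1", "r_bound"),
                  fixed = list(k2 = 10, r_free = 0.05, dead_time = 2e-3),
                  n_starts = 2)
fit <- monte_carlo_ci(fit, n_iterations = 200, seed = 7)
fit
#> <slp_fit> mechanism model2, 12 traces, RSS = 0.01755
#>           estimate        sd  ci_lower  ci_upper
#> k1       1.604e+08 2.204e+05 1.600e+08 1.608e+08
#> k_minus1 1.569e+00 2.789e-02 1.507e+00 1.620e+00
#> r_bound  2.501e-01 5.457e-05 2.500e-01 2.502e-01
#>   (uncertainty from 190 Monte Carlo refits)

signif(derived_rates(fit), 4)
#>        kd      kapp
#> 9.779e-09 1.386e+08
```

The fit recovers the generating constants: a dissociation constant of
~9.8 nM (truth 10 nM from *k*₋₁/*k*₁) and an apparent labeling rate
constant of 1.386×10⁸ M⁻¹s⁻¹ (truth 1.39×10⁸), with Monte Carlo 95%
intervals covering both. `binding_energy(9.78e-9)` converts the
affinity to −47.6 kJ/mol at 37 °C.

A thin command-line wrapper over the same pipeline lives at
`inst/cli/slpkin.R` (`simulate`, `fit`, `recover` subcommands driven by
a JSON config).

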