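# Shared builders for the study designs exercised across the test files.

log_spaced_times <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}

# Two-step rate constants reconstructed from an apparent rate constant
# and a dissociation constant at fixed covalent rate k2.
live580_rates <- function(kapp = 1.39e8, kd = 9.99e-9, k2 = 10) {
  k1 <- kapp * k2 / (k2 - kapp * kd)
  list(k1 = k1, k_minus1 = kd * k1, k2 = k2)
}

# Stopped-flow design: 1:1 mixing series, log time grid, anisotropy.
stopped_flow_design <- function(params, concs = c(0.125, 0.25, 0.5, 1) * 1e-6,
                                seed = 1, noise_sd = 0.002,
                                n_points = 1000, t_end = 10,
                                dead_time = 2e-3) {
  experiment_design(
    mechanism = "model2", params = params,
    protein_totals = concs, substrate_totals = concs,
    response = signal_response(r_free = 0.05, r_bound = 0.25,
                               dead_time = dead_time),
    time_grid = list(from = 1e-3, to = t_end, n = n_points, spacing = "log"),
    replicates = 3, noise_sd = noise_sd, signal_type = "anisotropy",
    seed = seed)
}

# Plate-reader design: fixed substrate, protein series, linear time grid.
plate_reader_design <- function(kapp, protein_totals, substrate_total,
                                seed = 1, noise_sd = 0.005, t_end = 1800,
                                n_points = 121) {
  experiment_design(
    mechanism = "model1", params = list(kapp = kapp),
    protein_totals = protein_totals, substrate_totals = substrate_total,
    response = signal_response(r_free = 0.05, r_bound = 0.30),
    time_grid = list(from = 0, to = t_end, n = n_points, spacing = "linear"),
    replicates = 3, noise_sd = noise_sd, signal_type = "fp", seed = seed)
}
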