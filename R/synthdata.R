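# Synthetic datasets with the statistical structure of stopped-flow and
# microplate-reader labeling experiments: mechanism simulation, signal
# projection, dead-time truncation, and additive i.i.d. Gaussian noise on
# the signal (never on times or concentrations). All generators are pure
# functions of (design, seed).

#' Design of a synthetic kinetic labeling experiment
#'
#' Full recipe for generating kinetic traces: mechanism and true
#' parameters, the concentration grid, the time grid, the signal-response
#' model (including instrument dead time and delay), replication and
#' noise. Defaults mirror the bench protocols this generator emulates:
#' triplicate measurements; log-spaced time grids for stopped flow (to
#' resolve the fast phase) and linear grids for plate readers; anisotropy
#' noise SD 0.002 for stopped flow and FP noise SD 5 mP for plate
#' readers.
#'
#' @param mechanism `"model1"`, `"model2"`, `"aging"`, or `"competition"`.
#' @param params Named list of true rate constants for the mechanism
#'   (e.g. `list(kapp = 2.57e4)` or `list(k1 =, k_minus1 =, k2 =)`).
#' @param protein_totals Protein concentrations, molar (one trace per
#'   condition).
#' @param substrate_totals Substrate concentration(s), molar: either one
#'   value recycled across conditions or one per condition (stopped-flow
#'   1:1 mixing passes the same vector twice).
#' @param competitor_totals Competitor concentrations (competition
#'   mechanism only), recycled like `substrate_totals`.
#' @param response A [signal_response()] with the true r_free/r_bound,
#'   dead time and delay.
#' @param time_grid `list(from =, to =, n =, spacing = "log"|"linear")`;
#'   `from` may be 0 only for linear spacing.
#' @param replicates Number of replicate traces per condition (default 3).
#' @param noise_sd Additive Gaussian noise SD in signal units (fractional
#'   polarization/anisotropy; 5 mP = 0.005).
#' @param signal_type `"fp"` or `"anisotropy"`.
#' @param seed Integer seed (required).
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(mechanism = c("model1", "model2", "aging",
                                            "competition"),
                              params, protein_totals, substrate_totals,
                              competitor_totals = NULL, response,
                              time_grid = list(from = 0, to = 600, n = 120,
                                               spacing = "linear"),
                              replicates = 3, noise_sd = 0.005,
                              signal_type = c("fp", "anisotropy"),
                              seed) {
  mechanism <- match.arg(mechanism)
  signal_type <- match.arg(signal_type)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop_config("an integer seed is required")
  }
  if (!is.list(params) || is.null(names(params))) {
    stop_config("params must be a named list of rate constants")
  }
  needed <- mechanism_rate_names(mechanism)
  if (!all(needed %in% names(params))) {
    stop_config("mechanism ", mechanism, " needs parameters: ",
                paste(needed, collapse = ", "))
  }
  if (mechanism == "competition" && is.null(competitor_totals)) {
    stop_config("competition designs need competitor_totals")
  }
  n_cond <- length(protein_totals)
  if (any(protein_totals < 0)) stop_config("concentrations must be >= 0")
  substrate_totals <- rep_len(substrate_totals, n_cond)
  competitor_totals <- if (is.null(competitor_totals)) rep(0, n_cond)
                       else rep_len(competitor_totals, n_cond)
  stopifnot(inherits(response, "signal_response"))
  check_scalar_nonneg(noise_sd, "noise_sd")
  spacing <- time_grid$spacing %||% "linear"
  if (!spacing %in% c("linear", "log")) stop_config("spacing must be linear or log")
  if (spacing == "log" && time_grid$from <= 0) {
    stop_config("log time spacing needs from > 0")
  }
  structure(
    list(mechanism = mechanism, params = params,
         protein_totals = as.numeric(protein_totals),
         substrate_totals = as.numeric(substrate_totals),
         competitor_totals = as.numeric(competitor_totals),
         response = response, time_grid = time_grid,
         replicates = as.integer(replicates), noise_sd = noise_sd,
         signal_type = signal_type, seed = as.integer(seed)),
    class = "experiment_design")
}

design_times <- function(design) {
  tg <- design$time_grid
  if ((tg$spacing %||% "linear") == "log") {
    log_spaced(tg$from, tg$to, tg$n)
  } else {
    seq(tg$from, tg$to, length.out = tg$n)
  }
}

rate_params_object <- function(mechanism, params) {
  switch(mechanism,
    model1 = rate_parameters_model1(params$kapp),
    model2 = rate_parameters_model2(params$k1, params$k_minus1, params$k2),
    aging = rate_parameters_aging(params$kapp, params$k3),
    competition = rate_parameters_competition(params$kapp_S, params$kapp_I))
}

simulate_design_condition <- function(design, i, times) {
  rp <- rate_params_object(design$mechanism, design$params)
  p0 <- design$protein_totals[i]
  s0 <- design$substrate_totals[i]
  i0 <- design$competitor_totals[i]
  switch(design$mechanism,
    model1 = simulate_model1(rp, p0, s0, times),
    model2 = simulate_model2(rp, p0, s0, times),
    aging = simulate_aging(rp, p0, s0, times),
    competition = simulate_competition(rp, p0, s0, i0, times))
}

#' Generate a synthetic kinetic dataset
#'
#' Simulates the designed mechanism for every concentration condition,
#' projects the species trajectories onto the FP/anisotropy observable
#' (applying dead-time truncation and delay), and adds i.i.d. Gaussian
#' noise per point independently for each replicate. Deterministic for a
#' given design (the design's seed is the only randomness source).
#'
#' @param design An [experiment_design()].
#' @return A list of class `kinetic_dataset` with `traces` (list of
#'   [kinetic_trace()], replicates nested within conditions) and `truth`
#'   (the generating design, parameters and noiseless signals).
#' @export
generate_kinetic_dataset <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  times <- design_times(design)
  n_cond <- length(design$protein_totals)
  clean <- vector("list", n_cond)
  for (i in seq_len(n_cond)) {
    traj <- simulate_design_condition(design, i, times)
    clean[[i]] <- project_signal(traj, design$response,
                                 substrate_total = design$substrate_totals[i],
                                 signal_type = design$signal_type)
  }
  set.seed(design$seed)
  traces <- list()
  k <- 0L
  for (i in seq_len(n_cond)) {
    for (r in seq_len(design$replicates)) {
      tr <- clean[[i]]
      tr$signal <- tr$signal + stats::rnorm(length(tr$signal),
                                            sd = design$noise_sd)
      tr$replicate_id <- r
      k <- k + 1L
      traces[[k]] <- tr
    }
  }
  structure(list(traces = traces,
                 truth = list(mechanism = design$mechanism,
                              params = design$params,
                              response = design$response,
                              noiseless = clean, design = design)),
            class = "kinetic_dataset")
}

#' Generate a synthetic direct-binding isotherm dataset
#'
#' Evaluates the single-site isotherm at the designed protein
#' concentrations, replicates it, and adds Gaussian FP noise. The
#' optional anchor pseudo-point (the FP of the fully bound probe assigned
#' to a huge nominal protein concentration) is attached noiselessly, as
#' in the bench protocol.
#'
#' @param kd True dissociation constant, molar.
#' @param fp_min,fp_max True plateaus (fractional FP).
#' @param probe_total Probe concentration, molar.
#' @param protein_concentrations Titration grid, molar (may include 0).
#' @param noise_sd Gaussian FP noise SD (fractional; 2 mP = 0.002).
#' @param replicates Replicates per concentration (default 3).
#' @param anchor_concentration Optional anchor concentration (e.g. 0.005);
#'   `NULL` for no anchor.
#' @param seed Integer seed.
#' @return List of class `isotherm_dataset` with `data` (an
#'   [isotherm_data()]) and `truth`.
#' @export
generate_isotherm_dataset <- function(kd, fp_min, fp_max, probe_total,
                                      protein_concentrations,
                                      noise_sd = 0.002, replicates = 3,
                                      anchor_concentration = NULL, seed) {
  check_scalar_positive(kd, "kd")
  if (!length(protein_concentrations)) stop_config("empty concentration grid")
  if (missing(seed)) stop_config("an integer seed is required")
  conc <- rep(protein_concentrations, each = replicates)
  clean <- isotherm_predict(kd, fp_min, fp_max, conc)
  set.seed(seed)
  fp <- clean + stats::rnorm(length(clean), sd = noise_sd)
  anchor <- if (!is.null(anchor_concentration)) {
    list(concentration = anchor_concentration, fp = fp_max)
  }
  data <- isotherm_data(conc, fp, probe_total, anchor_point = anchor)
  structure(list(data = data,
                 truth = list(kd = kd, fp_min = fp_min, fp_max = fp_max,
                              probe_total = probe_total,
                              noise_sd = noise_sd, replicates = replicates,
                              anchor_concentration = anchor_concentration,
                              seed = seed, noiseless = clean)),
            class = "isotherm_dataset")
}

#' Generate a synthetic FP competition titration
#'
#' Computes the exact two-ligand competitive equilibrium at each
#' competitor concentration, maps the probe-bound fraction to FP between
#' the free-dye and bound-dye plateaus, replicates, and adds Gaussian
#' noise. Warns when the designed competitor grid does not span the
#' transition around the truth I50.
#'
#' @param protein_total,probe_total,probe_kd Assay concentrations, molar.
#' @param competitor_kd True competitor dissociation constant, molar.
#' @param competitor_concentrations Titration grid, molar, > 0.
#' @param fp_free,fp_bound FP of free and fully bound probe (fractional).
#' @param noise_sd Gaussian FP noise SD (fractional; 3 mP = 0.003).
#' @param replicates Replicates per concentration (default 3).
#' @param seed Integer seed.
#' @return List of class `competition_dataset` with `concentrations`,
#'   `fp_values`, `replicate`, and `truth`.
#' @export
generate_competition_dataset <- function(protein_total, probe_total, probe_kd,
                                         competitor_kd,
                                         competitor_concentrations,
                                         fp_free, fp_bound,
                                         noise_sd = 0.003, replicates = 3,
                                         seed) {
  if (missing(seed)) stop_config("an integer seed is required")
  if (any(competitor_concentrations <= 0)) {
    stop_config("competitor concentrations must be > 0")
  }
  if (is.finite(competitor_kd)) {
    i50_truth <- kd_to_i50(competitor_kd, protein_total, probe_total, probe_kd)
    if (i50_truth < min(competitor_concentrations) ||
        i50_truth > max(competitor_concentrations)) {
      warning("competitor grid does not span the transition (truth I50 = ",
              signif(i50_truth, 3), " M)")
    }
  }
  bound <- vapply(competitor_concentrations, function(i0) {
    probe_bound_fraction_at(protein_total, probe_total, probe_kd, i0,
                            competitor_kd)
  }, numeric(1))
  clean <- fp_free + (fp_bound - fp_free) * bound
  conc <- rep(competitor_concentrations, each = replicates)
  clean_rep <- rep(clean, each = replicates)
  set.seed(seed)
  fp <- clean_rep + stats::rnorm(length(clean_rep), sd = noise_sd)
  structure(list(concentrations = conc, fp_values = fp,
                 replicate = rep(seq_len(replicates),
                                 times = length(competitor_concentrations)),
                 truth = list(protein_total = protein_total,
                              probe_total = probe_total, probe_kd = probe_kd,
                              competitor_kd = competitor_kd,
                              fp_free = fp_free, fp_bound = fp_bound,
                              noise_sd = noise_sd, replicates = replicates,
                              seed = seed, noiseless = clean)),
            class = "competition_dataset")
}
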