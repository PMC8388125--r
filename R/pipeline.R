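# Pipeline orchestration: validated run configurations and the three
# commands (simulate, fit, recover) used from R or from the thin
# command-line wrapper in inst/cli/slpkin.R. Every command is
# deterministic given config + seed, and every report embeds the config
# hash and the seeds used.

config_keys <- list(
  simulate = c("design", "output_dir"),
  fit = c("bundle", "trace_csvs", "mechanism", "free", "fixed",
          "fit_substrate_scale", "n_starts", "seed", "monte_carlo",
          "temperature", "output_dir"),
  recover = c("design", "mechanism", "free", "fixed", "n_seeds", "seed",
              "n_starts", "output_dir")
)

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Validate a run configuration
#'
#' Checks a configuration list (or JSON file) against the schema of one
#' of the pipeline commands; unknown keys are rejected so typos fail
#' loudly instead of silently using defaults.
#'
#' @param config A named list, or the path of a JSON file holding one.
#' @param command `"simulate"`, `"fit"`, or `"recover"`.
#' @return The validated configuration list, invisibly augmented with
#'   its hash in `attr(, "hash")`.
#' @export
validate_run_config <- function(config,
                                command = c("simulate", "fit", "recover")) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    config <- as.list(read_json_file(config, "config file"))
  }
  if (!is.list(config)) stop_config("config must be a named list or JSON path")
  known <- config_keys[[command]]
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_config("unknown config field(s) for '", command, "': ",
                paste(unknown, collapse = ", "))
  }
  if (command %in% c("simulate", "recover") && is.null(config$design)) {
    stop_config("config field 'design' is required")
  }
  if (command == "fit") {
    if (is.null(config$bundle) && is.null(config$trace_csvs)) {
      stop_config("config needs 'bundle' or 'trace_csvs'")
    }
    if (is.null(config$mechanism)) stop_config("config field 'mechanism' is required")
  }
  attr(config, "hash") <- config_hash(config)
  invisible(config)
}

as_design <- function(x) {
  if (inherits(x, "experiment_design")) x else design_from_list(as.list(x))
}

#' Simulate a synthetic experiment and write it as a fixture bundle
#'
#' @param config Configuration list (or JSON path) with fields `design`
#'   (an [experiment_design()] or its list form) and `output_dir`.
#' @return The bundle directory, invisibly. Prints a short truth summary.
#' @export
run_simulate <- function(config) {
  config <- validate_run_config(config, "simulate")
  design <- as_design(config$design)
  out <- config$output_dir %||% stop_config("config field 'output_dir' is required")
  dataset <- generate_kinetic_dataset(design)
  write_fixture_bundle(dataset, out)
  cat(sprintf("simulated %d traces (%s mechanism, seed %d) -> %s\n",
              length(dataset$traces), design$mechanism, design$seed, out))
  cat("truth:", paste(sprintf("%s = %.6g", names(design$params),
                              unlist(design$params)), collapse = ", "), "\n")
  invisible(out)
}

#' Fit a mechanism to a bundle or trace files and write reports
#'
#' Reads a fixture bundle (or loose trace CSVs with JSON sidecars), runs
#' [fit_global()] (plus [monte_carlo_ci()] when configured), and writes
#' `report.json` and a human-readable `report.tsv` to `output_dir`,
#' including the derived dissociation constant, apparent rate constant
#' and binding free energy where the mechanism defines them.
#'
#' @param config Configuration list (or JSON path); see
#'   [validate_run_config()] for the schema.
#' @return The fit (`slp_fit`), invisibly.
#' @export
run_fit <- function(config) {
  config <- validate_run_config(config, "fit")
  traces <- if (!is.null(config$bundle)) {
    ds <- read_fixture_bundle(config$bundle)
    if (!inherits(ds, "kinetic_dataset")) {
      stop_config("bundle does not contain kinetic traces")
    }
    ds$traces
  } else {
    lapply(config$trace_csvs, read_trace)
  }
  fit <- fit_global(traces, mechanism = config$mechanism,
                    free = config$free,
                    fixed = as.list(config$fixed %||% list()),
                    fit_substrate_scale = isTRUE(config$fit_substrate_scale),
                    n_starts = config$n_starts %||% 5,
                    seed = config$seed %||% 1)
  if (!is.null(config$monte_carlo)) {
    mc <- config$monte_carlo
    fit <- monte_carlo_ci(fit, n_iterations = mc$n %||% 1000,
                          discard_fraction = mc$discard_fraction %||% 0.05,
                          seed = mc$seed %||% (config$seed %||% 1))
  }
  temperature <- config$temperature %||% 310.15
  derived <- derived_rates(fit)
  report <- list(
    mechanism = fit$mechanism,
    estimates = as.list(fit$estimates),
    sd = as.list(fit$sd),
    ci = apply(fit$ci, 1, function(r) list(lower = r[[1]], upper = r[[2]])),
    rss = fit$rss,
    convergence = fit$convergence,
    identifiability = fit$identifiability,
    derived = if (length(derived)) {
      list(kd_M = unname(derived["kd"]),
           kapp_M_per_s = unname(derived["kapp"]),
           binding_energy_kJ_mol = binding_energy(unname(derived["kd"]),
                                                  temperature),
           temperature_K = temperature)
    },
    monte_carlo = if (!is.null(fit$mc)) {
      fit$mc[c("n_requested", "n_kept", "fail_rate", "discard_fraction", "seed")]
    },
    seeds = list(fit = fit$options$seed),
    tolerances = list(rtol = fit$options$rtol, atol = fit$options$atol),
    package_version = as.character(utils::packageVersion("slpkin")),
    config_hash = attr(config, "hash"))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_json_file(report, file.path(config$output_dir, "report.json"))
    tab <- data.frame(parameter = names(fit$estimates),
                      estimate = fit$estimates, sd = fit$sd,
                      ci_lower = fit$ci[, "lower"], ci_upper = fit$ci[, "upper"])
    utils::write.table(format(tab, digits = 6),
                       file.path(config$output_dir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (i in seq_along(fit$residuals)) {
      utils::write.csv(
        data.frame(time_s = fit$traces[[i]]$times,
                   residual = fit$residuals[[i]]),
        file.path(config$output_dir, sprintf("residuals_%03d.csv", i)),
        row.names = FALSE)
    }
  }
  invisible(fit)
}

#' Parameter-recovery study: generate, fit, summarize over many seeds
#'
#' Repeats generate-then-fit over `n_seeds` child seeds of the design and
#' tabulates, per free parameter: the median estimate, the median
#' relative error against the generating truth, and the fraction of runs
#' whose (linearized) 95% CI covered the truth.
#'
#' @param config Configuration list with `design`, optional `mechanism`
#'   (defaults to the design's), `free`/`fixed`/`n_starts` fit options,
#'   `n_seeds` (default 20), and `seed` for the child-seed stream
#'   (default: the design seed).
#' @return A data frame with one row per recovered parameter and
#'   attributes `estimates` (the per-seed estimate matrix) and
#'   `config_hash`.
#' @export
run_recover <- function(config) {
  config <- validate_run_config(config, "recover")
  design <- as_design(config$design)
  mechanism <- config$mechanism %||% design$mechanism
  n_seeds <- config$n_seeds %||% 20
  seeds <- child_seeds(config$seed %||% design$seed, n_seeds)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    d <- design
    d$seed <- seeds[i]
    ds <- generate_kinetic_dataset(d)
    fit <- fit_global(ds$traces, mechanism = mechanism,
                      free = config$free,
                      fixed = as.list(config$fixed %||% list()),
                      n_starts = config$n_starts %||% 3, seed = seeds[i])
    rows[[i]] <- fit
  }
  params <- rows[[1]]$free_names
  truth <- unlist(design$params)[intersect(names(design$params), params)]
  if ("r_bound" %in% params) {
    truth <- c(truth, r_bound = design$response$r_bound)
  }
  est <- t(vapply(rows, function(f) f$estimates[params],
                  numeric(length(params))))
  colnames(est) <- params
  summary <- do.call(rbind, lapply(params, function(nm) {
    tv <- if (nm %in% names(truth)) truth[[nm]] else NA_real_
    cover <- if (is.na(tv)) NA_real_ else {
      mean(vapply(rows, function(f) {
        f$ci[nm, "lower"] <= tv && tv <= f$ci[nm, "upper"]
      }, logical(1)))
    }
    data.frame(parameter = nm, truth = tv,
               median_estimate = stats::median(est[, nm]),
               median_rel_error = if (is.na(tv)) NA_real_ else
                 stats::median(abs(est[, nm] - tv) / tv),
               ci_coverage = cover)
  }))
  attr(summary, "estimates") <- est
  attr(summary, "config_hash") <- attr(config, "hash")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(format(summary, digits = 6),
                       file.path(config$output_dir, "recovery.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary
}
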