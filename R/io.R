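# Fixture-bundle I/O: plain-text, lossless round trip of generated data
# together with the generating truth and design. Layout:
#   manifest.json                 schema version + dataset kind
#   design.json / truth.json      generator recipe and generating truth
#   traces/trace_###.csv (+.json) time_s,signal per trace + metadata sidecar
#   isotherm.csv / competition.csv for titration datasets

BUNDLE_SCHEMA_VERSION <- 1L

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_json_file <- function(path, what) {
  if (!file.exists(path)) {
    stop_config("malformed bundle: missing ", what, " (", basename(path), ")")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

response_to_list <- function(r) {
  list(r_free = r$r_free, r_bound = r$r_bound, r_bound_b = r$r_bound_b,
       offset = r$offset, dead_time = r$dead_time, delay = r$delay,
       intensity_weights = r$intensity_weights)
}

response_from_list <- function(l) {
  signal_response(r_free = l$r_free, r_bound = l$r_bound,
                  r_bound_b = l$r_bound_b %||% l$r_bound,
                  offset = l$offset %||% 0, dead_time = l$dead_time %||% 0,
                  delay = l$delay %||% 0,
                  intensity_weights = l$intensity_weights)
}

design_to_list <- function(d) {
  list(mechanism = d$mechanism, params = d$params,
       protein_totals = d$protein_totals,
       substrate_totals = d$substrate_totals,
       competitor_totals = d$competitor_totals,
       response = response_to_list(d$response),
       time_grid = d$time_grid, replicates = d$replicates,
       noise_sd = d$noise_sd, signal_type = d$signal_type, seed = d$seed)
}

design_from_list <- function(l) {
  experiment_design(
    mechanism = l$mechanism, params = as.list(l$params),
    protein_totals = l$protein_totals,
    substrate_totals = l$substrate_totals,
    competitor_totals = l$competitor_totals,
    response = response_from_list(l$response),
    time_grid = as.list(l$time_grid), replicates = l$replicates,
    noise_sd = l$noise_sd, signal_type = l$signal_type, seed = l$seed)
}

write_trace_files <- function(trace, dir, stem) {
  mP <- identical(trace$io_unit, "mP")
  df <- data.frame(time_s = trace$times,
                   signal = if (mP) 1000 * trace$signal else trace$signal)
  names(df)[2] <- if (mP) "signal_mP" else "signal"
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                   file.path(dir, paste0(stem, ".csv")),
                   row.names = FALSE, quote = FALSE)
  write_json_file(
    list(protein_total_M = trace$protein_total,
         substrate_total_M = trace$substrate_total,
         competitor_total_M = trace$competitor_total,
         signal_type = trace$signal_type,
         replicate_id = trace$replicate_id,
         unit = trace$io_unit),
    file.path(dir, paste0(stem, ".json")))
}

#' Read one kinetic trace from its CSV + JSON sidecar
#'
#' @param csv_path Path to a `time_s,signal` (or `signal_mP`) CSV; the
#'   metadata sidecar is the same path with a `.json` extension.
#' @return A [kinetic_trace()] with the signal in fractional units and
#'   the original I/O unit recorded in `io_unit`.
#' @export
read_trace <- function(csv_path) {
  if (!file.exists(csv_path)) stop_config("no such trace file: ", csv_path)
  side <- read_json_file(sub("\\.csv$", ".json", csv_path),
                         "trace metadata sidecar")
  for (fld in c("protein_total_M", "substrate_total_M", "signal_type")) {
    if (is.null(side[[fld]])) {
      stop_config("malformed bundle: sidecar lacks field ", fld)
    }
  }
  df <- utils::read.csv(csv_path)
  if (!"time_s" %in% names(df)) stop_config("trace CSV lacks time_s column")
  mP <- "signal_mP" %in% names(df)
  if (!mP && !"signal" %in% names(df)) {
    stop_config("trace CSV lacks signal/signal_mP column")
  }
  sig <- if (mP) df$signal_mP / 1000 else df$signal
  kinetic_trace(times = df$time_s, signal = sig,
                protein_total = side$protein_total_M,
                substrate_total = side$substrate_total_M,
                competitor_total = side$competitor_total_M %||% 0,
                signal_type = side$signal_type,
                replicate_id = side$replicate_id %||% 1L,
                io_unit = if (mP) "mP" else "fraction")
}

#' Write a generated dataset as a plain-text fixture bundle
#'
#' Serializes a dataset from the generators (kinetic, isotherm or
#' competition) to a directory of CSV files plus JSON sidecars holding
#' the design, the generating truth and a schema-versioned manifest.
#' [read_fixture_bundle()] restores it losslessly.
#'
#' @param dataset A `kinetic_dataset`, `isotherm_dataset` or
#'   `competition_dataset`.
#' @param directory Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  kind <- if (inherits(dataset, "kinetic_dataset")) "kinetic"
          else if (inherits(dataset, "isotherm_dataset")) "isotherm"
          else if (inherits(dataset, "competition_dataset")) "competition"
          else stop_config("unknown dataset type")
  write_json_file(list(schema_version = BUNDLE_SCHEMA_VERSION, kind = kind),
                  file.path(directory, "manifest.json"))
  if (kind == "kinetic") {
    tdir <- file.path(directory, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_along(dataset$traces)) {
      write_trace_files(dataset$traces[[i]], tdir, sprintf("trace_%03d", i))
    }
    write_json_file(design_to_list(dataset$truth$design),
                    file.path(directory, "design.json"))
    write_json_file(list(mechanism = dataset$truth$mechanism,
                         params = dataset$truth$params,
                         response = response_to_list(dataset$truth$response)),
                    file.path(directory, "truth.json"))
  } else if (kind == "isotherm") {
    d <- dataset$data
    df <- data.frame(concentration_M = d$protein_concentrations,
                     fp = d$fp_values,
                     replicate = rep_len(seq_len(dataset$truth$replicates),
                                         length(d$fp_values)))
    utils::write.csv(format(df, digits = 15, trim = TRUE),
                     file.path(directory, "isotherm.csv"),
                     row.names = FALSE, quote = FALSE)
    write_json_file(list(probe_total_M = d$probe_total,
                         anchor_point = d$anchor_point),
                    file.path(directory, "isotherm.json"))
    write_json_file(dataset$truth[setdiff(names(dataset$truth), "noiseless")],
                    file.path(directory, "truth.json"))
  } else {
    df <- data.frame(concentration_M = dataset$concentrations,
                     fp = dataset$fp_values, replicate = dataset$replicate)
    utils::write.csv(format(df, digits = 15, trim = TRUE),
                     file.path(directory, "competition.csv"),
                     row.names = FALSE, quote = FALSE)
    write_json_file(dataset$truth[setdiff(names(dataset$truth), "noiseless")],
                    file.path(directory, "truth.json"))
  }
  invisible(directory)
}

#' Read a fixture bundle back into a dataset
#'
#' @param directory A directory written by [write_fixture_bundle()].
#' @return The restored dataset, with the same class and contents as the
#'   object that was written (including the regenerated noiseless truth
#'   signals for kinetic bundles).
#' @export
read_fixture_bundle <- function(directory) {
  manifest <- read_json_file(file.path(directory, "manifest.json"), "manifest")
  if (is.null(manifest$schema_version) || manifest$schema_version > BUNDLE_SCHEMA_VERSION) {
    stop_config("malformed bundle: unsupported schema_version")
  }
  kind <- manifest$kind %||% stop_config("malformed bundle: manifest lacks kind")
  if (kind == "kinetic") {
    design <- design_from_list(
      read_json_file(file.path(directory, "design.json"), "design"))
    files <- sort(list.files(file.path(directory, "traces"),
                             pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop_config("malformed bundle: no trace files")
    traces <- lapply(files, read_trace)
    truth_raw <- read_json_file(file.path(directory, "truth.json"), "truth")
    # regenerate the noiseless signals from the stored design
    regen <- generate_kinetic_dataset(design)
    structure(list(traces = traces,
                   truth = list(mechanism = truth_raw$mechanism,
                                params = as.list(truth_raw$params),
                                response = response_from_list(truth_raw$response),
                                noiseless = regen$truth$noiseless,
                                design = design)),
              class = "kinetic_dataset")
  } else if (kind == "isotherm") {
    df <- utils::read.csv(file.path(directory, "isotherm.csv"))
    side <- read_json_file(file.path(directory, "isotherm.json"),
                           "isotherm metadata")
    truth <- read_json_file(file.path(directory, "truth.json"), "truth")
    anchor <- if (!is.null(side$anchor_point) &&
                  !is.null(side$anchor_point$concentration)) {
      list(concentration = side$anchor_point$concentration,
           fp = side$anchor_point$fp)
    }
    truth <- as.list(truth)
    truth$noiseless <- isotherm_predict(truth$kd, truth$fp_min, truth$fp_max,
                                        df$concentration_M)
    structure(list(data = isotherm_data(df$concentration_M, df$fp,
                                        side$probe_total_M,
                                        anchor_point = anchor),
                   truth = truth),
              class = "isotherm_dataset")
  } else if (kind == "competition") {
    df <- utils::read.csv(file.path(directory, "competition.csv"))
    truth <- as.list(read_json_file(file.path(directory, "truth.json"), "truth"))
    structure(list(concentrations = df$concentration_M, fp_values = df$fp,
                   replicate = df$replicate, truth = truth),
              class = "competition_dataset")
  } else {
    stop_config("malformed bundle: unknown kind '", kind, "'")
  }
}
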