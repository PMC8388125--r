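#' Fluorescence polarization from channel intensities
#'
#' Computes fluorescence polarization from the parallel and perpendicular
#' emission intensities, \deqn{FP = (I_\parallel - G I_\perp) /
#' (I_\parallel + G I_\perp),} where `G` is the instrument grating
#' (G-)factor correcting for the polarization bias of the detection path.
#'
#' @param i_parallel Emission intensity parallel to the excitation
#'   polarization (arbitrary units, >= 0).
#' @param i_perpendicular Emission intensity perpendicular to the excitation
#'   polarization (same units, >= 0).
#' @param grating_factor Instrument calibration factor `G` (dimensionless,
#'   default 1).
#' @return Fluorescence polarization, a dimensionless value in `[-1, 1]`.
#'   Multiply by 1000 for millipolarization (mP).
#' @examples
#' fp_from_intensities(3, 1)            # 0.5
#' fp_anisotropy_convert(0.5, "to_anisotropy")  # 0.4
#' @seealso [fp_anisotropy_convert()]
#' @export
fp_from_intensities <- function(i_parallel, i_perpendicular, grating_factor = 1) {
  if (any(i_parallel < 0) || any(i_perpendicular < 0)) {
    stop_config("intensities must be >= 0")
  }
  check_scalar_positive(grating_factor, "grating_factor")
  denom <- i_parallel + grating_factor * i_perpendicular
  if (any(denom == 0)) {
    stop_numeric("undefined signal: both intensities zero")
  }
  (i_parallel - grating_factor * i_perpendicular) / denom
}

#' Convert between fluorescence polarization and anisotropy
#'
#' Polarization P and anisotropy r describe the same emission ratio with
#' different perpendicular weights: `r = 2P / (3 - P)` and
#' `P = 3r / (2 + r)`. The round trip is an exact identity.
#'
#' @param value Polarization (in `[-1, 1]`) or anisotropy (in `[-0.5, 1]`)
#'   depending on `direction`. Vectorized.
#' @param direction `"to_anisotropy"` (input is FP) or `"to_fp"` (input is
#'   anisotropy).
#' @return Converted value(s).
#' @export
fp_anisotropy_convert <- function(value,
                                  direction = c("to_anisotropy", "to_fp")) {
  direction <- match.arg(direction)
  if (any(!is.finite(value))) stop_config("value must be finite")
  if (direction == "to_anisotropy") {
    if (any(value < -1 | value > 1)) {
      stop_config("polarization must lie in [-1, 1]")
    }
    2 * value / (3 - value)
  } else {
    if (any(value < -0.5 | value > 1)) {
      stop_config("anisotropy must lie in [-0.5, 1]")
    }
    3 * value / (2 + value)
  }
}

#' Signal-response model mapping bound state to FP/anisotropy
#'
#' Describes how species concentrations translate into the recorded signal:
#' free substrate emits `r_free`, any protein-bound or reacted substrate
#' species emits `r_bound` (the noncovalent complex and the covalent product
#' are assumed indistinguishable in FP), and nonfluorescent competitor
#' species contribute nothing. `dead_time` truncates points the instrument
#' cannot record after mixing; `delay` is a fixed clock offset between
#' mixing and the recorded time axis.
#'
#' @param r_free Signal of the unbound substrate (FP or anisotropy units,
#'   as a fraction; mP / 1000).
#' @param r_bound Signal of bound/reacted substrate.
#' @param r_bound_b Signal of the aged product state in the aging mechanism;
#'   defaults to `r_bound`.
#' @param offset Additive baseline, default 0.
#' @param dead_time Instrument dead time in seconds (points with reaction
#'   time < `dead_time` are dropped, not interpolated).
#' @param delay Fixed offset in seconds added to reaction times on output.
#' @param intensity_weights Optional named per-species relative intensity
#'   weights (default all 1): mole-fraction mixing is weighted by
#'   `w * conc` instead of `conc`. Intensity changes on binding are
#'   typically small for these probes, so the default is unweighted.
#' @return An object of class `signal_response`.
#' @export
signal_response <- function(r_free, r_bound, r_bound_b = r_bound,
                            offset = 0, dead_time = 0, delay = 0,
                            intensity_weights = NULL) {
  for (v in c(r_free, r_bound, r_bound_b, offset)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_config("signal responses must be single finite numbers")
    }
  }
  check_scalar_nonneg(dead_time, "dead_time")
  check_scalar_nonneg(delay, "delay")
  structure(
    list(r_free = r_free, r_bound = r_bound, r_bound_b = r_bound_b,
         offset = offset, dead_time = dead_time, delay = delay,
         intensity_weights = intensity_weights),
    class = "signal_response"
  )
}

#' One kinetic trace with its metadata
#'
#' Container for a single FP or anisotropy time course together with the
#' reactant concentrations of the well/shot it came from. Signals are held
#' internally as fractional polarization (or anisotropy); `io_unit`
#' records whether files for this trace are written/read as mP.
#'
#' @param times Observation times in seconds, strictly increasing.
#' @param signal FP or anisotropy values (fractional units).
#' @param protein_total,substrate_total,competitor_total Total
#'   concentrations in molar; competitor defaults to 0.
#' @param signal_type `"fp"` or `"anisotropy"`.
#' @param replicate_id Identifier of the replicate this trace belongs to.
#' @param io_unit `"fraction"` or `"mP"`; affects file I/O only.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, protein_total, substrate_total,
                          competitor_total = 0,
                          signal_type = c("fp", "anisotropy"),
                          replicate_id = 1L, io_unit = c("fraction", "mP")) {
  signal_type <- match.arg(signal_type)
  io_unit <- match.arg(io_unit)
  if (length(times) != length(signal)) {
    stop_config("times and signal must have equal length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_config("times must be strictly increasing")
  }
  if (any(!is.finite(signal))) stop_config("signal must be finite")
  check_scalar_nonneg(protein_total, "protein_total")
  check_scalar_nonneg(substrate_total, "substrate_total")
  check_scalar_nonneg(competitor_total, "competitor_total")
  structure(
    list(times = as.numeric(times), signal = as.numeric(signal),
         protein_total = protein_total, substrate_total = substrate_total,
         competitor_total = competitor_total, signal_type = signal_type,
         replicate_id = replicate_id, io_unit = io_unit),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(
    "<kinetic_trace> %d points, %.3g-%.3g s, %s; P=%.3g M, S=%.3g M%s (rep %s)\n",
    length(x$times), min(x$times), max(x$times), x$signal_type,
    x$protein_total, x$substrate_total,
    if (x$competitor_total > 0) sprintf(", I=%.3g M", x$competitor_total) else "",
    as.character(x$replicate_id)))
  invisible(x)
}

# Species columns that carry the bound-substrate signal, per mechanism.
bound_species <- function(mechanism) {
  switch(mechanism,
    model1      = "PS",
    model2      = c("PSi", "PS"),
    aging       = c("PSa", "PSb"),
    competition = "PS",
    stop_config("unknown mechanism: ", mechanism))
}

#' Project a species trajectory onto the FP/anisotropy observable
#'
#' Maps simulated species concentrations to the recorded signal by
#' mole-fraction weighting over the substrate pool:
#' `signal(t) = offset + r_free * [S]/S_tot + r_bound * [bound]/S_tot`,
#' where "bound" collects the noncovalent complex and covalent product (and
#' the aged product weighted by `r_bound_b` in the aging mechanism).
#' Competitor-derived species are nonfluorescent and contribute nothing.
#' Points with reaction time earlier than the instrument dead time are
#' dropped, and the remaining times are shifted by the fixed delay.
#'
#' @param trajectory A `species_trajectory` from one of the simulators.
#' @param response A [signal_response()].
#' @param substrate_total Total substrate (probe) concentration in molar;
#'   defaults to the trajectory's own total.
#' @param signal_type `"fp"` or `"anisotropy"` label for the output trace.
#' @param replicate_id Replicate label for the output trace.
#' @return A [kinetic_trace()] of noiseless model signal.
#' @export
project_signal <- function(trajectory, response,
                           substrate_total = trajectory$substrate_total,
                           signal_type = c("fp", "anisotropy"),
                           replicate_id = 1L) {
  signal_type <- match.arg(signal_type)
  stopifnot(inherits(trajectory, "species_trajectory"),
            inherits(response, "signal_response"))
  check_scalar_positive(substrate_total, "substrate_total")
  sp <- trajectory$species
  bnd <- bound_species(trajectory$mechanism)
  if (!all(c("S", bnd) %in% colnames(sp))) {
    stop_config("trajectory lacks species required by the response model")
  }
  w <- function(name) {
    iw <- response$intensity_weights
    if (is.null(iw) || is.null(iw[[name]])) 1 else iw[[name]]
  }
  r_of <- function(name) if (name == "PSb") response$r_bound_b else response$r_bound
  num <- w("S") * response$r_free * sp[, "S"]
  den <- w("S") * sp[, "S"]
  for (b in bnd) {
    num <- num + w(b) * r_of(b) * sp[, b]
    den <- den + w(b) * sp[, b]
  }
  # Unweighted mixing divides by the substrate pool; with intensity
  # weights the mixing becomes intensity-fraction weighting.
  sig <- if (is.null(response$intensity_weights)) {
    response$offset + num / substrate_total
  } else {
    response$offset + num / den
  }
  keep <- trajectory$times >= response$dead_time
  if (!any(keep)) stop_config("dead time removes every simulated point")
  kinetic_trace(
    times = trajectory$times[keep] + response$delay,
    signal = sig[keep],
    protein_total = trajectory$protein_total,
    substrate_total = substrate_total,
    competitor_total = trajectory$competitor_total %||% 0,
    signal_type = signal_type, replicate_id = replicate_id
  )
}
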