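# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("slpkin_config_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("slpkin_numeric_error", "error")))
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_config(name, " must be a single strictly positive finite number")
  }
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_config(name, " must be a single finite number >= 0")
  }
  invisible(x)
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)) ||
      any(times < 0)) {
    stop_config("times must be finite, nonnegative seconds")
  }
  if (is.unsorted(times)) stop_config("times must be nondecreasing")
  invisible(times)
}

# Derive a stream of child seeds from one user-facing seed; keeps every
# child below 2^31 so it is a valid R integer seed.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

log_spaced <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}
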