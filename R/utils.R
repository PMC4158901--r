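# Internal helpers shared across modules.

# Classed conditions so the CLI can map validation errors to exit status 2
# and computational failures to exit status 1.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("propcoloc_validation_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("propcoloc_numeric_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' Trapezoid integral of y over ordered grid x.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoid; returns vector of length(x), starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Deterministic sub-seed derivation (kept below .Machine$integer.max).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 16807 + 104729) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
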