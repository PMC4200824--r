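# Small shared helpers. Coordinates are 0-based half-open internally and
# converted to 1-based closed only when printing reports.

#' Harmonic-number constants used by diversity estimators
#'
#' `a_n = sum(1/i, i = 1..n-1)` and `b_n = sum(1/i^2, i = 1..n-1)` appear in
#' Watterson's theta and in the normalising constants of Tajima's D and
#' Fu and Li's D*.
#'
#' @param n sample size (number of sequences), `n >= 2`.
#' @return a numeric scalar.
#' @export
harmonic_a <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

#' @rdname harmonic_a
#' @export
harmonic_b <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1)^2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a reproducible child seed from a global seed and a stream index,
# kept inside the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647)
}

stop_user <- function(...) stop(sprintf(...), call. = FALSE)

is_flagged_undefined <- function(x) {
  is.na(x) && isTRUE(attr(x, "undefined"))
}

undefined_stat <- function(reason) {
  structure(NA_real_, undefined = TRUE, reason = reason)
}
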