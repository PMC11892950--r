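#' Derive a child seed from a parent seed
#'
#' All randomness in the package flows from one explicit integer seed. When a
#' routine needs several independent random streams (one per sample group, one
#' per replicate, ...), it derives child seeds with this function rather than
#' consuming the global RNG state, so every stage is reproducible in isolation.
#'
#' @param seed parent integer seed (non-negative, < 2^31).
#' @param index integer stream index (vectorised).
#' @return integer vector of child seeds in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed < 2^31)
  m <- 2147483647
  # Multipliers kept small enough that all intermediates are exact doubles.
  x <- ((seed %% m) * 69621 + (index %% m) * 7919 + 12345) %% m
  as.integer(x %% (m - 1) + 1)
}

#' Extract the off-diagonal lower-triangle vector of a square matrix
#' @param m square matrix.
#' @return numeric vector of m[i, j] for i > j.
#' @keywords internal
lower_vec <- function(m) m[lower.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @keywords internal
#' @noRd
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
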