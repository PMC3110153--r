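#' Derive a reproducible RNG substream seed
#'
#' Combines a master seed with a string label (and optionally an integer
#' index) into a 31-bit seed by polynomial string hashing. Used so that the
#' draws for one probe/chain do not depend on which other probes are present
#' or on scheduling order.
#'
#' @param seed master integer seed.
#' @param label character scalar (e.g. a probe identifier or stage name).
#' @param index optional non-negative integer (e.g. a chain number).
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, label, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime; products below stay exact in doubles
  h <- (seed %% m + m) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 131 + index + 1) %% m
  as.integer(h)
}

assert_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || (!allow_zero && x == min)) {
    abort(sprintf("`%s` must be %s %s.", name,
                  if (allow_zero) ">=" else ">", format(min)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
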