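#' Orthonormal polynomial basis of the phenotype
#'
#' Builds the degree-`degree` orthonormal polynomial regressors of a
#' covariate (here, average heat scores): the columns of the Q factor of the
#' Vandermonde matrix `[1, x, x^2, ...]`, i.e. Gram-Schmidt with unit-norm
#' columns. `P0` is the constant column; `P1` is a positive multiple of the
#' centered covariate; signs are fixed so every column's leading (highest
#' power) coefficient is positive, which makes "quadratic coefficient > 0"
#' mean a convex (U-shaped) trend downstream.
#'
#' @param x numeric covariate vector, length at least `degree + 1`, with at
#'   least `degree + 1` distinct values.
#' @param degree polynomial degree (default 2: linear + quadratic; 3 is
#'   available for compatibility with older third-order analyses).
#' @return an object of class `ortho_basis`: a list with `x`, `degree` and
#'   a numeric matrix `P` of `degree + 1` orthonormal columns
#'   `P0, P1, ..., P<degree>`.
#' @export
#' @examples
#' b <- build_basis(c(1, 2, 3))
#' round(crossprod(b$P), 12)  # identity
build_basis <- function(x, degree = 2L) {
  degree <- assert_count(degree, "degree", min = 1L)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric values.")
  }
  n <- length(x)
  if (n < degree + 1L) {
    abort(sprintf("need at least %d observations for degree %d.",
                  degree + 1L, degree))
  }
  if (length(unique(x)) < degree + 1L) {
    abort("degenerate design: fewer distinct covariate values than degree + 1.")
  }
  # scale to [-1, 1] before powering for numerical stability; the final
  # basis spans the same polynomial space (affine invariance)
  xs <- (x - mean(range(x))) / (diff(range(x)) / 2)
  V <- outer(xs, 0:degree, `^`)
  qrd <- qr(V)
  Q <- qr.Q(qrd)[, seq_len(degree + 1L), drop = FALSE]
  R <- qr.R(qrd)
  flip <- sign(diag(R))
  flip[flip == 0] <- 1
  Q <- sweep(Q, 2, flip, `*`)
  colnames(Q) <- paste0("P", 0:degree)
  structure(list(x = x, degree = degree, P = Q), class = "ortho_basis")
}

#' @export
print.ortho_basis <- function(x, ...) {
  cat(sprintf("<ortho_basis> degree %d over %d covariate values\n",
              x$degree, length(x$x)))
  invisible(x)
}

#' Basis columns as a tibble
#'
#' @param x an `ortho_basis`.
#' @param ... unused.
#' @return tibble with the covariate and one column per basis polynomial.
#' @exportS3Method generics::tidy
tidy.ortho_basis <- function(x, ...) {
  bind_cols(tibble(x = x$x), as_tibble(x$P))
}
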