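#' SCAD penalty specification
#'
#' @param lambda non-negative tuning parameter.
#' @param a SCAD shape constant, must exceed 2; default 3.7.
#' @param norm_matrices optional list of per-group symmetric positive-definite
#'   matrices defining generalized group norms `||theta_m||_{K_m}`; `NULL`
#'   (default) means the plain Euclidean norm.
#' @return Object of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda, a = 3.7, norm_matrices = NULL) {
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be non-negative")
  if (!is.finite(a) || a <= 2) stop("SCAD shape constant a must exceed 2")
  if (!is.null(norm_matrices)) {
    ok <- vapply(norm_matrices, function(K) {
      is.matrix(K) && isSymmetric(K) && all(eigen(K, TRUE, TRUE)$values > 0)
    }, logical(1))
    if (!all(ok)) stop("norm_matrices must be symmetric positive definite")
  }
  structure(list(lambda = lambda, a = a, norm_matrices = norm_matrices),
            class = "penalty_spec")
}

#' SCAD penalty derivative
#'
#' `p'_lambda(w) = lambda I(w <= lambda) + max(0, a lambda - w) I(w > lambda) / (a - 1)`:
#' flat at `lambda` near zero, linearly decaying, and exactly zero beyond
#' `a lambda`, which is what leaves large effects unshrunk.
#'
#' @param w non-negative scalar or vector of group-coefficient norms.
#' @param spec a [penalty_spec()].
#' @return Penalty derivative value(s), same length as `w`.
#' @export
scad_derivative <- function(w, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(w < 0)) stop("w must be non-negative")
  lambda <- spec$lambda
  a <- spec$a
  ifelse(w <= lambda, lambda, pmax(0, a * lambda - w) / (a - 1))
}

#' SCAD penalty function
#'
#' Antiderivative of [scad_derivative()] with `p_lambda(0) = 0`: equal to
#' `lambda * w` on `[0, lambda]`, quadratic on `(lambda, a*lambda]`, and
#' constant `(a + 1) lambda^2 / 2` beyond.
#'
#' @inheritParams scad_derivative
#' @return Penalty value(s).
#' @export
scad_penalty <- function(w, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(w < 0)) stop("w must be non-negative")
  lambda <- spec$lambda
  a <- spec$a
  out <- ifelse(
    w <= lambda,
    lambda * w,
    ifelse(
      w <= a * lambda,
      (2 * a * lambda * w - w^2 - lambda^2) / (2 * (a - 1)),
      (a + 1) * lambda^2 / 2
    )
  )
  as.numeric(out)
}

# Exact minimizer over s >= 0 of (s - nu)^2 / 2 + p_lambda(s): the SCAD
# "firm" threshold. Requires a > 2.
scad_firm <- function(nu, lambda, a) {
  if (lambda == 0) return(nu)
  if (nu <= 2 * lambda) {
    max(0, nu - lambda)
  } else if (nu <= a * lambda) {
    ((a - 1) * nu - a * lambda) / (a - 2)
  } else {
    nu
  }
}
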