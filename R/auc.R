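#' Per-group linear-model parameters
#'
#' Bundle of the two groups' coefficient vectors and error standard
#' deviations for the induced ROC model: `y_D = z' theta_D + sigma_D eps`
#' and `y_Dbar = z' theta_Dbar + sigma_Dbar eps`, with standard-normal
#' errors.
#'
#' @param theta_diseased,theta_nondiseased length-`d` coefficient vectors.
#' @param sigma_diseased,sigma_nondiseased positive error standard
#'   deviations.
#' @return An object of class `roc_model_parameters`.
#' @export
model_parameters <- function(theta_diseased, theta_nondiseased,
                             sigma_diseased, sigma_nondiseased) {
  theta_diseased <- as.numeric(theta_diseased)
  theta_nondiseased <- as.numeric(theta_nondiseased)
  if (length(theta_diseased) != length(theta_nondiseased)) {
    stop("theta vectors must have equal length")
  }
  if (!is.finite(sigma_diseased) || !is.finite(sigma_nondiseased) ||
      sigma_diseased <= 0 || sigma_nondiseased <= 0) {
    stop("sigma values must be strictly positive")
  }
  structure(
    list(theta_diseased = theta_diseased,
         theta_nondiseased = theta_nondiseased,
         sigma_diseased = sigma_diseased,
         sigma_nondiseased = sigma_nondiseased,
         d = length(theta_diseased)),
    class = "roc_model_parameters"
  )
}

#' @export
print.roc_model_parameters <- function(x, ...) {
  cat(sprintf("ROC regression parameters (d = %d)\n", x$d))
  cat("  theta_diseased:    ", paste(signif(x$theta_diseased, 4), collapse = " "), "\n")
  cat("  theta_nondiseased: ", paste(signif(x$theta_nondiseased, 4), collapse = " "), "\n")
  cat(sprintf("  sigma (diseased / non-diseased): %.4g / %.4g\n",
              x$sigma_diseased, x$sigma_nondiseased))
  invisible(x)
}

#' Covariate-specific AUC of the two-group Gaussian model
#'
#' Under per-group homoscedastic Gaussian linear models, the probability that
#' a diseased subject's test result exceeds a non-diseased subject's at
#' covariate profile `z0` is
#' \deqn{AUC(z_0) = \Phi\left(\frac{z_0^\top(\theta_D - \theta_{\bar D})}
#'   {\sqrt{\sigma_{\bar D}^2 + \sigma_D^2}}\right).}
#'
#' @param params a [model_parameters()] object.
#' @param z0 covariate profile, length `d`.
#' @param offset optional scalar added to the numerator of the probit
#'   argument; used to restore per-group response centers (the intercept
#'   difference diseased minus non-diseased) after fitting on centered data.
#' @return AUC value in (0, 1).
#' @export
auc_from_parameters <- function(params, z0, offset = 0) {
  stopifnot(inherits(params, "roc_model_parameters"))
  z0 <- as.numeric(z0)
  if (length(z0) != params$d) stop("z0 must have length d = ", params$d)
  u <- (sum(z0 * (params$theta_diseased - params$theta_nondiseased)) + offset) /
    sqrt(params$sigma_nondiseased^2 + params$sigma_diseased^2)
  stats::pnorm(u)
}

#' Gradient of the covariate-specific AUC in stacked coordinates
#'
#' Derivative of [auc_from_parameters()] with respect to the stacked
#' coefficient vector `theta = theta_Dbar (x) (1,0)' + theta_D (x) (0,1)'`
#' (non-diseased coefficient of covariate m in position `2m - 1`, diseased in
#' position `2m`):
#' \deqn{\partial\mu/\partial\theta = \phi(u)\, (z_0 \otimes (-1, 1)^\top) /
#'   \sqrt{\sigma_{\bar D}^2 + \sigma_D^2}.}
#'
#' @inheritParams auc_from_parameters
#' @return Numeric vector of length `2d`.
#' @export
auc_gradient <- function(params, z0, offset = 0) {
  stopifnot(inherits(params, "roc_model_parameters"))
  z0 <- as.numeric(z0)
  if (length(z0) != params$d) stop("z0 must have length d = ", params$d)
  s <- sqrt(params$sigma_nondiseased^2 + params$sigma_diseased^2)
  u <- (sum(z0 * (params$theta_diseased - params$theta_nondiseased)) + offset) / s
  as.vector(stats::dnorm(u) * rbind(-z0, z0) / s)
}

#' Focus specification: the AUC at one covariate profile
#'
#' Packages the focus functional of the FIC — the AUC at a profile `z0` —
#' together with its value and gradient at given parameters.
#'
#' @inheritParams auc_from_parameters
#' @return Object of class `focus_spec` with fields `z0`, `focus_value`,
#'   `gradient` (length `2d`, stacked coordinates), and `offset`.
#' @export
focus_spec <- function(params, z0, offset = 0) {
  structure(
    list(z0 = as.numeric(z0),
         focus_value = auc_from_parameters(params, z0, offset),
         gradient = auc_gradient(params, z0, offset),
         offset = offset),
    class = "focus_spec"
  )
}

#' Stack and unstack per-group coefficient vectors
#'
#' The fused design interleaves the two groups' coefficients so that
#' covariate `m` owns the consecutive column pair `(2m - 1, 2m)` =
#' (non-diseased, diseased). These helpers convert between the per-group and
#' stacked layouts.
#'
#' @param theta_nondiseased,theta_diseased length-`d` vectors.
#' @return `stack_coefficients()` returns the length-`2d` interleaved vector;
#'   `unstack_coefficients()` returns a list with elements
#'   `theta_nondiseased` and `theta_diseased`.
#' @export
stack_coefficients <- function(theta_nondiseased, theta_diseased) {
  stopifnot(length(theta_nondiseased) == length(theta_diseased))
  as.vector(rbind(theta_nondiseased, theta_diseased))
}

#' @rdname stack_coefficients
#' @param theta length-`2d` stacked coefficient vector.
#' @export
unstack_coefficients <- function(theta) {
  stopifnot(length(theta) %% 2 == 0)
  d <- length(theta) / 2
  list(theta_nondiseased = theta[2 * seq_len(d) - 1],
       theta_diseased = theta[2 * seq_len(d)])
}
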