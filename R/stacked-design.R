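#' Fuse the two group regressions into one stacked weighted design
#'
#' Builds the single weighted least-squares problem whose solution equals the
#' two per-group fits: responses are concatenated (non-diseased first), and
#' each covariate row is embedded by a Kronecker product so that covariate
#' `m` occupies the column pair `(2m - 1, 2m)` — non-diseased rows touch only
#' the odd column of the pair, diseased rows only the even one. Row weights
#' are the inverse group error variances, so unequal group variances are
#' handled by weighting.
#'
#' @param sample a centered [two_group_sample()].
#' @param sigma_nondiseased,sigma_diseased positive error standard deviations
#'   used to form the weights `1/sigma^2`.
#' @return Object of class `stacked_design` with fields `response` (length
#'   `n`), `design` (`n x 2d`), `weights`, `groups` (list of `d` column-index
#'   pairs), `transformed` (FALSE), and bookkeeping sizes.
#' @export
build_stacked_design <- function(sample, sigma_nondiseased, sigma_diseased) {
  stopifnot(inherits(sample, "two_group_sample"))
  if (!isTRUE(sample$centered)) stop("sample must be centered first")
  if (sigma_nondiseased <= 0 || sigma_diseased <= 0) {
    stop("sigma values must be strictly positive")
  }
  d <- sample$d
  n_nd <- sample$n_nondiseased
  n_d <- sample$n_diseased
  n <- n_nd + n_d
  Z <- matrix(0, n, 2 * d)
  odd <- 2 * seq_len(d) - 1
  Z[seq_len(n_nd), odd] <- sample$z_nondiseased
  Z[n_nd + seq_len(n_d), odd + 1] <- sample$z_diseased
  structure(
    list(
      response = c(sample$y_nondiseased, sample$y_diseased),
      design = Z,
      weights = c(rep(sigma_nondiseased^-2, n_nd), rep(sigma_diseased^-2, n_d)),
      groups = lapply(seq_len(d), function(m) c(2 * m - 1, 2 * m)),
      transformed = FALSE,
      n_nondiseased = n_nd,
      n_diseased = n_d,
      n = n,
      d = d
    ),
    class = "stacked_design"
  )
}

#' Absorb the weights into the stacked design
#'
#' Scales each row of the response and design by the square root of its
#' weight, so ordinary (unweighted) least squares and group-penalized fits on
#' the transformed data equal their weighted counterparts on the original.
#'
#' @param design an untransformed [build_stacked_design()] result.
#' @return The design with `response` and `design` rescaled and
#'   `transformed = TRUE`.
#' @export
apply_weights <- function(design) {
  stopifnot(inherits(design, "stacked_design"))
  if (isTRUE(design$transformed)) stop("design is already transformed")
  sw <- sqrt(design$weights)
  design$response <- design$response * sw
  design$design <- design$design * sw
  design$transformed <- TRUE
  design
}

#' @export
print.stacked_design <- function(x, ...) {
  cat("Stacked two-group design\n")
  cat(sprintf("  n = %d (%d non-diseased + %d diseased), d = %d factor groups (2 columns each)\n",
              x$n, x$n_nondiseased, x$n_diseased, x$d))
  cat(sprintf("  weights absorbed: %s\n", x$transformed))
  invisible(x)
}

#' Penalized objective of the fused problem
#'
#' Evaluates `||Y - Z theta||^2 / (2n) + sum_m p_lambda(||theta_m||_{K_m})`
#' on a transformed stacked design — the single-objective form of the two
#' weighted per-group sums of squares plus a group penalty.
#'
#' @param design a transformed `stacked_design`.
#' @param theta stacked coefficient vector, length `2d`.
#' @param spec a [penalty_spec()]; its `norm_matrices` (if any) define the
#'   per-group norms, otherwise the plain Euclidean norm is used.
#' @param penalized logical vector (length `d`) marking which groups are
#'   penalized; defaults to all.
#' @return Scalar objective value.
#' @export
penalized_objective <- function(design, theta, spec,
                                penalized = rep(TRUE, design$d)) {
  stopifnot(inherits(design, "stacked_design"), isTRUE(design$transformed))
  r <- design$response - as.vector(design$design %*% theta)
  pen <- 0
  for (m in seq_len(design$d)) {
    if (!penalized[m]) next
    tm <- theta[design$groups[[m]]]
    w <- if (is.null(spec$norm_matrices)) {
      sqrt(sum(tm^2))
    } else {
      sqrt(drop(crossprod(tm, spec$norm_matrices[[m]] %*% tm)))
    }
    pen <- pen + scad_penalty(w, spec)
  }
  sum(r^2) / (2 * design$n) + pen
}

#' Two-sum weighted objective on the original per-group data
#'
#' The same penalized criterion written as two per-group residual sums of
#' squares, each divided by its error variance; equals
#' [penalized_objective()] on the transformed stacked design at the stacked
#' coefficients. Mainly useful for verification.
#'
#' @param sample a centered [two_group_sample()].
#' @param theta_nondiseased,theta_diseased per-group coefficient vectors.
#' @param sigma_nondiseased,sigma_diseased error standard deviations.
#' @param spec a [penalty_spec()].
#' @return Scalar objective value.
#' @export
two_sum_objective <- function(sample, theta_nondiseased, theta_diseased,
                              sigma_nondiseased, sigma_diseased, spec) {
  stopifnot(inherits(sample, "two_group_sample"))
  n <- sample$n_nondiseased + sample$n_diseased
  r_nd <- sample$y_nondiseased -
    as.vector(sample$z_nondiseased %*% theta_nondiseased)
  r_d <- sample$y_diseased - as.vector(sample$z_diseased %*% theta_diseased)
  rss <- sum(r_nd^2) / sigma_nondiseased^2 + sum(r_d^2) / sigma_diseased^2
  pen <- 0
  for (m in seq_len(sample$d)) {
    tm <- c(theta_nondiseased[m], theta_diseased[m])
    w <- if (is.null(spec$norm_matrices)) {
      sqrt(sum(tm^2))
    } else {
      sqrt(drop(crossprod(tm, spec$norm_matrices[[m]] %*% tm)))
    }
    pen <- pen + scad_penalty(w, spec)
  }
  rss / (2 * n) + pen
}
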