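#' Two-group diagnostic test data
#'
#' Container for continuous test results measured on diseased and
#' non-diseased subjects together with their covariates. This is the raw
#' input to the induced ROC regression: a homoscedastic Gaussian linear
#' model is fitted within each group and the covariate-specific ROC/AUC is
#' derived from the two fits.
#'
#' @param y_nondiseased numeric vector of test results for the non-diseased
#'   group.
#' @param y_diseased numeric vector of test results for the diseased group.
#' @param z_nondiseased numeric matrix (rows = non-diseased subjects) of
#'   covariates; must have the same number of columns as `z_diseased`.
#' @param z_diseased numeric matrix of covariates for the diseased group.
#' @param centered logical; `TRUE` once responses (per group) and covariates
#'   (pooled) have been mean-centered. See [center_two_group()].
#' @param response_centers named numeric pair, the per-group response means
#'   removed by centering.
#' @param covariate_centers length-`d` numeric vector of pooled covariate
#'   means removed by centering.
#'
#' @return An object of class `two_group_sample` with fields as above plus
#'   `n_nondiseased`, `n_diseased`, and `d`.
#' @seealso [center_two_group()], [estimate_group_variances()],
#'   [build_stacked_design()]
#' @export
two_group_sample <- function(y_nondiseased, y_diseased, z_nondiseased,
                             z_diseased, centered = FALSE,
                             response_centers = c(nondiseased = 0, diseased = 0),
                             covariate_centers = NULL) {
  y_nondiseased <- as.numeric(y_nondiseased)
  y_diseased <- as.numeric(y_diseased)
  z_nondiseased <- as.matrix(z_nondiseased)
  z_diseased <- as.matrix(z_diseased)
  storage.mode(z_nondiseased) <- "double"
  storage.mode(z_diseased) <- "double"
  if (ncol(z_nondiseased) != ncol(z_diseased)) {
    stop("covariate matrices must have the same number of columns (d)")
  }
  if (length(y_nondiseased) != nrow(z_nondiseased) ||
      length(y_diseased) != nrow(z_diseased)) {
    stop("response length must match covariate row count in each group")
  }
  if (length(y_nondiseased) < 1L || length(y_diseased) < 1L) {
    stop("each group must contain at least one observation")
  }
  if (anyNA(y_nondiseased) || anyNA(y_diseased) ||
      anyNA(z_nondiseased) || anyNA(z_diseased)) {
    stop("missing values are not allowed")
  }
  d <- ncol(z_nondiseased)
  if (is.null(covariate_centers)) covariate_centers <- numeric(d)
  obj <- structure(
    list(
      y_nondiseased = y_nondiseased,
      y_diseased = y_diseased,
      z_nondiseased = z_nondiseased,
      z_diseased = z_diseased,
      centered = isTRUE(centered),
      response_centers = response_centers,
      covariate_centers = covariate_centers,
      n_nondiseased = length(y_nondiseased),
      n_diseased = length(y_diseased),
      d = d
    ),
    class = "two_group_sample"
  )
  obj
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat("Two-group test-result sample\n")
  cat(sprintf("  non-diseased: n = %d, diseased: n = %d, covariates: d = %d\n",
              x$n_nondiseased, x$n_diseased, x$d))
  cat(sprintf("  centered: %s\n", x$centered))
  invisible(x)
}

#' Center a two-group sample
#'
#' Removes the pooled mean from every covariate column and the per-group mean
#' from each response. Centering the covariates at zero puts the two groups'
#' coefficients on a comparable scale; response centers are stored so the AUC
#' can be evaluated on the original scale afterwards (the intercept
#' difference is added back).
#'
#' @param sample an uncentered [two_group_sample()].
#' @return A centered `two_group_sample` carrying the removed centers.
#' @export
center_two_group <- function(sample) {
  stopifnot(inherits(sample, "two_group_sample"))
  if (isTRUE(sample$centered)) stop("sample is already centered")
  z_all <- rbind(sample$z_nondiseased, sample$z_diseased)
  cc <- colMeans(z_all)
  spread <- apply(z_all, 2, function(col) max(col) - min(col))
  if (any(spread == 0)) {
    stop("degenerate input: zero-variance covariate column(s) ",
         paste(which(spread == 0), collapse = ", "))
  }
  m_nd <- mean(sample$y_nondiseased)
  m_d <- mean(sample$y_diseased)
  two_group_sample(
    y_nondiseased = sample$y_nondiseased - m_nd,
    y_diseased = sample$y_diseased - m_d,
    z_nondiseased = sweep(sample$z_nondiseased, 2, cc),
    z_diseased = sweep(sample$z_diseased, 2, cc),
    centered = TRUE,
    response_centers = c(nondiseased = m_nd, diseased = m_d),
    covariate_centers = cc
  )
}

#' Full-model residual variances per group
#'
#' Estimates each group's error variance from the unpenalized least-squares
#' fit of that group's response on all `d` covariates. The estimates are the
#' plug-in weights of the stacked weighted regression and are held fixed
#' during penalized fitting; the error variance is not treated as a model
#' parameter.
#'
#' @param sample a [two_group_sample()]; each group must have more
#'   observations than covariates.
#' @return Named numeric vector `c(nondiseased = , diseased = )` of residual
#'   variance estimates.
#' @export
estimate_group_variances <- function(sample) {
  stopifnot(inherits(sample, "two_group_sample"))
  one <- function(y, z, label) {
    n <- length(y)
    # an intercept is always included: covariates are centered on the pooled
    # sample, so each group's covariate means need not vanish
    X <- cbind(1, z)
    if (n <= ncol(X)) {
      stop("group '", label, "' needs more observations than covariates ",
           "for a full-model variance estimate")
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      stop("full design is rank deficient in group '", label, "'")
    }
    res <- qr.resid(qx, y)
    sum(res^2) / (n - ncol(X))
  }
  c(nondiseased = one(sample$y_nondiseased, sample$z_nondiseased, "nondiseased"),
    diseased = one(sample$y_diseased, sample$z_diseased, "diseased"))
}
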