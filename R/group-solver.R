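# Core groupwise coordinate-descent machinery shared by the group SCAD,
# group LASSO, and separate (ungrouped) SCAD fits. Groups are orthonormalized
# (QR within group, scaled so Q'Q = n I) before penalization, which gives the
# per-group subproblem a closed-form threshold; coefficients are
# back-transformed afterwards. Penalizing the orthonormalized norm amounts to
# the generalized group norm ||theta_m||_{K_m} with K_m = Z'_m Z_m / n.

ZTOL <- 1e-8

grp_orthonormalize <- function(X, groups) {
  n <- nrow(X)
  Qlist <- vector("list", length(groups))
  Rlist <- vector("list", length(groups))
  for (m in seq_along(groups)) {
    idx <- groups[[m]]
    qrm <- qr(X[, idx, drop = FALSE])
    if (qrm$rank < length(idx)) {
      stop("design group ", m, " is rank deficient")
    }
    Qm <- qr.Q(qrm)
    Rm <- qr.R(qrm)
    sgn <- sign(diag(Rm))
    sgn[sgn == 0] <- 1
    Qm <- sweep(Qm, 2, sgn, `*`)
    Rm <- sgn * Rm
    Qlist[[m]] <- Qm * sqrt(n)
    Rlist[[m]] <- Rm / sqrt(n)
  }
  list(Q = Qlist, R = Rlist, n = n)
}

grp_penalty_term <- function(bnorms, penalized, lambda, a, penalty) {
  if (lambda == 0 || !any(penalized)) return(0)
  w <- bnorms[penalized]
  if (penalty == "scad") {
    sum(ifelse(w <= lambda, lambda * w,
               ifelse(w <= a * lambda,
                      (2 * a * lambda * w - w^2 - lambda^2) / (2 * (a - 1)),
                      (a + 1) * lambda^2 / 2)))
  } else {
    lambda * sum(w)
  }
}

# Coordinate descent on orthonormalized groups. `ortho` comes from
# grp_orthonormalize; `b` is the coefficient vector in orthonormalized
# coordinates, stored as a list per group.
grp_cd_fit <- function(ortho, y, lambda, a, penalty = c("scad", "lasso"),
                       penalized = rep(TRUE, length(ortho$Q)),
                       init = NULL, max_iter = 500L, tol = 1e-8) {
  penalty <- match.arg(penalty)
  M <- length(ortho$Q)
  n <- ortho$n
  b <- if (is.null(init)) {
    lapply(ortho$Q, function(Qm) numeric(ncol(Qm)))
  } else {
    init
  }
  fitted <- numeric(length(y))
  for (m in seq_len(M)) {
    if (any(b[[m]] != 0)) fitted <- fitted + as.vector(ortho$Q[[m]] %*% b[[m]])
  }
  r <- y - fitted
  obj_old <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    delta_max <- 0
    for (m in seq_len(M)) {
      Qm <- ortho$Q[[m]]
      u <- as.vector(crossprod(Qm, r)) / n + b[[m]]
      if (!penalized[m] || lambda == 0) {
        bn <- u
      } else {
        nu <- sqrt(sum(u^2))
        s <- if (penalty == "scad") {
          scad_firm(nu, lambda, a)
        } else {
          max(0, nu - lambda)
        }
        bn <- if (nu > 0) (s / nu) * u else u * 0
      }
      db <- bn - b[[m]]
      if (any(db != 0)) {
        r <- r - as.vector(Qm %*% db)
        b[[m]] <- bn
        delta_max <- max(delta_max, max(abs(db)))
      }
    }
    # coefficient-change stopping: an objective-change rule alone leaves
    # O(sqrt(tol)) coefficient error near the optimum
    bscale <- 1 + max(abs(unlist(b)))
    if (delta_max <= tol * bscale) break
    bnorms <- vapply(b, function(v) sqrt(sum(v^2)), numeric(1))
    obj <- sum(r^2) / (2 * n) +
      grp_penalty_term(bnorms, penalized, lambda, a, penalty)
    if (is.finite(obj_old) && abs(obj_old - obj) <= (tol^2) * (abs(obj_old) + 1e-12)) break
    obj_old <- obj
  }
  # snap numerically-dead groups to exact zero
  for (m in seq_len(M)) {
    if (penalized[m] && lambda > 0 && sqrt(sum(b[[m]]^2)) < ZTOL &&
        any(b[[m]] != 0)) {
      r <- r + as.vector(ortho$Q[[m]] %*% b[[m]])
      b[[m]] <- b[[m]] * 0
    }
  }
  bnorms <- vapply(b, function(v) sqrt(sum(v^2)), numeric(1))
  obj <- sum(r^2) / (2 * n) +
    grp_penalty_term(bnorms, penalized, lambda, a, penalty)
  list(b = b, residual = r, objective = obj, bnorms = bnorms, iters = iters)
}

grp_backtransform <- function(ortho, b, p_total, groups) {
  theta <- numeric(p_total)
  for (m in seq_along(groups)) {
    if (all(b[[m]] == 0)) next
    theta[groups[[m]]] <- backsolve(ortho$R[[m]], b[[m]])
  }
  theta
}

# assemble a penalized_fit record from an engine state
make_penalized_fit <- function(theta, groups, lambda, objective, residual, n,
                               penalty_kind) {
  gnorm <- vapply(groups, function(idx) sqrt(sum(theta[idx]^2)), numeric(1))
  active <- which(gnorm > 0)
  df <- sum(lengths(groups)[active])
  structure(
    list(theta = theta,
         active_groups = active,
         lambda = lambda,
         objective_value = objective,
         sigma_hat_sq = sum(residual^2) / n,
         df = df,
         n = n,
         groups = groups,
         penalty_kind = penalty_kind),
    class = "penalized_fit"
  )
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("Penalized fit (%s), lambda = %.5g\n", x$penalty_kind, x$lambda))
  cat(sprintf("  active groups (%d): %s\n", length(x$active_groups),
              if (length(x$active_groups)) paste(x$active_groups, collapse = " ") else "none"))
  cat(sprintf("  df = %d, sigma_hat_sq = %.5g, objective = %.6g\n",
              x$df, x$sigma_hat_sq, x$objective_value))
  invisible(x)
}

#' Group SCAD fit of the fused ROC regression
#'
#' Minimizes `||Y - Z theta||^2/(2n) + sum_m p_lambda(||theta_m||_{K_m})` on
#' the transformed stacked design by groupwise coordinate descent; each
#' covariate's (non-diseased, diseased) coefficient pair enters or leaves the
#' model together. Within-group orthonormalization makes the per-group update
#' an exact closed-form SCAD threshold. The solver is run from the zero and
#' the least-squares starts (or a supplied warm start) and the lower
#' objective is kept.
#'
#' @param design a transformed [build_stacked_design()] result (see
#'   [apply_weights()]).
#' @param spec a [penalty_spec()].
#' @param unpenalized_groups integer vector of factor indices exempt from the
#'   penalty (empty by default).
#' @param init optional warm start: a `penalized_fit` or stacked coefficient
#'   vector.
#' @return A `penalized_fit`: stacked coefficients `theta`, `active_groups`,
#'   `lambda`, `objective_value`, `sigma_hat_sq` (transformed-scale
#'   `||residual||^2/n`), and `df`.
#' @export
fit_group_scad <- function(design, spec, unpenalized_groups = integer(0),
                           init = NULL) {
  stopifnot(inherits(design, "stacked_design"), inherits(spec, "penalty_spec"))
  if (!isTRUE(design$transformed)) stop("design must be transformed (apply_weights) first")
  if (design$n < 1) stop("design has no data rows")
  if (length(unpenalized_groups) &&
      !all(unpenalized_groups %in% seq_len(design$d))) {
    stop("unpenalized_groups must be factor indices in 1..d")
  }
  if (spec$lambda == 0) {
    qx <- qr(design$design)
    theta <- qr.coef(qx, design$response)
    theta[is.na(theta)] <- 0
    r <- design$response - as.vector(design$design %*% theta)
    return(make_penalized_fit(unname(theta), design$groups, 0,
                              sum(r^2) / (2 * design$n), r, design$n,
                              "group_scad"))
  }
  ortho <- grp_orthonormalize(design$design, design$groups)
  penalized <- !(seq_len(design$d) %in% unpenalized_groups)
  starts <- list(NULL)
  if (!is.null(init)) {
    theta0 <- if (inherits(init, "penalized_fit")) init$theta else as.numeric(init)
    binit <- lapply(seq_len(design$d), function(m) {
      as.vector(ortho$R[[m]] %*% theta0[design$groups[[m]]])
    })
    starts <- c(starts, list(binit))
  }
  # least-squares start (exact for lambda = 0, helpful escape elsewhere)
  bls <- grp_cd_fit(ortho, design$response, 0, spec$a, "scad", penalized)$b
  starts <- c(starts, list(bls))
  best <- NULL
  for (s in starts) {
    fit <- grp_cd_fit(ortho, design$response, spec$lambda, spec$a, "scad",
                      penalized, init = s)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  theta <- grp_backtransform(ortho, best$b, 2 * design$d, design$groups)
  make_penalized_fit(theta, design$groups, spec$lambda, best$objective,
                     best$residual, design$n, "group_scad")
}

# smallest lambda at which all penalized groups are zero (KKT bound on the
# orthonormalized scale)
lambda_max_group <- function(design, unpenalized_groups = integer(0),
                             a = 3.7) {
  ortho <- grp_orthonormalize(design$design, design$groups)
  penalized <- !(seq_len(design$d) %in% unpenalized_groups)
  r0 <- design$response
  if (any(!penalized)) {
    cols <- unlist(design$groups[unpenalized_groups])
    r0 <- qr.resid(qr(design$design[, cols, drop = FALSE]), design$response)
  }
  mx <- 0
  for (m in seq_len(design$d)) {
    if (!penalized[m]) next
    mx <- max(mx, sqrt(sum((crossprod(ortho$Q[[m]], r0) / design$n)^2)))
  }
  mx
}

#' Tuning-parameter grid
#'
#' Log-spaced decreasing grid from the smallest value that zeroes every
#' penalized group down to `min_ratio` times it.
#'
#' @param design a transformed `stacked_design`.
#' @param nlambda grid length (default 100).
#' @param min_ratio ratio of smallest to largest grid value (default 0.001).
#' @param unpenalized_groups factor indices exempt from the penalty.
#' @return Decreasing numeric vector of length `nlambda`.
#' @export
lambda_grid <- function(design, nlambda = 100L, min_ratio = 0.001,
                        unpenalized_groups = integer(0)) {
  lmax <- lambda_max_group(design, unpenalized_groups)
  if (lmax <= 0) lmax <- 1e-4
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

# shared path driver
grp_path <- function(design, grid, a, penalty, unpenalized_groups,
                     penalty_kind) {
  stopifnot(inherits(design, "stacked_design"), isTRUE(design$transformed))
  if (any(grid < 0)) stop("grid values must be non-negative")
  if (is.unsorted(rev(grid), strictly = TRUE)) {
    stop("grid must be strictly decreasing")
  }
  ortho <- grp_orthonormalize(design$design, design$groups)
  penalized <- !(seq_len(design$d) %in% unpenalized_groups)
  fits <- vector("list", length(grid))
  b <- NULL
  for (k in seq_along(grid)) {
    res <- grp_cd_fit(ortho, design$response, grid[k], a, penalty, penalized,
                      init = b)
    b <- res$b
    theta <- grp_backtransform(ortho, b, 2 * design$d, design$groups)
    fits[[k]] <- make_penalized_fit(theta, design$groups, grid[k],
                                    res$objective, res$residual, design$n,
                                    penalty_kind)
  }
  structure(list(fits = fits, grid = grid, penalty_kind = penalty_kind,
                 unpenalized_groups = unpenalized_groups, n = design$n),
            class = "solution_path")
}

#' Group SCAD solution path
#'
#' Fits [fit_group_scad()] over a decreasing tuning grid with warm starts
#' (large to small lambda).
#'
#' @param design a transformed `stacked_design`.
#' @param grid strictly decreasing positive lambda values; defaults to
#'   [lambda_grid()].
#' @param a SCAD shape constant.
#' @param unpenalized_groups factor indices exempt from the penalty.
#' @return A `solution_path`: list of `penalized_fit`s and the grid.
#' @export
group_scad_path <- function(design, grid = NULL, a = 3.7,
                            unpenalized_groups = integer(0)) {
  if (is.null(grid)) {
    grid <- lambda_grid(design, unpenalized_groups = unpenalized_groups)
  }
  grp_path(design, grid, a, "scad", unpenalized_groups, "group_scad")
}

#' Group LASSO path over the extension factors
#'
#' Stage-2 machinery of the focused selection procedure: factors in the
#' Stage-1 narrow set stay unpenalized while the remaining ("extension")
#' factors receive a group-LASSO penalty `tau * sum ||gamma_l||`. As `tau`
#' decreases the active extension set grows from empty toward full, tracing
#' the candidate submodels the FIC will score.
#'
#' @param design a transformed `stacked_design`.
#' @param narrow_groups integer vector, the Stage-1 narrow factor set (never
#'   penalized).
#' @param grid strictly decreasing non-negative tau values; defaults to a
#'   log-spaced grid below the KKT bound.
#' @param nlambda,min_ratio grid construction parameters when `grid` is NULL.
#' @return A `solution_path` with `penalty_kind = "group_lasso"`.
#' @export
group_lasso_path <- function(design, narrow_groups, grid = NULL,
                             nlambda = 100L, min_ratio = 0.001) {
  if (length(narrow_groups) && !all(narrow_groups %in% seq_len(design$d))) {
    stop("narrow_groups must be a subset of 1..d")
  }
  if (is.null(grid)) {
    tmax <- lambda_max_group(design, unpenalized_groups = narrow_groups)
    if (tmax <= 0) tmax <- 1e-4
    grid <- exp(seq(log(tmax), log(tmax * min_ratio), length.out = nlambda))
  }
  grp_path(design, grid, 3.7, "lasso", narrow_groups, "group_lasso")
}

#' @export
print.solution_path <- function(x, ...) {
  cat(sprintf("Solution path (%s): %d fits, tuning range [%.4g, %.4g]\n",
              x$penalty_kind, length(x$grid), min(x$grid), max(x$grid)))
  sizes <- vapply(x$fits, function(f) length(f$active_groups), integer(1))
  cat(sprintf("  active-set sizes: %d (sparsest) to %d (densest)\n",
              min(sizes), max(sizes)))
  invisible(x)
}

#' Separate (ungrouped) SCAD fit for one group's regression
#'
#' The comparison baseline: SCAD-penalized selection applied to a single
#' group's linear model on its own, so the diseased and non-diseased models
#' may select different covariates. Coefficients are penalized individually
#' (groups of size one).
#'
#' @param sample a centered [two_group_sample()].
#' @param spec a [penalty_spec()].
#' @param group_label `"diseased"` or `"nondiseased"`.
#' @param init optional warm start (length-`d` coefficient vector).
#' @return A `penalized_fit` with length-`d` `theta`; `active_groups` indexes
#'   selected covariates and `df` counts them.
#' @export
fit_separate_scad <- function(sample, spec, group_label = c("diseased", "nondiseased"),
                              init = NULL) {
  group_label <- match.arg(group_label)
  path <- separate_scad_path(sample, group_label, grid = spec$lambda,
                             a = spec$a, init = init)
  path$fits[[1]]
}

#' Separate SCAD solution path for one group
#'
#' @inheritParams fit_separate_scad
#' @param grid decreasing lambda values; defaults to a log-spaced grid from
#'   the per-group KKT bound.
#' @param a SCAD shape constant.
#' @param nlambda,min_ratio grid construction parameters when `grid` is NULL.
#' @return A `solution_path` with `penalty_kind = "separate_scad"`.
#' @export
separate_scad_path <- function(sample, group_label = c("diseased", "nondiseased"),
                               grid = NULL, a = 3.7, nlambda = 100L,
                               min_ratio = 0.001, init = NULL) {
  stopifnot(inherits(sample, "two_group_sample"))
  group_label <- match.arg(group_label)
  if (!isTRUE(sample$centered)) stop("sample must be centered first")
  y <- if (group_label == "diseased") sample$y_diseased else sample$y_nondiseased
  X <- if (group_label == "diseased") sample$z_diseased else sample$z_nondiseased
  d <- ncol(X)
  groups <- as.list(seq_len(d))
  ortho <- grp_orthonormalize(X, groups)
  n <- length(y)
  if (is.null(grid)) {
    lmax <- max(abs(vapply(seq_len(d), function(m) {
      sum(ortho$Q[[m]] * y) / n
    }, numeric(1))))
    if (lmax <= 0) lmax <- 1e-4
    grid <- exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
  }
  grid <- as.numeric(grid)
  if (length(grid) > 1 && is.unsorted(rev(grid), strictly = TRUE)) {
    stop("grid must be strictly decreasing")
  }
  penalized <- rep(TRUE, d)
  fits <- vector("list", length(grid))
  b <- if (is.null(init)) NULL else {
    lapply(seq_len(d), function(m) as.vector(ortho$R[[m]] * init[m]))
  }
  for (k in seq_along(grid)) {
    res <- grp_cd_fit(ortho, y, grid[k], a, "scad", penalized, init = b)
    # single fits also try the least-squares start, as in fit_group_scad
    if (length(grid) == 1L) {
      alt <- grp_cd_fit(ortho, y, grid[k], a, "scad", penalized,
                        init = grp_cd_fit(ortho, y, 0, a, "scad", penalized)$b)
      if (alt$objective < res$objective) res <- alt
    }
    b <- res$b
    theta <- grp_backtransform(ortho, b, d, groups)
    fits[[k]] <- make_penalized_fit(theta, groups, grid[k], res$objective,
                                    res$residual, n, "separate_scad")
  }
  structure(list(fits = fits, grid = grid, penalty_kind = "separate_scad",
                 unpenalized_groups = integer(0), n = n),
            class = "solution_path")
}
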