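# Shared fixtures and independent oracles used across the test files.
# Oracles deliberately avoid the package's coordinate-descent code path:
# brute force enumerates zero patterns and minimizes numerically with optim.

# small random two-group sample (uncentered)
toy_sample <- function(seed, n_nd = 6, n_d = 6, d = 2,
                       theta_nd = NULL, theta_d = NULL, sigma = 1) {
  set.seed(seed)
  if (is.null(theta_nd)) theta_nd <- stats::rnorm(d)
  if (is.null(theta_d)) theta_d <- stats::rnorm(d)
  z_nd <- matrix(stats::rnorm(n_nd * d), n_nd, d)
  z_d <- matrix(stats::rnorm(n_d * d), n_d, d)
  y_nd <- as.vector(z_nd %*% theta_nd) + sigma * stats::rnorm(n_nd)
  y_d <- as.vector(z_d %*% theta_d) + sigma * stats::rnorm(n_d)
  two_group_sample(y_nd, y_d, z_nd, z_d)
}

toy_design <- function(seed, ...) {
  smp <- center_two_group(toy_sample(seed, ...))
  apply_weights(build_stacked_design(smp, 1, 1))
}

# per-group norm matrices matching the solver's orthonormalized-group
# penalty: K_m = Z'_m Z_m / n on the transformed design
gram_norms <- function(design) {
  lapply(design$groups, function(idx) {
    crossprod(design$design[, idx, drop = FALSE]) / design$n
  })
}

# objective used by both solver and oracle (via penalized_objective);
# norms may be precomputed once per design to keep the oracle fast
oracle_objective <- function(design, theta, lambda, a, norms = NULL) {
  if (is.null(norms)) norms <- gram_norms(design)
  spec <- penalty_spec(lambda, a, norm_matrices = norms)
  penalized_objective(design, theta, spec)
}

# exhaustive zero-pattern brute force: for each subset of active groups,
# numerically minimize the smooth restriction with optim from several starts
brute_force_group_scad <- function(design, lambda, a = 3.7) {
  d <- design$d
  norms <- gram_norms(design)
  best <- Inf
  best_theta <- numeric(2 * d)
  for (mask in 0:(2^d - 1)) {
    active <- which(bitwAnd(mask, 2^(seq_len(d) - 1)) > 0)
    cols <- unlist(design$groups[active])
    if (length(cols) == 0) {
      val <- oracle_objective(design, numeric(2 * d), lambda, a, norms)
      if (val < best) {
        best <- val
        best_theta <- numeric(2 * d)
      }
      next
    }
    Xa <- design$design[, cols, drop = FALSE]
    ls <- qr.coef(qr(Xa), design$response)
    obj <- function(th) {
      theta <- numeric(2 * d)
      theta[cols] <- th
      oracle_objective(design, theta, lambda, a, norms)
    }
    for (start in list(ls, 0.3 * ls, rep(0.01, length(cols)))) {
      opt <- tryCatch(
        stats::optim(start, obj, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-13)),
        error = function(e) NULL
      )
      if (is.null(opt)) {
        opt <- stats::optim(start, obj, method = "Nelder-Mead",
                            control = list(maxit = 3000, reltol = 1e-13))
      }
      if (opt$value < best) {
        best <- opt$value
        best_theta <- numeric(2 * d)
        best_theta[cols] <- opt$par
      }
    }
  }
  # polish the winner
  act <- abs(best_theta) > 0
  if (any(act)) {
    opt <- stats::optim(best_theta[act], function(th) {
      theta <- numeric(2 * d)
      theta[act] <- th
      oracle_objective(design, theta, lambda, a, norms)
    }, method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14))
    if (opt$value < best) {
      best <- opt$value
      best_theta[act] <- opt$par
    }
  }
  list(objective = best, theta = best_theta)
}

# design whose factor groups are exactly orthonormal on the transformed
# scale (within-group QR makes same-parity columns orthogonal; opposite
# parity is orthogonal by construction)
orthogonal_design <- function(seed, n_per_group = 8, d = 3) {
  set.seed(seed)
  n_total <- 2 * n_per_group
  orth_cols <- function(n, d) {
    # column squared norms equal the total stacked size so Z'Z/n = I there
    qr.Q(qr(matrix(stats::rnorm(n * d), n, d))) * sqrt(n_total)
  }
  z_nd <- orth_cols(n_per_group, d)
  z_d <- orth_cols(n_per_group, d)
  y_nd <- stats::rnorm(n_per_group)
  y_d <- stats::rnorm(n_per_group)
  smp <- two_group_sample(y_nd, y_d, z_nd, z_d, centered = TRUE)
  apply_weights(build_stacked_design(smp, 1, 1))
}

# 1-D SCAD oracle: grid minimization of (scalar-coefficient) penalized RSS
scalar_scad_oracle <- function(y, x, lambda, a = 3.7) {
  n <- length(y)
  spec <- penalty_spec(lambda, a)
  xs <- sqrt(sum(x^2) / n)  # orthonormalized scale of the single column
  objective <- function(b) {
    sum((y - x * b)^2) / (2 * n) + scad_penalty(abs(b) * xs, spec)
  }
  grid <- seq(-5, 5, length.out = 20001)
  vals <- vapply(grid, objective, numeric(1))
  k <- which.min(vals)
  opt <- stats::optimize(objective, c(grid[max(1, k - 2)], grid[min(length(grid), k + 2)]))
  if (opt$objective < vals[k]) list(b = opt$minimum, objective = opt$objective)
  else list(b = grid[k], objective = vals[k])
}
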