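test_that("centering removes per-group response means and pooled covariate means", {
  smp <- two_group_sample(
    y_nondiseased = c(2, 4), y_diseased = c(6, 8),
    z_nondiseased = matrix(c(1, 2), 2, 1),
    z_diseased = matrix(c(3, 6), 2, 1)
  )
  cs <- center_two_group(smp)
  expect_equal(cs$y_nondiseased, c(-1, 1))
  expect_equal(cs$y_diseased, c(-1, 1))
  expect_equal(unname(cs$response_centers), c(3, 7))
  expect_equal(as.vector(rbind(cs$z_nondiseased, cs$z_diseased)),
               c(-2, -1, 0, 3))
  expect_true(cs$centered)
  expect_error(center_two_group(cs), "already centered")
})

test_that("centering already-centered data is a near no-op and errors on constant columns", {
  smp <- toy_sample(3, d = 3)
  cs1 <- center_two_group(smp)
  # re-center manually constructed copy of the centered values
  cs2 <- center_two_group(two_group_sample(
    cs1$y_nondiseased, cs1$y_diseased, cs1$z_nondiseased, cs1$z_diseased))
  expect_equal(unname(cs2$response_centers), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(cs2$covariate_centers), rep(0, 3), tolerance = 1e-12)
  expect_equal(cs2$z_diseased, cs1$z_diseased, tolerance = 1e-12)

  bad <- two_group_sample(1:3, 4:6, matrix(1, 3, 1), matrix(1, 3, 1))
  expect_error(center_two_group(bad), "zero-variance")
})

test_that("stacked design follows the Kronecker embedding and parity sparsity", {
  smp <- two_group_sample(
    y_nondiseased = 1, y_diseased = 2,
    z_nondiseased = matrix(5, 1, 1), z_diseased = matrix(7, 1, 1),
    centered = TRUE
  )
  des <- build_stacked_design(smp, 2, 2)
  expect_equal(des$design, matrix(c(5, 0, 0, 7), 2, 2, byrow = TRUE))
  # stacked coefficients reproduce the per-group linear predictors
  a <- 0.3; b <- -1.2
  expect_equal(as.vector(des$design %*% stack_coefficients(a, b)),
               c(5 * a, 7 * b))
  expect_equal(des$weights, rep(0.25, 2))
})

test_that("parity-sparsity and group partition invariants hold on random designs", {
  for (seed in 1:5) {
    smp <- center_two_group(toy_sample(seed, n_nd = 7, n_d = 5, d = 4))
    des <- build_stacked_design(smp, 1.3, 0.8)
    odd <- seq(1, 2 * des$d, by = 2)
    expect_true(all(des$design[seq_len(des$n_nondiseased), odd + 1] == 0))
    expect_true(all(des$design[des$n_nondiseased + seq_len(des$n_diseased), odd] == 0))
    expect_equal(sort(unlist(des$groups)), seq_len(2 * des$d))
    expect_equal(des$weights,
                 c(rep(1.3^-2, des$n_nondiseased), rep(0.8^-2, des$n_diseased)))
    # stack/unstack round trip
    theta <- rnorm(2 * des$d)
    u <- unstack_coefficients(theta)
    expect_identical(stack_coefficients(u$theta_nondiseased, u$theta_diseased),
                     theta)
  }
})

test_that("weight absorption reproduces weighted least squares", {
  smp <- center_two_group(toy_sample(11, n_nd = 3, n_d = 3, d = 1))
  des <- build_stacked_design(smp, 2, 0.5)
  tdes <- apply_weights(des)
  expect_error(apply_weights(tdes), "already transformed")
  # row with weight 0.25 is scaled by 0.5
  expect_equal(tdes$response[1], des$response[1] * 0.5)
  expect_equal(tdes$design[1, ], des$design[1, ] * 0.5)
  # OLS on transformed data equals WLS normal equations on the original
  ols <- qr.coef(qr(tdes$design), tdes$response)
  W <- diag(des$weights)
  wls <- solve(t(des$design) %*% W %*% des$design,
               t(des$design) %*% W %*% des$response)
  expect_equal(unname(ols), as.vector(wls), tolerance = 1e-10)
})

test_that("the two-sum objective equals the stacked transformed objective", {
  smp <- center_two_group(toy_sample(21, n_nd = 6, n_d = 5, d = 3))
  tdes <- apply_weights(build_stacked_design(smp, 1.7, 0.9))
  spec <- penalty_spec(0.4)
  for (seed in 1:5) {
    set.seed(seed)
    th_nd <- rnorm(3); th_d <- rnorm(3)
    expect_equal(
      two_sum_objective(smp, th_nd, th_d, 1.7, 0.9, spec),
      penalized_objective(tdes, stack_coefficients(th_nd, th_d), spec),
      tolerance = 1e-10
    )
  }
})

test_that("AUC formula, bounds, and monotonicity", {
  pars <- model_parameters(c(1, 2), c(1, 2), 1.5, 0.7)
  expect_equal(auc_from_parameters(pars, c(3, -1)), 0.5)
  # strictly increasing in z0' (theta_D - theta_Dbar)
  pars2 <- model_parameters(c(2, 1), c(1, 0.5), 1, 1)
  lift <- vapply(seq(0, 2, by = 0.25), function(t) {
    auc_from_parameters(pars2, c(t, t))
  }, numeric(1))
  expect_true(all(diff(lift) > 0))
  expect_true(all(lift > 0 & lift < 1))
  expect_error(model_parameters(1, 1, -1, 1), "positive")
  expect_error(auc_from_parameters(pars, 1), "length d")
})

test_that("all printed true AUC values regenerate to 3 decimals", {
  printed <- list(
    `1` = c(0.611, 0.838, 0.955),
    `2` = c(0.613, 0.805, 0.957),
    `3` = c(0.613, 0.806, 0.958)
  )
  for (id in 1:3) {
    st <- make_setting(id)
    expect_equal(round(st$true_auc, 3), printed[[as.character(id)]])
  }
})

test_that("AUC gradient matches the stacked closed form and finite differences", {
  pars <- model_parameters(1, 1, 1, 1)
  g <- auc_gradient(pars, 1)
  expect_equal(g, dnorm(0) / sqrt(2) * c(-1, 1), tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:4) {
    d <- sample(2:5, 1)
    pars <- model_parameters(rnorm(d), rnorm(d), runif(1, 0.5, 2),
                             runif(1, 0.5, 2))
    z0 <- rnorm(d)
    g <- auc_gradient(pars, z0)
    # (-, +) pairs proportional to z0m
    expect_equal(g[2 * seq_len(d)], -g[2 * seq_len(d) - 1])
    h <- 1e-6
    fd <- vapply(seq_len(2 * d), function(j) {
      bump <- function(s) {
        th <- stack_coefficients(pars$theta_nondiseased, pars$theta_diseased)
        th[j] <- th[j] + s * h
        u <- unstack_coefficients(th)
        auc_from_parameters(
          model_parameters(u$theta_diseased, u$theta_nondiseased,
                           pars$sigma_diseased, pars$sigma_nondiseased), z0)
      }
      (bump(1) - bump(-1)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("group variance estimation is consistent and symmetric", {
  # noiseless data recovers ~zero variance
  smp <- toy_sample(5, n_nd = 10, n_d = 10, d = 2, sigma = 0)
  cs <- center_two_group(smp)
  v <- estimate_group_variances(cs)
  expect_lt(max(v), 1e-20)

  # simulated sigma_D = 2 at n = 5000 lands within 5% of 4
  st <- make_setting(1)
  big <- generate_setting_data(st, 99, n_nondiseased = 5000, n_diseased = 5000)
  vb <- estimate_group_variances(center_two_group(big))
  expect_lt(abs(vb[["diseased"]] - 4) / 4, 0.05)
  expect_lt(abs(vb[["nondiseased"]] - 4) / 4, 0.05)

  # swapping group labels swaps the estimates
  smp2 <- toy_sample(6, n_nd = 8, n_d = 8, d = 2)
  sw <- two_group_sample(smp2$y_diseased, smp2$y_nondiseased,
                         smp2$z_diseased, smp2$z_nondiseased)
  v1 <- estimate_group_variances(center_two_group(smp2))
  v2 <- estimate_group_variances(center_two_group(sw))
  expect_equal(unname(v1), unname(rev(v2)))

  # more covariates than observations per group is an error
  tiny <- two_group_sample(1:3, 1:3, matrix(rnorm(9), 3), matrix(rnorm(9), 3),
                           centered = TRUE)
  expect_error(estimate_group_variances(tiny), "more observations")
})
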