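test_that("fic_components: orthogonal design gives omega = -dmu/dgamma, dense oracle agrees", {
  des <- orthogonal_design(19, n_per_group = 8, d = 3)
  pars <- model_parameters(c(1, 0.5, 0.2), c(0.5, 0.2, 0.1), 1, 1)
  foc <- focus_spec(pars, rep(0.7, 3))
  comps <- fic_components(des, narrow = 1L, focus = foc)
  idx1 <- unlist(des$groups[2:3])
  expect_equal(comps$omega, -foc$gradient[idx1], tolerance = 1e-10)

  # general design: blocks match an explicit dense inversion of J
  des2 <- toy_design(23, n_nd = 6, n_d = 6, d = 2)
  pars2 <- model_parameters(c(1, 0.4), c(0.3, 0.2), 1.2, 0.8)
  foc2 <- focus_spec(pars2, c(0.5, -1))
  comps2 <- fic_components(des2, narrow = 1L, focus = foc2)
  J <- crossprod(des2$design) / des2$n
  Jinv <- solve(J)
  idx0 <- c(1, 2); idx1 <- c(3, 4)
  expect_equal(comps2$Q, Jinv[idx1, idx1], tolerance = 1e-10)
  omega_dense <- J[idx1, idx0] %*% solve(J[idx0, idx0]) %*%
    foc2$gradient[idx0] - foc2$gradient[idx1]
  expect_equal(comps2$omega, as.vector(omega_dense), tolerance = 1e-10)
  # delta_hat = sqrt(n) * full-model extension coefficients
  full <- refit_selected(des2, 1:2)
  expect_equal(comps2$delta_hat, sqrt(des2$n) * full[idx1])

  expect_error(fic_components(des2, narrow = 1:2, focus = foc2), "degenerate")
})

test_that("fic_score limits: full set has zero bias, empty set has zero variance", {
  des <- toy_design(29, n_nd = 8, n_d = 8, d = 3)
  pars <- model_parameters(rnorm(3), rnorm(3), 1, 1)
  foc <- focus_spec(pars, rep(0.5, 3))
  comps <- fic_components(des, narrow = 1L, focus = foc)
  full <- fic_score(comps, 2:3)
  expect_equal(full$squared_bias_term, 0, tolerance = 1e-10)
  expect_equal(full$total, full$variance_term, tolerance = 1e-10)
  empty <- fic_score(comps, integer(0))
  expect_equal(empty$variance_term, 0)
  expect_equal(empty$squared_bias_term, sum(comps$omega * comps$delta_hat)^2)
  expect_equal(empty$total, empty$squared_bias_term)
  expect_error(fic_score(comps, 1L), "extension factors")
  # totals decompose additively
  one <- fic_score(comps, 2L)
  expect_equal(one$total, one$squared_bias_term + one$variance_term)
})

test_that("FIC variance term is monotone under candidate-set inclusion", {
  for (seed in c(7, 15)) {
    des <- toy_design(seed, n_nd = 12, n_d = 12, d = 4)
    pars <- model_parameters(rnorm(4), rnorm(4), 1, 1)
    foc <- focus_spec(pars, runif(4, -1, 1))
    comps <- fic_components(des, narrow = 1L, focus = foc)
    ext <- comps$ext_factors
    subsets <- lapply(0:(2^3 - 1), function(k) ext[bitwAnd(k, 2^(0:2)) > 0])
    vterm <- vapply(subsets, function(s) fic_score(comps, s)$variance_term,
                    numeric(1))
    for (i in seq_along(subsets)) {
      for (j in seq_along(subsets)) {
        if (all(subsets[[i]] %in% subsets[[j]])) {
          expect_lte(vterm[i], vterm[j] + 1e-10)
        }
      }
    }
  }
})

test_that("select_tau_fic picks the scorewise-best candidate set on the path", {
  des <- toy_design(33, n_nd = 10, n_d = 10, d = 3)
  pars <- model_parameters(rnorm(3), rnorm(3), 1, 1)
  foc <- focus_spec(pars, rep(0.8, 3))
  narrow <- 1L
  comps <- fic_components(des, narrow, foc)
  pth <- group_lasso_path(des, narrow, nlambda = 30)
  sel <- select_tau_fic(pth, comps)
  # the chosen set attains the minimum total among all distinct path sets
  expect_equal(min(sel$scores$total),
               fic_score(comps, sel$candidate_set)$total)
  expect_true(all(narrow %in% sel$final_set))
  expect_true(sel$tau %in% pth$grid)

  # delta ~ 0: empty extension set wins (variance monotonicity)
  c0 <- comps
  c0$delta_hat <- c0$delta_hat * 0
  sel0 <- select_tau_fic(pth, c0)
  expect_equal(sel0$candidate_set, integer(0))
  expect_equal(sel0$final_set, 1L)

  # huge delta aligned with omega: the full extension set wins
  cbig <- comps
  cbig$delta_hat <- as.vector(solve(cbig$Q, cbig$omega)) * 1e4
  cbig$delta_hat <- cbig$delta_hat / sqrt(sum(cbig$delta_hat^2)) * 1e4
  selbig <- select_tau_fic(pth, cbig)
  expect_equal(selbig$candidate_set, comps$ext_factors)
})

test_that("two candidate sets: selection equals the direct two-score comparison", {
  des <- orthogonal_design(47, n_per_group = 10, d = 2)
  pars <- model_parameters(c(1, 0.3), c(0.4, 0.1), 1, 1)
  foc <- focus_spec(pars, c(0.7, 0.7))
  comps <- fic_components(des, 1L, foc)
  # a path whose only distinct extension sets are {} and {2}
  tmax <- rocsel:::lambda_max_group(des, 1L)
  pth <- group_lasso_path(des, 1L, grid = c(tmax * 1.01, tmax * 0.01))
  sets <- lapply(pth$fits, function(f) setdiff(f$active_groups, 1L))
  expect_identical(sets, list(integer(0), 2L))
  sel <- select_tau_fic(pth, comps)
  s_empty <- fic_score(comps, integer(0))$total
  s_full <- fic_score(comps, 2L)$total
  expect_equal(sel$candidate_set,
               if (s_empty <= s_full) integer(0) else 2L)
})

test_that("stage 1 separates strong factors from nulls and keeps the narrow set in stage 2", {
  # near-noiseless data with three strong factors among eight
  st <- make_setting(1, delta_scale = 0)
  smp <- generate_setting_data(st, 202)
  cs <- center_two_group(smp)
  # shrink the noise dramatically for a separation regime
  smp2 <- two_group_sample(
    as.vector(cs$z_nondiseased %*% st$params$theta_nondiseased) + 0.01 * rnorm(50),
    as.vector(cs$z_diseased %*% st$params$theta_diseased) + 0.01 * rnorm(50),
    cs$z_nondiseased, cs$z_diseased
  )
  cs2 <- center_two_group(smp2)
  v <- estimate_group_variances(cs2)
  des <- apply_weights(build_stacked_design(cs2, sqrt(v[1]), sqrt(v[2])))
  expect_equal(stage1_narrow_model(des), 1:3)

  # the final set never removes stage-1 factors
  fit <- two_stage_fit(smp, st$test_points)
  for (r in fit$results) {
    expect_true(all(fit$narrow_set %in% r$final_set))
  }
})

test_that("two_stage_fit end-to-end: recovery, degenerate profile, audit fields", {
  # strong narrow-only truth: final set contains the narrow truth and the
  # AUC estimate is close to the closed-form value
  st <- make_setting(1, delta_scale = 0)
  set.seed(9)
  big_n <- 400L
  smp <- generate_setting_data(st, 303, n_nondiseased = big_n, n_diseased = big_n)
  fit <- two_stage_fit(smp, st$test_points[2, ])
  expect_true(all(1:3 %in% fit$results[[1]]$final_set))
  truth <- auc_from_parameters(st$params, st$test_points[2, ])
  expect_lt(abs(fit$results[[1]]$auc - truth), 0.05)
  expect_true(fit$lambda > 0)
  expect_true(is.numeric(fit$results[[1]]$tau))

  # z0 = 0: plug-in AUC is exactly 0.5 on centered data
  fit0 <- two_stage_fit(smp, rep(0, 8))
  expect_equal(fit0$results[[1]]$auc, 0.5)
})

test_that("the focus profile can change the selected extension set", {
  # correlated covariates with two borderline local extension effects: the
  # profile reweights omega, so different z0 favor different candidate sets
  # (with orthogonal covariates the per-factor decision would be invariant
  # to the profile's weight magnitudes)
  set.seed(12)
  n <- 40
  L <- chol(0.6 + 0.4 * diag(3))
  th_d <- c(2, 0.5, 0.3)
  th_nd <- c(0.5, -0.2, 0.45)
  z_nd <- matrix(rnorm(n * 3), n, 3) %*% L
  z_d <- matrix(rnorm(n * 3), n, 3) %*% L
  smp <- center_two_group(two_group_sample(
    z_nd %*% th_nd + rnorm(n), z_d %*% th_d + rnorm(n), z_nd, z_d))
  v <- estimate_group_variances(smp)
  des <- apply_weights(build_stacked_design(
    smp, sqrt(v[["nondiseased"]]), sqrt(v[["diseased"]])))
  tf <- unstack_coefficients(refit_selected(des, 1:3))
  pars <- model_parameters(tf$theta_diseased, tf$theta_nondiseased,
                           sqrt(v[["diseased"]]), sqrt(v[["nondiseased"]]))
  narrow <- 1L
  pth <- group_lasso_path(des, narrow, nlambda = 40)
  profiles <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                   c(1, 0, 1), c(0, 1, 1), c(1, 1, 1), c(1, -1, 0),
                   c(1, 0, -1), c(2, 1, -1), c(-1, 2, 0.5), c(0.5, -2, 1))
  sets <- lapply(profiles, function(z0) {
    comps <- fic_components(des, narrow, focus_spec(pars, z0))
    select_tau_fic(pth, comps)$final_set
  })
  expect_gte(length(unique(sets)), 2)
  # every selection still contains the narrow set
  expect_true(all(vapply(sets, function(s) narrow %in% s, logical(1))))
})
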