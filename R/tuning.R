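# Tuning-parameter selectors over a solution path. All four criteria score
# each grid point from the fit's residual variance on the fitting
# (weight-absorbed) scale, sigma_hat_sq = ||resid||^2 / n, and its group df,
# df = sum of active group sizes; ties are broken toward the larger tuning
# value (the sparser model, since paths run from large to small).

criterion_table <- function(path, n) {
  data.frame(
    tuning_value = path$grid,
    sigma_hat_sq = vapply(path$fits, `[[`, numeric(1), "sigma_hat_sq"),
    df = vapply(path$fits, `[[`, numeric(1), "df")
  )
}

pick_min <- function(path, score) {
  k <- which(score == min(score, na.rm = TRUE))[1]
  list(lambda = path$grid[k], fit = path$fits[[k]], index = k, score = score)
}

#' BIC selector for the tuning parameter
#'
#' Chooses the grid value minimizing `log(sigma_hat_lambda^2) +
#' df_lambda * log(n) / n`. With the group SCAD this selector recovers the
#' narrow model consistently as n grows.
#'
#' @param path a `solution_path` (see [group_scad_path()]).
#' @param n sample size entering the BIC penalty; defaults to the path's
#'   fitting sample size.
#' @return List with `lambda`, the chosen `fit`, grid `index`, and the
#'   `score` vector.
#' @export
bic_select <- function(path, n = path$n) {
  stopifnot(inherits(path, "solution_path"), length(path$fits) > 0)
  tab <- criterion_table(path, n)
  if (any(tab$sigma_hat_sq <= 0)) {
    stop("degenerate saturated fit: sigma_hat_sq = 0 on the path")
  }
  pick_min(path, log(tab$sigma_hat_sq) + tab$df * log(n) / n)
}

#' AIC selector
#'
#' Score `log(sigma_hat_lambda^2) + 2 df_lambda / n`.
#' @inheritParams bic_select
#' @return As [bic_select()].
#' @export
aic_select <- function(path, n = path$n) {
  stopifnot(inherits(path, "solution_path"), length(path$fits) > 0)
  tab <- criterion_table(path, n)
  if (any(tab$sigma_hat_sq <= 0)) {
    stop("degenerate saturated fit: sigma_hat_sq = 0 on the path")
  }
  pick_min(path, log(tab$sigma_hat_sq) + 2 * tab$df / n)
}

#' Generalized cross-validation selector
#'
#' Score `sigma_hat_lambda^2 / (1 - df_lambda / n)^2`; grid points with
#' `df >= n` are excluded with a warning.
#' @inheritParams bic_select
#' @return As [bic_select()].
#' @export
gcv_select <- function(path, n = path$n) {
  stopifnot(inherits(path, "solution_path"), length(path$fits) > 0)
  tab <- criterion_table(path, n)
  score <- tab$sigma_hat_sq / (1 - tab$df / n)^2
  bad <- tab$df >= n
  if (any(bad)) {
    warning(sum(bad), " grid point(s) with df >= n excluded from GCV")
    score[bad] <- NA_real_
  }
  if (all(is.na(score))) stop("GCV undefined at every grid point")
  pick_min(path, score)
}

# fold assignment stratified by disease status so each fold keeps the group
# ratio; returns an integer fold id per stacked-design row
stratified_folds <- function(design, folds, seed) {
  set.seed(seed)
  f <- integer(design$n)
  f[seq_len(design$n_nondiseased)] <-
    sample(rep_len(seq_len(folds), design$n_nondiseased))
  f[design$n_nondiseased + seq_len(design$n_diseased)] <-
    sample(rep_len(seq_len(folds), design$n_diseased))
  f
}

subset_design <- function(design, rows) {
  keep_nd <- sum(rows <= design$n_nondiseased)
  structure(
    list(response = design$response[rows],
         design = design$design[rows, , drop = FALSE],
         weights = design$weights[rows],
         groups = design$groups,
         transformed = design$transformed,
         n_nondiseased = keep_nd,
         n_diseased = length(rows) - keep_nd,
         n = length(rows),
         d = design$d),
    class = "stacked_design"
  )
}

#' K-fold cross-validation selector
#'
#' Refits the penalized path on each training split and scores held-out
#' squared prediction error. Folds are stratified by disease status; the
#' error is measured on the weight-absorbed scale by default (`scale =
#' "raw"` divides held-out residuals by the square-root weights first).
#'
#' @param design a transformed `stacked_design`.
#' @param grid decreasing tuning grid shared across folds; defaults to
#'   [lambda_grid()] on the full data.
#' @param folds number of folds (>= 2), default 5.
#' @param seed integer seed for fold assignment.
#' @param a SCAD shape constant.
#' @param penalty `"scad"` or `"lasso"`.
#' @param unpenalized_groups factor indices exempt from the penalty.
#' @param scale residual scale for the CV error.
#' @return List with `lambda`, full-data `fit` at the chosen value, grid
#'   `index`, the `score` (CV error) vector, and `fold_id`.
#' @export
cv_select <- function(design, grid = NULL, folds = 5L, seed = 1L, a = 3.7,
                      penalty = c("scad", "lasso"),
                      unpenalized_groups = integer(0),
                      scale = c("weighted", "raw")) {
  stopifnot(inherits(design, "stacked_design"), isTRUE(design$transformed))
  penalty <- match.arg(penalty)
  scale <- match.arg(scale)
  if (folds < 2) stop("folds must be at least 2")
  if (is.null(grid)) {
    grid <- lambda_grid(design, unpenalized_groups = unpenalized_groups)
  }
  fold_id <- stratified_folds(design, folds, seed)
  sse <- numeric(length(grid))
  for (k in seq_len(folds)) {
    train <- which(fold_id != k)
    test <- which(fold_id == k)
    sub <- subset_design(design, train)
    pth <- grp_path(sub, grid, a, penalty, unpenalized_groups, "cv_inner")
    for (j in seq_along(grid)) {
      res <- design$response[test] -
        as.vector(design$design[test, , drop = FALSE] %*% pth$fits[[j]]$theta)
      if (scale == "raw") res <- res / sqrt(design$weights[test])
      sse[j] <- sse[j] + sum(res^2)
    }
  }
  full <- grp_path(design, grid, a, penalty, unpenalized_groups,
                   if (penalty == "scad") "group_scad" else "group_lasso")
  sel <- pick_min(full, sse / design$n)
  sel$fold_id <- fold_id
  sel
}

#' Selection F-measure against the true narrow model
#'
#' Harmonic mean of precision (`|selected & truth| / |selected|`) and recall
#' (`|selected & truth| / |truth|`); 0 when both are 0 or nothing is
#' selected, 1 exactly when `selected` equals the truth.
#'
#' @param selected integer vector of selected factor indices.
#' @param truth integer vector, the true narrow-model factor indices
#'   (nonempty).
#' @return Scalar in `[0, 1]`.
#' @export
selection_fmeasure <- function(selected, truth) {
  truth <- unique(as.integer(truth))
  if (length(truth) == 0) stop("truth set must be nonempty")
  selected <- unique(as.integer(selected))
  if (length(selected) == 0) return(0)
  tp <- length(intersect(selected, truth))
  precision <- tp / length(selected)
  recall <- tp / length(truth)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}
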