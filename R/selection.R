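#' Default regularization-path grid
#'
#' 100 logarithmically equally spaced lambda values spanning `[0.01, 100]`,
#' the grid searched by 10-fold cross-validation in [ridge_select()] and
#' [lasso_select()].
#'
#' @param n_points number of grid points.
#' @param lambda_min,lambda_max grid endpoints.
#' @return Increasing numeric vector of length `n_points`.
#' @export
default_lambda_grid <- function(n_points = 100, lambda_min = 0.01, lambda_max = 100) {
  10^seq(log10(lambda_min), log10(lambda_max), length.out = n_points)
}

# standardize features to mean 0 / unit population variance; constant columns
# are left centered at 0 so they can never be selected
standardize_features <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, pop_sd)
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  list(X = Xs, center = mu, scale = s)
}

binary_response <- function(table) {
  y <- table$label
  classes <- sort(unique(y))
  if (length(classes) != 2) abort("selection requires exactly two classes")
  as.numeric(y == classes[1])  # first sorted level coded 1
}

new_selection_result <- function(method, feature_names, scores, selected,
                                 lambda_opt = NULL, cv_curve = NULL) {
  stopifnot(length(scores) == length(feature_names))
  structure(list(method = method,
                 scores = tibble(feature = feature_names,
                                 score = unname(scores),
                                 selected = feature_names %in% selected),
                 selected = selected, lambda_opt = lambda_opt,
                 cv_curve = cv_curve),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d of %d features selected%s\n",
              x$method, length(x$selected), nrow(x$scores),
              if (!is.null(x$lambda_opt))
                sprintf(", lambda_opt = %.4g", x$lambda_opt) else ""))
  invisible(x)
}

#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$scores

#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(method = x$method, n_selected = length(x$selected),
         n_features = nrow(x$scores),
         lambda_opt = x$lambda_opt %||% NA_real_)
}

# retention rule shared by RF-MDA / RFE / ridge: positive score after
# rounding at 1e-4, capped at the top `cap` features
retain_by_score <- function(feature_names, scores, cutoff = NULL, cap = 20) {
  if (is.null(cutoff)) cutoff <- 1e-4
  pos <- which(round(scores, 4) >= cutoff & scores > 0)
  if (length(pos) > cap) pos <- pos[order(scores[pos], decreasing = TRUE)][seq_len(cap)]
  feature_names[sort(pos)]
}

#' Random-forest permutation importance (mean decrease in accuracy)
#'
#' Fits a random forest to the binary task and scores each feature by the
#' mean drop in out-of-bag accuracy when that feature's column is permuted,
#' averaged over `n_repeats` independent permutations. A constant column
#' scores exactly 0 by construction.
#'
#' @param table a `feature_table` with a binary `label`.
#' @param n_trees number of trees.
#' @param n_repeats permutation repeats per feature.
#' @param seed integer seed (forest and permutations).
#' @param cutoff,cap retention rule: keep features with score above `cutoff`
#'   (rounded at 1e-4), at most `cap` of them.
#' @return A `selection_result` with method `"RF_MDA"`.
#' @export
rf_mda_importance <- function(table, n_trees = 300, n_repeats = 5, seed = 0L,
                              cutoff = NULL, cap = 20) {
  X <- ft_features(table)
  fnames <- colnames(X)
  if (ncol(X) == 0) abort("no features")
  y <- factor(table$label)
  if (nlevels(y) != 2) abort("RF-MDA requires a binary task")
  if (n_repeats < 1) abort("`n_repeats` must be >= 1")
  df <- data.frame(.y = y, X, check.names = FALSE)
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = df, num.trees = n_trees,
    keep.inbag = TRUE, seed = seed, num.threads = 1,
    case.weights = table$weight
  )
  oob_mask <- !vapply(rf$inbag.counts, function(cnt) cnt > 0,
                      logical(nrow(df)))  # n x trees, TRUE where OOB
  y_int <- as.integer(y)
  # per-tree out-of-bag accuracy, averaged over trees (Breiman's accounting:
  # each tree is scored on its own out-of-bag samples)
  oob_acc <- function(data) {
    pred <- predict(rf, data, predict.all = TRUE, num.threads = 1)$predictions
    correct <- (pred == y_int) & oob_mask
    n_oob <- colSums(oob_mask)
    mean((colSums(correct) / n_oob)[n_oob > 0])
  }
  base_acc <- oob_acc(df)
  set.seed(seed)
  drops <- matrix(0, n_repeats, length(fnames))
  for (r in seq_len(n_repeats)) {
    for (j in seq_along(fnames)) {
      if (pop_sd(X[, j]) == 0) next  # permuting a constant is a no-op
      dfp <- df
      dfp[[fnames[j]]] <- sample(dfp[[fnames[j]]])
      drops[r, j] <- base_acc - oob_acc(dfp)
    }
  }
  scores <- colMeans(drops)
  new_selection_result("RF_MDA", fnames, scores,
                       retain_by_score(fnames, scores, cutoff, cap))
}

# coefficient-magnitude ranking used by RFE
rfe_rank_once <- function(X, y, weights, estimator, seed) {
  if (estimator == "lr") {
    std <- standardize_features(X)
    fit <- suppressWarnings(glmnet::glmnet(
      std$X, y, family = "binomial", alpha = 0, lambda = 1 / length(y),
      weights = weights, standardize = FALSE
    ))
    abs(as.numeric(fit$beta))
  } else {
    df <- data.frame(.y = y, X, check.names = FALSE)
    rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                         num.trees = 200, importance = "impurity",
                         seed = seed, num.threads = 1, case.weights = weights)
    unname(rf$variable.importance[colnames(X)])
  }
}

#' Recursive feature elimination
#'
#' Repeatedly fits a base estimator and drops the feature with the smallest
#' importance (coefficient magnitude for the regularized logistic estimator,
#' impurity importance for the forest) until `n_keep` features remain. The
#' recorded score of a feature is its elimination rank: `p` for the last
#' survivor down to 1 for the first feature dropped.
#'
#' @param table a `feature_table` with binary labels.
#' @param estimator `"lr"` (default) or `"rf"`.
#' @param n_keep number of features to retain, `1 <= n_keep <= p`.
#' @param seed integer seed (forest estimator).
#' @return A `selection_result` with method `"RFE"`; scores are ranks.
#' @export
rfe_select <- function(table, estimator = c("lr", "rf"), n_keep = 20, seed = 0L) {
  estimator <- match.arg(estimator)
  X <- ft_features(table)
  fnames <- colnames(X)
  p <- ncol(X)
  if (n_keep < 1 || n_keep > p) abort("`n_keep` must lie in [1, p]")
  y <- factor(table$label)
  if (nlevels(y) != 2) abort("RFE requires a binary task")
  y01 <- as.numeric(y == levels(y)[1])
  # full elimination order: score = survival rank (p for the last survivor)
  remaining <- seq_len(p)
  rank_score <- numeric(p)
  step <- 0
  while (length(remaining) > 1) {
    imp <- rfe_rank_once(X[, remaining, drop = FALSE], y01, table$weight,
                         estimator, seed + step)
    worst <- remaining[which.min(imp)]
    step <- step + 1
    rank_score[worst] <- step
    remaining <- setdiff(remaining, worst)
  }
  rank_score[remaining] <- p
  selected <- fnames[rank_score > p - n_keep]
  new_selection_result("RFE", fnames, rank_score, selected)
}

# closed-form ridge solution on standardized X, centered y:
# beta = (X'X + lambda I)^{-1} X'y  (objective RSS + lambda * ||beta||^2)
ridge_beta <- function(Xs, yc, lambda) {
  p <- ncol(Xs)
  solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yc))
}

cv_folds_assign <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' Ridge-regression feature scoring with a cross-validated lambda grid
#'
#' Solves the L2-penalized least-squares problem
#' `min sum (y_i - yhat_i)^2 + lambda * sum beta_j^2` in closed form on
#' standardized features, with the binary labels coded 0/1 as the response.
#' `lambda` is chosen from the grid (default 100 log-spaced points in
#' `[0.01, 100]`) by 10-fold cross-validated mean squared error; scores are
#' the absolute standardized coefficients at the optimum.
#'
#' @param table a `feature_table` with binary labels.
#' @param lambda_grid candidate lambda values (see [default_lambda_grid()]).
#' @param cv_folds number of cross-validation folds.
#' @param seed fold-assignment seed.
#' @param cutoff,cap retention rule as in [rf_mda_importance()].
#' @return A `selection_result` with method `"RIDGE"`, `lambda_opt` and the
#'   `(lambda, mean MSE)` curve.
#' @export
ridge_select <- function(table, lambda_grid = default_lambda_grid(),
                         cv_folds = 10, seed = 0L, cutoff = NULL, cap = 20) {
  if (length(lambda_grid) == 0) abort("`lambda_grid` is empty")
  X <- ft_features(table)
  y <- binary_response(table)
  std <- standardize_features(X)
  yc <- y - mean(y)
  fold <- cv_folds_assign(length(y), cv_folds, seed)
  mse <- matrix(NA_real_, cv_folds, length(lambda_grid))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    Xtr <- std$X[tr, , drop = FALSE]; ytr <- yc[tr]
    Xte <- std$X[!tr, , drop = FALSE]; yte <- yc[!tr]
    XtX <- crossprod(Xtr); Xty <- crossprod(Xtr, ytr)
    for (l in seq_along(lambda_grid)) {
      beta <- solve(XtX + diag(lambda_grid[l], ncol(Xtr)), Xty)
      mse[f, l] <- mean((yte - Xte %*% beta)^2)
    }
  }
  cv_curve <- tibble(lambda = lambda_grid, mean_mse = colMeans(mse))
  lambda_opt <- lambda_grid[which.min(cv_curve$mean_mse)]
  beta_opt <- ridge_beta(std$X, yc, lambda_opt)
  scores <- abs(as.numeric(beta_opt))
  new_selection_result("RIDGE", colnames(X), scores,
                       retain_by_score(colnames(X), scores, cutoff, cap),
                       lambda_opt = lambda_opt, cv_curve = cv_curve)
}

#' LASSO feature selection with a cross-validated lambda grid
#'
#' Minimizes `sum (y_i - yhat_i)^2 + lambda * sum |beta_j|` on standardized
#' features with the 0/1-coded labels as response (solved by glmnet, whose
#' penalty scale is mapped as `lambda / (2n)`). `lambda` is chosen on the
#' grid by cross-validated mean squared error, and the selected features are
#' those with nonzero coefficients at the optimum.
#'
#' @inheritParams ridge_select
#' @return A `selection_result` with method `"LASSO"`.
#' @export
lasso_select <- function(table, lambda_grid = default_lambda_grid(),
                         cv_folds = 10, seed = 0L) {
  if (length(lambda_grid) == 0) abort("`lambda_grid` is empty")
  X <- ft_features(table)
  y <- binary_response(table)
  if (pop_sd(y) == 0) abort("constant response")
  std <- standardize_features(X)
  yc <- y - mean(y)
  n <- length(y)
  glmnet_lambda <- sort(lambda_grid, decreasing = TRUE) / (2 * n)
  fold <- cv_folds_assign(n, cv_folds, seed)
  fit_cv <- glmnet::cv.glmnet(std$X, yc, alpha = 1, lambda = glmnet_lambda,
                              foldid = fold, standardize = FALSE,
                              intercept = FALSE, thresh = 1e-12)
  lambda_opt <- fit_cv$lambda.min * 2 * n
  beta <- as.numeric(glmnet::coef.glmnet(fit_cv, s = fit_cv$lambda.min))[-1]
  scores <- abs(beta)
  selected <- colnames(X)[beta != 0]
  cv_curve <- tibble(lambda = rev(fit_cv$lambda) * 2 * n,
                     mean_mse = rev(fit_cv$cvm))
  new_selection_result("LASSO", colnames(X), scores, selected,
                       lambda_opt = lambda_opt, cv_curve = cv_curve)
}

#' Fit the LASSO path at fixed lambda values (no cross-validation)
#'
#' Exposes the penalized solution itself so shrinkage behavior can be
#' examined directly: coefficients at `lambda >= lambda_max = max |X'y|`
#' (standardized, centered response) are all zero, and at `lambda = 0` the
#' solution matches ordinary least squares on full-rank designs.
#'
#' @param table a `feature_table`.
#' @param lambda single penalty value on the RSS + lambda*L1 scale.
#' @return Named numeric vector of standardized coefficients.
#' @export
lasso_path_beta <- function(table, lambda) {
  X <- ft_features(table)
  y <- binary_response_or_numeric(table)
  std <- standardize_features(X)
  yc <- y - mean(y)
  n <- length(y)
  # decreasing path ending at the requested lambda stabilizes the solver
  lmax <- 2 * max(abs(crossprod(std$X, yc)))  # all-zero point on that scale
  lo <- max(lambda, lmax * 1e-4)
  lam_seq <- exp(seq(log(lmax * 1.1), log(lo), length.out = 20))
  lam_seq[length(lam_seq)] <- lo  # exact endpoint, no float duplicate
  if (lambda < lo) lam_seq <- c(lam_seq, lambda)
  Xfit <- std$X
  if (ncol(Xfit) == 1) Xfit <- cbind(Xfit, 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(Xfit, yc, alpha = 1, lambda = lam_seq / (2 * n),
                        standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda / (2 * n),
                                         exact = TRUE, x = Xfit, y = yc))[-1]
  setNames(beta[seq_len(ncol(std$X))], colnames(X))
}

binary_response_or_numeric <- function(table) {
  if (is.numeric(table$label)) return(table$label)
  v <- suppressWarnings(as.numeric(table$label))
  if (!anyNA(v)) return(v)
  binary_response(table)
}

#' Feature-selection dispatcher
#'
#' Runs one of the four selectors with its per-method defaults and retention
#' rule: LASSO keeps nonzero-coefficient features; RF-MDA, RFE and ridge keep
#' positively scored features (configurable cutoff / top-k cap).
#'
#' @param table a `feature_table` with binary labels.
#' @param method `"RF_MDA"`, `"RFE"`, `"LASSO"` or `"RIDGE"`.
#' @param seed integer seed.
#' @param config named list of per-method overrides (`n_trees`, `n_repeats`,
#'   `estimator`, `n_keep`, `lambda_grid`, `cv_folds`, `cutoff`, `cap`).
#' @return A `selection_result`.
#' @export
select_features <- function(table, method = c("RF_MDA", "RFE", "LASSO", "RIDGE"),
                            seed = 0L, config = list()) {
  method <- match.arg(method)
  cfg <- function(name, default) config[[name]] %||% default
  switch(method,
    RF_MDA = rf_mda_importance(table, n_trees = cfg("n_trees", 300),
                               n_repeats = cfg("n_repeats", 5), seed = seed,
                               cutoff = cfg("cutoff", NULL), cap = cfg("cap", 20)),
    RFE = rfe_select(table, estimator = cfg("estimator", "lr"),
                     n_keep = cfg("n_keep", 20), seed = seed),
    LASSO = lasso_select(table, lambda_grid = cfg("lambda_grid", default_lambda_grid()),
                         cv_folds = cfg("cv_folds", 10), seed = seed),
    RIDGE = ridge_select(table, lambda_grid = cfg("lambda_grid", default_lambda_grid()),
                         cv_folds = cfg("cv_folds", 10), seed = seed,
                         cutoff = cfg("cutoff", NULL), cap = cfg("cap", 20))
  )
}

#' Write a selection result as CSV plus JSON metadata
#'
#' @param result a `selection_result`.
#' @param path CSV path (feature, score, selected); method, lambda and CV
#'   curve go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  readr::write_csv(result$scores, path)
  meta <- list(method = result$method, lambda_opt = result$lambda_opt,
               selected = result$selected)
  if (!is.null(result$cv_curve)) meta$cv_curve <- result$cv_curve
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
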