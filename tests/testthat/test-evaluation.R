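test_that("confusion metrics follow the definitional arithmetic", {
  perfect <- metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(perfect[1, 1:4]), c(accuracy = 1, precision = 1,
                                          recall = 1, f1 = 1))
  m <- metrics(c(TP = 8, FP = 2, FN = 2, TN = 8))
  expect_equal(unlist(m[1, 1:4]), c(accuracy = 0.8, precision = 0.8,
                                    recall = 0.8, f1 = 0.8))
  # zero denominator flags rather than throws
  z <- metrics(c(TP = 0, TN = 5, FP = 0, FN = 5))
  expect_true(z$flagged)
  expect_equal(z$precision, 0)
  expect_error(metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("confusion counts partition the evaluated samples", {
  set.seed(2)
  truth <- sample(c("P", "F"), 50, replace = TRUE)
  pred <- sample(c("P", "F"), 50, replace = TRUE)
  cc <- confusion_counts(truth, pred, positive = "P")
  expect_equal(sum(cc), 50)
  expect_equal(unname(cc["TP"]), sum(truth == "P" & pred == "P"))
})

test_that("ROC endpoints, monotonicity and the trivial AUC cases hold", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  flat <- roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(flat$auc, 0.5)
  expect_equal(nrow(flat$roc_points) >= 2, TRUE)
  set.seed(5)
  for (rep in 1:5) {
    n <- 50
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$roc_points$fpr[1], 0)
    expect_equal(r$roc_points$tpr[nrow(r$roc_points)], 1)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoidal AUC equals the concordance oracle up to n = 200", {
  set.seed(6)
  scores <- c(rnorm(120, 0.5), rnorm(80, 0))
  labels <- rep(c(TRUE, FALSE), c(120, 80))
  expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels),
               tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(7)
  scores <- rnorm(80)
  labels <- runif(80) < plogis(2 * scores)
  got <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("stratified 60/20/20 split is exact, proportional and seeded", {
  labels <- rep(daqu_grades(), each = 100)
  sp <- stratified_split(labels, seed = 3)
  expect_length(sp$train, 180)
  expect_length(sp$validation, 60)
  expect_length(sp$test, 60)
  expect_setequal(c(sp$train, sp$validation, sp$test), 1:300)
  for (g in daqu_grades()) {
    expect_equal(sum(labels[sp$test] == g), 20)
  }
  expect_identical(stratified_split(labels, seed = 3), sp)
  expect_false(identical(stratified_split(labels, seed = 4), sp))
  all_train <- stratified_split(labels, ratios = c(1, 0, 0))
  expect_length(all_train$train, 300)
  expect_error(stratified_split(c("P", "P", "F"), seed = 1), "3 members")
  expect_error(stratified_split(labels, ratios = c(0.5, 0.3, 0.3)), "sum")
})

test_that("cross-validation aggregates match the per-fold reports", {
  tb <- planted_table(11, n = 60, effect = 2)
  cv <- cross_validate(model_spec("LR", seed = 1), tb, folds = 5, seed = 2)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(cv$per_fold$accuracy))
  expect_equal(cv$summary$mean[cv$summary$metric == "f1"],
               mean(cv$per_fold$f1))
  # separable data scores 1 in every fold
  sep <- separable_table(seed = 2, n = 40)
  cvs <- cross_validate(model_spec("LR"), sep, folds = 4, seed = 1)
  expect_equal(mean(cvs$per_fold$accuracy), 1)
  expect_error(cross_validate(model_spec("LR"), tb, folds = 1), "folds")
  expect_error(cross_validate(model_spec("LR"), tb, folds = 40), "class size")
})

test_that("segmentation benchmark produces one metric row per method", {
  ds <- test_corpus(10, seed = 7)
  bench <- segmentation_benchmark(ds, seed = 1)
  expect_equal(nrow(bench), 3)
  expect_setequal(bench$method, c("threshold", "kmeans", "morph_fusion"))
  expect_true(all(!bench$failed))
  expect_true(all(bench$accuracy >= 0 & bench$accuracy <= 1, na.rm = TRUE))
  # determinism of metric rows (timings excluded)
  bench2 <- segmentation_benchmark(ds, seed = 1)
  expect_equal(dplyr::select(bench, -seconds),
               dplyr::select(bench2, -seconds))
})

test_that("k-means degrades under shadows where morphological fusion holds", {
  p <- test_params(shadow_strength = 0.4)
  jac <- function(img, method) {
    seg <- segment(img, method, seg_params(seed = 5))
    sum(seg$mask & img$truth$block) / sum(seg$mask | img$truth$block)
  }
  jk <- jm <- numeric(0)
  for (s in 1:4) {
    img <- generate_daqu_image("P", p, seed = 50 + s)
    jk <- c(jk, jac(img, "kmeans"))
    jm <- c(jm, jac(img, "morph_fusion"))
  }
  expect_lt(mean(jk), mean(jm))
})

test_that("selector x model grid covers every cell deterministically", {
  tb <- planted_table(12, n = 60, effect = 2)
  res <- grid_experiment(tb, selectors = c("RFE", "LASSO"),
                         models = c("LR", "KNN"), seed = 1)
  expect_equal(nrow(res$accuracy), 4)
  res_all <- grid_experiment(tb, selectors = c("ALL", "RFE"),
                             models = c("LR"), seed = 1)
  expect_equal(nrow(res_all$accuracy), 2)
  res2 <- grid_experiment(tb, selectors = c("RFE", "LASSO"),
                          models = c("LR", "KNN"), seed = 1)
  expect_equal(res$accuracy, res2$accuracy)
  tb3 <- planted_table(12, n = 60)
  tb3$grade <- tb3$label <- rep(c("P", "S"), 30)
  expect_error(grid_experiment(tb3), "P vs F")
})

test_that("PCA boundary plot writes a PNG with ordered components", {
  tb <- planted_table(13, n = 60, effect = 2)
  path <- withr::local_tempfile(fileext = ".png")
  out <- pca_boundary_plot(tb, model_spec("LR"), path, grid_n = 40)
  expect_true(file.exists(path))
  magic <- readBin(path, "raw", 8)
  expect_identical(magic[2:4], charToRaw("PNG"))
  scores <- out$pca$x
  expect_equal(colMeans(scores), rep(0, ncol(scores)), tolerance = 1e-9,
               ignore_attr = TRUE)
  vars <- apply(scores, 2, var)
  expect_true(all(diff(vars) <= 1e-9))
  const <- feature_table(data.frame(a = rep(1, 10), b = rep(2, 10)),
                         rep(c("P", "F"), 5))
  expect_error(pca_boundary_plot(const, model_spec("LR"), path), "constant")
})
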