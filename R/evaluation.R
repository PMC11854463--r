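#' Confusion counts for a binary task
#'
#' @param truth,pred vectors of class labels.
#' @param positive the positive-class label (layer 1: the pooled `"PF"`;
#'   layer 2: `"P"`).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  c(TP = sum(truth_pos & pred_pos), TN = sum(!truth_pos & !pred_pos),
    FP = sum(!truth_pos & pred_pos), FN = sum(truth_pos & !pred_pos))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' the F1 harmonic mean. A zero denominator yields a flagged 0 (column
#' `flagged`) rather than an error, so large experiment grids always
#' complete.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN` (total > 0).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `flagged`.
#' @export
#' @examples
#' metrics(c(TP = 8, TN = 8, FP = 2, FN = 2))
metrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0)) abort("counts must be non-negative TP/TN/FP/FN")
  total <- sum(counts)
  if (total == 0) abort("all counts are zero")
  flagged <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { flagged <<- TRUE; 0 } else num / den
  }
  accuracy <- (counts["TP"] + counts["TN"]) / total
  precision <- safe_div(counts["TP"], counts["TP"] + counts["FP"])
  recall <- safe_div(counts["TP"], counts["TP"] + counts["FN"])
  f1 <- if (precision + recall == 0) { flagged <- TRUE; 0 } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(accuracy = unname(accuracy), precision = unname(precision),
         recall = unname(recall), f1 = unname(f1), flagged = flagged)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct score values as thresholds (ties grouped), anchoring
#' the curve at (0, 0) and (1, 1), and integrates trapezoidally. With tied
#' scores this equals the Mann-Whitney concordance statistic with half credit
#' for ties.
#'
#' @param scores real-valued positive-class scores.
#' @param labels binary truth; either logical, 0/1, or labels with
#'   `positive` given.
#' @param positive positive-class label when `labels` is not logical/0-1.
#' @return List with `roc_points` (tibble `fpr`, `tpr`, non-decreasing, from
#'   (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (!is.null(positive)) labels <- labels == positive
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tpr <- c(0, tp[last] / n_pos, 1)
  fpr <- c(0, fp[last] / n_neg, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc_points = tibble(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified train/validation/test split
#'
#' Splits indices into train/validation/test preserving per-class proportions
#' within rounding; the partition is exact (disjoint and exhaustive) and
#' deterministic per seed. Defaults to the 60/20/20 protocol.
#'
#' @param labels class labels (every class needs at least 3 members).
#' @param ratios length-3 non-negative ratios summing to 1.
#' @param seed integer seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 0L) {
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-8) {
    abort("`ratios` must be three non-negative numbers summing to 1")
  }
  tab <- table(labels)
  if (any(tab < 3)) abort("every class needs at least 3 members")
  set.seed(as.integer(seed))
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- round(n * ratios[1])
    n_va <- round(n * ratios[2])
    if (n_tr + n_va > n) n_va <- n - n_tr
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$validation <- c(out$validation, idx[seq_len(n_va) + n_tr])
    if (n_tr + n_va < n) {
      out$test <- c(out$test, idx[(n_tr + n_va + 1):n])
    }
  }
  lapply(out, sort)
}

# deterministic stratified fold labels in 1..folds
stratified_fold_assign <- function(labels, folds, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold
}

eval_report <- function(counts, roc = NULL, model_desc = "", split_id = "",
                        seed = NA_integer_) {
  m <- metrics(counts)
  tibble(model = model_desc, split = split_id, seed = seed,
         TP = counts["TP"], TN = counts["TN"], FP = counts["FP"], FN = counts["FN"],
         accuracy = m$accuracy, precision = m$precision, recall = m$recall,
         f1 = m$f1, auc = if (is.null(roc)) NA_real_ else roc$auc,
         flagged = m$flagged)
}

#' Stratified k-fold cross-validation of a model spec
#'
#' @param spec a [model_spec()].
#' @param table a binary `feature_table`.
#' @param folds number of folds (each class must fill every fold).
#' @param seed fold-assignment seed.
#' @return List with `per_fold` (tibble of per-fold metrics) and `summary`
#'   (mean and sd of each metric).
#' @export
cross_validate <- function(spec, table, folds = 5, seed = 0L) {
  if (folds < 2) abort("`folds` must be >= 2")
  y <- as.character(table$label)
  if (folds > min(table(y))) abort("`folds` exceeds the smallest class size")
  fold <- stratified_fold_assign(y, folds, seed)
  pos <- positive_level(sort(unique(y)), attr(table, "task"))
  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- new_feature_table(table[fold != f, , drop = FALSE],
                            attr(table, "layer"), attr(table, "task"))
    te <- table[fold == f, , drop = FALSE]
    model <- train_model(spec, tr)
    pr <- predict(model, te)
    counts <- confusion_counts(te$label, pr$.pred_class, pos)
    roc <- if (length(unique(te$label)) == 2) {
      roc_auc(pr$.pred_score, te$label, positive = pos)
    } else NULL
    dplyr::mutate(eval_report(counts, roc, spec$algorithm,
                              sprintf("fold%d", f), seed),
                  fold = f)
  })
  num <- c("accuracy", "precision", "recall", "f1", "auc")
  summary <- tibble(
    metric = num,
    mean = vapply(num, function(m) mean(per_fold[[m]], na.rm = TRUE), 0,
                  USE.NAMES = FALSE),
    sd = vapply(num, function(m) sd(per_fold[[m]]), 0, USE.NAMES = FALSE)
  )
  list(per_fold = per_fold, summary = summary)
}

#' Train/test evaluation of one spec on a feature table
#'
#' Convenience harness: stratified 60/20/20 split, fit on the training set,
#' metrics on the test set.
#'
#' @inheritParams cross_validate
#' @param ratios split ratios.
#' @return One-row metrics tibble (an `eval_report`).
#' @export
holdout_evaluate <- function(spec, table, ratios = c(0.6, 0.2, 0.2), seed = 0L) {
  y <- as.character(table$label)
  split <- stratified_split(y, ratios, seed)
  tr <- new_feature_table(table[split$train, , drop = FALSE],
                          attr(table, "layer"), attr(table, "task"))
  te <- table[split$test, , drop = FALSE]
  pos <- positive_level(sort(unique(y)), attr(table, "task"))
  model <- train_model(spec, tr)
  pr <- predict(model, te)
  counts <- confusion_counts(te$label, pr$.pred_class, pos)
  roc <- if (length(unique(te$label)) == 2) {
    roc_auc(pr$.pred_score, te$label, positive = pos)
  } else NULL
  eval_report(counts, roc, spec$algorithm, "test", seed)
}

#' Compare the three segmentation back-ends on the layer-1 task
#'
#' For each method: segment the corpus, extract layer-1 features, train a
#' logistic-regression classifier under the layer-1 class weights on the
#' stratified 60/20/20 split, and report test metrics plus wall-clock
#' processing time (reported only, never asserted). A method failing on more
#' than 10% of images is flagged and skipped while the others proceed.
#'
#' @param dataset a balanced `daqu_dataset`.
#' @param methods segmentation methods to compare.
#' @param classifier_spec model for the comparison (default LR).
#' @param seed split seed.
#' @param seg_parameters shared [seg_params()].
#' @return Tibble: one row per method with metrics, `seconds` and `failed`.
#' @export
segmentation_benchmark <- function(dataset,
                                   methods = c("threshold", "kmeans", "morph_fusion"),
                                   classifier_spec = model_spec("LR"),
                                   seed = 0L, seg_parameters = seg_params()) {
  purrr::map_dfr(methods, function(m) {
    t0 <- proc.time()["elapsed"]
    tab <- tryCatch(
      build_feature_table(dataset, "L1", method = m, params = seg_parameters),
      error = function(e) NULL)
    secs <- unname(proc.time()["elapsed"] - t0)
    if (is.null(tab) || nrow(tab) < 0.9 * nrow(dataset$manifest)) {
      return(tibble(method = m, failed = TRUE, seconds = secs))
    }
    rep <- holdout_evaluate(classifier_spec, tab, seed = seed)
    dplyr::bind_cols(tibble(method = m, failed = FALSE, seconds = secs),
                     rep[, c("accuracy", "precision", "recall", "f1", "auc")])
  })
}

#' Selector x model accuracy grid for the layer-2 task
#'
#' Crosses feature-selection methods with classifiers on a premium/first
#' grade feature table: the selector runs on the training split, each model
#' is fitted on the selected features and scored on the test split. Cells
#' whose selector returns no features are flagged rather than fatal.
#'
#' @param table a layer-2 `feature_table` (grades P and F only).
#' @param selectors selector names (optionally including `"ALL"`, the
#'   identity selector baseline).
#' @param models classifier algorithm names.
#' @param seed split/selector/model seed.
#' @param detail_floor accuracy threshold above which full detail metrics are
#'   reported in `details`.
#' @return List with `accuracy` (selector x model tibble) and `details`
#'   (long tibble of full metrics).
#' @export
grid_experiment <- function(table,
                            selectors = c("RF_MDA", "RFE", "LASSO", "RIDGE"),
                            models = c("SVM", "RF", "LR", "KNN", "S_RF", "S_LR"),
                            seed = 0L, detail_floor = 0) {
  if (!all(unique(table$grade) %in% c("P", "F"))) {
    abort("grid_experiment expects a layer-2 (P vs F) table")
  }
  split <- stratified_split(as.character(table$label), seed = seed)
  tr_idx <- split$train; te_idx <- split$test
  details <- list(); acc <- list()
  for (sel in selectors) {
    tr <- new_feature_table(table[tr_idx, , drop = FALSE], attr(table, "layer"),
                            attr(table, "task"))
    feats <- if (sel == "ALL") ft_feature_names(table) else {
      res <- tryCatch(select_features(tr, sel, seed = seed),
                      error = function(e) NULL)
      if (is.null(res)) character(0) else res$selected
    }
    for (mod in models) {
      if (length(feats) == 0) {
        acc[[length(acc) + 1]] <- tibble(selector = sel, model = mod,
                                        accuracy = NA_real_, flagged = TRUE)
        next
      }
      tr_sub <- new_feature_table(tr[, c(ft_meta_cols, feats), drop = FALSE],
                                  "L2", "P_vs_F")
      te_sub <- table[te_idx, c(ft_meta_cols, feats), drop = FALSE]
      model <- train_model(model_spec(mod, seed = seed), tr_sub)
      pr <- predict(model, te_sub)
      counts <- confusion_counts(te_sub$label, pr$.pred_class, "P")
      roc <- roc_auc(pr$.pred_score, te_sub$label, positive = "P")
      rep <- eval_report(counts, roc, mod, "test", seed)
      acc[[length(acc) + 1]] <- tibble(selector = sel, model = mod,
                                      accuracy = rep$accuracy, flagged = FALSE)
      if (rep$accuracy >= detail_floor) {
        details[[length(details) + 1]] <- dplyr::mutate(rep, selector = sel)
      }
    }
  }
  list(accuracy = dplyr::bind_rows(acc),
       details = dplyr::bind_rows(details))
}

#' PCA decision-boundary plot
#'
#' Projects the features onto the first two principal components, trains the
#' model on the 2-D scores, rasterizes its decision regions over the score
#' range and overlays the sample scatter. Purely diagnostic.
#'
#' @param table a binary `feature_table` (at least two non-constant
#'   features).
#' @param spec a [model_spec()].
#' @param out_path PNG output path.
#' @param grid_n raster resolution per axis.
#' @return Invisibly, a list with the `prcomp` fit, the trained model and the
#'   ggplot object; the plot is written to `out_path`.
#' @export
pca_boundary_plot <- function(table, spec = model_spec("RF"), out_path,
                              grid_n = 120) {
  X <- ft_features(table)
  if (ncol(X) < 2) abort("need at least two features")
  if (all(apply(X, 2, pop_sd) == 0)) abort("constant feature table")
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pca$x[, 1:2, drop = FALSE]
  tab2 <- feature_table(data.frame(PC1 = scores[, 1], PC2 = scores[, 2]),
                        labels = table$label, weights = table$weight,
                        layer = attr(table, "layer"), task = attr(table, "task"))
  model <- train_model(spec, tab2)
  rng1 <- range(scores[, 1]); rng2 <- range(scores[, 2])
  pad <- 0.08
  gx <- seq(rng1[1] - pad * diff(rng1), rng1[2] + pad * diff(rng1), length.out = grid_n)
  gy <- seq(rng2[1] - pad * diff(rng2), rng2[2] + pad * diff(rng2), length.out = grid_n)
  grid <- tidyr::expand_grid(PC1 = gx, PC2 = gy)
  pr <- predict(model, grid)
  grid$region <- pr$.pred_class
  pts <- tibble(PC1 = scores[, 1], PC2 = scores[, 2], label = table$label)
  gg <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = grid,
                         ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                      fill = .data$region), alpha = 0.3) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                     color = .data$label), size = 1.4) +
    ggplot2::labs(title = sprintf("%s decision regions in PCA space",
                                  spec$algorithm),
                  x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
  grDevices::png(out_path, width = 900, height = 700, res = 120)
  print(gg)
  grDevices::dev.off()
  invisible(list(pca = pca, model = model, plot = gg))
}
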