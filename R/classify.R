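#' Model specification
#'
#' Describes one of the supported classifiers and its hyperparameters.
#' Defaults: SVM with RBF kernel and `C = 1` (gamma `1/(p * var)` via e1071);
#' random forest with 500 trees; L2-regularized logistic regression with unit
#' regularization strength; KNN with `k = 5` and distance ties broken by the
#' smallest training index. Stacking specs (`S_RF`, `S_LR`) fix the base
#' learners to RF, LR and KNN and take `folds` for the out-of-fold
#' meta-feature construction.
#'
#' @param algorithm one of `"SVM"`, `"RF"`, `"LR"`, `"KNN"`, `"S_RF"`,
#'   `"S_LR"`.
#' @param seed integer seed used wherever the algorithm is stochastic.
#' @param ... hyperparameter overrides (`cost`, `n_trees`, `k`, `lambda`,
#'   `folds`, `meta_feature` = `"prob"` or `"label"`).
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(algorithm = c("SVM", "RF", "LR", "KNN", "S_RF", "S_LR"),
                       seed = 0L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    SVM = list(cost = 1),
    RF = list(n_trees = 500),
    LR = list(lambda_strength = 1),
    KNN = list(k = 5),
    S_RF = list(folds = 5, meta_feature = "prob"),
    S_LR = list(folds = 5, meta_feature = "prob"))
  hp <- modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# standardization bound at fit time; trees consume raw features
needs_scaling <- function(algorithm) algorithm %in% c("SVM", "LR", "KNN")

scale_apply <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

check_binary_table <- function(table) {
  y <- factor(table$label)
  if (nlevels(y) < 2) abort("training table has a single class")
  if (nlevels(y) > 2) abort("base learners handle binary tasks only")
  y
}

positive_level <- function(levels_, task) {
  # layer-1 positive class is the pooled {P, F}; layer-2 positive class is P
  if ("PF" %in% levels_) "PF" else if ("P" %in% levels_) "P" else levels_[1]
}

#' Train a single base classifier
#'
#' Fits one of SVM, RF, LR or KNN on a binary feature table. Sample weights
#' are honored where the algorithm supports them (forest case weights,
#' logistic-regression observation weights); predictions expose both the
#' class and a positive-class score usable for ROC analysis. Fits are
#' deterministic given the spec seed.
#'
#' @param spec a [model_spec()] for `"SVM"`, `"RF"`, `"LR"` or `"KNN"`.
#' @param table a `feature_table` with a binary `label`.
#' @return An object of class `"daqu_model"`.
#' @export
train_base <- function(spec, table) {
  y <- check_binary_table(table)
  X <- ft_features(table)
  pos <- positive_level(levels(y), attr(table, "task"))
  scaling <- NULL
  if (needs_scaling(spec$algorithm)) {
    std <- standardize_features(X)
    scaling <- list(center = std$center, scale = std$scale)
    X <- std$X
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    SVM = {
      set.seed(spec$seed)
      e1071::svm(X, y, kernel = "radial", cost = hp$cost, probability = TRUE)
    },
    RF = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = hp$n_trees, probability = TRUE,
                     seed = spec$seed, num.threads = 1,
                     case.weights = table$weight)
    },
    LR = {
      Xfit <- if (ncol(X) == 1) cbind(X, .pad0 = 0) else X  # glmnet needs p >= 2
      suppressWarnings(glmnet::glmnet(
        Xfit, y, family = "binomial", alpha = 0,
        lambda = hp$lambda_strength / nrow(X),
        weights = table$weight, standardize = FALSE))
    },
    KNN = list(X = X, y = y, k = hp$k),
    abort("train_base handles SVM, RF, LR, KNN")
  )
  structure(list(spec = spec, fit = fit, scaling = scaling,
                 feature_names = ft_feature_names(table),
                 classes = levels(y), positive = pos),
            class = "daqu_model")
}

#' @export
print.daqu_model <- function(x, ...) {
  cat(sprintf("<daqu_model> %s on %d features (%s vs %s, positive %s)\n",
              x$spec$algorithm, length(x$feature_names),
              x$classes[1], x$classes[2], x$positive))
  invisible(x)
}

# deterministic KNN: Euclidean distances, neighbor ties broken by smallest
# training index, score = fraction of the k neighbors in the positive class
knn_predict <- function(fit, X, positive) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(fit$X))) +
    outer(rep(1, nrow(X)), rowSums(fit$X^2)) - 2 * X %*% t(fit$X)
  score <- apply(d2, 1, function(di) {
    nb <- order(di, seq_along(di))[seq_len(fit$k)]
    mean(fit$y[nb] == positive)
  })
  score
}

#' Predict with a trained base or stacking model
#'
#' @param object a `daqu_model`.
#' @param new_table a `feature_table` (or tibble containing the bound feature
#'   columns, same order).
#' @param ... unused.
#' @return A tibble with columns `.pred_class` and `.pred_score` (probability
#'   or decision score for the positive class).
#' @export
predict.daqu_model <- function(object, new_table, ...) {
  have <- intersect(object$feature_names, names(new_table))
  if (length(have) != length(object$feature_names)) {
    abort("prediction data lacks the features bound at fit time")
  }
  X <- as.matrix(new_table[, object$feature_names, drop = FALSE])
  if (!is.null(object$scaling)) X <- scale_apply(X, object$scaling)
  pos <- object$positive
  neg <- setdiff(object$classes, pos)
  score <- switch(object$spec$algorithm,
    SVM = {
      pr <- predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    RF = {
      pr <- predict(object$fit, data.frame(X, check.names = FALSE),
                    num.threads = 1)$predictions
      pr[, pos]
    },
    LR = {
      if (!is.null(object$fit$beta) && ".pad0" %in% rownames(object$fit$beta)) {
        X <- cbind(X, .pad0 = 0)
      }
      p2 <- as.numeric(predict(object$fit, X, type = "response"))
      # glmnet models Pr(second factor level)
      if (object$classes[2] == pos) p2 else 1 - p2
    },
    KNN = knn_predict(object$fit, X, pos)
  )
  tibble(.pred_class = ifelse(score >= 0.5, pos, neg),
         .pred_score = as.numeric(score))
}

#' Train a stacked ensemble (S-RF or S-LR)
#'
#' Base learners RF, LR and KNN are trained on the task; their out-of-fold
#' positive-class probabilities form the n x 3 meta-feature matrix on which
#' the meta learner (random forest for S-RF, logistic regression for S-LR) is
#' fitted. At prediction time the base learners — refitted on the full
#' training data — generate meta-features for new samples. Out-of-fold
#' construction keeps the meta learner from seeing base-learner fits of its
#' own training rows.
#'
#' @param spec a [model_spec()] with algorithm `"S_RF"` or `"S_LR"`.
#' @param table a `feature_table` with a binary `label`.
#' @return An object of class `"daqu_stacking"` (also usable with
#'   [predict.daqu_model()] semantics via its own `predict` method).
#' @export
train_stacking <- function(spec, table) {
  if (!spec$algorithm %in% c("S_RF", "S_LR")) {
    abort("`spec` must be S_RF or S_LR")
  }
  y <- check_binary_table(table)
  folds <- spec$hyperparameters$folds
  if (folds < 2) abort("`folds` must be >= 2")
  if (folds > nrow(table)) abort("`folds` exceeds the number of samples")
  base_algos <- c("RF", "LR", "KNN")
  pos <- positive_level(levels(y), attr(table, "task"))

  fold <- stratified_fold_assign(as.character(y), folds, spec$seed)
  meta <- matrix(NA_real_, nrow(table), length(base_algos),
                 dimnames = list(NULL, paste0("meta_", base_algos)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    sub <- table[tr, , drop = FALSE]
    sub <- new_feature_table(sub, attr(table, "layer"), attr(table, "task"))
    for (b in seq_along(base_algos)) {
      m <- train_base(model_spec(base_algos[b], seed = spec$seed), sub)
      pr <- predict(m, table[!tr, , drop = FALSE])
      if (spec$hyperparameters$meta_feature == "label") {
        meta[!tr, b] <- as.numeric(pr$.pred_class == pos)
      } else {
        meta[!tr, b] <- pr$.pred_score
      }
    }
  }
  base_models <- lapply(base_algos, function(a) {
    train_base(model_spec(a, seed = spec$seed), table)
  })
  names(base_models) <- base_algos

  meta_table <- feature_table(as.data.frame(meta), labels = as.character(y),
                              weights = table$weight,
                              layer = attr(table, "layer"),
                              task = attr(table, "task"))
  meta_algo <- if (spec$algorithm == "S_RF") "RF" else "LR"
  meta_model <- train_base(model_spec(meta_algo, seed = spec$seed), meta_table)

  structure(list(spec = spec, base_models = base_models,
                 meta_model = meta_model, meta_features = meta,
                 feature_names = ft_feature_names(table),
                 classes = levels(y), positive = pos),
            class = c("daqu_stacking", "daqu_model"))
}

#' @export
predict.daqu_stacking <- function(object, new_table, ...) {
  meta_feature <- object$spec$hyperparameters$meta_feature
  meta <- sapply(object$base_models, function(m) {
    pr <- predict(m, new_table)
    if (meta_feature == "label") {
      as.numeric(pr$.pred_class == object$positive)
    } else {
      pr$.pred_score
    }
  })
  if (is.null(dim(meta))) meta <- matrix(meta, nrow = 1)
  colnames(meta) <- paste0("meta_", names(object$base_models))
  predict(object$meta_model, as_tibble(as.data.frame(meta)))
}

#' Train a classifier of any supported algorithm
#'
#' Dispatcher over [train_base()] and [train_stacking()].
#'
#' @inheritParams train_base
#' @return A `daqu_model` or `daqu_stacking`.
#' @export
train_model <- function(spec, table) {
  if (spec$algorithm %in% c("S_RF", "S_LR")) train_stacking(spec, table)
  else train_base(spec, table)
}

#' Two-layer Daqu grade classifier
#'
#' Trains the full hierarchical decision: segmentation (configured back-end)
#' feeds layer-1 features on which a model separates second grade from the
#' pooled premium/first grade (class weights 1/1/2 by default); premium and
#' first-grade images then feed the layer-2 features, the configured selector
#' retains a feature subset, and the layer-2 model separates premium from
#' first grade on that subset.
#'
#' @param dataset a `daqu_dataset` containing all three grades.
#' @param seg_method segmentation back-end name.
#' @param selector_method one of the [select_features()] methods.
#' @param layer1_spec,layer2_spec [model_spec()]s for the two stages.
#' @param seg_parameters a [seg_params()] list.
#' @param selector_config per-method selector overrides.
#' @param dark_v_threshold,scale forwarded to feature extraction.
#' @param seed seed forwarded to the selector.
#' @return An object of class `"two_layer_classifier"`.
#' @export
train_two_layer <- function(dataset,
                            seg_method = "morph_fusion",
                            selector_method = "RF_MDA",
                            layer1_spec = model_spec("RF"),
                            layer2_spec = model_spec("S_RF"),
                            seg_parameters = seg_params(),
                            selector_config = list(),
                            dark_v_threshold = 0.25, scale = NULL,
                            seed = 0L) {
  if (!all(daqu_grades() %in% dataset$manifest$grade)) {
    abort("stage train_two_layer: all three grades must be present")
  }
  # segment each image once; both feature layers reuse the same masks
  segs <- attr(dataset, "segmentations") %||%
    purrr::map(dataset$images, segment, method = seg_method,
               params = seg_parameters)
  attr(dataset, "segmentations") <- segs
  l1 <- build_feature_table(dataset, "L1", method = seg_method,
                            params = seg_parameters,
                            dark_v_threshold = dark_v_threshold, scale = scale)
  layer1 <- train_model(layer1_spec, l1)
  l2 <- build_feature_table(dataset, "L2", method = seg_method,
                            params = seg_parameters,
                            dark_v_threshold = dark_v_threshold, scale = scale)
  selector <- select_features(l2, selector_method, seed = seed,
                              config = selector_config)
  sel_feats <- selector$selected
  if (length(sel_feats) == 0) abort("stage selector: empty feature subset")
  l2_sub <- new_feature_table(
    l2[, c(ft_meta_cols, sel_feats), drop = FALSE], "L2", "P_vs_F")
  layer2 <- train_model(layer2_spec, l2_sub)
  structure(list(layer1 = layer1, selector = selector, layer2 = layer2,
                 seg_method = seg_method, seg_parameters = seg_parameters,
                 dark_v_threshold = dark_v_threshold, scale = scale),
            class = "two_layer_classifier")
}

#' @export
print.two_layer_classifier <- function(x, ...) {
  cat(sprintf(paste0("<two_layer_classifier> seg %s | L1 %s | selector %s ",
                     "(%d features) | L2 %s\n"),
              x$seg_method, x$layer1$spec$algorithm, x$selector$method,
              length(x$selector$selected), x$layer2$spec$algorithm))
  invisible(x)
}

image_feature_row <- function(model, image, layer, seg) {
  fv <- extract_features(image, seg, layer, model$dark_v_threshold, model$scale)
  as_tibble(as.data.frame(t(fv)))
}

#' Predict the grade of a Daqu image with a two-layer classifier
#'
#' Layer 1 decides second grade versus the pooled premium/first grade; images
#' routed to second grade never touch layer 2 (`layer2_invoked` reports the
#' routing). Otherwise layer-2 features are extracted, the stored selector's
#' subset applied, and the layer-2 model separates premium from first grade.
#'
#' @param model a `two_layer_classifier`.
#' @param image a `daqu_image` or H x W x 3 raster.
#' @return A one-row tibble: `grade`, `layer1_score`, `layer2_score`
#'   (`NA` when layer 2 was not invoked) and `layer2_invoked`.
#' @export
predict_grade <- function(model, image) {
  seg <- segment(image, model$seg_method, model$seg_parameters)
  if (seg$degenerate) {
    abort(paste0("stage segmentation: degenerate mask for method ",
                 model$seg_method))
  }
  row1 <- image_feature_row(model, image, "L1", seg)
  p1 <- predict(model$layer1, row1)
  if (p1$.pred_class == "S") {
    return(tibble(grade = "S", layer1_score = p1$.pred_score,
                  layer2_score = NA_real_, layer2_invoked = FALSE))
  }
  row2 <- image_feature_row(model, image, "L2", seg)
  p2 <- predict(model$layer2, row2[, model$selector$selected, drop = FALSE])
  tibble(grade = p2$.pred_class, layer1_score = p1$.pred_score,
         layer2_score = p2$.pred_score, layer2_invoked = TRUE)
}
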