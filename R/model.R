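# Classification models for activity cliff compounds: random forest,
# extreme gradient boosting and an RBF support vector machine, each
# calibrated by grid search with stratified k-fold cross-validation
# (balanced accuracy as selection metric) and refit on the full training
# data with inverse-frequency class weights. Scores are
# probability-of-active for the tree ensembles and oriented decision values
# for the SVM.

#' Specify a classifier and its hyperparameter grid
#'
#' @param algo `"RF"`, `"XGB"` or `"SVM"`.
#' @param grid `data.frame` of candidate hyperparameter settings (one row
#'   per setting); `NULL` selects the built-in default grid:
#'   RF `ntree` \{100, 500\} x `max_depth` \{0 = unlimited, 10\};
#'   XGB `nrounds` \{100, 500\} x `max_depth` \{6, 10\} x `eta`
#'   \{0.1, 0.3\}; SVM (RBF kernel) `cost` \{0.1, 1, 10\} x `gamma`
#'   \{`NA` = 1/n-features heuristic, 0.01\}.
#' @param cv_folds folds of the stratified cross-validation (default 5).
#' @param seed integer seed for fold assignment and model fitting.
#' @return a `model_spec` object.
#' @export
model_spec <- function(algo = c("RF", "XGB", "SVM"), grid = NULL,
                       cv_folds = 5, seed = 1) {
  algo <- match.arg(algo)
  if (is.null(grid)) grid <- default_grid(algo)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, cv_folds >= 2)
  structure(list(algo = algo, grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

default_grid <- function(algo) {
  switch(algo,
    RF = expand.grid(ntree = c(100, 500), max_depth = c(0, 10)),
    XGB = expand.grid(nrounds = c(100, 500), max_depth = c(6, 10),
                      eta = c(0.1, 0.3)),
    SVM = expand.grid(cost = c(0.1, 1, 10), gamma = c(NA_real_, 0.01)))
}

#' Train a classifier with grid-search cross-validation
#'
#' Every grid row is scored by stratified k-fold cross-validation on the
#' training data using balanced accuracy of the thresholded predictions; the
#' best row (ties: first in grid order) is refit on all training data.
#' Minority classes smaller than the fold count shrink the effective fold
#' count; with fewer than 2 minority samples the first grid row is used
#' without cross-validation.
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (training compounds x features, with
#'   column names).
#' @param y 0/1 labels (both classes required).
#' @param weights named class weights (`"0"`, `"1"`); default
#'   [class_weights()] of `y`.
#' @return a `trained_model` with fields `spec`, `algo`, `chosen_params`,
#'   `cv_results`, `feature_ids`, and the fitted model.
#' @export
train_model <- function(spec, X, y, weights = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop_input("feature matrix needs column names")
  if (anyNA(X) || any(!is.finite(X))) stop_input("non-finite feature values")
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop_input("training labels contain one class only")
  weights <- weights %||% class_weights(y)
  grid <- spec$grid
  k <- min(spec$cv_folds, min(table(y)))
  cv <- NULL
  if (nrow(grid) > 1 && k >= 2) {
    folds <- with_seed(spec$seed, stratified_folds(y, k))
    cv_ba <- vapply(seq_len(nrow(grid)), function(g) {
      bas <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        fit <- fit_algo(spec$algo, grid[g, , drop = FALSE],
                        X[tr, , drop = FALSE], y[tr], weights,
                        seed = spec$seed + f)
        pred <- score_to_label(spec$algo,
                               score_algo(spec$algo, fit,
                                          X[!tr, , drop = FALSE]))
        cc <- confusion_counts(y[!tr], pred)
        if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) return(NA_real_)
        balanced_accuracy(cc)
      }, 1)
      mean(bas, na.rm = TRUE)
    }, 1)
    best <- which.max(cv_ba)
    cv <- cbind(grid, cv_ba = cv_ba)
  } else {
    best <- 1L
  }
  chosen <- grid[best, , drop = FALSE]
  fit <- fit_algo(spec$algo, chosen, X, y, weights, seed = spec$seed)
  structure(list(spec = spec, algo = spec$algo,
                 chosen_params = chosen, cv_results = cv,
                 feature_ids = colnames(X), fit = fit,
                 weights = weights, X = X, y = y),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %s on %d x %d, params: %s\n", x$algo,
              nrow(x$X), ncol(x$X),
              paste(names(x$chosen_params), unlist(x$chosen_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# fold id per sample, stratified by class
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_algo <- function(algo, params, X, y, weights, seed) {
  w0 <- unname(weights["0"]); w1 <- unname(weights["1"])
  switch(algo,
    RF = with_seed(seed, {
      maxnodes <- if (!is.null(params$max_depth) && params$max_depth > 0) {
        # a tree cannot have more leaves than training samples
        min(2^params$max_depth, nrow(X))
      } else NULL
      randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = params$ntree, classwt = c(w0, w1), maxnodes = maxnodes)
    }),
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(
        X, label = y, weight = ifelse(y == 1, w1, w0), nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    SVM = with_seed(seed, {
      gamma <- if (is.na(params$gamma)) 1 / ncol(X) else params$gamma
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = params$cost, gamma = gamma, scale = FALSE,
                 class.weights = c("0" = w0, "1" = w1))
    })
  )
}

# raw scores, oriented so that higher means more likely active (label 1)
score_algo <- function(algo, fit, X) {
  switch(algo,
    RF = unname(predict(fit, X, type = "prob")[, "1"]),
    XGB = {
      p <- predict(fit, xgboost::xgb.DMatrix(X, nthread = 1))
      as.numeric(p)
    },
    SVM = {
      pred <- predict(fit, X, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # e1071 orients decision values towards the first class of "a/b"
      if (startsWith(colnames(dv)[1], "1/")) dv[, 1] else -dv[, 1]
    })
}

score_to_label <- function(algo, scores) {
  thr <- if (algo == "SVM") 0 else 0.5
  as.integer(scores >= thr)
}

#' Predict real-valued activity scores
#'
#' @param model a [train_model()] result.
#' @param X feature matrix whose columns match the training representation
#'   exactly (same features, same order).
#' @return numeric vector of scores, higher = more likely active;
#'   probability-like in `[0, 1]` for RF/XGB (for RF, the fraction of trees
#'   voting active), signed decision values for SVM.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  X <- as.matrix(X)
  if (!identical(colnames(X), model$feature_ids)) {
    stop_input("feature columns do not match the training representation")
  }
  scores <- score_algo(model$algo, model$fit, X)
  names(scores) <- rownames(X)
  scores
}

#' Predict binary labels
#'
#' Thresholds [predict_scores()] at 0.5 (probability-like scores) or 0 (SVM
#' decision values).
#'
#' @inheritParams predict_scores
#' @return integer 0/1 vector.
#' @export
predict_labels <- function(model, X) {
  setNames(score_to_label(model$algo, predict_scores(model, X)),
           rownames(X))
}

#' 1-nearest-neighbor assay label transfer
#'
#' The control method: the profile assay most similar to the test assay
#' (Tanimoto over training compounds only; ties broken by ascending assay
#' id) is identified, and each test compound simply receives the label it
#' carries in that neighbor assay.
#'
#' @param m a [profiling_matrix()].
#' @param test_assay held-out assay.
#' @param profile_assays candidate neighbor assays (excluding the test
#'   assay).
#' @param train_compounds compounds used for the similarity computation.
#' @param test_compounds compounds to predict (disjoint from
#'   `train_compounds`).
#' @return named integer 0/1 vector of predicted labels, with attributes
#'   `j_nn` (the neighbor assay) and `tanimoto` (its similarity).
#' @export
one_nn_transfer <- function(m, test_assay, profile_assays, train_compounds,
                            test_compounds) {
  if (!length(profile_assays)) stop_input("empty profile assay set")
  if (length(intersect(train_compounds, test_compounds))) {
    stop_input("train and test compound sets overlap")
  }
  ranking <- rank_profile_assays(m, test_assay, profile_assays,
                                 train_compounds)
  j_nn <- ranking$profile_assay[1]
  pred <- pm_cells(m, test_compounds, j_nn)[, 1]
  out <- setNames(as.integer(pred), test_compounds)
  attr(out, "j_nn") <- j_nn
  attr(out, "tanimoto") <- ranking$tanimoto[1]
  out
}

#' Mean decrease in impurity feature importance
#'
#' For a trained random forest, sums the weighted Gini impurity decreases
#' over all nodes splitting on each feature,
#' `p(t) * (i(t) - p_L i(t_L) - p_R i(t_R))` with `p(t) = N_t / N` and
#' `p_L = N_tL / N_t`, averages over trees, and (by default) normalizes the
#' importances to sum to 1. Node sample counts and impurities are obtained
#' by routing the training data through every tree.
#'
#' @param model a [train_model()] result with `algo = "RF"`.
#' @param normalize normalize importances to sum to 1 (default `TRUE`).
#' @return named numeric vector of importances (one per feature, >= 0).
#' @export
mdi_importance <- function(model, normalize = TRUE) {
  stopifnot(inherits(model, "trained_model"))
  if (model$algo != "RF") {
    stop_input("MDI importance is defined for random forest models only")
  }
  X <- model$X
  y <- model$y
  N <- nrow(X)
  gini <- function(idx) {
    if (!length(idx)) return(0)
    p1 <- mean(y[idx] == 1)
    1 - p1^2 - (1 - p1)^2
  }
  acc <- setNames(numeric(ncol(X)), colnames(X))
  ntree <- model$fit$ntree
  for (k in seq_len(ntree)) {
    tr <- randomForest::getTree(model$fit, k, labelVar = FALSE)
    walk <- function(node, idx) {
      if (tr[node, "status"] == -1) return(invisible())
      v <- tr[node, "split var"]
      left <- idx[X[idx, v] <= tr[node, "split point"]]
      right <- setdiff(idx, left)
      p_t <- length(idx) / N
      p_l <- length(left) / length(idx)
      d <- gini(idx) - p_l * gini(left) - (1 - p_l) * gini(right)
      acc[v] <<- acc[v] + p_t * d
      walk(tr[node, "left daughter"], left)
      walk(tr[node, "right daughter"], right)
    }
    walk(1, seq_len(N))
  }
  acc <- acc / ntree
  acc[acc < 0] <- 0
  if (normalize && sum(acc) > 0) acc <- acc / sum(acc)
  acc
}
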