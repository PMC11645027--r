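# Classifier families behind one fit/predict surface:
#   svm_linear, svm_rbf  -> e1071::svm
#   knn                  -> stored-training nearest neighbours (uniform or
#                           distance-weighted votes)
#   dt                   -> rpart
#   rf                   -> ranger
#   gb                   -> xgboost (multi:softprob)
#   lr                   -> glmnet multinomial (L1 or L2)

ls_families <- function() {
  c("svm_linear", "svm_rbf", "knn", "dt", "rf", "gb", "lr", "mlp")
}

#' Hyperparameter grids for the classical model families
#'
#' Returns the full search grid per family: SVM costs spanning 0.1 to
#' 10^4 (with gamma 0.001 to 10 for the RBF kernel), 1 to 50 neighbours
#' with uniform or distance weights for KNN, tree depths 1 to 50 with
#' Gini or entropy splits for decision trees, forest/boosting grids over
#' ensemble size, depth and leaf sizes, and L1/L2 logistic regression
#' with C in 0.1 to 10. `NA` in a depth slot means unlimited depth.
#'
#' @return A named list of per-family grids (each a named list of value
#'   vectors).
#' @export
default_grids <- function() {
  list(
    svm_linear = list(C = c(0.1, 1, 10, 100, 1000, 10000)),
    svm_rbf = list(
      C = c(0.1, 1, 10, 100, 1000, 10000),
      gamma = c(0.001, 0.01, 0.1, 1, 10)
    ),
    knn = list(n_neighbors = 1:50, weights = c("uniform", "distance")),
    dt = list(max_depth = 1:50, criterion = c("gini", "entropy")),
    rf = list(
      n_estimators = c(50, 100, 200, 400, 600, 800, 1000, 1200),
      max_depth = c(NA, 5, 10, 20, 30, 50),
      min_samples_split = c(2, 5, 10),
      min_samples_leaf = c(1, 2, 4),
      bootstrap = c(TRUE, FALSE)
    ),
    gb = list(
      n_estimators = c(50, 100, 200, 400, 600, 800, 1000, 1200),
      learning_rate = c(0.1, 0.01, 0.001),
      max_depth = c(NA, 5, 10, 20, 30, 50),
      min_samples_split = c(2, 5, 10),
      min_samples_leaf = c(1, 2, 4)
    ),
    lr = list(C = c(0.1, 1, 10), penalty = c("L1", "L2"))
  )
}

#' Tuned hyperparameters used as per-family defaults
#'
#' One configuration per family, each a representable point of the
#' corresponding [default_grids()] grid, used when fitting without a
#' fresh grid search.
#'
#' @return A named list of per-family parameter lists.
#' @export
default_hyperparameters <- function() {
  list(
    svm_linear = list(C = 10),
    svm_rbf = list(C = 10, gamma = 0.001),
    knn = list(n_neighbors = 5, weights = "distance"),
    dt = list(max_depth = 12, criterion = "entropy"),
    rf = list(
      n_estimators = 50, max_depth = NA, min_samples_split = 2,
      min_samples_leaf = 2, bootstrap = FALSE
    ),
    gb = list(
      n_estimators = 600, learning_rate = 0.01, max_depth = 5,
      min_samples_split = 10, min_samples_leaf = 1
    ),
    lr = list(C = 0.1, penalty = "L2")
  )
}

#' Fit one classifier
#'
#' Fits a classifier of the given family on a feature table. Families:
#' `"svm_linear"`, `"svm_rbf"`, `"knn"`, `"dt"` (decision tree), `"rf"`
#' (random forest), `"gb"` (gradient boosting), `"lr"` (multinomial
#' logistic regression) and `"mlp"` (see [mlp_train()]).
#'
#' @param train Feature table with a `group` label column.
#' @param family One of the family names above.
#' @param params Named list of hyperparameters (see [default_grids()]);
#'   missing entries take [default_hyperparameters()] values.
#' @param seed Seed for stochastic learners.
#' @return An object of class `ls_classifier` with a `predict()` method
#'   returning a factor of class labels.
#' @export
fit_classifier <- function(train, family, params = list(), seed = 42) {
  family <- match.arg(family, ls_families())
  if (family == "mlp") {
    spec <- do.call(mlp_spec, params)
    return(mlp_train(train, spec, seed = seed))
  }
  params <- utils::modifyList(default_hyperparameters()[[family]], params)
  x <- feature_matrix(train)
  y <- droplevels(as.factor(train$group))

  fit <- with_seed(derive_seed(seed, paste0("fit_", family)), {
    switch(family,
      svm_linear = e1071::svm(x, y, kernel = "linear", cost = params$C,
                              scale = FALSE),
      svm_rbf = e1071::svm(x, y, kernel = "radial", cost = params$C,
                           gamma = params$gamma, scale = FALSE),
      knn = list(x = x, y = y, k = params$n_neighbors,
                 weights = params$weights),
      dt = {
        df <- data.frame(.y = y, x)
        rpart::rpart(.y ~ ., data = df, method = "class",
          parms = list(split = if (params$criterion == "gini") "gini" else "information"),
          control = rpart::rpart.control(
            maxdepth = min(params$max_depth, 30), cp = 0, xval = 0
          )
        )
      },
      rf = ranger::ranger(
        x = x, y = y,
        num.trees = params$n_estimators,
        max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
        min.node.size = params$min_samples_leaf,
        replace = isTRUE(params$bootstrap),
        sample.fraction = if (isTRUE(params$bootstrap)) 1 else 1,
        seed = derive_seed(seed, "ranger"),
        num.threads = 1
      ),
      gb = xgboost::xgb.train(
        params = list(
          objective = "multi:softprob", num_class = nlevels(y),
          eta = params$learning_rate,
          max_depth = if (is.na(params$max_depth)) 10 else params$max_depth,
          min_child_weight = params$min_samples_leaf,
          nthread = 1, seed = derive_seed(seed, "xgb")
        ),
        data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L),
        nrounds = params$n_estimators, verbose = 0
      ),
      lr = glmnet::glmnet(
        x, y, family = "multinomial",
        alpha = if (params$penalty == "L1") 1 else 0,
        lambda = 1 / (params$C * nrow(x))
      )
    )
  })
  structure(
    list(family = family, params = params, fit = fit, levels = levels(y),
         feature_names = colnames(x)),
    class = "ls_classifier"
  )
}

# Distance-weighted KNN prediction on a stored training set.
knn_predict <- function(fit, newx) {
  d2 <- outer(rowSums(newx^2), rowSums(fit$x^2), "+") -
    2 * newx %*% t(fit$x)
  d2[d2 < 0] <- 0
  lev <- levels(fit$y)
  pred <- character(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    ord <- order(d2[i, ])[seq_len(fit$k)]
    dd <- sqrt(d2[i, ord])
    votes <- if (fit$weights == "distance") {
      if (any(dd == 0)) {
        w <- as.numeric(dd == 0)
      } else {
        w <- 1 / dd
      }
      tapply(w, fit$y[ord], sum, default = 0)
    } else {
      tapply(rep(1, fit$k), fit$y[ord], sum, default = 0)
    }
    pred[i] <- lev[which.max(votes)]
  }
  factor(pred, levels = lev)
}

#' @export
predict.ls_classifier <- function(object, newdata, ...) {
  newx <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  newx <- newx[, object$feature_names, drop = FALSE]
  lev <- object$levels
  out <- switch(object$family,
    svm_linear = ,
    svm_rbf = predict(object$fit, newx),
    knn = knn_predict(object$fit, newx),
    dt = predict(object$fit, data.frame(newx), type = "class"),
    rf = predict(object$fit, data = newx, num.threads = 1)$predictions,
    gb = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(newx))
      if (is.null(dim(p))) p <- matrix(p, ncol = length(lev), byrow = TRUE)
      factor(lev[max.col(p)], levels = lev)
    },
    lr = {
      p <- predict(object$fit, newx, type = "class")
      factor(as.character(p), levels = lev)
    }
  )
  factor(as.character(out), levels = lev)
}

# Stratified fold assignment for cross-validation.
stratified_folds <- function(y, n_folds, seed) {
  with_seed(derive_seed(seed, "folds"), {
    fold <- integer(length(y))
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
    fold
  })
}

#' Exhaustive grid-search cross-validation
#'
#' Evaluates every point of the cartesian hyperparameter grid by
#' stratified k-fold cross-validated accuracy on the training table, ties
#' broken by first-in-grid order, then refits the winner on the full
#' training table.
#'
#' @param train Feature table with a `group` label column.
#' @param family Classifier family, see [fit_classifier()].
#' @param grid Named list of hyperparameter value vectors; defaults to
#'   the family's [default_grids()] entry.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Seed governing fold assignment and stochastic learners.
#' @return A list of class `ls_grid_search`: `model` (the refitted
#'   winner), `best_params`, and `cv_results` (a tibble of every grid
#'   point with its mean CV accuracy).
#' @export
grid_search_train <- function(train, family, grid = NULL, cv_folds = 5,
                              seed = 42) {
  family <- match.arg(family, setdiff(ls_families(), "mlp"))
  grid <- grid %||% default_grids()[[family]]
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    abort("`grid` must contain at least one value per hyperparameter.")
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  y <- droplevels(as.factor(train$group))
  fold <- stratified_folds(y, cv_folds, seed)

  acc <- vapply(seq_len(nrow(combos)), function(i) {
    params <- as.list(combos[i, , drop = FALSE])
    fold_acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- train[fold != f, ]
      te <- train[fold == f, ]
      m <- fit_classifier(tr, family, params, seed = seed)
      mean(predict(m, te) == te$group)
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))

  best <- which.max(acc) # which.max returns the first maximum: grid order
  best_params <- as.list(combos[best, , drop = FALSE])
  model <- fit_classifier(train, family, best_params, seed = seed)
  structure(
    list(
      model = model,
      best_params = best_params,
      cv_results = dplyr::bind_cols(
        tibble::as_tibble(combos),
        tibble::tibble(cv_accuracy = acc)
      )
    ),
    class = "ls_grid_search"
  )
}
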