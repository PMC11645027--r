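#' Evaluate a fitted classifier on a test set
#'
#' Computes the confusion matrix (rows = true classes, columns =
#' predicted), overall accuracy (trace over total), and per-class
#' precision, recall and F1 aggregated by the chosen average. Classes
#' absent from the test set, or never predicted, get zero-division-guarded
#' metrics (0) and are flagged in the per-class table.
#'
#' @param model An `ls_classifier` (or an `ls_grid_search`, whose winner
#'   is used).
#' @param test Feature table with a `group` label column.
#' @param metric_average `"weighted"` (by true class support, default) or
#'   `"macro"`.
#' @return An object of class `ls_eval`: accuracy, precision, recall,
#'   f1, `per_class` tibble, `confusion_matrix`, and the model's
#'   hyperparameters. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' \donttest{
#' toy <- tibble::tibble(
#'   group = factor(rep(c("a", "b"), each = 20)),
#'   f1 = c(rnorm(20, 0), rnorm(20, 4))
#' )
#' parts <- split_cohort(toy, seed = 1)
#' m <- fit_classifier(parts$train, "svm_linear")
#' glance(evaluate_model(m, parts$test))
#' }
#' @export
evaluate_model <- function(model, test,
                           metric_average = c("weighted", "macro")) {
  metric_average <- match.arg(metric_average)
  if (inherits(model, "ls_grid_search")) model <- model$model
  if (nrow(test) == 0) abort("`test` is empty.")
  truth <- factor(as.character(test$group), levels = model$levels)
  pred <- predict(model, test)
  cm <- table(truth = truth, predicted = pred)

  support <- rowSums(cm)
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble::tibble(
    class = model$levels,
    support = as.integer(support),
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    degenerate = support == 0 | pred_pos == 0
  )
  if (any(per_class$degenerate)) {
    warn("Some classes are absent from the test set or never predicted; their metrics are zero-division guarded.")
  }

  w <- if (metric_average == "weighted") support / sum(support) else {
    rep(1 / length(support), length(support))
  }
  structure(
    list(
      accuracy = sum(tp) / sum(cm),
      precision = sum(w * precision),
      recall = sum(w * recall),
      f1 = sum(w * f1),
      per_class = per_class,
      confusion_matrix = cm,
      metric_average = metric_average,
      model_family = model$family,
      best_hyperparameters = model$params
    ),
    class = "ls_eval"
  )
}

#' @method print ls_eval
#' @export
print.ls_eval <- function(x, ...) {
  cat(sprintf(
    "<ls_eval: %s> accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f (%s average)\n",
    x$model_family, x$accuracy, x$precision, x$recall, x$f1, x$metric_average
  ))
  print(x$confusion_matrix)
  invisible(x)
}

#' Tidy an evaluation into per-class metrics
#'
#' @param x An `ls_eval`.
#' @param ... Unused.
#' @return A tibble with one row per class: support, precision, recall, f1.
#' @export
tidy.ls_eval <- function(x, ...) {
  x$per_class
}

#' One-row summary of an evaluation
#'
#' @param x An `ls_eval`.
#' @param ... Unused.
#' @return A one-row tibble: model, accuracy, precision, recall, f1,
#'   n_test.
#' @export
glance.ls_eval <- function(x, ...) {
  tibble::tibble(
    model = x$model_family,
    accuracy = x$accuracy,
    precision = x$precision,
    recall = x$recall,
    f1 = x$f1,
    metric_average = x$metric_average,
    n_test = sum(x$confusion_matrix)
  )
}

#' Per-epoch training-loss history of a fitted MLP
#'
#' @param x An `ls_mlp` from [mlp_train()].
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @export
tidy.ls_mlp <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$fit$history), loss = x$fit$history)
}
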