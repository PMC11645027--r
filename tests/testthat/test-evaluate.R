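# Build a classifier that deterministically predicts `pred` for `test`
# by storing each test point as its own 1-nearest-neighbour with the
# desired output label.
mock_predictor <- function(test, pred) {
  structure(
    list(
      family = "knn",
      params = list(n_neighbors = 1, weights = "uniform"),
      fit = list(x = as.matrix(test[setdiff(names(test), "group")]),
                 y = factor(pred, levels = levels(test$group)),
                 k = 1, weights = "uniform"),
      levels = levels(test$group),
      feature_names = setdiff(names(test), "group")
    ),
    class = "ls_classifier"
  )
}

test_that("perfect predictions give unit metrics and a diagonal matrix", {
  test <- tibble::tibble(
    group = factor(rep(c("a", "b", "c"), each = 4)),
    f1 = seq_len(12)
  )
  ev <- evaluate_model(mock_predictor(test, test$group), test)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
  expect_equal(sum(ev$confusion_matrix) - sum(diag(ev$confusion_matrix)), 0)
})

test_that("metrics match hand computation for a fixed confusion matrix", {
  # target matrix (rows true, cols predicted):
  #   [[5,0,0],
  #    [1,4,0],
  #    [0,2,3]]
  truth <- rep(c("a", "b", "c"), each = 5)
  pred <- c(rep("a", 5), "a", rep("b", 4), "b", "b", "c", "c", "c")
  test <- tibble::tibble(
    group = factor(truth),
    f1 = seq_len(15)
  )
  ev <- evaluate_model(mock_predictor(test, pred), test, "macro")
  expect_equal(as.vector(ev$confusion_matrix),
               c(5, 1, 0, 0, 4, 2, 0, 0, 3))
  expect_equal(ev$accuracy, 12 / 15)
  # hand-computed per class: precision 5/6, 2/3, 1; recall 1, .8, .6
  expect_equal(tidy(ev)$precision, c(5 / 6, 2 / 3, 1))
  expect_equal(tidy(ev)$recall, c(1, 0.8, 0.6))
  expect_equal(tidy(ev)$f1, c(10 / 11, 8 / 11, 0.75))
  expect_equal(ev$precision, mean(c(5 / 6, 2 / 3, 1)))
  expect_equal(ev$f1, mean(c(10 / 11, 8 / 11, 0.75)))
  # equal support: weighted equals macro
  evw <- evaluate_model(mock_predictor(test, pred), test, "weighted")
  expect_equal(evw$precision, ev$precision)
})

test_that("an all-one-class predictor scores chance accuracy when balanced", {
  test <- tibble::tibble(
    group = factor(rep(c("a", "b", "c", "d"), each = 5)),
    f1 = seq_len(20)
  )
  expect_warning(
    ev <- evaluate_model(mock_predictor(test, rep("a", 20)), test),
    "never predicted"
  )
  expect_equal(ev$accuracy, 1 / 4)
  expect_true(all(tidy(ev)$degenerate[-1]))
})

test_that("glance produces the one-row report", {
  test <- tibble::tibble(group = factor(rep(c("a", "b"), 5)), f1 = 1:10)
  g <- glance(evaluate_model(mock_predictor(test, test$group), test))
  expect_equal(nrow(g), 1)
  expect_named(g, c("model", "accuracy", "precision", "recall", "f1",
                    "metric_average", "n_test"))
  expect_equal(g$n_test, 10L)
})

test_that("confusion-matrix row sums equal per-class test counts", {
  test <- tibble::tibble(
    group = factor(rep(c("a", "b", "c"), times = c(7, 5, 3))),
    f1 = seq_len(15)
  )
  set.seed(9)
  pred <- sample(c("a", "b", "c"), 15, replace = TRUE)
  ev <- suppressWarnings(evaluate_model(mock_predictor(test, pred), test))
  expect_equal(as.vector(rowSums(ev$confusion_matrix)), c(7, 5, 3))
  expect_equal(ev$accuracy,
               sum(diag(ev$confusion_matrix)) / sum(ev$confusion_matrix))
})
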