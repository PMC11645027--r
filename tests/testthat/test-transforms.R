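make_imbalanced <- function(seed = 1) {
  set.seed(seed)
  counts <- c(NonLS = 47, Stage1 = 29, Stage2 = 49, Young = 49)
  purrr::map_dfr(names(counts), function(g) {
    n <- counts[[g]]
    tibble::tibble(
      participant_id = sprintf("%s_%d", g, seq_len(n)),
      group = factor(g, levels = c("Young", "NonLS", "Stage1", "Stage2")),
      f1 = rnorm(n, which(names(counts) == g)),
      f2 = rnorm(n),
      f3 = rnorm(n)
    )
  })
}

test_that("SMOTE equalizes the study's class sizes at the majority count", {
  tab <- make_imbalanced()
  bal <- smote_balance(tab, k = 5, seed = 42)
  counts <- table(bal$group)
  expect_true(all(counts == 49))
  expect_equal(sum(bal$group == "Stage1"), 49) # 29 -> 49
  expect_equal(nrow(bal), 196)
})

test_that("SMOTE preserves originals and interpolates between class members", {
  tab <- make_imbalanced()
  bal <- smote_balance(tab, k = 5, seed = 42)
  expect_identical(bal[seq_len(nrow(tab)), names(tab)], tibble::as_tibble(tab))
  synth <- bal[-seq_len(nrow(tab)), ]
  expect_true(all(synth$group %in% c("NonLS", "Stage1")))
  # every synthetic point lies componentwise inside its class's range
  # (necessary consequence of segment interpolation between members)
  for (cls in unique(as.character(synth$group))) {
    orig <- tab[tab$group == cls, c("f1", "f2", "f3")]
    s <- synth[synth$group == cls, c("f1", "f2", "f3")]
    for (col in c("f1", "f2", "f3")) {
      expect_true(all(s[[col]] >= min(orig[[col]]) - 1e-12))
      expect_true(all(s[[col]] <= max(orig[[col]]) + 1e-12))
    }
  }
})

test_that("SMOTE is deterministic, identity on balance, and guards k", {
  tab <- make_imbalanced()
  expect_identical(smote_balance(tab, seed = 7), smote_balance(tab, seed = 7))
  balanced <- tab[tab$group %in% c("Stage2", "Young"), ]
  balanced$group <- droplevels(balanced$group)
  expect_identical(smote_balance(balanced, seed = 1),
                   tibble::as_tibble(balanced))
  expect_error(smote_balance(tab, k = 29), "smallest class")
})

test_that("stratified split honours per-class ceilings and the seed", {
  toy <- tibble::tibble(
    group = factor(rep(c("a", "b"), each = 5)),
    f1 = rnorm(10)
  )
  parts <- split_cohort(toy, test_fraction = 0.2, seed = 1)
  expect_equal(nrow(parts$test), 2)
  expect_equal(as.vector(table(parts$test$group)), c(1, 1))

  big <- make_imbalanced()
  bal <- smote_balance(big, seed = 42) # 196 rows, 4 x 49
  parts <- split_cohort(bal, test_fraction = 0.2, seed = 42)
  expect_equal(nrow(parts$test), 40)
  expect_true(all(table(parts$test$group) == 10))
  expect_equal(nrow(parts$train) + nrow(parts$test), 196)

  again <- split_cohort(bal, test_fraction = 0.2, seed = 42)
  expect_identical(parts$test, again$test)
  expect_error(split_cohort(toy[c(1, 6, 7), ], 0.2), "at least 2")
})

test_that("z-scoring fits on train only and standardizes train exactly", {
  train <- tibble::tibble(group = factor(c("a", "b")), f1 = c(1, 3))
  test <- tibble::tibble(group = factor(c("a")), f1 = 2)
  out <- zscore_transform(train, test)
  expect_equal(out$train$f1, c(-sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(out$test$f1, 0) # transformed with TRAIN stats

  # test statistics must not leak: same train, different test, same scaler
  out2 <- zscore_transform(train, dplyr::mutate(test, f1 = f1 + 100))
  expect_identical(out$scaler, out2$scaler)

  blobs <- make_blobs(n_per_class = 15)
  parts <- split_cohort(blobs, seed = 3)
  z <- zscore_transform(parts$train, parts$test)
  mus <- vapply(z$train[paste0("f", 1:4)], mean, numeric(1))
  sds <- vapply(z$train[paste0("f", 1:4)], sd, numeric(1))
  expect_true(all(abs(mus) < 1e-12))
  expect_equal(unname(sds), rep(1, 4))
})

test_that("constant columns are dropped with a warning; all-constant errors", {
  train <- tibble::tibble(group = factor(c("a", "b", "a", "b")),
                          f1 = rnorm(4), f2 = rep(3, 4))
  expect_warning(out <- zscore_transform(train, train), "constant")
  expect_false("f2" %in% names(out$train))
  allc <- tibble::tibble(group = factor(c("a", "b")), f1 = c(1, 1))
  expect_error(suppressWarnings(zscore_transform(allc, allc)), "constant")
})

test_that("PCA retains components per explained variance", {
  # data on a 3-dimensional subspace plus tiny noise -> 3 components at 0.99
  set.seed(11)
  basis <- matrix(rnorm(3 * 10), 3, 10)
  scores <- matrix(rnorm(60 * 3, sd = c(3, 2, 1)), 60, 3, byrow = TRUE)
  x <- scores %*% basis + matrix(rnorm(600, sd = 1e-4), 60, 10)
  d <- tibble::as_tibble(as.data.frame(x))
  names(d) <- paste0("f", 1:10)
  d$group <- factor(rep(c("a", "b"), 30))
  parts <- split_cohort(d, seed = 5)
  red <- pca_reduce(parts$train, parts$test, pca_variance = 0.99)
  expect_equal(red$n_components, 3)
  # components orthonormal
  g <- crossprod(red$rotation)
  expect_equal(g, diag(3), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("full-variance PCA keeps min(n-1, p) components of full-rank data", {
  blobs <- make_blobs(n_per_class = 10, p = 4)
  parts <- split_cohort(blobs, seed = 2)
  red <- pca_reduce(parts$train, parts$test, pca_variance = 1.0)
  expect_equal(red$n_components, min(nrow(parts$train) - 1, 4))
})

test_that("PCA reconstruction error decreases monotonically with k", {
  blobs <- make_blobs(n_per_class = 20, p = 6, sep = 2)
  parts <- split_cohort(blobs, seed = 4)
  xm <- as.matrix(parts$train[paste0("f", 1:6)])
  errs <- vapply(1:6, function(k) {
    red <- pca_reduce(parts$train, parts$test, n_components = k)
    recon <- as.matrix(red$train[paste0("PC", seq_len(k))]) %*% t(red$rotation)
    recon <- sweep(recon, 2, -red$center)
    sum((xm - recon)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))
})

test_that("mutual-information ranking puts signal first and noise last", {
  set.seed(21)
  n <- 120
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  d <- tibble::tibble(
    group = y,
    copy = as.numeric(y), # the label itself as a feature
    informative = as.numeric(y) * 2 + rnorm(n, sd = 0.3),
    noise = rnorm(n)
  )
  parts <- split_cohort(d, seed = 6)
  sel <- select_k_best_mi(parts$train, parts$test, k = 2, seed = 1)
  expect_equal(sel$scores$feature[1], "copy")
  expect_lt(sel$scores$mi[sel$scores$feature == "noise"],
            sel$scores$mi[sel$scores$feature == "informative"])
  expect_true(all(c("copy", "informative") %in% names(sel$train)))
  expect_false("noise" %in% names(sel$train))

  # k = p keeps every feature
  all_kept <- select_k_best_mi(parts$train, parts$test, k = 3, seed = 1)
  expect_setequal(setdiff(names(all_kept$train), "group"),
                  c("copy", "informative", "noise"))
  expect_error(select_k_best_mi(parts$train, parts$test, k = 9), "between")
})
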