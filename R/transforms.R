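# Column bookkeeping shared by the modeling stage: metadata columns are
# never treated as features.
meta_cols <- function(data) {
  intersect(names(data), c("participant_id", "group", "sex", "age_years",
                           "glfs_score"))
}

feature_cols <- function(data) {
  cand <- setdiff(names(data), meta_cols(data))
  cand[vapply(data[cand], is.numeric, logical(1))]
}

feature_matrix <- function(data) {
  as.matrix(data[feature_cols(data)])
}

#' Balance classes with SMOTE oversampling
#'
#' Grows every minority class to the majority class's size by
#' interpolating synthetic samples: each synthetic row is
#' `x + u * (x_nn - x)` for a random same-class sample `x`, one of its
#' `k` nearest same-class neighbours `x_nn` (Euclidean distance in
#' feature space), and `u ~ Uniform(0, 1)`. Original rows are preserved
#' verbatim; synthetic rows get generated participant ids and `NA`
#' metadata.
#'
#' @param data A feature table with a `group` label column and numeric
#'   feature columns.
#' @param k Number of nearest neighbours to interpolate towards.
#' @param seed Integer seed; the result is deterministic given it.
#' @param label_col Name of the class label column.
#'
#' @return The balanced tibble: all original rows, then synthetic rows.
#' @export
smote_balance <- function(data, k = 5, seed = 42, label_col = "group") {
  labels <- as.factor(data[[label_col]])
  counts <- table(droplevels(labels))
  n_max <- max(counts)
  fcols <- feature_cols(data)
  x <- as.matrix(data[fcols])

  deficits <- counts[counts < n_max]
  for (cls in names(deficits)) {
    n_cls <- counts[[cls]]
    if (n_cls <= k) {
      abort(sprintf(
        "Class '%s' has %d rows but k = %d; choose k < the smallest class size.",
        cls, n_cls, k
      ))
    }
  }
  if (length(deficits) == 0) {
    return(tibble::as_tibble(data))
  }

  synth <- with_seed(derive_seed(seed, "smote"), {
    purrr::map_dfr(names(deficits), function(cls) {
      idx <- which(labels == cls)
      xc <- x[idx, , drop = FALSE]
      d <- as.matrix(dist(xc))
      diag(d) <- Inf
      # k nearest same-class neighbours of every class member
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
      n_new <- n_max - length(idx)
      base <- sample.int(length(idx), n_new, replace = TRUE)
      pick <- sample.int(k, n_new, replace = TRUE)
      u <- runif(n_new)
      new_x <- xc[base, , drop = FALSE] +
        u * (xc[nn[cbind(base, pick)], , drop = FALSE] - xc[base, , drop = FALSE])
      out <- tibble::as_tibble(as.data.frame(new_x))
      names(out) <- fcols
      out[[label_col]] <- factor(rep(cls, n_new), levels = levels(labels))
      if ("participant_id" %in% names(data)) {
        out$participant_id <- sprintf("smote_%s_%03d", cls, seq_len(n_new))
      }
      out
    })
  })
  dplyr::bind_rows(tibble::as_tibble(data), synth)
}

#' Stratified train/test split
#'
#' Splits a feature table into train and test partitions, stratified by
#' class: each class contributes `ceiling(test_fraction * n_class)` rows
#' to the test set. Reproducible under `seed`.
#'
#' @inheritParams smote_balance
#' @param test_fraction Fraction of each class held out for testing.
#' @param seed Split seed (default 42).
#' @return A list with `train` and `test` tibbles (disjoint).
#' @export
split_cohort <- function(data, test_fraction = 0.2, seed = 42,
                         label_col = "group") {
  assert_scalar_number(test_fraction, "test_fraction", 0, upper = 1,
                       strict_lower = TRUE)
  if (test_fraction >= 1) abort("`test_fraction` must be strictly below 1.")
  labels <- as.factor(data[[label_col]])
  counts <- table(droplevels(labels))
  if (any(counts < 2)) {
    abort("Every class needs at least 2 rows for a stratified split.")
  }
  test_idx <- with_seed(derive_seed(seed, "split"), {
    unlist(purrr::map(names(counts), function(cls) {
      idx <- which(labels == cls)
      sample(idx, ceiling(test_fraction * length(idx)))
    }))
  })
  list(
    train = tibble::as_tibble(data[-test_idx, ]),
    test = tibble::as_tibble(data[test_idx, ])
  )
}

#' Z-score normalization fitted on the training set only
#'
#' Standardizes every feature column to training mean 0 and training
#' sample standard deviation 1, then applies the *training* statistics to
#' the test set, so no information flows from test to train. Constant
#' training columns are dropped with a warning.
#'
#' @param train,test Feature tables from [split_cohort()].
#' @return A list with transformed `train`, `test`, and the `scaler`
#'   (means, sds, retained columns).
#' @export
zscore_transform <- function(train, test) {
  fcols <- feature_cols(train)
  mu <- vapply(train[fcols], mean, numeric(1))
  sigma <- vapply(train[fcols], sd, numeric(1))
  keep <- sigma > 0
  if (!any(keep)) abort("All feature columns are constant; nothing to scale.")
  if (any(!keep)) {
    warn(paste0("Dropping constant feature column(s): ",
                paste(fcols[!keep], collapse = ", ")))
  }
  fcols <- fcols[keep]
  mu <- mu[keep]
  sigma <- sigma[keep]
  apply_scale <- function(d) {
    d <- d[c(setdiff(meta_cols(d), character()), fcols)]
    for (j in seq_along(fcols)) {
      d[[fcols[j]]] <- (d[[fcols[j]]] - unname(mu[j])) / unname(sigma[j])
    }
    tibble::as_tibble(d)
  }
  list(
    train = apply_scale(train),
    test = apply_scale(test),
    scaler = list(mean = mu, sd = sigma, columns = fcols)
  )
}

#' PCA dimensionality reduction
#'
#' Projects the (standardized) features onto principal components. The
#' number of retained components is the smallest count whose cumulative
#' explained variance reaches `pca_variance`, unless a fixed
#' `n_components` is given. By default components are fitted on the
#' training rows only and the test rows are projected with them; with
#' `whole_data_order = TRUE` the components are fitted on train and test
#' together (whole-dataset reduction).
#'
#' @param train,test Standardized feature tables.
#' @param pca_variance Target cumulative explained-variance fraction in
#'   (0, 1].
#' @param n_components Optional fixed component count (overrides
#'   `pca_variance`).
#' @param whole_data_order Fit the rotation on the pooled train + test rows?
#' @return A list with transformed `train` and `test` (columns
#'   `PC1...PCk` plus metadata), `rotation`, `center`,
#'   `explained_variance` and `n_components`.
#' @export
pca_reduce <- function(train, test, pca_variance = 0.95, n_components = NULL,
                       whole_data_order = FALSE) {
  assert_scalar_number(pca_variance, "pca_variance", 0, upper = 1,
                       strict_lower = TRUE)
  fit_data <- if (whole_data_order) dplyr::bind_rows(train, test) else train
  pc <- prcomp(feature_matrix(fit_data), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (!is.null(n_components)) {
    if (n_components < 1 || n_components > ncol(pc$rotation)) {
      abort("`n_components` is out of range.")
    }
    as.integer(n_components)
  } else {
    which(cumsum(ev) >= pca_variance - 1e-12)[1]
  }
  project <- function(d) {
    scores <- scale(feature_matrix(d), center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(k), drop = FALSE]
    out <- tibble::as_tibble(as.data.frame(scores))
    dplyr::bind_cols(d[meta_cols(d)], out)
  }
  list(
    train = project(train), test = project(test),
    rotation = pc$rotation[, seq_len(k), drop = FALSE],
    center = pc$center,
    explained_variance = ev, n_components = k
  )
}

# Plug-in mutual information (nats) between a continuous feature and a
# discrete label, with equal-frequency binning of the feature.
binned_mi <- function(x, y, n_bins) {
  probs <- seq(0, 1, length.out = n_bins + 1)
  brks <- unique(quantile(x, probs))
  if (length(brks) < 2) {
    return(0)
  }
  xb <- cut(x, breaks = brks, include.lowest = TRUE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Rank features by mutual information and keep the top k
#'
#' Scores every feature by its mutual information with the class label
#' (an equal-frequency binned plug-in estimate computed on the training
#' rows only), keeps the `k` highest-scoring features in both splits, and
#' returns the full ranking as importance scores. A tiny seeded jitter
#' breaks ties between duplicated feature values.
#'
#' @inheritParams zscore_transform
#' @param k Number of features to retain, `1 <= k <= p`.
#' @param seed Seed for the tie-breaking jitter.
#' @param n_bins Number of equal-frequency bins for the estimator.
#' @return A list with reduced `train` and `test`, and `scores`: a tibble
#'   of `feature`, `mi` sorted by decreasing importance.
#' @export
select_k_best_mi <- function(train, test, k, seed = 42, n_bins = 10) {
  fcols <- feature_cols(train)
  if (k < 1 || k > length(fcols)) {
    abort(sprintf("`k` must be between 1 and %d.", length(fcols)))
  }
  y <- as.factor(train$group)
  scores <- with_seed(derive_seed(seed, "mi"), {
    vapply(fcols, function(f) {
      x <- train[[f]]
      x <- x + rnorm(length(x), 0, max(1e-10, 1e-10 * sd(x)))
      binned_mi(x, y, n_bins)
    }, numeric(1))
  })
  ranked <- tibble::tibble(feature = fcols, mi = scores)
  ranked <- ranked[order(-ranked$mi), ]
  keep <- ranked$feature[seq_len(k)]
  subset_cols <- function(d) tibble::as_tibble(d[c(meta_cols(d), keep)])
  list(train = subset_cols(train), test = subset_cols(test), scores = ranked)
}
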