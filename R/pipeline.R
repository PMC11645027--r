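#' Modeling pipeline configuration
#'
#' Settings for [run_modeling()]. The default ordering is leak-free:
#' stratified split first, then SMOTE on the training rows only, z-score
#' scaling fitted on train, and PCA (or mutual-information selection)
#' fitted on train. `whole_data_order = TRUE` instead applies SMOTE to the
#' whole table before splitting and fits the PCA rotation on the pooled
#' train + test rows — the literal whole-dataset ordering — for
#' comparison.
#'
#' @param test_fraction Held-out fraction per class (default 0.2).
#' @param split_seed Seed for the stratified split (default 42).
#' @param smote Apply SMOTE class balancing?
#' @param smote_k SMOTE neighbour count (default 5).
#' @param whole_data_order Whole-dataset SMOTE/PCA ordering (see above)?
#' @param reduce `"pca"`, `"mi"`, or `"none"`.
#' @param pca_variance Cumulative explained-variance target for PCA.
#' @param select_k Feature count for mutual-information selection.
#' @param metric_average `"weighted"` or `"macro"` metric averaging.
#' @param models Character vector of model families to fit (see
#'   [fit_classifier()]); each is fitted with its
#'   [default_hyperparameters()] unless `grid_search = TRUE`.
#' @param grid_search Run [grid_search_train()] for the classical
#'   families instead of using the tuned defaults?
#' @param cv_folds Cross-validation folds for grid search.
#' @param mlp An [mlp_spec()] used when `"mlp"` is among `models`.
#' @param seed Seed for stochastic learners and SMOTE.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(test_fraction = 0.2, split_seed = 42,
                            smote = TRUE, smote_k = 5, whole_data_order = FALSE,
                            reduce = c("pca", "mi", "none"),
                            pca_variance = 0.95, select_k = 40,
                            metric_average = c("weighted", "macro"),
                            models = "mlp", grid_search = FALSE,
                            cv_folds = 5, mlp = mlp_spec(), seed = 42) {
  reduce <- match.arg(reduce)
  metric_average <- match.arg(metric_average)
  models <- match.arg(models, ls_families(), several.ok = TRUE)
  structure(
    list(
      test_fraction = test_fraction, split_seed = split_seed,
      smote = isTRUE(smote), smote_k = smote_k,
      whole_data_order = isTRUE(whole_data_order),
      reduce = reduce, pca_variance = pca_variance, select_k = select_k,
      metric_average = metric_average, models = models,
      grid_search = isTRUE(grid_search), cv_folds = cv_folds,
      mlp = mlp, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the classification stage on a feature table
#'
#' Applies the configured balancing / split / scaling / reduction chain
#' and fits and evaluates every requested model family.
#'
#' @param features Feature table with `group` labels (e.g. from
#'   [extract_cohort_features()]). Supplementary `cv_`-prefixed columns
#'   are dropped before modeling; the primary metrics are the feature
#'   set.
#' @param config A [pipeline_config()].
#' @return A list of class `ls_fit`: `reports` (named list of `ls_eval`
#'   per model), `transforms` (scaler / reduction metadata), and the
#'   resolved `config`. `glance()` gives one row of metrics per model.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(group_counts =
#'   c(NonLS = 8, Stage1 = 8, Stage2 = 8, Young = 8)), seed = 1)
#' feats <- extract_cohort_features(cohort)
#' fit <- run_modeling(feats, pipeline_config(models = "knn", reduce = "pca"))
#' glance(fit)
#' }
#' @export
run_modeling <- function(features, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- features[!grepl("^cv_", names(features))]
  data <- data[!is.na(data$group), ]
  data$group <- droplevels(as.factor(data$group))

  if (config$smote && config$whole_data_order) {
    data <- smote_balance(data, k = config$smote_k, seed = config$seed)
  }
  parts <- split_cohort(data, config$test_fraction, config$split_seed)
  train <- parts$train
  test <- parts$test
  if (config$smote && !config$whole_data_order) {
    train <- smote_balance(train, k = config$smote_k, seed = config$seed)
  }

  scaled <- zscore_transform(train, test)
  train <- scaled$train
  test <- scaled$test

  transforms <- list(scaler = scaled$scaler)
  if (config$reduce == "pca") {
    red <- pca_reduce(train, test, pca_variance = config$pca_variance,
                      whole_data_order = config$whole_data_order)
    train <- red$train
    test <- red$test
    transforms$pca <- red[c("rotation", "explained_variance", "n_components")]
  } else if (config$reduce == "mi") {
    red <- select_k_best_mi(train, test, k = config$select_k,
                            seed = config$seed)
    train <- red$train
    test <- red$test
    transforms$mi_scores <- red$scores
  }

  reports <- purrr::map(config$models, function(fam) {
    model <- if (fam == "mlp") {
      mlp_train(train, config$mlp, seed = config$seed)
    } else if (config$grid_search) {
      grid_search_train(train, fam, cv_folds = config$cv_folds,
                        seed = config$seed)
    } else {
      fit_classifier(train, fam, seed = config$seed)
    }
    evaluate_model(model, test, config$metric_average)
  })
  names(reports) <- config$models

  structure(
    list(reports = reports, transforms = transforms, config = config,
         n_train = nrow(train), n_test = nrow(test)),
    class = "ls_fit"
  )
}

#' @method print ls_fit
#' @export
print.ls_fit <- function(x, ...) {
  cat(sprintf("<ls_fit: %d train / %d test rows>\n", x$n_train, x$n_test))
  print(glance(x))
  invisible(x)
}

#' One row of test metrics per fitted model
#'
#' @param x An `ls_fit` from [run_modeling()].
#' @param ... Unused.
#' @return A tibble with one row per model family.
#' @export
glance.ls_fit <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}

#' Run the whole pipeline end to end
#'
#' Synthesizes (or ingests) a cohort, preprocesses and segments every
#' recording, extracts the 144-metric feature table, runs the
#' classification stage, and (optionally) writes every intermediate
#' artifact plus a run manifest to an output directory. All randomness
#' derives deterministically from `seed`, so identical calls give
#' identical artifacts.
#'
#' @param seed Global seed.
#' @param cohort Optional pre-built cohort (list of `profiles`,
#'   `recordings`); generated from `cohort_cfg` when `NULL`.
#' @param cohort_cfg A [cohort_config()].
#' @param preprocess A [preprocess_config()].
#' @param segmentation A [segmentation_config()].
#' @param pipeline A [pipeline_config()].
#' @param out_dir Optional directory for stage artifacts (manifest,
#'   feature CSV, per-model confusion matrices).
#' @return A list of class `ls_run`: `profiles`, `features`, `fit`, and
#'   `manifest` (a tibble of stage outputs).
#' @export
run_pipeline <- function(seed = 42, cohort = NULL,
                         cohort_cfg = cohort_config(),
                         preprocess = preprocess_config(),
                         segmentation = segmentation_config(),
                         pipeline = pipeline_config(),
                         out_dir = NULL) {
  stages <- list()
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_cfg, seed = seed)
    stages$synth <- sprintf("%d profiles, %d recordings",
                            nrow(cohort$profiles), length(cohort$recordings))
  } else {
    stages$synth <- sprintf("external cohort: %d recordings",
                            length(cohort$recordings))
  }
  features <- extract_cohort_features(cohort, preprocess, segmentation)
  stages$preprocess <- sprintf("target rate %g Hz", preprocess$target_rate_hz)
  stages$segment <- sprintf("%d recordings segmented", length(cohort$recordings))
  stages$features <- sprintf("%d x %d feature table", nrow(features),
                             sum(!grepl("^cv_", names(features))) - 3)
  fit <- run_modeling(features, pipeline)
  stages$fit <- paste(names(fit$reports), collapse = ", ")

  manifest <- tibble::tibble(
    stage = names(stages),
    output = unlist(stages),
    seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_manifest(cohort$profiles, file.path(out_dir, "cohort.csv"))
    write_feature_table(features, file.path(out_dir, "features.csv"))
    for (fam in names(fit$reports)) {
      utils::write.csv(fit$reports[[fam]]$confusion_matrix,
                       file.path(out_dir, paste0("confusion_", fam, ".csv")))
    }
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }
  structure(
    list(profiles = cohort$profiles, features = features, fit = fit,
         manifest = manifest),
    class = "ls_run"
  )
}

#' @method print ls_run
#' @export
print.ls_run <- function(x, ...) {
  cat("<ls_run>\n")
  print(x$manifest)
  print(glance(x$fit))
  invisible(x)
}
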