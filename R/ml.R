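# Machine-learning stage: PCA of the standardized feature table and
# random-forest regression of each cell-behavior feature on the actin block,
# with impurity-based variable importance scaled to a 0-100 axis.

#' Principal component analysis of the cohort feature table
#'
#' Standardizes the selected features (zero mean, unit variance) and
#' decomposes them with [stats::prcomp()]. Constant columns carry no
#' information and are dropped with a warning; rows with missing values in
#' the used columns are dropped with a message.
#'
#' @param cohort cohort feature table.
#' @param features feature columns to use; default all 13.
#' @return List of class `pca_result` with `scores` (organoid x component),
#'   `loadings` (feature x component), `explained_variance_ratio`, and the
#'   `organoid_id`/`treatment` labels of the retained rows.
#' @export
run_pca <- function(cohort, features = feature_names()) {
  stopifnot(is.data.frame(cohort))
  features <- intersect(features, names(cohort))
  x <- as.matrix(cohort[, features, drop = FALSE])
  keep <- stats::complete.cases(x)
  if (!all(keep))
    message(sprintf("dropping %d row(s) with missing features", sum(!keep)))
  x <- x[keep, , drop = FALSE]
  stop_if(nrow(x) < 3, "PCA needs at least 3 complete rows")
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(x)[const], collapse = ", ")),
            call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  stop_if(ncol(x) < 2, "PCA needs at least 2 non-constant features")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x,
    loadings = pc$rotation,
    explained_variance_ratio = evr,
    organoid_id = if ("organoid_id" %in% names(cohort))
      cohort$organoid_id[keep] else NULL,
    treatment = if ("treatment" %in% names(cohort))
      cohort$treatment[keep] else NULL
  ), class = "pca_result")
}

#' Split configuration for the forest analyses
#'
#' @param train_fraction fraction of organoids in the training split.
#' @param n_trees trees in the ensemble.
#' @param seed seed controlling both the split and the forest.
#' @return List of class `split_config`.
#' @export
split_config <- function(train_fraction = 0.75, n_trees = 100, seed = 42) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_trees >= 1)
  structure(list(train_fraction = train_fraction, n_trees = n_trees,
                 seed = as.integer(seed)), class = "split_config")
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Random-forest regression of one behavior feature on the actin features
#'
#' Pools all treatment groups, randomly splits the organoids into training
#' and validation sets, grows a regression forest of the response on the
#' eight actin features, and reports the coefficient of determination on
#' both splits together with the impurity-decrease (Gini) importance of
#' each predictor, scaled so the most important predictor reads 100.
#'
#' @param cohort cohort feature table.
#' @param response_name one of the five behavior features
#'   ([behavior_feature_names()]).
#' @param config a [split_config()].
#' @param predictors predictor columns; default the actin block.
#' @return List of class `importance_result`: `response`, `r2_train`,
#'   `r2_validation`, `importances` (named, 0-100), `n_train`, `n_validation`.
#' @export
fit_forest <- function(cohort, response_name, config = split_config(),
                       predictors = actin_feature_names()) {
  stopifnot(is.data.frame(cohort))
  stop_if(!response_name %in% names(cohort),
          sprintf("response '%s' not in cohort", response_name))
  cols <- c(predictors, response_name)
  stop_if(!all(cols %in% names(cohort)),
          "cohort lacks some predictor columns")
  dat <- cohort[stats::complete.cases(cohort[, cols]), cols, drop = FALSE]
  n <- nrow(dat)
  n_train <- floor(config$train_fraction * n)
  stop_if(n_train < 2 || n - n_train < 2, sprintf(
    "too few complete rows (%d) for a %.0f/%.0f split; need at least %d",
    n, 100 * config$train_fraction, 100 * (1 - config$train_fraction),
    ceiling(max(2 / config$train_fraction, 2 / (1 - config$train_fraction)))))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  idx <- sample.int(n, n_train)
  train <- dat[idx, , drop = FALSE]
  valid <- dat[-idx, , drop = FALSE]

  forest <- randomForest::randomForest(
    x = train[, predictors, drop = FALSE], y = train[[response_name]],
    ntree = config$n_trees)
  pred_train <- stats::predict(forest, train[, predictors, drop = FALSE])
  pred_valid <- stats::predict(forest, valid[, predictors, drop = FALSE])

  imp <- randomForest::importance(forest, type = 2)[, 1]
  scaled <- if (max(imp) > 0) 100 * imp / max(imp) else imp
  structure(list(
    response = response_name,
    r2_train = r_squared(train[[response_name]], pred_train),
    r2_validation = r_squared(valid[[response_name]], pred_valid),
    importances = scaled,
    n_train = n_train,
    n_validation = n - n_train
  ), class = "importance_result")
}

#' Forest importance report for all five behavior features
#'
#' Runs [fit_forest()] once per behavior feature with a shared seed (hence a
#' shared train/validation split whenever the complete-case rows coincide).
#'
#' @param cohort cohort feature table.
#' @param config a [split_config()].
#' @param responses response features; default the five behavior features.
#' @return Named list of `importance_result` objects.
#' @export
importance_report <- function(cohort, config = split_config(),
                              responses = behavior_feature_names()) {
  out <- lapply(responses, function(r) fit_forest(cohort, r, config))
  names(out) <- responses
  out
}

#' Flatten an importance report to a data frame
#'
#' @param report output of [importance_report()].
#' @return Data frame with columns `response`, `predictor`, `importance`,
#'   `r2_train`, `r2_validation`.
#' @export
importance_table <- function(report) {
  do.call(rbind, lapply(report, function(r) {
    data.frame(response = r$response, predictor = names(r$importances),
               importance = unname(r$importances), r2_train = r$r2_train,
               r2_validation = r$r2_validation, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}
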