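# Gradient-boosted classification of activity limitation.
#
# The classifier is an extreme-gradient-boosting (xgboost) model on 42
# features: age, sex and the 40 disease flags. Training is single-threaded
# and seeded so that fits are bit-reproducible.

#' Build the numeric feature matrix for the classifier
#'
#' @param records a survey tibble.
#' @param features character vector of feature names (subset of
#'   [feature_names()]).
#' @return a numeric matrix with one named column per feature (`sex`
#'   encoded as is-female 0/1).
#' @export
build_feature_matrix <- function(records, features = feature_names()) {
  missing <- setdiff(features, feature_names())
  extra <- setdiff(features, c("age", "sex", names(records)))
  if (length(extra) > 0) {
    abort(paste0("records lack model feature(s): ",
                 paste(extra, collapse = ", ")),
          class = "hlyr_schema_error")
  }
  cols <- lapply(features, function(f) {
    if (f == "age") as.numeric(records$age)
    else if (f == "sex") as.numeric(records$sex == "female")
    else as.numeric(records[[f]])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- features
  m
}

#' Stratified train/test split with a ceiling rule
#'
#' The test partition holds `ceiling(N * test_fraction)` records and the
#' training partition the remainder, so printed subset sizes are exactly
#' reproducible from N. Assignment is random given the seed and stratified
#' on the activity-limitation label (per-stratum test counts are allocated
#' by largest remainder so they always sum to the ceiling-rule total).
#'
#' @param records a survey tibble.
#' @param test_fraction proportion held out, strictly between 0 and 1.
#' @param seed integer RNG seed.
#' @param stratify_on column name used for stratification, or `NULL` for a
#'   simple random split.
#' @return a list with tibbles `train` and `test`; disjoint and exhaustive.
#' @export
#' @examples
#' split_sizes(1537773, 0.10) # the 90/10 sizes for a survey of 1,537,773
split_records <- function(records, test_fraction = 0.10, seed = 1L,
                          stratify_on = "activity_limitation") {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be strictly between 0 and 1",
          class = "hlyr_domain_error")
  }
  n <- nrow(records)
  if (n < 10) abort("need at least 10 records to split",
                    class = "hlyr_domain_error")
  n_test <- split_sizes(n, test_fraction)$test
  with_seed(seed, {
    if (is.null(stratify_on)) {
      idx <- sample.int(n, n_test)
    } else {
      strata <- records[[stratify_on]]
      groups <- split(seq_len(n), strata)
      raw <- vapply(groups, length, numeric(1)) * n_test / n
      base <- floor(raw)
      rem <- n_test - sum(base)
      # largest-remainder allocation so stratum test counts sum exactly
      take <- base + (rank(-(raw - base), ties.method = "first") <= rem)
      idx <- unlist(purrr::map2(groups, take,
                                function(g, k) sample(g, min(k, length(g)))),
                    use.names = FALSE)
    }
    list(train = records[-idx, , drop = FALSE],
         test = records[idx, , drop = FALSE])
  })
}

#' @rdname split_records
#' @param n total record count.
#' @return `split_sizes` returns a tibble with `train` and `test` counts
#'   under the ceiling rule.
#' @export
split_sizes <- function(n, test_fraction = 0.10) {
  n_test <- as.integer(ceiling(n * test_fraction))
  tibble::tibble(train = as.integer(n) - n_test, test = n_test)
}

#' Default boosting hyperparameters
#'
#' The hyperparameter configuration used as the fitting default: 200
#' boosting rounds of depth-9 trees with learning rate 0.1, minimum child
#' weight 2, maximum delta step 5 and 50% row subsampling — a setting that
#' suits a large, class-imbalanced survey classification task.
#'
#' @return a named list.
#' @export
default_hyperparameters <- function() {
  list(n_estimators = 200L, max_depth = 9L, eta = 0.1,
       min_child_weight = 2, max_delta_step = 5, subsample = 0.5)
}

# translate a hyperparameter record into xgb.train arguments
xgb_params <- function(hp) {
  list(objective = "binary:logistic",
       eta = hp$eta, max_depth = hp$max_depth,
       min_child_weight = hp$min_child_weight,
       max_delta_step = hp$max_delta_step,
       subsample = hp$subsample, nthread = 1)
}

#' Fit the activity-limitation classifier
#'
#' @param records training survey tibble (labels must contain both
#'   classes).
#' @param features feature subset to use, default all 42.
#' @param hyperparameters list as from [default_hyperparameters()].
#' @param seed integer seed; fits are deterministic given it.
#' @return an object of class `limitation_model` holding the fitted
#'   booster, the ordered feature names, the hyperparameters and training
#'   metadata.
#' @export
fit_limitation_model <- function(records, features = feature_names(),
                                 hyperparameters = default_hyperparameters(),
                                 seed = 1L) {
  y <- records$activity_limitation
  if (length(unique(y)) < 2) {
    abort("training labels contain a single class",
          class = "hlyr_degenerate_labels")
  }
  x <- build_feature_matrix(records, features)
  booster <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    xgboost::xgb.train(params = xgb_params(hyperparameters), data = dtrain,
                       nrounds = hyperparameters$n_estimators, verbose = 0)
  })
  structure(
    list(booster = booster, features = features,
         hyperparameters = hyperparameters,
         metadata = list(seed = as.integer(seed), n_train = nrow(records),
                         positive_rate = mean(y))),
    class = "limitation_model"
  )
}

#' Predict activity-limitation probabilities
#'
#' @param model a fitted `limitation_model`.
#' @param records survey tibble conforming to the model's feature schema.
#' @return numeric vector of probabilities in \[0, 1\], aligned with the
#'   input rows.
#' @export
predict_proba <- function(model, records) {
  stopifnot(inherits(model, "limitation_model"))
  if (nrow(records) == 0) return(numeric(0))
  x <- build_feature_matrix(records, model$features)
  as.numeric(predict(model$booster,
                     xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' @export
predict.limitation_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' @export
print.limitation_model <- function(x, ...) {
  cat("<limitation_model> xgboost classifier\n")
  cat("  features:", length(x$features), "   n_train:",
      x$metadata$n_train, "\n")
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.limitation_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  out <- tibble::tibble(feature = x$features) |>
    dplyr::left_join(
      tibble::tibble(feature = imp$Feature, gain = imp$Gain,
                     cover = imp$Cover, frequency = imp$Frequency),
      by = "feature"
    ) |>
    dplyr::mutate(dplyr::across(c("gain", "cover", "frequency"),
                                ~ dplyr::coalesce(.x, 0))) |>
    dplyr::arrange(dplyr::desc(.data$gain))
  out
}

#' @export
glance.limitation_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 n_train = x$metadata$n_train,
                 positive_rate = x$metadata$positive_rate,
                 n_estimators = x$hyperparameters$n_estimators,
                 max_depth = x$hyperparameters$max_depth,
                 eta = x$hyperparameters$eta)
}

# stratified fold assignment: within each class, folds are dealt round-robin
# after a seeded shuffle
stratified_folds <- function(y, k, seed = 1L) {
  if (min(table(y)) < k) {
    abort("fold count exceeds the minority-class count",
          class = "hlyr_degenerate_labels")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# mean validation AUROC of one hyperparameter point under stratified k-fold CV
cv_auroc <- function(x, y, hp, fold, seed = 1L) {
  k <- max(fold)
  aucs <- vapply(seq_len(k), function(i) {
    tr <- fold != i
    booster <- with_seed(seed + i, {
      dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr],
                                     nthread = 1)
      xgboost::xgb.train(params = xgb_params(hp), data = dtrain,
                         nrounds = hp$n_estimators, verbose = 0)
    })
    p <- as.numeric(predict(booster,
                            xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                                 nthread = 1)))
    auroc(y[!tr], p)
  }, numeric(1))
  mean(aucs)
}

#' Recursive feature elimination
#'
#' Starting from the full feature set, fits the boosting estimator,
#' removes the least important feature (by total gain), and repeats down
#' to one feature, recording the cross-validated AUROC at every feature
#' count. The selected subset is the count with the highest CV AUROC (ties
#' go to the smaller set).
#'
#' @param records training survey tibble.
#' @param features starting feature set.
#' @param hyperparameters estimator configuration (smaller settings than
#'   the final fit keep elimination affordable).
#' @param cv_folds stratified folds used for the per-count AUROC.
#' @param seed integer seed.
#' @return a list with `path` (tibble: `n_features`, `auroc`, list-column
#'   `features`) and `selected`, the argmax feature subset.
#' @export
select_features <- function(records, features = feature_names(),
                            hyperparameters = list(
                              n_estimators = 40L, max_depth = 4L, eta = 0.3,
                              min_child_weight = 1, max_delta_step = 0,
                              subsample = 1.0),
                            cv_folds = 5L, seed = 1L) {
  if (length(features) < 2) {
    abort("need at least 2 features", class = "hlyr_domain_error")
  }
  y <- records$activity_limitation
  if (length(unique(y)) < 2) {
    abort("labels contain a single class", class = "hlyr_degenerate_labels")
  }
  x_full <- build_feature_matrix(records, features)
  fold <- stratified_folds(y, cv_folds, seed)
  current <- features
  steps <- list()
  while (length(current) >= 1) {
    x <- x_full[, current, drop = FALSE]
    auc <- cv_auroc(x, y, hyperparameters, fold, seed)
    steps[[length(steps) + 1]] <-
      tibble::tibble(n_features = length(current), auroc = auc,
                     features = list(current))
    if (length(current) == 1) break
    booster <- with_seed(seed, {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(params = xgb_params(hyperparameters), data = dtrain,
                         nrounds = hyperparameters$n_estimators, verbose = 0)
    })
    imp <- xgboost::xgb.importance(model = booster)
    gain <- setNames(rep(0, length(current)), current)
    gain[imp$Feature] <- imp$Gain
    # drop the weakest feature; ties drop the later column
    weakest <- names(gain)[max(which(gain == min(gain)))]
    current <- setdiff(current, weakest)
  }
  path <- dplyr::bind_rows(steps)
  best <- path |>
    dplyr::filter(.data$auroc == max(.data$auroc)) |>
    dplyr::slice_min(.data$n_features, n = 1, with_ties = FALSE)
  list(path = path, selected = best$features[[1]])
}

#' The 480-point example hyperparameter grid
#'
#' An illustrative grid whose axes multiply to 480 configurations and
#' contain the default winning point of [default_hyperparameters()]:
#' `n_estimators` in \{100, 150, 200, 250, 300\}, `max_depth` in
#' \{3, 6, 9, 12\}, `eta` in \{0.05, 0.1, 0.3\}, `min_child_weight` in
#' \{1, 2\}, `max_delta_step` in \{0, 5\}, `subsample` in \{0.5, 1.0\}.
#' Exhaustive search over a grid of this size is a batch job; tests and
#' examples use far smaller grids via [hyperparameter_grid()].
#'
#' @return a tibble with one row per configuration.
#' @export
default_search_grid <- function() {
  hyperparameter_grid(
    n_estimators = c(100L, 150L, 200L, 250L, 300L),
    max_depth = c(3L, 6L, 9L, 12L),
    eta = c(0.05, 0.1, 0.3),
    min_child_weight = c(1, 2),
    max_delta_step = c(0, 5),
    subsample = c(0.5, 1.0)
  )
}

#' @rdname default_search_grid
#' @param n_estimators,max_depth,eta,min_child_weight,max_delta_step,subsample
#'   axis values; the grid is their Cartesian product.
#' @export
hyperparameter_grid <- function(n_estimators = 200L, max_depth = 9L,
                                eta = 0.1, min_child_weight = 2,
                                max_delta_step = 5, subsample = 0.5) {
  tibble::as_tibble(expand.grid(
    n_estimators = n_estimators, max_depth = max_depth, eta = eta,
    min_child_weight = min_child_weight, max_delta_step = max_delta_step,
    subsample = subsample, KEEP.OUT.ATTRS = FALSE
  ))
}

#' Cross-validated grid search over boosting hyperparameters
#'
#' Evaluates every grid row by stratified k-fold cross-validated AUROC and
#' returns the best configuration together with the full CV table. Ties on
#' AUROC are broken in favour of the simpler model: fewer trees, then
#' shallower depth.
#'
#' @param records training survey tibble.
#' @param grid a tibble of configurations, see [hyperparameter_grid()].
#' @param features feature subset.
#' @param folds number of stratified CV folds.
#' @param seed integer seed.
#' @return a list with `best` (a one-row tibble) and `cv_table` (the grid
#'   with a `mean_auroc` column, sorted best-first).
#' @export
grid_search <- function(records, grid, features = feature_names(),
                        folds = 5L, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) {
    abort("hyperparameter grid is empty", class = "hlyr_domain_error")
  }
  y <- records$activity_limitation
  x <- build_feature_matrix(records, features)
  fold <- stratified_folds(y, folds, seed)
  grid$mean_auroc <- vapply(seq_len(nrow(grid)), function(i) {
    cv_auroc(x, y, as.list(grid[i, ]), fold, seed)
  }, numeric(1))
  cv_table <- dplyr::arrange(grid, dplyr::desc(.data$mean_auroc),
                             .data$n_estimators, .data$max_depth)
  list(best = cv_table[1, ], cv_table = cv_table)
}

#' Persist / restore a fitted limitation model
#'
#' The model bundle is a directory holding the booster in xgboost's JSON
#' format plus the feature list, hyperparameters and metadata as JSON.
#'
#' @param model a `limitation_model`.
#' @param dir bundle directory (created if needed).
#' @return `save_limitation_model` returns `dir` invisibly;
#'   `load_limitation_model` returns the restored model.
#' @export
save_limitation_model <- function(model, dir) {
  stopifnot(inherits(model, "limitation_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.json"))
  jsonlite::write_json(
    list(features = model$features,
         hyperparameters = model$hyperparameters,
         metadata = model$metadata),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_limitation_model
#' @export
load_limitation_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  structure(
    list(booster = xgboost::xgb.load(file.path(dir, "booster.json")),
         features = meta$features,
         hyperparameters = as.list(meta$hyperparameters),
         metadata = as.list(meta$metadata)),
    class = "limitation_model"
  )
}
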