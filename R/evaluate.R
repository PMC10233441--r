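# Model evaluation: discrimination, calibration, threshold selection,
# feature importance and Monte-Carlo Shapley attribution.

# AUROC by the rank (Mann-Whitney) formulation; ties get average ranks
auroc <- function(labels, probabilities) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUROC needs both classes present", class = "hlyr_degenerate_labels")
  }
  r <- rank(probabilities)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC with a stratified percentile-bootstrap confidence interval
#'
#' The point estimate uses the rank (Mann-Whitney) formulation; the
#' interval comes from `n_boot` resamples drawn separately within the
#' positive and negative class (so every resample keeps both classes).
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities, aligned with `labels`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf_level confidence level of the percentile interval.
#' @return a tibble with `auroc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), n_boot = 200)
roc_auc <- function(labels, probabilities, n_boot = 1000L, seed = 1L,
                    conf_level = 0.95) {
  est <- auroc(labels, probabilities)
  y <- as.numeric(labels)
  pos <- which(y == 1)
  neg <- which(y == 0)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      auroc(y[idx], probabilities[idx])
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(boots, c(a, 1 - a)))
  tibble::tibble(auroc = est, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot))
}

#' Binary cross-entropy (log loss)
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities.
#' @param eps probabilities are clipped to `[eps, 1 - eps]` before taking
#'   logs.
#' @return mean negative log-likelihood per observation.
#' @export
log_loss <- function(labels, probabilities, eps = 1e-15) {
  check_probability(probabilities)
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Reliability (calibration) curve
#'
#' Splits predictions into `bins` equal-width probability bins on \[0, 1\]
#' and reports, per non-empty bin, the mean predicted probability and the
#' empirical fraction of positives. Bin counts partition the sample.
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities.
#' @param bins number of equal-width bins (default 10).
#' @return a tibble of class `calibration_curve` with columns `bin`,
#'   `mean_predicted`, `fraction_positive`, `n`.
#' @export
calibration_curve <- function(labels, probabilities, bins = 10L) {
  check_probability(probabilities)
  edges <- seq(0, 1, length.out = bins + 1)
  bin <- pmin(findInterval(probabilities, edges, rightmost.closed = TRUE),
              bins)
  out <- tibble::tibble(bin = bin, y = as.numeric(labels),
                        p = probabilities) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_predicted = mean(.data$p),
                     fraction_positive = mean(.data$y),
                     n = dplyr::n()) |>
    dplyr::arrange(.data$bin)
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Cost-benefit threshold selection
#'
#' Scores each candidate threshold with a mean cost that counts a false
#' positive as +1, a false negative as -1 and correct calls as 0:
#' `cost(t) = (#FP - #FN) / n`. The chosen cutoff minimizes `|cost(t)|`;
#' ties are broken by the smallest threshold. At the optimum the number of
#' predicted positives roughly matches the number of true positives, so
#' predicted prevalence is unbiased — the property that matters when
#' predictions feed a prevalence schedule.
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities.
#' @param grid candidate thresholds (default 0 to 1 in steps of 0.01).
#' @return a list with `cutoff`, `cost` (at the cutoff) and `curve`, a
#'   tibble of `threshold` and `mean_cost`.
#' @export
cost_benefit_cutoff <- function(labels, probabilities,
                                grid = seq(0, 1, by = 0.01)) {
  if (length(grid) == 0) {
    abort("threshold grid is empty", class = "hlyr_domain_error")
  }
  y <- as.numeric(labels)
  n <- length(y)
  cost <- vapply(grid, function(t) {
    pred <- probabilities >= t
    (sum(pred & y == 0) - sum(!pred & y == 1)) / n
  }, numeric(1))
  i <- which(abs(cost) == min(abs(cost)))[1] # grid is ascending: smallest t
  curve <- tibble::tibble(threshold = grid, mean_cost = cost)
  class(curve) <- c("cost_curve", class(curve))
  list(cutoff = grid[i], cost = cost[i], curve = curve)
}

#' Confusion-matrix metrics at a cutoff
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities.
#' @param cutoff classification threshold in \[0, 1\]; predictions at or
#'   above it are positive.
#' @return a one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_metrics <- function(labels, probabilities, cutoff) {
  check_probability(cutoff, "cutoff")
  y <- as.numeric(labels)
  pred <- probabilities >= cutoff
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    accuracy = (tp + tn) / length(y)
  )
}

#' Normalized permutation feature importance
#'
#' Importance of a feature is the mean increase in error (1 - AUROC) when
#' that feature's column is randomly shuffled, over `repeats` shuffles.
#' Raw importances below zero are clipped to 0 and the vector is divided
#' by its maximum, so the most influential feature scores exactly 1.0.
#'
#' @param model a fitted `limitation_model`.
#' @param records evaluation survey tibble.
#' @param repeats shuffles per feature (default 5).
#' @param seed integer seed.
#' @return a tibble of class `permutation_importance` with columns
#'   `feature`, `raw` (mean error increase) and `importance` (normalized),
#'   sorted by importance.
#' @export
permutation_importance <- function(model, records, repeats = 5L, seed = 1L) {
  stopifnot(inherits(model, "limitation_model"))
  if (length(model$features) < 2) {
    abort("need at least 2 features", class = "hlyr_domain_error")
  }
  y <- records$activity_limitation
  x <- build_feature_matrix(records, model$features)
  base_err <- 1 - auroc(y, predict_booster(model, x))
  raw <- with_seed(seed, {
    vapply(model$features, function(f) {
      mean(vapply(seq_len(repeats), function(r) {
        xs <- x
        xs[, f] <- sample(xs[, f])
        (1 - auroc(y, predict_booster(model, xs))) - base_err
      }, numeric(1)))
    }, numeric(1))
  })
  clipped <- pmax(raw, 0)
  if (max(clipped) <= 0) {
    warn("no feature increased the error when shuffled; importances all zero")
    importance <- clipped
  } else {
    importance <- clipped / max(clipped)
  }
  out <- tibble::tibble(feature = model$features, raw = unname(raw),
                        importance = unname(importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  class(out) <- c("permutation_importance", class(out))
  out
}

predict_booster <- function(model, x) {
  as.numeric(predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Monte-Carlo Shapley attribution for a single record
#'
#' Permutation-sampling estimate of per-feature Shapley contributions on
#' the probability scale: for each draw, a random feature ordering and a
#' random background record are taken, and each feature's marginal effect
#' is the change in predicted probability when it switches from the
#' background value to the record's value, given the features preceding it
#' in the ordering. Contributions plus the base value (mean background
#' prediction) converge to the record's prediction.
#'
#' @param model a fitted `limitation_model`.
#' @param record a one-row survey tibble.
#' @param background a survey tibble of reference records.
#' @param n_draws Monte-Carlo permutations (>= 1).
#' @param seed integer seed.
#' @return a list with `contributions` (named vector over features),
#'   `base_value`, `prediction` and `n_draws`.
#' @export
mc_shapley <- function(model, record, background, n_draws = 200L, seed = 1L) {
  stopifnot(inherits(model, "limitation_model"), nrow(record) == 1)
  if (nrow(background) == 0) {
    abort("background sample is empty", class = "hlyr_domain_error")
  }
  if (n_draws < 1) abort("n_draws must be >= 1", class = "hlyr_domain_error")
  feats <- model$features
  p <- length(feats)
  x <- build_feature_matrix(record, feats)
  bg <- build_feature_matrix(background, feats)
  contrib <- matrix(0, nrow = n_draws, ncol = p,
                    dimnames = list(NULL, feats))
  with_seed(seed, {
    for (d in seq_len(n_draws)) {
      ord <- sample.int(p)
      z <- bg[sample.int(nrow(bg), 1), ]
      cur <- z
      prev <- predict_booster(model, matrix(cur, nrow = 1,
                                            dimnames = list(NULL, feats)))
      for (j in ord) {
        cur[j] <- x[1, j]
        val <- predict_booster(model, matrix(cur, nrow = 1,
                                             dimnames = list(NULL, feats)))
        contrib[d, j] <- val - prev
        prev <- val
      }
    }
  })
  base_value <- mean(predict_booster(model, bg))
  list(contributions = colMeans(contrib), base_value = base_value,
       prediction = predict_booster(model, x), n_draws = n_draws)
}

#' Full evaluation report
#'
#' Convenience wrapper computing the whole evaluation surface on a test
#' set: AUROC with bootstrap CI, log loss, 10-bin calibration, the
#' cost-benefit cutoff, confusion metrics at that cutoff, and normalized
#' permutation importance.
#'
#' @param model a fitted `limitation_model`.
#' @param test test survey tibble.
#' @param n_boot bootstrap resamples for the AUROC CI.
#' @param repeats permutation-importance shuffles per feature.
#' @param seed integer seed.
#' @return a list of class `evaluation_report`.
#' @export
evaluate_model <- function(model, test, n_boot = 1000L, repeats = 5L,
                           seed = 1L) {
  p <- predict_proba(model, test)
  y <- test$activity_limitation
  auc <- roc_auc(y, p, n_boot = n_boot, seed = seed)
  cb <- cost_benefit_cutoff(y, p)
  out <- list(
    auroc = auc,
    log_loss = log_loss(y, p),
    calibration = calibration_curve(y, p),
    cutoff = cb$cutoff,
    cost_curve = cb$curve,
    confusion = confusion_metrics(y, p, cb$cutoff),
    importance = permutation_importance(model, test, repeats = repeats,
                                        seed = seed),
    n_test = length(y)
  )
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n =", x$n_test, "\n")
  cat(sprintf("  AUROC %.3f (95%% CI %.3f-%.3f)   log loss %.4f\n",
              x$auroc$auroc, x$auroc$ci_low, x$auroc$ci_high, x$log_loss))
  cat(sprintf("  cost-benefit cutoff %.2f   sensitivity %.3f   specificity %.3f\n",
              x$cutoff, x$confusion$sensitivity, x$confusion$specificity))
  cat("  top features:",
      paste(head(x$importance$feature, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' Writes the scalar metrics plus the calibration and cost curves; curves
#' can also be exported individually as CSV with [readr::write_csv()].
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(metrics = as.list(glance(report)),
         calibration = tibble::as_tibble(report$calibration),
         cost_curve = tibble::as_tibble(report$cost_curve),
         importance = tibble::as_tibble(report$importance)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc$auroc, auroc_ci_low = x$auroc$ci_low,
    auroc_ci_high = x$auroc$ci_high, log_loss = x$log_loss,
    cutoff = x$cutoff, sensitivity = x$confusion$sensitivity,
    specificity = x$confusion$specificity, ppv = x$confusion$ppv,
    npv = x$confusion$npv, accuracy = x$confusion$accuracy,
    n_test = x$n_test
  )
}
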