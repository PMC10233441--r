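test_that("rank-formula AUROC matches exhaustive pair counting", {
  # hand-checkable 4-point instance: 3 of 4 positive-negative pairs concordant
  expect_equal(hlyr:::auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(hlyr:::auroc(c(0, 1), c(0.2, 0.9)), 1.0)

  set.seed(41)
  for (r in 1:10) {
    n <- sample(20:500, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    # coarse probabilities force ties, exercising the average-rank path
    p <- round(runif(n), 1)
    expect_equal(hlyr:::auroc(y, p), oracle_auroc_pairs(y, p))
  }
  expect_error(hlyr:::auroc(c(1, 1), c(0.2, 0.3)),
               class = "hlyr_degenerate_labels")
})

test_that("AUROC of uninformative predictions is near one half", {
  set.seed(42)
  y <- rbinom(10000, 1, 0.3)
  p <- runif(10000)
  a <- hlyr:::auroc(y, p)
  expect_gt(a, 0.48); expect_lt(a, 0.52)
})

test_that("bootstrap interval brackets the AUROC estimate", {
  set.seed(43)
  y <- rbinom(400, 1, 0.3)
  p <- plogis(y + rnorm(400))
  res <- roc_auc(y, p, n_boot = 300, seed = 7)
  expect_lte(res$ci_low, res$auroc)
  expect_gte(res$ci_high, res$auroc)
  expect_gt(res$ci_high - res$ci_low, 0)
})

test_that("calibration bins partition the sample and track true rates", {
  set.seed(44)
  p <- runif(20000)
  y <- rbinom(20000, 1, p) # perfectly calibrated by construction
  cal <- calibration_curve(y, p, bins = 10)
  expect_equal(sum(cal$n), 20000)
  expect_true(all(abs(cal$fraction_positive - cal$mean_predicted) <=
                    3 * sqrt(cal$mean_predicted *
                               (1 - cal$mean_predicted) / cal$n)))

  cal2 <- calibration_curve(c(0, 0, 0), c(0.05, 0.05, 0.05))
  expect_equal(nrow(cal2), 1)
  expect_equal(cal2$fraction_positive, 0)
})

test_that("cost-benefit cutoff minimizes |mean cost| with smallest-t ties", {
  res <- cost_benefit_cutoff(c(1, 0), c(0.9, 0.1), grid = c(0, 0.5, 1))
  expect_equal(res$cutoff, 0.5)
  expect_equal(res$cost, 0)

  # brute-force agreement on 100 random instances
  set.seed(45)
  grid <- seq(0, 1, by = 0.01)
  for (r in 1:100) {
    n <- 200
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(y)) < 2) next
    p <- runif(n)
    res <- cost_benefit_cutoff(y, p, grid)
    costs <- sapply(grid, function(t) {
      pred <- p >= t
      (sum(pred & y == 0) - sum(!pred & y == 1)) / n
    })
    best <- grid[which(abs(costs) == min(abs(costs)))[1]]
    expect_equal(res$cutoff, best)
  }

  # all-negative labels: optimum is the first threshold predicting nobody
  y0 <- rep(0, 50)
  p0 <- runif(50, 0, 0.62)
  res0 <- cost_benefit_cutoff(y0, p0, grid)
  expect_equal(sum(p0 >= res0$cutoff), 0)
  expect_equal(res0$cutoff, min(grid[sapply(grid, function(t) sum(p0 >= t) == 0)]))

  expect_error(cost_benefit_cutoff(c(0, 1), c(0.2, 0.8), grid = numeric(0)),
               class = "hlyr_domain_error")
})

test_that("confusion metrics agree with a hand-built 2x2", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.4, 0.2, 0.7, 0.3, 0.2, 0.1)
  m <- confusion_metrics(y, p, cutoff = 0.5)
  # at 0.5: TP{0.9,0.8}=2 FN{0.4,0.2}=2 FP{0.7}=1 TN{0.3,0.2,0.1}=3
  expect_equal(unlist(m[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 1, tn = 3, fn = 2))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 0.6)
  expect_equal(m$accuracy, 5 / 8)

  perfect <- confusion_metrics(y, as.numeric(y), cutoff = 0.5)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy")]) == 1))
  expect_equal(confusion_metrics(y, p, cutoff = 0)$sensitivity, 1)
})

test_that("permutation importance is normalized and nulls score near zero", {
  lc <- default_limitation_coeffs()
  lc$disease["dental_disease"] <- 0
  pop <- generate_population(
    generator_config(6000, seed = 19, limitation_coeffs = lc))
  hp <- list(n_estimators = 40L, max_depth = 4L, eta = 0.3,
             min_child_weight = 1, max_delta_step = 0, subsample = 1.0)
  feats <- c("age", "depression_or_other_mental_disease", "back_pain",
             "arthritis", "dental_disease")
  m <- fit_limitation_model(pop, features = feats, hyperparameters = hp,
                            seed = 6)
  imp <- permutation_importance(m, pop, repeats = 5, seed = 6)
  expect_equal(max(imp$importance), 1)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_lt(abs(imp$raw[imp$feature == "dental_disease"]), 0.005)
  expect_equal(imp$feature[1], "age")
})

test_that("the evaluation report assembles all metrics coherently", {
  pop <- small_population(4000, seed = 28)
  sp <- split_records(pop, 0.25, seed = 28)
  hp <- list(n_estimators = 40L, max_depth = 4L, eta = 0.3,
             min_child_weight = 1, max_delta_step = 0, subsample = 1.0)
  m <- fit_limitation_model(sp$train, hyperparameters = hp, seed = 12)
  rep <- evaluate_model(m, sp$test, n_boot = 100, repeats = 2, seed = 12)
  g <- glance(rep)
  expect_true(g$auroc_ci_low <= g$auroc && g$auroc <= g$auroc_ci_high)
  expect_equal(sum(rep$calibration$n), nrow(sp$test))
  expect_equal(max(rep$importance$importance), 1)
  expect_gte(g$log_loss, 0)
  expect_output(print(rep), "AUROC")

  path <- tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$metrics$auroc, g$auroc)
  expect_equal(length(back$calibration$n), nrow(rep$calibration))
})

test_that("Monte-Carlo Shapley contributions satisfy efficiency", {
  pop <- small_population(1500, seed = 20)
  hp <- list(n_estimators = 25L, max_depth = 3L, eta = 0.3,
             min_child_weight = 1, max_delta_step = 0, subsample = 1.0)
  feats <- c("age", "back_pain", "hypertension")
  m <- fit_limitation_model(pop, features = feats, hyperparameters = hp,
                            seed = 7)
  bg <- pop[1:100, ]
  record <- pop[which(pop$age >= 80)[1], ]
  sh <- mc_shapley(m, record, bg, n_draws = 150, seed = 8)
  expect_lt(abs(sh$base_value + sum(sh$contributions) - sh$prediction), 0.02)

  # a constant column can never move a prediction
  pop2 <- pop
  pop2$gout <- 0L
  m2 <- fit_limitation_model(pop2, features = c(feats, "gout"),
                             hyperparameters = hp, seed = 7)
  sh2 <- mc_shapley(m2, pop2[5, ], pop2[1:100, ], n_draws = 60, seed = 9)
  expect_equal(unname(sh2$contributions["gout"]), 0)

  # single-feature model: the lone feature explains the whole gap
  m3 <- fit_limitation_model(pop, features = c("age", "sex"),
                             hyperparameters = hp, seed = 7)
  sh3 <- mc_shapley(m3, record, bg, n_draws = 400, seed = 10)
  expect_equal(sh3$base_value + sum(sh3$contributions), sh3$prediction,
               tolerance = 0.02)
  expect_error(mc_shapley(m3, record, bg[0, ], n_draws = 10),
               class = "hlyr_domain_error")
  expect_error(mc_shapley(m3, record, bg, n_draws = 0),
               class = "hlyr_domain_error")
})
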