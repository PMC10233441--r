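test_that("the ceiling-rule split reproduces printed subset sizes", {
  s <- split_sizes(1537773, 0.10)
  expect_equal(s$test, 153778L)
  expect_equal(s$train, 1383995L)
  expect_equal(split_sizes(10, 0.10)$test, 1L)
  expect_equal(split_sizes(10, 0.10)$train, 9L)
  expect_equal(split_sizes(100, 0.25)$test, 25L)
})

test_that("splitting is disjoint, exhaustive and stratified", {
  pop <- small_population(1000, seed = 9)
  pop$id <- seq_len(nrow(pop))
  sp <- split_records(pop, 0.25, seed = 2)
  expect_equal(nrow(sp$test), 250)
  expect_equal(nrow(sp$train), 750)
  expect_setequal(c(sp$train$id, sp$test$id), pop$id)
  # stratification keeps the class balance within one record per stratum
  n_pos <- sum(pop$activity_limitation)
  expect_lt(abs(sum(sp$test$activity_limitation) - 0.25 * n_pos), 1)
  expect_error(split_records(pop, 1.2), class = "hlyr_domain_error")
  expect_error(split_records(pop, 0), class = "hlyr_domain_error")
})

test_that("fits are deterministic and refuse degenerate labels", {
  pop <- small_population(2000, seed = 10)
  hp <- list(n_estimators = 20L, max_depth = 3L, eta = 0.3,
             min_child_weight = 1, max_delta_step = 0, subsample = 0.5)
  m1 <- fit_limitation_model(pop, hyperparameters = hp, seed = 5)
  m2 <- fit_limitation_model(pop, hyperparameters = hp, seed = 5)
  probe <- small_population(200, seed = 12)
  expect_identical(predict_proba(m1, probe), predict_proba(m2, probe))

  single <- pop
  single$activity_limitation <- 1L
  expect_error(fit_limitation_model(single, hyperparameters = hp),
               class = "hlyr_degenerate_labels")
})

test_that("predictions are probabilities, order-equivariant and schema-checked", {
  pop <- small_population(2000, seed = 13)
  hp <- list(n_estimators = 20L, max_depth = 3L, eta = 0.3,
             min_child_weight = 1, max_delta_step = 0, subsample = 1.0)
  m <- fit_limitation_model(pop, hyperparameters = hp, seed = 5)
  probe <- small_population(300, seed = 14)
  p <- predict_proba(m, probe)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(predict_proba(m, probe[0, ]), 0)

  perm <- sample(nrow(probe))
  expect_equal(predict_proba(m, probe[perm, ]), p[perm])

  expect_error(predict_proba(m, probe[setdiff(names(probe), "gout")]),
               regexp = "gout", class = "hlyr_schema_error")

  # elderly respondents outrank the young and healthy on average
  hi <- probe[probe$age >= 75, ]
  lo <- probe[probe$age <= 30, ]
  expect_gt(mean(predict_proba(m, hi)), mean(predict_proba(m, lo)))
})

test_that("recursive feature elimination keeps a label-copy feature to the end", {
  pop <- small_population(1500, seed = 15)
  pop$diabetes <- pop$activity_limitation # perfect predictor
  res <- select_features(pop, features = c("diabetes", "gout"),
                         cv_folds = 3, seed = 2)
  expect_equal(res$path$n_features, c(2, 1))
  expect_equal(res$selected, "diabetes")
})

test_that("a label-independent feature is eliminated early", {
  # dental disease is given no effect on the limitation label, while the
  # other candidate features keep strong effects
  lc <- default_limitation_coeffs()
  lc$disease["dental_disease"] <- 0
  feats <- c("age", "depression_or_other_mental_disease", "back_pain",
             "arthritis", "hypertension", "dental_disease")
  hits <- 0
  for (r in 1:5) {
    pop <- generate_population(
      generator_config(3000, seed = 300 + r, limitation_coeffs = lc))
    res <- select_features(pop, features = feats, cv_folds = 3,
                           seed = 400 + r)
    # eliminated first = absent from the 5-feature step
    kept5 <- res$path$features[[which(res$path$n_features == 5)]]
    if (!("dental_disease" %in% kept5)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("grid search returns the CV-AUROC argmax with simplicity ties", {
  expect_equal(nrow(default_search_grid()), 480)
  win <- default_hyperparameters()
  hit <- dplyr::filter(default_search_grid(),
                       .data$n_estimators == win$n_estimators,
                       .data$max_depth == win$max_depth,
                       .data$eta == win$eta,
                       .data$min_child_weight == win$min_child_weight,
                       .data$max_delta_step == win$max_delta_step,
                       .data$subsample == win$subsample)
  expect_equal(nrow(hit), 1)

  pop <- small_population(1500, seed = 16)
  one <- hyperparameter_grid(n_estimators = 10L, max_depth = 2L, eta = 0.3,
                             min_child_weight = 1, max_delta_step = 0,
                             subsample = 1.0)
  res1 <- grid_search(pop, one, folds = 3, seed = 3)
  expect_equal(res1$best$n_estimators, 10L)

  grid <- hyperparameter_grid(n_estimators = c(5L, 30L),
                              max_depth = c(2L, 4L), eta = 0.3,
                              min_child_weight = 1, max_delta_step = 0,
                              subsample = 1.0)
  res <- grid_search(pop, grid, folds = 3, seed = 3)
  expect_equal(nrow(res$cv_table), 4)
  expect_true(all(res$best$mean_auroc >= res$cv_table$mean_auroc))
  expect_error(grid_search(pop, grid[0, ], folds = 3),
               class = "hlyr_domain_error")
  tiny <- pop[c(which(pop$activity_limitation == 1)[1:2],
                which(pop$activity_limitation == 0)[1:20]), ]
  expect_error(grid_search(tiny, grid, folds = 5),
               class = "hlyr_degenerate_labels")
})

test_that("a model bundle survives a save/load round trip", {
  pop <- small_population(1000, seed = 17)
  hp <- list(n_estimators = 15L, max_depth = 3L, eta = 0.3,
             min_child_weight = 1, max_delta_step = 0, subsample = 1.0)
  m <- fit_limitation_model(pop, hyperparameters = hp, seed = 4)
  dir <- tempfile("bundle")
  save_limitation_model(m, dir)
  m2 <- load_limitation_model(dir)
  probe <- small_population(100, seed = 18)
  expect_equal(predict_proba(m2, probe), predict_proba(m, probe))
  expect_equal(m2$features, m$features)
})
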