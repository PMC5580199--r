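test_that("chance level is the reciprocal of the class count", {
  expect_equal(chance_level(3), 1 / 3)
  expect_equal(round(100 * chance_level(3), 2), 33.33)
  expect_equal(chance_level(2), 0.5)
  expect_equal(chance_level(4), 0.25)
  expect_error(chance_level(1), ">= 2")
})

test_that("perfectly separable classes cross-validate to accuracy 1", {
  set.seed(41)
  dat <- random_features(90, shift_by_class = 25)
  cv <- rf_crossvalidate(dat$features, dat$labels,
                         grid = data.frame(num_trees = 100L, max_depth = 0L,
                                           mtry_rule = "sqrt"),
                         seed = 7)
  expect_equal(cv$mean_accuracy, 1)
  expect_identical(sum(cv$confusion), cv$n_samples)
})

test_that("folds are near-equal, each sample validated exactly once", {
  set.seed(42)
  dat <- random_features(95)
  cv <- rf_crossvalidate(dat$features, dat$labels,
                         grid = data.frame(num_trees = 50L, max_depth = 5L,
                                           mtry_rule = "sqrt"),
                         seed = 3)
  sizes <- table(cv$fold_id)
  expect_identical(length(sizes), 10L)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_identical(sum(cv$confusion), 95L)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  expect_equal(cv$sd_accuracy, sd(cv$fold_accuracy))
})

test_that("cross-validation is reproducible from its seed", {
  set.seed(43)
  dat <- random_features(60)
  g <- data.frame(num_trees = c(50L, 100L), max_depth = 0L,
                  mtry_rule = "sqrt")
  cv1 <- rf_crossvalidate(dat$features, dat$labels, grid = g, seed = 11)
  cv2 <- rf_crossvalidate(dat$features, dat$labels, grid = g, seed = 11)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  expect_identical(cv1$confusion, cv2$confusion)
})

test_that("training is pure in its inputs and survives serialization", {
  set.seed(44)
  dat <- random_features(80, shift_by_class = 3)
  probe <- random_features(25)$features
  b1 <- rf_train(dat$features, dat$labels, seed = 5)
  b2 <- rf_train(dat$features, dat$labels, seed = 5)
  p1 <- predict_risk(b1, probe)
  expect_identical(p1, predict_risk(b2, probe))
  expect_identical(b1$fingerprint, b2$fingerprint)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_risk_model(b1, tmp)
  expect_identical(predict_risk(load_risk_model(tmp), probe), p1)
  # different seeds are both valid bundles
  b3 <- rf_train(dat$features, dat$labels, seed = 6)
  expect_s3_class(b3, "risk_model")
})

test_that("training points from well-separated clusters recover their label", {
  set.seed(45)
  dat <- random_features(60, shift_by_class = 25)
  b <- rf_train(dat$features, dat$labels, seed = 2)
  pred <- predict_risk(b, dat$features)
  expect_identical(as.character(pred$label), as.character(dat$labels))
})

test_that("probabilities normalize and ties break toward higher risk", {
  set.seed(46)
  dat <- random_features(120)
  b <- rf_train(dat$features, dat$labels, seed = 9)
  pred <- predict_risk(b, random_features(100)$features)
  expect_equal(rowSums(pred[c("p_low", "p_medium", "p_high")]),
               rep(1, 100), tolerance = 1e-12)
  # deterministic tie-break on exact probability ties
  tie <- matrix(c(0.2, 0.4, 0.4, 0.4, 0.4, 0.2, 1/3, 1/3, 1/3),
                3, 3, byrow = TRUE,
                dimnames = list(NULL, risk_levels()))
  expect_identical(as.character(asthmawatch:::prob_to_label(tie)),
                   c("high", "medium", "high"))
})

test_that("missing features at prediction time use the stored training medians", {
  set.seed(47)
  dat <- random_features(80, shift_by_class = 4)
  b <- rf_train(dat$features, dat$labels, seed = 1)
  probe <- dat$features[1:5, ]
  probe$percent_pef <- NA_real_
  filled <- probe
  filled$percent_pef <- b$medians[["percent_pef"]]
  expect_identical(predict_risk(b, probe), predict_risk(b, filled))
})

test_that("feature-order and data-contract violations are loud errors", {
  set.seed(48)
  dat <- random_features(40)
  b <- rf_train(dat$features, dat$labels, seed = 1)
  scrambled <- dat$features[, c(2:1, 3:ncol(dat$features))]
  expect_error(predict_risk(b, scrambled), "declared order")
  expect_error(rf_train(dat$features[1:10, ], dat$labels[1:10]),
               "at least 20")
  one_class <- dat
  one_class$labels[] <- "low"
  expect_error(rf_train(one_class$features, one_class$labels),
               "single class")
  expect_error(rf_crossvalidate(dat$features[1:5, ], dat$labels[1:5]),
               "at least")
})

test_that("a class absent from training predicts with probability zero", {
  set.seed(51)
  labels <- factor(sample(c("medium", "high"), 40, TRUE),
                   levels = risk_levels())
  x <- as.data.frame(matrix(rnorm(40 * 16), 40,
                            dimnames = list(NULL, feature_names())))
  b <- rf_train(x, labels, seed = 1)
  p <- predict_risk(b, x)
  expect_true(all(p$p_low == 0))
  expect_equal(rowSums(p[c("p_low", "p_medium", "p_high")]), rep(1, 40))
  cv <- rf_crossvalidate(x, labels,
                         grid = data.frame(num_trees = 50L, max_depth = 0L,
                                           mtry_rule = "sqrt"), seed = 2)
  expect_identical(sum(cv$confusion), 40L)
})

test_that("the naive Bayes baseline runs in the same CV harness", {
  set.seed(49)
  dat <- random_features(80, shift_by_class = 25)
  cv <- rf_crossvalidate(dat$features, dat$labels,
                         grid = data.frame(num_trees = 1L, max_depth = 0L,
                                           mtry_rule = "sqrt"),
                         seed = 2, engine = "naive_bayes")
  expect_gt(cv$mean_accuracy, 0.9)
})

test_that("grid search selects inside training folds only", {
  # the winning hyperparameters are recorded per outer fold and come from
  # the declared grid
  set.seed(50)
  dat <- random_features(60, shift_by_class = 2)
  g <- data.frame(num_trees = c(50L, 100L), max_depth = c(0L, 5L),
                  mtry_rule = "sqrt")
  cv <- rf_crossvalidate(dat$features, dat$labels, grid = g, seed = 4)
  for (p in cv$fold_params)
    expect_true(p$num_trees %in% g$num_trees && p$max_depth %in% g$max_depth)
})
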