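separable_data <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.3)
  x <- cbind(signal = y + rnorm(n, 0, 0.05), junk = runif(n))
  list(x = x, y = y)
}

test_that("all three algorithms separate a separable problem", {
  d <- separable_data()
  for (alg in c("xgboost", "random_forest", "logreg")) {
    hp <- if (alg == "xgboost") list(nrounds = 30) else
      if (alg == "random_forest") list(n_estimators = 50) else list()
    bag <- if (alg == "logreg") list(enabled = TRUE, n_iterations = 20) else NULL
    m <- train(d, model_spec(alg, hyperparameters = hp, bagging = bag,
                             seed = 4))
    expect_equal(pr_roc(predict(m, d$x), d$y)$aupr, 1, tolerance = 1e-6)
  }
})

test_that("training is deterministic per seed and class weight is n_neg/n_pos", {
  d <- separable_data(seed = 2)
  m1 <- train(d, model_spec("xgboost", hyperparameters = list(nrounds = 20),
                            seed = 7))
  m2 <- train(d, model_spec("xgboost", hyperparameters = list(nrounds = 20),
                            seed = 7))
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  expect_equal(m1$class_weight, sum(d$y == 0) / sum(d$y == 1))
  unweighted <- train(d, model_spec("xgboost",
                                    hyperparameters = list(nrounds = 20),
                                    class_weight_mode = "none"))
  expect_equal(unweighted$class_weight, 1)
})

test_that("degenerate label sets and disabled logreg bagging are errors", {
  d <- separable_data()
  d$y <- rep(1, length(d$y))
  expect_error(train(d, model_spec("xgboost")), "positive and")
  expect_error(model_spec("logreg", bagging = list(enabled = FALSE)),
               "mandatory")
})

test_that("label shuffling drives held-out AUPR to the prevalence", {
  set.seed(5)
  n <- 2000  # large enough that the AP estimator's small-sample bias is small
  x <- matrix(runif(n * 4), n)
  colnames(x) <- paste0("f", 1:4)
  prevalence <- 0.3
  auprs <- vapply(1:10, function(s) {
    set.seed(5000 + s)  # label stream independent of the x stream
    y <- rbinom(n, 1, prevalence)
    idx <- sample(n, n / 2)
    m <- train(list(x = x[idx, ], y = y[idx]),
               model_spec("xgboost", hyperparameters = list(nrounds = 20),
                          seed = s))
    pr_roc(predict(m, x[-idx, ]), y[-idx])$aupr
  }, numeric(1))
  expect_lt(abs(mean(auprs) - prevalence), 0.05)
})

test_that("permutation importance finds a planted predictor and is reproducible", {
  set.seed(11)
  n <- 500
  y <- rbinom(n, 1, 0.4)
  x <- cbind(planted = y + rnorm(n, 0, 0.1),
             noise1 = runif(n), noise2 = runif(n))
  m <- train(list(x = x, y = y),
             model_spec("xgboost", hyperparameters = list(nrounds = 30),
                        seed = 3))
  imp <- permutation_importance(m, x, labels = y, repeats = 8, seed = 2)
  expect_equal(imp$feature[which.max(imp$mean_decrease)], "planted")
  noise_rows <- imp[imp$feature != "planted", ]
  expect_true(all(abs(noise_rows$mean_decrease) <
                    2 * noise_rows$sd_decrease + 1e-9))
  imp2 <- permutation_importance(m, x, labels = y, repeats = 8, seed = 2)
  expect_identical(imp$mean_decrease, imp2$mean_decrease)
  expect_error(permutation_importance(m, x, labels = y, repeats = 0), "repeats")
  expect_equal(attr(imp, "baseline_aupr"), pr_roc(predict(m, x), y)$aupr)
})

test_that("bagged logistic regression averages member probabilities", {
  d <- separable_data(seed = 9)
  m <- train(d, model_spec("logreg",
                           bagging = list(enabled = TRUE, n_iterations = 15),
                           seed = 1))
  expect_equal(nrow(m$fit), 15)
  p <- predict(m, d$x)
  expect_true(all(p >= 0 & p <= 1))
  # manual recomputation of the mean member probability
  eta <- cbind(1, d$x) %*% t(m$fit)
  expect_equal(p, rowMeans(1 / (1 + exp(-eta))))
})
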