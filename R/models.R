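#' Model specification for the PU classifiers
#'
#' Captures algorithm, hyperparameters, class-weight mode, bagging and seed.
#' The shipped defaults are the tuned values used throughout: XGBoost with
#' `min_child_weight = 10`, `colsample_bytree = 0.6`, `subsample = 0.6`,
#' `max_depth = 8`, `reg_lambda = 10`, `eta = 0.1` (`nrounds = 100`); random
#' forest with `n_estimators = 500`, `max_depth = 8`, `max_samples = 0.6`,
#' `max_features = 0.6`; logistic regression with mandatory bagging over 100
#' bootstrap resamples. Under the balanced class-weight mode the positive
#' class is weighted by `n_neg / n_pos`, countering the heavy excess of
#' unlabeled pairs.
#'
#' @param algorithm `"xgboost"`, `"random_forest"` or `"logreg"`.
#' @param hyperparameters named list overriding the defaults above.
#' @param class_weight_mode `"balanced"` (positive weight `n_neg/n_pos`) or
#'   `"none"`.
#' @param bagging list `(enabled, n_iterations)`; mandatory for logreg
#'   (default 100 iterations), built into the tree models.
#' @param seed RNG seed for training.
#' @param nthread threads for xgboost (1 keeps training deterministic).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("xgboost", "random_forest", "logreg"),
                       hyperparameters = list(),
                       class_weight_mode = c("balanced", "none"),
                       bagging = NULL, seed = 1, nthread = 1) {
  algorithm <- match.arg(algorithm)
  class_weight_mode <- match.arg(class_weight_mode)
  defaults <- switch(algorithm,
    xgboost = list(min_child_weight = 10, colsample_bytree = 0.6,
                   subsample = 0.6, max_depth = 8, reg_lambda = 10,
                   eta = 0.1, nrounds = 100),
    random_forest = list(n_estimators = 500, max_depth = 8,
                         max_samples = 0.6, max_features = 0.6),
    logreg = list()
  )
  hp <- modifyList(defaults, hyperparameters)
  if (algorithm == "logreg") {
    if (is.null(bagging)) bagging <- list(enabled = TRUE, n_iterations = 100)
    if (!isTRUE(bagging$enabled)) {
      stop("bagging is mandatory for logistic regression")
    }
  } else if (is.null(bagging)) {
    bagging <- list(enabled = FALSE, n_iterations = 0)
  }
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 class_weight_mode = class_weight_mode, bagging = bagging,
                 seed = seed, nthread = nthread),
            class = "model_spec")
}

#' Train a positive-unlabeled classifier
#'
#' Fits the classifier described by a [model_spec()] on a feature table (or a
#' list with `x` and `y`). The positive class is weighted by `n_neg / n_pos`
#' under the balanced mode; bagged logistic regression fits 100 members on
#' bootstrap resamples of the rows (with replacement) and predicts the mean
#' member probability. Training is deterministic given the spec's seed and a
#' single thread.
#'
#' @param features a [assemble_feature_table()] result, or `list(x, y)` with
#'   a numeric matrix and 0/1 labels.
#' @param spec a [model_spec()].
#' @return list of class `ot_model` with the fitted object(s), the feature
#'   names, the class weight and the spec.
#' @export
train <- function(features, spec = model_spec()) {
  if (inherits(features, "feature_table")) {
    xy <- feature_xy(features)
  } else if (is.list(features) && all(c("x", "y") %in% names(features))) {
    xy <- features
  } else {
    stop("features must be a feature_table or list(x, y)")
  }
  x <- xy$x
  y <- xy$y
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("training needs at least one positive and one negative label")
  }
  w <- if (spec$class_weight_mode == "balanced") n_neg / n_pos else 1
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    xgboost = {
      set.seed(spec$seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = spec$nthread)
      params <- list(objective = "binary:logistic",
                     max_depth = hp$max_depth, eta = hp$eta,
                     min_child_weight = hp$min_child_weight,
                     subsample = hp$subsample,
                     colsample_bytree = hp$colsample_bytree,
                     lambda = hp$reg_lambda, scale_pos_weight = w,
                     nthread = spec$nthread, seed = spec$seed)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$nrounds, verbose = 0)
    },
    random_forest = {
      ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                     num.trees = hp$n_estimators, max.depth = hp$max_depth,
                     sample.fraction = hp$max_samples,
                     mtry = max(1L, floor(hp$max_features * ncol(x))),
                     probability = TRUE, replace = TRUE,
                     class.weights = c(1, w),
                     num.threads = spec$nthread, seed = spec$seed)
    },
    logreg = {
      set.seed(spec$seed)
      n_iter <- spec$bagging$n_iterations
      xi <- cbind(1, x)
      obs_w <- ifelse(y == 1, w, 1)
      coefs <- matrix(0, n_iter, ncol(xi))
      for (b in seq_len(n_iter)) {
        idx <- sample.int(nrow(xi), replace = TRUE)
        f <- suppressWarnings(
          glm.fit(xi[idx, , drop = FALSE], y[idx], weights = obs_w[idx],
                  family = binomial())
        )
        cf <- f$coefficients
        cf[is.na(cf)] <- 0
        coefs[b, ] <- cf
      }
      coefs
    }
  )
  structure(list(algorithm = spec$algorithm, fit = fit,
                 feature_names = colnames(x), class_weight = w, spec = spec),
            class = "ot_model")
}

#' Predict scores from a trained model
#'
#' @param object an `ot_model` from [train()].
#' @param newdata a feature table, data.frame or numeric matrix containing
#'   the model's feature columns.
#' @param ... unused.
#' @return numeric vector of predicted positive-class probabilities.
#' @export
predict.ot_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) {
    feature_xy(newdata, object$feature_names)$x
  } else if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    newdata[, object$feature_names, drop = FALSE]
  }
  storage.mode(x) <- "double"
  switch(object$algorithm,
    xgboost = {
      d <- xgboost::xgb.DMatrix(x, nthread = object$spec$nthread)
      as.numeric(predict(object$fit, d))
    },
    random_forest = {
      p <- predict(object$fit, data = as.data.frame(x),
                   num.threads = object$spec$nthread)$predictions
      as.numeric(p[, "1"])
    },
    logreg = {
      eta <- cbind(1, x) %*% t(object$fit)
      rowMeans(1 / (1 + exp(-eta)))
    }
  )
}

#' Permutation feature importance by AUPR decrease
#'
#' For each feature column, shuffles that column within the evaluation set
#' `repeats` times, re-scores the model and records the decrease of AUPR from
#' the unshuffled baseline (mean and standard deviation over repeats). More
#' important features produce a larger decrease; decreases near zero (within
#' noise) indicate uninformative columns.
#'
#' @param model an `ot_model`.
#' @param features evaluation feature table (or numeric matrix).
#' @param labels 0/1 labels (taken from the feature table when omitted).
#' @param repeats shuffles per feature (must be >= 1).
#' @param seed RNG seed.
#' @return data.frame of class `importance_report` with `feature`,
#'   `mean_decrease`, `sd_decrease`; attributes `baseline_aupr`, `repeats`,
#'   `seed`.
#' @export
permutation_importance <- function(model, features, labels = NULL,
                                   repeats = 10, seed = 1) {
  if (repeats < 1) stop("repeats must be >= 1")
  if (inherits(features, "feature_table")) {
    if (is.null(labels)) labels <- features$label
    x <- feature_xy(features, model$feature_names)$x
  } else {
    x <- features[, model$feature_names, drop = FALSE]
  }
  if (is.null(labels)) stop("labels are required")
  baseline <- pr_roc(predict(model, x), labels)$aupr
  set.seed(seed)
  out <- lapply(model$feature_names, function(col) {
    dec <- vapply(seq_len(repeats), function(r) {
      xs <- x
      xs[, col] <- xs[sample.int(nrow(xs)), col]
      baseline - pr_roc(predict(model, xs), labels)$aupr
    }, numeric(1))
    data.frame(feature = col, mean_decrease = mean(dec),
               sd_decrease = sd(dec))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, baseline_aupr = baseline, repeats = repeats, seed = seed,
            class = c("importance_report", "data.frame"))
}
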