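#' Fit one of the five reference classifiers
#'
#' A uniform wrapper around the five classical classifiers used for the
#' feature-validity experiments, fixed to the evaluation protocol's
#' hyperparameters with no tuning: SVM with RBF kernel and `C = 1`
#' (e1071), decision tree with `maxdepth = 10` (rpart), random forest with
#' 100 trees and `max.depth = 10` (ranger), XGBoost with 100 rounds and
#' `max_depth = 10`, and 5-nearest-neighbours. All remaining settings are the
#' delegated libraries' defaults. KNN is implemented with a deterministic
#' stable distance tie-break and returns full per-class vote fractions so
#' every classifier exposes the same probability interface.
#'
#' @param x Numeric feature matrix (rows = windows).
#' @param y Factor of class labels (its levels fix the class order).
#' @param classifier One of `"xgb"`, `"rf"`, `"svm"`, `"knn"`, `"dt"`.
#' @param seed Integer seed for the stochastic learners (rf, xgb).
#' @return An object of class `eeg_classifier` with a [predict][predict.eeg_classifier] method.
#' @export
fit_classifier <- function(x, y, classifier = c("xgb", "rf", "svm", "knn", "dt"),
                           seed = 1L) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  lv <- levels(y)
  if (length(lv) < 2L) stop("need at least two classes")
  set.seed(seed)
  fit <- switch(classifier,
    svm = e1071::svm(x, y, kernel = "radial", cost = 1, probability = TRUE),
    dt = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = 10, xval = 0))
    },
    rf = ranger::ranger(x = x, y = y, num.trees = 100, max.depth = 10,
                        probability = TRUE, seed = seed, num.threads = 1),
    xgb = {
      d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      params <- if (length(lv) == 2L)
        list(objective = "binary:logistic", max_depth = 10, nthread = 1, seed = seed)
      else
        list(objective = "multi:softprob", num_class = length(lv),
             max_depth = 10, nthread = 1, seed = seed)
      xgboost::xgb.train(params = params, data = d, nrounds = 100, verbose = 0)
    },
    knn = list(train_x = x, train_y = y, k = 5L)
  )
  structure(list(classifier = classifier, fit = fit, levels = lv,
                 features = colnames(x), seed = seed),
            class = "eeg_classifier")
}

# deterministic k-NN vote fractions: neighbours ordered by (distance, index)
.knn_prob <- function(train_x, train_y, newx, k, lv) {
  prob <- matrix(0, nrow(newx), length(lv), dimnames = list(NULL, lv))
  tsq <- rowSums(train_x^2)
  for (i in seq_len(nrow(newx))) {
    d2 <- tsq - 2 * drop(train_x %*% newx[i, ]) + sum(newx[i, ]^2)
    nb <- order(d2)[seq_len(k)]   # order() is stable: ties keep training order
    tab <- table(factor(train_y[nb], levels = lv))
    prob[i, ] <- as.numeric(tab) / k
  }
  prob
}

#' Predict classes or class probabilities
#'
#' @param object An `eeg_classifier` from [fit_classifier()].
#' @param newdata Numeric feature matrix with the training columns.
#' @param type `"class"` for predicted labels (factor) or `"prob"` for a
#'   matrix of per-class probabilities (columns in training level order).
#' @param ... Unused.
#' @export
predict.eeg_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) colnames(newdata) <- object$features
  lv <- object$levels
  prob <- switch(object$classifier,
    svm = {
      p <- attr(stats::predict(object$fit, newdata, probability = TRUE),
                "probabilities")
      p[, lv, drop = FALSE]
    },
    dt = {
      df <- as.data.frame(newdata)
      p <- stats::predict(object$fit, df, type = "prob")
      p[, lv, drop = FALSE]
    },
    rf = {
      p <- stats::predict(object$fit, data = newdata, num.threads = 1)$predictions
      p[, lv, drop = FALSE]
    },
    xgb = {
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(newdata))
      if (is.null(dim(p))) p <- cbind(1 - p, p)  # binary: prob of level 2
      colnames(p) <- lv
      p
    },
    knn = .knn_prob(object$fit$train_x, object$fit$train_y, newdata,
                    object$fit$k, lv)
  )
  if (type == "prob") return(prob)
  factor(lv[max.col(prob, ties.method = "first")], levels = lv)
}

#' @export
print.eeg_classifier <- function(x, ...) {
  cat(sprintf("<eeg_classifier> %s on %d features, classes: %s\n",
              x$classifier, length(x$features), paste(x$levels, collapse = ", ")))
  invisible(x)
}
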