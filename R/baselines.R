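#' Registry of baseline classifiers
#'
#' The comparison harness can swap the convolutional classifier for any
#' of five standard alternatives — bagging, logistic regression, Gaussian
#' naive Bayes, AdaBoost and a multilayer perceptron — all behind the same
#' `fit()` / [predict_proba()] contract. The registry also contains
#' `"cnn"` so [run_cv()] selects every model the same way.
#'
#' Implementations: bagged trees via `randomForest` with `mtry = p` (every
#' split considers all features, i.e. plain bagging); logistic regression
#' via ridge-penalised `glmnet` at a fixed small lambda; naive Bayes via
#' `e1071`; AdaBoost.M1 over `rpart` decision stumps (implemented here,
#' scores via logistic calibration of the boosted margin); MLP via
#' `nnet`.
#'
#' @return Named list of classifier specifications (class
#'   `baseline_spec`). Each is fitted with `fit(spec, X, y, seed = )`.
#' @examples
#' names(baseline_classifiers())
#' @export
baseline_classifiers <- function() {
  spec <- function(name, fit_fun, pred_fun) {
    structure(list(name = name, fit_fun = fit_fun, pred_fun = pred_fun),
              class = "baseline_spec")
  }
  list(
    cnn = spec("cnn", NULL, NULL), # resolved specially by the CV harness
    bagging = spec(
      "bagging",
      function(X, y, seed) with_seed(seed, {
        randomForest::randomForest(
          x = X, y = factor(y, levels = c(0, 1)),
          mtry = ncol(X), ntree = 100
        )
      }),
      function(fitted, X) unname(predict(fitted, X, type = "prob")[, "1"])
    ),
    logistic = spec(
      "logistic",
      function(X, y, seed) {
        glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                       alpha = 0, lambda = 0.01)
      },
      function(fitted, X) {
        as.vector(predict(fitted, X, type = "response"))
      }
    ),
    naive_bayes = spec(
      "naive_bayes",
      function(X, y, seed) {
        e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1)))
      },
      function(fitted, X) {
        unname(predict(fitted, as.data.frame(X), type = "raw")[, "1"])
      }
    ),
    adaboost = spec(
      "adaboost",
      function(X, y, seed) adaboost_fit(X, y, n_rounds = 50, seed = seed),
      function(fitted, X) adaboost_score(fitted, X)
    ),
    mlp = spec(
      "mlp",
      function(X, y, seed) with_seed(seed, {
        nnet::nnet(x = X, y = y, size = 16, decay = 1e-4, maxit = 200,
                   entropy = TRUE, MaxNWts = 100000, trace = FALSE)
      }),
      function(fitted, X) as.vector(predict(fitted, X))
    )
  )
}

#' @rdname baseline_classifiers
#' @param object A `baseline_spec` from the registry.
#' @param X Feature matrix; `y` binary labels.
#' @param y Binary labels (0/1).
#' @param seed RNG seed for stochastic learners.
#' @param ... Unused.
#' @method fit baseline_spec
#' @export
fit.baseline_spec <- function(object, X, y, seed = 1L, ...) {
  if (is.null(object$fit_fun)) {
    stop_mdlink("the 'cnn' registry entry is fitted via build_cnn()/fit()",
                "mdlink_bad_input")
  }
  if (length(unique(y)) < 2L) {
    stop_mdlink("training labels contain a single class", "mdlink_single_class")
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  structure(
    list(name = object$name, fitted = object$fit_fun(Xs, y, seed),
         pred_fun = object$pred_fun, width = ncol(X),
         center = center, scale = scale),
    class = "baseline_classifier"
  )
}

#' @rdname predict_proba
#' @export
predict_proba.baseline_classifier <- function(clf, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != clf$width) {
    stop_mdlink(paste0("descriptor width ", ncol(X),
                       " does not match fitted width ", clf$width),
                "mdlink_dim_mismatch")
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X <- sweep(sweep(X, 2, clf$center), 2, clf$scale, "/")
  p <- clf$pred_fun(clf$fitted, X)
  pmin(pmax(p, 0), 1)
}

# --- AdaBoost.M1 with decision stumps ---------------------------------------
# Discrete AdaBoost on rpart stumps (maxdepth 1). The score is a logistic
# squashing of the weighted margin, which maps the boosted vote into [0, 1].

adaboost_fit <- function(X, y, n_rounds = 50, seed = 1L) {
  df <- as.data.frame(X)
  yy <- ifelse(y == 1, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fitm <- rpart::rpart(
        yf ~ ., data = cbind(df, yf = factor(yy, levels = c(-1, 1))),
        weights = w,
        method = "class",
        control = rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2,
                                       xval = 0)
      )
      pred <- ifelse(predict(fitm, df, type = "class") == "1", 1, -1)
      err <- sum(w * (pred != yy))
      if (err >= 0.5 || length(unique(pred)) == 1L && err > 0) break
      err <- max(err, 1e-10)
      alpha <- 0.5 * log((1 - err) / err)
      w <- w * exp(-alpha * yy * pred)
      w <- w / sum(w)
      used <- used + 1L
      stumps[[used]] <- fitm
      alphas[used] <- alpha
      if (err < 1e-9) break
    }
  })
  if (used == 0L) {
    stop_mdlink("AdaBoost found no stump better than chance", "mdlink_fit_failed")
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)])
}

adaboost_score <- function(model, X) {
  df <- as.data.frame(X)
  margin <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[m]], df, type = "class") == "1", 1, -1)
    margin <- margin + model$alphas[m] * pred
  }
  1 / (1 + exp(-2 * margin))
}
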