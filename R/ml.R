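#' Specification of a standard machine-learning model
#'
#' Thin description of task + algorithm + settings + seed, used by
#' [fit_ml()]. Compatibility: regression supports `LR`, `MLP`, `SVM`,
#' `KNN`, `Bagging`, `RF`; classification supports `LDA`, `Logistic`,
#' `NaiveBayes`, `MLP`, `SVM`, `KNN`, `Bagging`, `RF`.
#'
#' @param task `"regression"` (predict the INR) or `"classification"`
#'   (predict Within/Out).
#' @param algorithm Algorithm name (see above).
#' @param seed Integer seed fixed before fitting, stored for exact refit.
#' @param ... Algorithm settings passed through to the backing library
#'   (e.g. `k` for KNN, `size`/`decay` for MLP, `ntree` for forests).
#' @return An object of class `ml_spec`.
#' @export
ml_spec <- function(task = c("regression", "classification"),
                    algorithm, seed = 1L, ...) {
  task <- match.arg(task)
  compat <- list(
    regression = c("LR", "MLP", "SVM", "KNN", "Bagging", "RF"),
    classification = c("LDA", "Logistic", "NaiveBayes", "MLP", "SVM",
                       "KNN", "Bagging", "RF")
  )
  if (!algorithm %in% compat[[task]]) {
    rlang::abort(sprintf("algorithm `%s` does not support task `%s`.",
                         algorithm, task))
  }
  structure(list(task = task, algorithm = algorithm,
                 seed = as.integer(seed), settings = list(...)),
            class = "ml_spec")
}

#' Fit a standard ML model on a feature table
#'
#' Adapters over established implementations: `lm`/`glm` for linear and
#' logistic regression, [nnet::nnet()] for the multilayer perceptron,
#' [e1071::svm()] and [e1071::naiveBayes()], [caret::knnreg()] /
#' [caret::knn3()] for nearest neighbours, and [randomForest::randomForest()]
#' for the random forest (bagging = a forest with `mtry = p`). The
#' feature table is never mutated; the spec and seed are stored so a
#' refit reproduces the model exactly.
#'
#' @param features A `ptml_features` table (needs `inr` for regression,
#'   `output_class` for classification).
#' @param spec An [ml_spec()].
#' @return An object of class `ptml_ml` with a uniform
#'   `predict(object, features)` method returning a numeric vector
#'   (regression) or `Within`/`Out` labels (classification).
#' @export
fit_ml <- function(features, spec) {
  stopifnot(inherits(spec, "ml_spec"))
  cols <- feature_names(features)
  X <- as.matrix(features[cols])
  y <- if (spec$task == "regression") {
    features$inr
  } else {
    factor(features$output_class, levels = c("Out", "Within"))
  }
  s <- spec$settings
  fit <- withr::with_seed(spec$seed, switch(
    spec$algorithm,
    LR = stats::lm.fit(cbind(1, X), y),
    Logistic = stats::glm.fit(cbind(1, X), as.numeric(y == "Within"),
                              family = stats::binomial()),
    LDA = fit_lda(features, labels = y,
                  lambda = s$lambda %||% 1e-6, columns = cols),
    NaiveBayes = e1071::naiveBayes(x = as.data.frame(X), y = y),
    MLP = nnet::nnet(X, if (spec$task == "regression") y else
                       stats::model.matrix(~ y - 1)[, 2],
                     size = s$size %||% 5, decay = s$decay %||% 0.01,
                     maxit = s$maxit %||% 200,
                     linout = spec$task == "regression",
                     entropy = spec$task == "classification",
                     MaxNWts = 1e5, trace = FALSE),
    SVM = e1071::svm(X, y,
                     kernel = s$kernel %||% "radial",
                     cost = s$cost %||% 1,
                     probability = FALSE),
    KNN = if (spec$task == "regression") {
      caret::knnreg(X, y, k = s$k %||% 1L)
    } else {
      caret::knn3(X, y, k = s$k %||% 1L)
    },
    Bagging = randomForest::randomForest(X, y, ntree = s$ntree %||% 100L,
                                         mtry = ncol(X)),
    RF = randomForest::randomForest(X, y, ntree = s$ntree %||% 100L),
    rlang::abort(sprintf("unknown algorithm `%s`.", spec$algorithm))
  ))
  structure(list(spec = spec, fit = fit, columns = colnames(X)),
            class = "ptml_ml")
}

#' @export
predict.ptml_ml <- function(object, features, ...) {
  X <- as.matrix(features[object$columns])
  spec <- object$spec
  fit <- object$fit
  if (spec$algorithm == "LR") {
    b <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)  # aliased -> dropped
    return(as.vector(cbind(1, X) %*% b))
  }
  if (spec$algorithm == "Logistic") {
    b <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    p <- stats::plogis(as.vector(cbind(1, X) %*% b))
    return(ifelse(p > 0.5, "Within", "Out"))
  }
  if (spec$algorithm == "LDA") {
    return(score_linear(tibble::as_tibble(as.data.frame(X)), fit)$class)
  }
  if (spec$algorithm == "NaiveBayes") {
    return(as.character(stats::predict(fit, as.data.frame(X))))
  }
  if (spec$algorithm == "MLP") {
    p <- as.vector(stats::predict(fit, X))
    if (spec$task == "regression") return(p)
    return(ifelse(p > 0.5, "Within", "Out"))
  }
  if (spec$algorithm == "KNN" && spec$task == "classification") {
    return(as.character(stats::predict(fit, X, type = "class")))
  }
  p <- stats::predict(fit, X)
  if (spec$task == "regression") as.vector(p) else as.character(p)
}

#' @export
print.ptml_ml <- function(x, ...) {
  cat(sprintf("<ptml_ml> %s %s (seed %d, %d features)\n",
              x$spec$algorithm, x$spec$task, x$spec$seed,
              length(x$columns)))
  invisible(x)
}
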