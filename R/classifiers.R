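# Ten classifiers behind one fit/predict contract:
#
#   GNB         Gaussian naive Bayes
#   KNN         K-nearest neighbours, K = 10
#   LDA         linear discriminant analysis (as a classifier)
#   LR          multinomial logistic regression, L2 penalty, C = 1
#   RF          random forest, 100 trees
#   SVM_LIN     linear SVM, C = 1
#   SVM_LIN_CV  linear SVM, C tuned by inner-CV grid search
#   SVM_RBF     RBF SVM, C = 1, median-distance kernel scale
#   SVM_RBF_CV  RBF SVM, C and kernel scale tuned by inner-CV grid search
#   NN          multi-layer perceptron, one hidden layer of 128 units
#
# Stochastic methods (RF, NN, KNN tie-breaking) consume the spec seed so that
# fits and predictions are reproducible.

#' Names of the available classifiers
#' @param include_nn Include the neural network (`NN`). The standard benchmark
#'   grid excludes it; see [run_grid()].
#' @return Character vector of registry names.
#' @export
clf_methods <- function(include_nn = TRUE) {
  m <- c("GNB", "KNN", "LDA", "LR", "RF", "SVM_LIN", "SVM_LIN_CV",
         "SVM_RBF", "SVM_RBF_CV")
  if (include_nn) c(m, "NN") else m
}

default_grid <- function(method) {
  switch(method,
         SVM_LIN_CV = list(C = c(0.01, 0.1, 1, 10, 100)),
         SVM_RBF_CV = list(C = c(0.01, 0.1, 1, 10, 100),
                           scale_mult = c(0.01, 0.1, 1, 10)),
         list())
}

#' Specify a classifier
#'
#' @param method One of [clf_methods()].
#' @param fixed_params Named list overriding method defaults (`K` for KNN,
#'   `trees` for RF, `C` for the SVMs and LR, `hidden` / `maxit` for NN).
#' @param tunable_grid Named list of hyperparameter candidate vectors for the
#'   `*_CV` methods. Defaults: `C` in {0.01, 0.1, 1, 10, 100}; RBF kernel
#'   scale as {0.01, 0.1, 1, 10} times the median-distance heuristic.
#'   Non-CV methods must have an empty grid.
#' @param seed Integer seed consumed by stochastic methods.
#' @return A `clf_spec` object.
#' @export
clf_spec <- function(method, fixed_params = list(), tunable_grid = NULL,
                     seed = 1L) {
  method <- match.arg(method, clf_methods())
  is_cv <- grepl("_CV$", method)
  if (is.null(tunable_grid)) tunable_grid <- default_grid(method)
  if (is_cv && length(tunable_grid) == 0L) {
    stop(method, " requires a nonempty tunable_grid")
  }
  if (!is_cv && length(tunable_grid) > 0L) {
    stop(method, " is not CV-tuned; tunable_grid must be empty")
  }
  defaults <- switch(method,
                     KNN = list(K = 10L),
                     RF = list(trees = 100L),
                     LR = list(C = 1),
                     SVM_LIN = list(C = 1),
                     SVM_RBF = list(C = 1),
                     NN = list(hidden = 128L, maxit = 200L),
                     list())
  fixed <- utils::modifyList(defaults, fixed_params)
  structure(list(method = method, fixed_params = fixed,
                 tunable_grid = tunable_grid, seed = as.integer(seed)),
            class = "clf_spec")
}

#' @export
print.clf_spec <- function(x, ...) {
  cat(sprintf("<clf_spec> %s", x$method))
  if (length(x$fixed_params)) {
    cat(" [", paste(names(x$fixed_params), unlist(x$fixed_params),
                    sep = "=", collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Fit a classifier
#'
#' @param spec A [clf_spec()].
#' @param features Numeric matrix (rows = samples).
#' @param labels Label vector, one per row; at least two classes.
#' @param hyper Named list of tuned hyperparameter values (normally supplied
#'   by [nested_grid_search()]; `NULL` uses `fixed_params` defaults).
#' @return A `fitted_clf` object.
#' @export
fit_classifier <- function(spec, features, labels, hyper = NULL) {
  stopifnot(inherits(spec, "clf_spec"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- factor(as.character(labels))
  if (nrow(X) != length(y)) stop("features and labels differ in length")
  if (nlevels(y) < 2L) stop("need at least two classes to fit a classifier")
  if (any(!is.finite(X))) stop("non-finite feature values")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  par <- utils::modifyList(spec$fixed_params, hyper %||% list())
  m <- spec$method
  model <- with_seed(derive_seed(spec$seed, 7L), switch(
    m,
    GNB = e1071::naiveBayes(X, y),
    KNN = list(train = X, cl = y, K = as.integer(par$K %||% 10L)),
    LDA = lda_quiet(X, grouping = y),
    LR = nnet::multinom(y ~ ., data = data.frame(y = y, X),
                        decay = 1 / (par$C %||% 1), trace = FALSE,
                        maxit = 200L,
                        MaxNWts = (ncol(X) + 2L) * (nlevels(y) + 1L) + 10L),
    RF = randomForest::randomForest(X, y, ntree = as.integer(par$trees %||% 100L)),
    SVM_LIN = e1071::svm(X, y, kernel = "linear", cost = par$C %||% 1,
                         scale = FALSE),
    SVM_LIN_CV = e1071::svm(X, y, kernel = "linear", cost = par$C %||% 1,
                            scale = FALSE),
    SVM_RBF = {
      scale0 <- median_dist(X) * (par$scale_mult %||% 1)
      e1071::svm(X, y, kernel = "radial", cost = par$C %||% 1,
                 gamma = 1 / (2 * scale0^2), scale = FALSE)
    },
    SVM_RBF_CV = {
      scale0 <- median_dist(X) * (par$scale_mult %||% 1)
      e1071::svm(X, y, kernel = "radial", cost = par$C %||% 1,
                 gamma = 1 / (2 * scale0^2), scale = FALSE)
    },
    NN = {
      h <- as.integer(par$hidden %||% 128L)
      nnet::nnet(X, class.ind(y), size = h, softmax = nlevels(y) > 2L,
                 entropy = nlevels(y) == 2L,
                 maxit = as.integer(par$maxit %||% 200L), trace = FALSE,
                 MaxNWts = h * (ncol(X) + 1L) + nlevels(y) * (h + 1L) + 10L)
    }
  ))
  structure(list(spec = spec, model = model, classes = levels(y),
                 p = ncol(X), hyper = hyper %||% list()),
            class = "fitted_clf")
}

class.ind <- function(y) {
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Predict labels with a fitted classifier
#'
#' @param object A `fitted_clf`.
#' @param features Numeric matrix with the training dimensionality. A 0-row
#'   matrix yields an empty prediction.
#' @param ... Unused.
#' @return Character vector of predicted labels (all from the training set).
#' @export
predict.fitted_clf <- function(object, features, ...) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) return(character(0))
  if (ncol(X) != object$p) {
    stop("feature dimensionality (", ncol(X), ") differs from training (",
         object$p, ")")
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  m <- object$spec$method
  pred <- switch(
    m,
    GNB = stats::predict(object$model, X),
    KNN = with_seed(derive_seed(object$spec$seed, 8L),
                    class::knn(object$model$train, X, object$model$cl,
                               k = object$model$K)),
    LDA = stats::predict(object$model, X)$class,
    LR = stats::predict(object$model, newdata = data.frame(X), type = "class"),
    RF = stats::predict(object$model, X),
    NN = {
      pr <- stats::predict(object$model, X)
      if (ncol(pr) == 1L) {
        factor(object$classes[(pr[, 1] > 0.5) + 1L], levels = object$classes)
      } else {
        factor(colnames(pr)[max.col(pr, ties.method = "first")],
               levels = object$classes)
      }
    },
    stats::predict(object$model, X)  # SVM variants
  )
  as.character(pred)
}
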