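# Classifier layer: LDA, QDA, kNN, linear SVM, random forest behind one
# deterministic fit/predict surface with train-statistics standardization.

#' Classifier specification
#'
#' @param name one of `"lda"`, `"qda"`, `"knn"`, `"svm_linear"`, `"rf"`.
#' @param k neighbors for kNN.
#' @param cost regularization C for the linear SVM.
#' @param n_trees trees for the random forest.
#' @param seed seed for the (only) stochastic classifier, the forest.
#' @param grid optional named list of hyperparameter grids for
#'   [tune_hyperparameters()], e.g. `list(k = c(1, 5, 15))`.
#' @param tuning_subject subject id reserved for hyperparameter tuning and
#'   excluded from evaluation, or `NULL`.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("lda", "qda", "knn", "svm_linear", "rf"),
                            k = 5, cost = 1, n_trees = 100, seed = 1L,
                            grid = NULL, tuning_subject = NULL) {
  name <- match.arg(name)
  stop_if_not(is_count(k), "k must be a positive integer")
  stop_if_not(cost > 0, "cost must be > 0")
  stop_if_not(is_count(n_trees), "n_trees must be a positive integer")
  structure(list(name = name, k = as.integer(k), cost = cost,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 grid = grid, tuning_subject = tuning_subject),
            class = "classifier_spec")
}

# z-score columns by training statistics; drop (near-)constant columns.
standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd_ <- apply(train, 2, stats::sd)
  keep <- which(sd_ > 1e-10)
  stop_if_not(length(keep) >= 1, "all training features are constant")
  list(
    train = scale(train[, keep, drop = FALSE], center = mu[keep], scale = sd_[keep]),
    test = scale(test[, keep, drop = FALSE], center = mu[keep], scale = sd_[keep])
  )
}

# deterministic kNN: Euclidean distance, majority vote; voting ties go to
# the smallest class index in sorted label order (determinism rule).
knn_predict <- function(train, labels, test, k) {
  lv <- sort(unique(labels))
  li <- match(labels, lv)
  tr_sq <- rowSums(train^2)
  n_test <- nrow(test)
  pred <- integer(n_test)
  chunk <- max(1L, floor(2e6 / max(1L, nrow(train))))
  for (start in seq(1L, n_test, by = chunk)) {
    idx <- start:min(n_test, start + chunk - 1L)
    Te <- test[idx, , drop = FALSE]
    d2 <- outer(rep(1, length(idx)), tr_sq) - 2 * Te %*% t(train) +
      rowSums(Te^2)
    for (r in seq_along(idx)) {
      nb <- li[order(d2[r, ])[seq_len(k)]]
      tab <- tabulate(nb, nbins = length(lv))
      pred[idx[r]] <- which.max(tab)  # which.max takes the smallest index on ties
    }
  }
  lv[pred]
}

#' Fit a classifier on training rows and predict test rows
#'
#' Features are z-scored with training-set statistics only (constant
#' training columns are dropped from both sets). All classifiers are
#' deterministic given the spec, the data, and the spec's seed (used by the
#' random forest); kNN breaks voting ties toward the smallest class index.
#'
#' @param spec a [classifier_spec()].
#' @param train numeric matrix of training feature rows.
#' @param train_labels class labels, length `nrow(train)`; at least 2
#'   classes.
#' @param test numeric matrix with the training dimensionality.
#' @param test_labels true labels for the test rows.
#' @param no_motion rest-class label recorded in the result.
#' @return a [prediction_record()].
#' @export
fit_predict <- function(spec, train, train_labels, test, test_labels,
                        no_motion) {
  stop_if_not(inherits(spec, "classifier_spec"), "spec must be a classifier_spec")
  train <- as.matrix(train); test <- as.matrix(test)
  stop_if_not(ncol(test) == ncol(train),
              "test dimensionality differs from training")
  stop_if_not(length(unique(train_labels)) >= 2,
              "training rows contain a single class")
  z <- standardize_train_test(train, test)
  y <- factor(train_labels, levels = sort(unique(as.character(train_labels))))
  pred <- switch(spec$name,
    lda = {
      fit <- MASS::lda(z$train, grouping = y)
      as.character(stats::predict(fit, z$test)$class)
    },
    qda = {
      fit <- MASS::qda(z$train, grouping = y)
      as.character(stats::predict(fit, z$test)$class)
    },
    knn = knn_predict(z$train, as.character(y), z$test, spec$k),
    svm_linear = {
      fit <- e1071::svm(z$train, y, kernel = "linear", cost = spec$cost,
                        scale = FALSE)
      as.character(stats::predict(fit, z$test))
    },
    rf = with_seed(spec$seed, {
      fit <- randomForest::randomForest(z$train, y, ntree = spec$n_trees)
      as.character(stats::predict(fit, z$test))
    }))
  prediction_record(pred, as.character(test_labels), no_motion)
}
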