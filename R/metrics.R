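# Evaluation statistics: total error rate, active error rate, and the
# Davies-Bouldin separability index.

#' Prediction record
#'
#' Pairs a classifier's predictions with the true labels and identifies the
#' no-motion (rest) class needed by the active error rate.
#'
#' @param p predicted class vector.
#' @param l true class vector, same length.
#' @param no_motion the rest-class label.
#' @return an object of class `prediction_record`.
#' @export
prediction_record <- function(p, l, no_motion) {
  stop_if_not(length(p) == length(l), "p and l must have equal length")
  stop_if_not(length(p) >= 1, "empty prediction record")
  structure(list(p = as.character(p), l = as.character(l),
                 no_motion = as.character(no_motion), N = length(p)),
            class = "prediction_record")
}

#' Total error rate (percent)
#'
#' `100 x (1 - #correct / N)`: the prevalence of all misclassifications in
#' a test set.
#'
#' @param record a [prediction_record()].
#' @return percentage in \[0, 100\].
#' @examples
#' ter(prediction_record(c(1, 2, 3, 3), c(1, 2, 3, 1), no_motion = 1))  # 25
#' @export
ter <- function(record) {
  stop_if_not(inherits(record, "prediction_record"), "need a prediction_record")
  100 * (1 - sum(record$p == record$l) / record$N)
}

#' Active error rate (percent)
#'
#' The share of active-class predictions that are wrong:
#' `100 x #{p != l and p != NM} / #{p != NM}`. False predictions of the
#' no-motion class are ignored (they carry a lower cost: the device does
#' nothing rather than moving wrongly). When every prediction is the
#' no-motion class the rate is undefined and `NA` is returned with a
#' warning, never 0.
#'
#' The published denominator is sometimes printed positionally as
#' "predictions different from class 1"; `convention = "printed"` selects
#' that reading (the first class in sorted label order is treated as the
#' rest class) instead of the explicit `no_motion` label.
#'
#' @param record a [prediction_record()].
#' @param convention `"no_motion"` (default) or `"printed"`.
#' @return percentage in \[0, 100\], or `NA` if undefined.
#' @examples
#' aer(prediction_record(c(2, 2, 1, 3), c(2, 3, 3, 1), no_motion = 1))  # 66.67
#' @export
aer <- function(record, convention = c("no_motion", "printed")) {
  stop_if_not(inherits(record, "prediction_record"), "need a prediction_record")
  convention <- match.arg(convention)
  nm <- if (convention == "no_motion") record$no_motion else
    sort(unique(c(record$p, record$l)))[1]
  active <- record$p != nm
  if (!any(active)) {
    warning("AER undefined: every prediction is the no-motion class")
    return(NA_real_)
  }
  100 * sum(active & record$p != record$l) / sum(active)
}

#' Davies-Bouldin separability index
#'
#' For clusters `i` with mean `mu_i`, within-cluster dispersion
#' `S_i = (1/N_i) sum_j (x_j - mu_i)' (x_j - mu_i)` (mean squared
#' deviation) and between-cluster separation
#' `D_ij = (mu_i - mu_j)' (mu_i - mu_j)` (squared Euclidean), the overlap
#' of a pair is `R_ij = (S_i + S_j) / D_ij` and the index is the average
#' over clusters of each cluster's worst (largest) overlap. Lower values
#' indicate better-separated clusters. `squared = FALSE` uses the
#' root-variant (`S_i` a true multi-dimensional standard deviation and
#' `D_ij` a Euclidean distance) instead.
#'
#' Coincident cluster means make an overlap infinite; the index is then
#' `+Inf` with a warning rather than an error.
#'
#' @param features numeric matrix (observations x dimensions) or a
#'   `feature_matrix`.
#' @param cluster_labels cluster assignment vector, length `nrow(features)`;
#'   every cluster must be nonempty and there must be at least 2 clusters.
#' @param squared use the squared-dispersion form (default) or the
#'   root form.
#' @return nonnegative scalar (possibly `+Inf`).
#' @examples
#' x <- matrix(c(0, 2, 10, 12), ncol = 1)
#' dbi(x, c("a", "a", "b", "b"))  # 0.02
#' @export
dbi <- function(features, cluster_labels, squared = TRUE) {
  if (inherits(features, "feature_matrix")) features <- features$values
  X <- as.matrix(features)
  labs <- as.character(cluster_labels)
  stop_if_not(nrow(X) == length(labs), "one label per observation required")
  cl <- unique(labs)
  K <- length(cl)
  stop_if_not(K >= 2, "need at least 2 clusters")
  mu <- do.call(rbind, lapply(cl, function(g) {
    colMeans(X[labs == g, , drop = FALSE])
  }))
  S <- vapply(seq_len(K), function(i) {
    Xi <- X[labs == cl[i], , drop = FALSE]
    mean(rowSums((Xi - matrix(mu[i, ], nrow(Xi), ncol(X), byrow = TRUE))^2))
  }, numeric(1))
  if (!squared) S <- sqrt(S)
  D <- as.matrix(stats::dist(mu))^2
  if (!squared) D <- sqrt(D)
  worst <- vapply(seq_len(K), function(i) {
    r <- (S[i] + S[-i]) / D[i, -i]
    max(r)
  }, numeric(1))
  if (any(!is.finite(worst))) {
    warning("coincident cluster means: overlap is infinite")
    return(Inf)
  }
  mean(worst)
}
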