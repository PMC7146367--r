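# Metrics, split enumeration, classifiers, experiment driver, tuning.

test_that("split plans enumerate the documented counts", {
  expect_length(make_splits("intra", 1:3, 1:4, 1), 12)
  expect_length(make_splits("inter", 1:5, 1, 1), 20)
  expect_length(make_splits("single_vs_all", 1:5, 1:2, 1), 10)
  expect_length(make_splits("multi_vs_all", 1:5, 1, 1, n_train = 2), 10)
  expect_error(make_splits("multi_vs_all", 1:5, 1, 1), "n_train",
               class = "emg_parameter_error")
  # structural invariants
  for (pl in make_splits("inter", 1:4, 1:2, 1)) {
    expect_length(intersect(pl$train_conditions, pl$test_conditions), 0)
  }
  for (pl in make_splits("single_vs_all", 1:4, 1:2, 1)) {
    expect_length(pl$train_conditions, 1)
    expect_equal(pl$test_conditions, 1:4)
  }
  # subsampling cap is seeded and bounded
  plans <- make_splits("multi_vs_all", 1:10, 1, 1, n_train = 5, max_sets = 20)
  expect_length(plans, 20)
  expect_identical(plans, make_splits("multi_vs_all", 1:10, 1, 1, n_train = 5,
                                      max_sets = 20))
})

test_that("TER and AER reproduce hand-computed anchors", {
  expect_equal(ter(prediction_record(1:4, 1:4, 1)), 0)
  expect_equal(ter(prediction_record(c(1, 2, 3, 3), c(1, 2, 3, 1), 1)), 25)
  expect_equal(aer(prediction_record(c(2, 2, 1, 3), c(2, 3, 3, 1), 1)),
               200 / 3, tolerance = 1e-12)
  expect_equal(aer(prediction_record(c(2, 3), c(2, 3), 1)), 0)
  expect_warning(v <- aer(prediction_record(c(1, 1), c(2, 3), 1)), "undefined")
  expect_true(is.na(v))
  # printed-denominator reading treats the first sorted class as rest
  r <- prediction_record(c(2, 2, 1, 3), c(2, 3, 3, 1), no_motion = 2)
  expect_equal(aer(r, convention = "printed"), 200 / 3, tolerance = 1e-12)
})

test_that("TER/AER match brute-force counting on random records", {
  set.seed(21)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    n <- sample(1:100, 1)
    p <- sample(k, n, replace = TRUE)
    l <- sample(k, n, replace = TRUE)
    rec <- prediction_record(p, l, no_motion = 1)
    expect_identical(ter(rec), o_ter(as.character(p), as.character(l)))
    expect_identical(suppressWarnings(aer(rec)),
                     o_aer(as.character(p), as.character(l), "1"))
  }
})

test_that("DBI follows the printed squared form and its hand anchor", {
  x <- matrix(c(0, 2, 10, 12), ncol = 1)
  expect_equal(dbi(x, c("a", "a", "b", "b")), 0.02, tolerance = 1e-12)
  # singleton clusters at distinct points have zero dispersion
  expect_equal(dbi(matrix(c(0, 5), ncol = 1), c("a", "b")), 0)
  # shrinking within-cluster spread strictly decreases the index
  mk <- function(s) rbind(cbind(rnorm(30, 0, s), rnorm(30, 0, s)),
                          cbind(rnorm(30, 4, s), rnorm(30, 4, s)))
  set.seed(31)
  wide <- dbi(mk(1), rep(c("a", "b"), each = 30))
  narrow <- dbi(mk(0.2), rep(c("a", "b"), each = 30))
  expect_lt(narrow, wide)
  # doubling mean separation at fixed dispersion decreases the index
  set.seed(32)
  base <- matrix(rnorm(60), ncol = 2)
  labs <- rep(c("a", "b"), each = 15)
  shift1 <- base; shift1[labs == "b", ] <- shift1[labs == "b", ] + 2
  shift2 <- base; shift2[labs == "b", ] <- shift2[labs == "b", ] + 4
  expect_lt(dbi(shift2, labs), dbi(shift1, labs))
  expect_warning(v <- dbi(rbind(base, base), rep(c("a", "b"), each = 30)),
                 "coincident")
  expect_identical(v, Inf)
  # root-variant stays available
  expect_equal(dbi(x, c("a", "a", "b", "b"), squared = FALSE), 0.2,
               tolerance = 1e-12)
})

test_that("DBI matches a brute-force oracle on random clusterings", {
  set.seed(41)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    d <- sample(1:8, 1)
    n <- sample(k:100, 1)
    labs <- as.character(c(sample(k), sample(k, n - k, replace = TRUE)))
    X <- matrix(rnorm(n * d), ncol = d)
    expect_equal(dbi(X, labs), o_dbi(X, labs), tolerance = 1e-9)
  }
})

test_that("classifiers separate what is separable and not what is not", {
  set.seed(51)
  mk_gauss <- function(n, mu) cbind(rnorm(n, mu[1]), rnorm(n, mu[2]))
  train <- rbind(mk_gauss(500, c(0, 0)), mk_gauss(500, c(10, 10)))
  test <- rbind(mk_gauss(500, c(0, 0)), mk_gauss(500, c(10, 10)))
  y <- rep(c("a", "b"), each = 500)
  for (cls in c("lda", "qda", "knn", "svm_linear", "rf")) {
    rec <- fit_predict(classifier_spec(cls), train, y, test, y, no_motion = "a")
    expect_equal(ter(rec), 0, label = cls)
  }
  # kNN with k = 1 on the training set itself is perfect
  rec <- fit_predict(classifier_spec("knn", k = 1), train, y, train, y, "a")
  expect_equal(ter(rec), 0)
  # identical features for all classes => chance-level accuracy
  set.seed(52)
  junk_tr <- matrix(rnorm(600 * 3), ncol = 3)
  junk_te <- matrix(rnorm(300 * 3), ncol = 3)
  y3 <- rep(c("a", "b", "c"), each = 200)
  rec <- fit_predict(classifier_spec("lda"), junk_tr, y3, junk_te,
                     rep(c("a", "b", "c"), each = 100), "a")
  acc <- 100 - ter(rec)
  expect_lt(abs(acc - 100 / 3), 100 * qnorm(0.995) * sqrt(1 / 3 * 2 / 3 / 300) + 1)
  expect_error(fit_predict(classifier_spec("lda"), junk_tr, rep("a", 600),
                           junk_te, rep("a", 300), "a"), "single class")
  expect_error(fit_predict(classifier_spec("lda"), junk_tr, y3,
                           junk_te[, 1:2], rep("a", 300), "a"),
               "dimensionality")
})

test_that("deterministic kNN agrees with the reference where ties cannot occur", {
  skip_if_not_installed("class")
  set.seed(61)
  train <- matrix(rnorm(200 * 4), ncol = 4)
  y <- sample(c("a", "b", "c"), 200, replace = TRUE)
  test <- matrix(rnorm(80 * 4), ncol = 4)
  rec <- fit_predict(classifier_spec("knn", k = 1), train, y, test,
                     rep("a", 80), "a")
  ref <- as.character(class::knn(scale(train),
                                 scale(test, center = colMeans(train),
                                       scale = apply(train, 2, sd)),
                                 cl = y, k = 1))
  expect_equal(rec$p, ref)
})

test_that("run_experiment enumerates splits and aggregates consistently", {
  fm <- fake_feature_matrix(n_per_cell = 6, classes = c("nm", "g1", "g2"),
                            conditions = 1:5, trials = 1:10, sep = 4, sd = 1)
  spec <- classifier_spec("lda")
  res <- run_experiment(fm, "intra", spec, no_motion = "nm")
  expect_equal(nrow(res$rows), 50)
  expect_equal(res$rows$accuracy + res$rows$ter, rep(100, 50))
  s <- res$summary
  expect_equal(unname(s["mean"]), mean(res$rows$accuracy), tolerance = 1e-12)
  expect_equal(unname(s["sd"]), sd(res$rows$accuracy), tolerance = 1e-12)
  expect_equal(unname(s["min"]), min(res$rows$accuracy))
  expect_equal(unname(s["max"]), max(res$rows$accuracy))
  expect_equal(unname(res$subject_means["1"]), mean(res$rows$accuracy))
  tab <- format_results_table(res)
  expect_match(tab$accuracy, "\\(")
})

test_that("hyperparameter tuning picks the best grid point and guards reuse", {
  fm <- fake_feature_matrix(n_per_cell = 5, classes = c("nm", "g1", "g2"),
                            conditions = 1:2, trials = 1:3,
                            subjects = 1:2, sep = 3, sd = 1)
  spec1 <- classifier_spec("knn", grid = list(k = 5), tuning_subject = 1)
  tuned1 <- tune_hyperparameters(spec1, fm, no_motion = "nm")
  expect_equal(tuned1$k, 5)
  spec <- classifier_spec("knn", grid = list(k = c(1, 5, 15)),
                          tuning_subject = 1)
  tuned <- tune_hyperparameters(spec, fm, no_motion = "nm")
  tab <- attr(tuned, "tuning_table")
  expect_equal(tuned$k, tab$k[which.max(tab$accuracy)])
  expect_equal(attr(tuned, "tuning_accuracy"), max(tab$accuracy))
  # the tuning subject must not leak into evaluation
  expect_error(run_experiment(fm, "intra", tuned, no_motion = "nm"),
               "tuning subject")
  res <- run_experiment(drop_subject(fm, 1), "intra", tuned, no_motion = "nm")
  expect_false(1 %in% res$rows$subject_id)
})
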