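# Experiment driver: execute every split plan of a framework on a feature
# matrix, per subject, and aggregate accuracy as Mean +/- SD (Min, Max).

#' Drop one subject's rows from a feature matrix
#'
#' Used to remove the hyperparameter-tuning subject before evaluation.
#'
#' @param fm a `feature_matrix`.
#' @param subject_id subject to remove.
#' @return the reduced `feature_matrix`.
#' @export
drop_subject <- function(fm, subject_id) {
  keep <- fm$meta$subject_id != subject_id
  stop_if_not(any(keep), "dropping this subject would empty the feature matrix")
  structure(list(values = fm$values[keep, , drop = FALSE],
                 feature_names = fm$feature_names,
                 feature_set = fm$feature_set,
                 meta = fm$meta[keep, , drop = FALSE]),
            class = "feature_matrix")
}

#' Run one (feature set, classifier, framework) experiment
#'
#' Enumerates every leave-one-trial-out split plan of the framework for
#' each subject present in the feature matrix, fits the classifier on the
#' training rows (training conditions, held-out trial excluded) and
#' evaluates on the held-out trial of the test conditions. The held-out
#' trial is excluded from training under every framework: the
#' one-vs-all and multi-vs-all frameworks test on *all* conditions, which
#' would otherwise place the very windows under test into the training set.
#'
#' @param fm a [extract_set()] feature matrix carrying condition and trial
#'   metadata.
#' @param framework one of `"intra"`, `"inter"`, `"single_vs_all"`,
#'   `"multi_vs_all"`.
#' @param spec a [classifier_spec()]. If it names a `tuning_subject`, that
#'   subject is excluded from evaluation.
#' @param no_motion the rest-class label (for the active error rate).
#' @param n_train training-condition count for `multi_vs_all`.
#' @param max_sets,seed passed to [make_splits()].
#' @return an object of class `eval_result`: list with `rows` (one data
#'   frame row per split: subject, train/test conditions, held-out trial,
#'   accuracy, TER, AER), `summary` (mean/sd/min/max of accuracy),
#'   `subject_means` (subject-averaged accuracy), and the run descriptors.
#' @export
run_experiment <- function(fm, framework, spec, no_motion,
                           n_train = NULL, max_sets = 1000, seed = 1L) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  meta <- fm$meta
  subjects <- sort(unique(meta$subject_id))
  if (!is.null(spec$tuning_subject)) {
    stop_if_not(!(spec$tuning_subject %in% subjects),
                "the tuning subject must be excluded from the evaluation feature matrix (see drop_subject())")
  }
  rows <- list()
  for (s in subjects) {
    s_idx <- which(meta$subject_id == s)
    conds <- unique(meta$condition_value[s_idx])
    trials <- sort(unique(meta$trial_index[s_idx]))
    stop_if_not(length(trials) >= 2, "leave-one-trial-out needs >= 2 trials")
    plans <- make_splits(framework, conds, trials, s,
                         n_train = n_train, max_sets = max_sets, seed = seed)
    for (pl in plans) {
      tr_idx <- s_idx[meta$condition_value[s_idx] %in% pl$train_conditions &
                        meta$trial_index[s_idx] != pl$held_out_trial]
      te_idx <- s_idx[meta$condition_value[s_idx] %in% pl$test_conditions &
                        meta$trial_index[s_idx] == pl$held_out_trial]
      rec <- fit_predict(spec, fm$values[tr_idx, , drop = FALSE],
                         meta$motion_label[tr_idx],
                         fm$values[te_idx, , drop = FALSE],
                         meta$motion_label[te_idx], no_motion)
      t_ <- ter(rec)
      a_ <- suppressWarnings(aer(rec))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s,
        framework = framework,
        train_conditions = paste(pl$train_conditions, collapse = "+"),
        test_conditions = paste(pl$test_conditions, collapse = "+"),
        held_out_trial = pl$held_out_trial,
        n_train_conditions = length(pl$train_conditions),
        n_test = rec$N,
        accuracy = 100 - t_,
        ter = t_,
        aer = a_,
        stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  structure(list(
    rows = rows,
    summary = summarize_accuracy(rows$accuracy),
    subject_means = vapply(split(rows$accuracy, rows$subject_id), mean,
                           numeric(1)),
    framework = framework,
    classifier = spec$name,
    feature_set = fm$feature_set
  ), class = "eval_result")
}

summarize_accuracy <- function(acc) {
  c(mean = mean(acc), sd = stats::sd(acc), min = min(acc), max = max(acc))
}

#' @export
print.eval_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<eval_result> %s + %s, %s: %.1f+/-%.1f (%.1f, %.1f) over %d splits\n",
              x$feature_set, x$classifier, x$framework,
              s["mean"], s["sd"], s["min"], s["max"], nrow(x$rows)))
  invisible(x)
}

#' Grid-search hyperparameters on a held-out tuning subject
#'
#' Evaluates every point of the spec's hyperparameter grid with the
#' intra-condition framework on the tuning subject's rows only, and
#' returns the spec fixed at the best point (highest mean accuracy; the
#' first grid point wins ties). The tuning subject is recorded in the
#' returned spec so [run_experiment()] excludes it downstream.
#'
#' @param spec a [classifier_spec()] with non-`NULL` `grid` and
#'   `tuning_subject`.
#' @param fm feature matrix containing the tuning subject's rows.
#' @param no_motion rest-class label.
#' @return the tuned [classifier_spec()], with attributes
#'   `tuning_accuracy` (best mean accuracy) and `tuning_table` (accuracy
#'   per grid point).
#' @export
tune_hyperparameters <- function(spec, fm, no_motion) {
  stop_if_not(!is.null(spec$grid) && length(spec$grid) >= 1,
              "spec carries no hyperparameter grid")
  stop_if_not(!is.null(spec$tuning_subject), "spec names no tuning subject")
  idx <- which(fm$meta$subject_id == spec$tuning_subject)
  stop_if_not(length(idx) >= 1, "tuning subject absent from the feature matrix")
  tune_fm <- structure(list(values = fm$values[idx, , drop = FALSE],
                            meta = fm$meta[idx, , drop = FALSE],
                            feature_set = fm$feature_set),
                       class = "feature_matrix")
  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cand <- spec
    for (p in names(grid)) cand[[p]] <- grid[[p]][g]
    cand$tuning_subject <- NULL  # evaluate on the tuning subject itself
    res <- run_experiment(tune_fm, "intra", cand, no_motion)
    acc[g] <- res$summary["mean"]
  }
  best <- which.max(acc)
  out <- spec
  for (p in names(grid)) out[[p]] <- grid[[p]][best]
  out$grid <- NULL
  attr(out, "tuning_accuracy") <- acc[best]
  attr(out, "tuning_table") <- cbind(grid, accuracy = acc)
  out
}

#' Render results as a Mean+/-SD (Min, Max) table
#'
#' @param results a list of [run_experiment()] results.
#' @return a data frame with one formatted row per
#'   (feature set, classifier, framework) cell.
#' @export
format_results_table <- function(results) {
  if (inherits(results, "eval_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    s <- r$summary
    data.frame(feature_set = r$feature_set, classifier = r$classifier,
               framework = r$framework,
               accuracy = sprintf("%.1f±%.1f (%.1f, %.1f)",
                                  s["mean"], s["sd"], s["min"], s["max"]),
               stringsAsFactors = FALSE)
  }))
}
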