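# Cross-validation frameworks over confound conditions, leave-one-trial-out
# within subject.

#' Enumerate train/test split plans under a cross-validation framework
#'
#' The four frameworks differ only in which confound conditions feed the
#' training and test sets; every plan additionally holds one trial
#' (repetition) out: training uses the remaining trials of the training
#' conditions, testing uses only the held-out trial of the test conditions.
#'
#' * `intra` (x vs x): train and test in the same single condition — the
#'   performance upper bound. One plan per (condition, trial).
#' * `inter` (x vs y): train in one condition, test in a different one —
#'   the lower bound. One plan per ordered condition pair per trial.
#' * `single_vs_all` (x vs all): train in one condition, test in all.
#' * `multi_vs_all` (N vs all): train in `n_train` conditions, test in all;
#'   all `choose(|conditions|, n_train)` training sets are enumerated, and
#'   if there are more than `max_sets` a seeded uniform subsample is used.
#'
#' @param framework one of `"intra"`, `"inter"`, `"single_vs_all"`,
#'   `"multi_vs_all"`.
#' @param conditions ordered vector of condition values.
#' @param trials ordered vector of trial indices (>= 2).
#' @param subject_id subject the plans apply to.
#' @param n_train number of training conditions (`multi_vs_all` only).
#' @param max_sets cap on enumerated training sets for `multi_vs_all`.
#' @param seed seed for the subsample when the cap binds.
#' @return a list of `split_plan` objects with fields `framework`,
#'   `train_conditions`, `test_conditions`, `held_out_trial`, `subject_id`.
#' @examples
#' length(make_splits("inter", 1:5, 1:1, subject_id = 1))  # 20 ordered pairs
#' @export
make_splits <- function(framework = c("intra", "inter", "single_vs_all",
                                      "multi_vs_all"),
                        conditions, trials, subject_id,
                        n_train = NULL, max_sets = 1000, seed = 1L) {
  framework <- match.arg(framework)
  stop_if_not(length(conditions) >= 1, "conditions must be nonempty")
  stop_if_not(length(trials) >= 1, "trials must be nonempty")
  plan <- function(train, test, trial) {
    structure(list(framework = framework, train_conditions = train,
                   test_conditions = test, held_out_trial = trial,
                   subject_id = subject_id),
              class = "split_plan")
  }
  train_sets <- switch(framework,
    intra = ,
    single_vs_all = as.list(conditions),
    inter = {
      pairs <- expand.grid(train = conditions, test = conditions)
      pairs <- pairs[pairs$train != pairs$test, ]
      lapply(seq_len(nrow(pairs)),
             function(i) list(train = pairs$train[i], test = pairs$test[i]))
    },
    multi_vs_all = {
      stop_if_not(!is.null(n_train), "n_train is required for multi_vs_all",
                  class = "emg_parameter_error")
      stop_if_not(is_count(n_train) && n_train <= length(conditions),
                  "n_train must be in 1..|conditions|",
                  class = "emg_parameter_error")
      sets <- utils::combn(conditions, n_train, simplify = FALSE)
      if (length(sets) > max_sets) {
        sets <- with_seed(derive_seed(seed, 404L),
                          sets[sort(sample.int(length(sets), max_sets))])
      }
      sets
    })
  out <- list()
  for (tr in train_sets) {
    for (trial in trials) {
      out[[length(out) + 1L]] <- switch(framework,
        intra = plan(tr, tr, trial),
        inter = plan(tr$train, tr$test, trial),
        single_vs_all = plan(tr, conditions, trial),
        multi_vs_all = plan(tr, conditions, trial))
    }
  }
  out
}
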