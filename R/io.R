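# Plain-text serialization: one CSV per recording (rows = channels) with a
# JSON metadata sidecar, a top-level JSON manifest, and CSV feature/result
# tables.

#' Write a dataset of recordings to a directory
#'
#' Writes `rec_NNNN.csv` (channels x samples, no header) and
#' `rec_NNNN.json` (subject_id, motion_label, condition_kind,
#' condition_value, trial_index, fs) per recording, plus `manifest.json`
#' listing every pair.
#'
#' @param recordings list of [emg_recording()] objects.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    stem <- sprintf("rec_%04d", i)
    utils::write.table(r$data, file.path(dir, paste0(stem, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    side <- list(subject_id = r$subject_id, motion_label = r$motion_label,
                 condition_kind = r$condition_kind,
                 condition_value = r$condition_value,
                 trial_index = r$trial_index, fs = r$fs)
    jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
    entries[[i]] <- c(side, list(data = paste0(stem, ".csv"),
                                 sidecar = paste0(stem, ".json")))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n_recordings = length(recordings),
                            recordings = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list of [emg_recording()] objects.
#' @export
read_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  stop_if_not(file.exists(manifest),
              sprintf("no manifest.json under '%s'", dir))
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(m$recordings, function(e) {
    dat <- as.matrix(utils::read.csv(file.path(dir, e$data), header = FALSE))
    dimnames(dat) <- NULL
    emg_recording(dat, fs = e$fs, subject_id = e$subject_id,
                  motion_label = e$motion_label,
                  condition_kind = e$condition_kind,
                  condition_value = e$condition_value,
                  trial_index = e$trial_index)
  })
}

#' Write a feature matrix to CSV
#'
#' Header: `subject,motion,condition,trial,<FEAT[ch]>,...`.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- cbind(data.frame(subject = fm$meta$subject_id,
                         motion = fm$meta$motion_label,
                         condition = fm$meta$condition_value,
                         trial = fm$meta$trial_index,
                         stringsAsFactors = FALSE),
              as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @param feature_set set name to record on the object.
#' @param condition_kind condition kind to record in the metadata.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path, feature_set = NA_character_,
                                condition_kind = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("subject", "motion", "condition", "trial")
  stop_if_not(all(meta_cols %in% names(df)), "not a feature-matrix CSV")
  values <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  structure(list(values = values, feature_names = colnames(values),
                 feature_set = feature_set,
                 meta = data.frame(subject_id = df$subject,
                                   motion_label = df$motion,
                                   condition_kind = condition_kind,
                                   condition_value = df$condition,
                                   trial_index = df$trial,
                                   stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

#' Write experiment results
#'
#' Writes one tidy CSV row per split and a JSON summary keyed by
#' `(feature_set, classifier, framework)`.
#'
#' @param results list of [run_experiment()] results.
#' @param csv_path,json_path output paths.
#' @return `csv_path`, invisibly.
#' @export
write_results <- function(results, csv_path, json_path) {
  if (inherits(results, "eval_result")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    cbind(data.frame(feature_set = r$feature_set, classifier = r$classifier,
                     stringsAsFactors = FALSE), r$rows)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  summ <- lapply(results, function(r) {
    list(feature_set = r$feature_set, classifier = r$classifier,
         framework = r$framework,
         mean = unname(r$summary["mean"]), sd = unname(r$summary["sd"]),
         min = unname(r$summary["min"]), max = unname(r$summary["max"]),
         subject_means = as.list(r$subject_means))
  })
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
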