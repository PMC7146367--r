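# Named feature sets from the myoelectric-control literature and the
# window-set -> feature-matrix extraction surface.

.feature_sets <- list(
  TD    = c("MAV", "ZC", "SSC", "WL"),
  TDAR  = c("MAV", "ZC", "SSC", "WL", "AR4"),
  TSTD  = c("MAVFD", "DASDV", "WAMP", "ZC", "MFL", "SampEn", "TDPSD"),
  LSF4  = c("LS", "MFL", "MSR", "WAMP"),
  LSF9  = c("LS", "MFL", "MSR", "WAMP", "ZC", "RMS", "IEMG", "DASDV", "VAR"),
  TDPSD = c("TDPSD"),
  Hjorth = c("ACT", "MOB", "COMP")
)

#' Named feature-set specification
#'
#' Resolves one of the literature's named per-channel feature bundles:
#' `TD` (Hudgins' time domain: MAV, ZC, SSC, WL), `TDAR` (TD + order-4 AR
#' coefficients), `TSTD` (topologically selected time domain: MAVFD,
#' DASDV, WAMP, ZC, MFL, SampEn plus the six spectral-moment descriptors),
#' `LSF4` / `LSF9` (low-sampling-frequency sets), `TDPSD` (the six
#' spectral-moment descriptors alone), and `Hjorth` (activity, mobility,
#' complexity).
#'
#' @param name a set name.
#' @param params named list of per-feature parameter overrides, e.g.
#'   `list(WAMP = list(threshold = 0.01), TDPSD = list(fused = FALSE))`.
#' @return an object of class `feature_set_spec` with fields `name`,
#'   `features`, `params`, `n_per_channel`.
#' @examples
#' feature_set_spec("TD")$features
#' @export
feature_set_spec <- function(name, params = list()) {
  members <- .feature_sets[[name]]
  stop_if_not(!is.null(members), sprintf("unknown feature set '%s'", name),
              class = "emg_lookup_error")
  bad <- setdiff(names(params), members)
  stop_if_not(length(bad) == 0,
              sprintf("parameters given for features not in set: %s",
                      paste(bad, collapse = ", ")))
  n_per <- sum(vapply(members, function(f) .feature_catalog[[f]]$n_out, numeric(1)))
  structure(list(name = name, features = members, params = params,
                 n_per_channel = as.integer(n_per)),
            class = "feature_set_spec")
}

#' Names of the available feature sets
#' @return character vector of set names.
#' @export
list_feature_sets <- function() names(.feature_sets)

feature_col_names <- function(spec, n_channels) {
  unlist(lapply(spec$features, function(f) {
    n_out <- .feature_catalog[[f]]$n_out
    base <- if (n_out == 1) f else paste0(f, "_", seq_len(n_out))
    as.vector(vapply(seq_len(n_channels),
                     function(ch) paste0(base, "[", ch, "]"),
                     character(n_out)))
  }))
}

#' Extract a named feature set from a window set
#'
#' Computes every feature of the set on every channel of every window.
#' Column order is feature-major: all channels of the first set member,
#' then all channels of the second, and so on; multi-valued features
#' contribute consecutive columns per channel (`AR4_1[3]` is the first AR
#' coefficient of channel 3). Window metadata is carried over unchanged.
#'
#' @param window_set a [segment()] result.
#' @param spec a [feature_set_spec()], or a set name.
#' @return an object of class `feature_matrix`: list with `values`
#'   (`n_windows x d` numeric matrix, `d = n_per_channel x channels`),
#'   `feature_names`, `feature_set`, and the aligned `meta` data frame.
#' @examples
#' cfg <- generator_config(n_subjects = 1, motion_classes = c("rest", "grip"),
#'                         conditions = 1:2, reps_per_condition = 1,
#'                         trial_duration = 0.3)
#' ws <- segment(generate_dataset(cfg))
#' fm <- extract_set(ws, "TD")
#' dim(fm$values)
#' @export
extract_set <- function(window_set, spec) {
  stop_if_not(inherits(window_set, "window_set"), "window_set must come from segment()")
  if (is.character(spec)) spec <- feature_set_spec(spec)
  stop_if_not(inherits(spec, "feature_set_spec"), "spec must be a feature_set_spec")
  d <- dim(window_set$windows)
  n_w <- d[1]; n_ch <- d[2]
  blocks <- vector("list", length(spec$features))
  for (fi in seq_along(spec$features)) {
    f <- spec$features[fi]
    entry <- .feature_catalog[[f]]
    args <- utils::modifyList(entry$params, spec$params[[f]] %||% list())
    cols <- matrix(NA_real_, nrow = n_w, ncol = entry$n_out * n_ch)
    for (ch in seq_len(n_ch)) {
      W <- window_set$windows[, ch, , drop = FALSE]
      dim(W) <- c(n_w, d[3])
      idx <- ((ch - 1) * entry$n_out + 1):(ch * entry$n_out)
      vf <- vfeat[[f]]
      if (!is.null(vf) && entry$n_out == 1) {
        cols[, idx] <- do.call(vf, c(list(W), args))
      } else {
        res <- try(t(apply(W, 1, function(x) do.call(entry$fn, c(list(x), args)))),
                   silent = TRUE)
        if (inherits(res, "try-error")) {
          stop(sprintf("feature '%s' failed on channel %d: %s", f, ch,
                       attr(res, "condition")$message))
        }
        if (entry$n_out == 1) res <- matrix(res, ncol = 1)
        cols[, idx] <- res
      }
    }
    blocks[[fi]] <- cols
  }
  values <- do.call(cbind, blocks)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop(sprintf("non-finite feature value at window %d (feature column %d)",
                 bad[1, 1], bad[1, 2]))
  }
  colnames(values) <- feature_col_names(spec, n_ch)
  structure(list(values = values, feature_names = colnames(values),
                 feature_set = spec$name, meta = window_set$meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d windows x %d features\n",
              x$feature_set, nrow(x$values), ncol(x$values)))
  invisible(x)
}
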