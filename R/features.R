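# Per-channel time-domain feature catalog. The myoelectric literature names
# these features without fixing formulas; the conventions implemented here
# are the canonical ones and are stated in each entry's documentation.

EPS <- 1e-12

# counter for log-argument clamps inside the spectral-moment descriptors
.clamp_env <- new.env(parent = emptyenv())
.clamp_env$n <- 0L

#' Number of log-argument clamps performed by the spectral-moment descriptors
#'
#' The time-domain power-spectral descriptors take logs of moment
#' differences that can be non-positive on degenerate windows; such
#' arguments are clamped at a small epsilon and counted. `reset` zeroes the
#' counter.
#'
#' @param reset if `TRUE`, reset the counter to zero after reading it.
#' @return the number of clamps since the last reset.
#' @export
tdpsd_clamp_count <- function(reset = FALSE) {
  n <- .clamp_env$n
  if (reset) .clamp_env$n <- 0L
  n
}

clamp_log <- function(x) {
  bad <- x < EPS
  if (any(bad)) {
    .clamp_env$n <- .clamp_env$n + sum(bad)
    x[bad] <- EPS
  }
  log(x)
}

# --- scalar feature kernels -------------------------------------------------

feat_MAV   <- function(x, ...) mean(abs(x))
feat_IEMG  <- function(x, ...) sum(abs(x))
feat_RMS   <- function(x, ...) sqrt(mean(x^2))
feat_VAR   <- function(x, ...) stats::var(x)
feat_WL    <- function(x, ...) sum(abs(diff(x)))
feat_DASDV <- function(x, ...) sqrt(mean(diff(x)^2))
feat_MAVFD <- function(x, ...) mean(abs(diff(x)))
feat_MFL   <- function(x, ...) log10(sqrt(max(sum(diff(x)^2), EPS)))
feat_MSR   <- function(x, ...) mean(sqrt(abs(x)))

feat_ZC <- function(x, threshold = 0, ...) {
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) > threshold)
}

feat_SSC <- function(x, threshold = 0, ...) {
  n <- length(x)
  if (n < 3) return(0)
  mid <- x[2:(n - 1)]
  sum((mid - x[1:(n - 2)]) * (mid - x[3:n]) > threshold)
}

feat_WAMP <- function(x, threshold = 0.02, ...) sum(abs(diff(x)) > threshold)

# L-scale: second L-moment, via the order-statistics estimator
# l2 = 2*b1 - b0, b1 = (1/n) sum_{i} ((i-1)/(n-1)) x_(i).
feat_LS <- function(x, ...) {
  n <- length(x)
  xs <- sort(x)
  b0 <- mean(xs)
  b1 <- sum((seq_len(n) - 1) / (n - 1) * xs) / n
  2 * b1 - b0
}

feat_ACT <- function(x, ...) stats::var(x)

hjorth_mobility <- function(x) {
  v <- stats::var(x)
  if (v <= 0) return(0)
  sqrt(stats::var(diff(x)) / v)
}

feat_MOB <- function(x, ...) hjorth_mobility(x)

feat_COMP <- function(x, ...) {
  m <- hjorth_mobility(x)
  if (m <= 0) return(0)
  hjorth_mobility(diff(x)) / m
}

# Yule-Walker AR coefficients (order p): demean, biased autocovariances,
# solve the Toeplitz system. Sign convention: x_t = sum_k a_k x_{t-k} + e_t
# (matches stats::ar.yw's $ar).
feat_AR4 <- function(x, order = 4, ...) {
  n <- length(x)
  stop_if_not(n >= order + 1, "window too short for AR fit")
  xc <- x - mean(x)
  r <- vapply(0:order, function(k) {
    sum(xc[1:(n - k)] * xc[(k + 1):n]) / n
  }, numeric(1))
  if (r[1] <= 0) return(rep(0, order))
  a <- solve(stats::toeplitz(r[1:order]), r[2:(order + 1)])
  as.numeric(a)
}

# Sample entropy (m = 2, r = 0.2 * SD, natural log, self-matches excluded):
# -log(A/B) with B the number of template pairs matching at length m and A
# at length m + 1 (Chebyshev distance). Degenerate windows (zero variance,
# or no matches at either length) return 0.
feat_SampEn <- function(x, m = 2, r_factor = 0.2, ...) {
  n <- length(x)
  stop_if_not(n >= m + 2, "window too short for sample entropy")
  s <- stats::sd(x)
  if (s == 0) return(0)
  r <- r_factor * s
  n_t <- n - m  # templates of length m+1 (use same count for both lengths)
  # pairwise Chebyshev distances over templates, vectorized per lag
  B <- 0L; A <- 0L
  for (lag in seq_len(n_t - 1)) {
    i <- seq_len(n_t - lag)
    j <- i + lag
    dm <- abs(x[i] - x[j])
    for (k in seq_len(m - 1)) dm <- pmax(dm, abs(x[i + k] - x[j + k]))
    hit_m <- dm <= r
    B <- B + sum(hit_m)
    dm1 <- pmax(dm, abs(x[i + m] - x[j + m]))
    A <- A + sum(dm1 <= r)
  }
  if (B == 0 || A == 0) return(0)
  -log(A / B)
}

# Six time-domain power-spectral descriptors per channel. From the window x,
# square roots of the zeroth, second and fourth spectral moments are formed
# in the time domain (Parseval), power-rescaled (m <- m^0.1 / 0.1), and
# turned into log-domain descriptors; the same descriptors computed from a
# log-power transform of the window act as an orientation reference, and
# the two vectors are fused by a normalized correlation-like product.
tdpsd_descriptors <- function(x) {
  d1 <- diff(x); d2 <- diff(d1)
  m0 <- sqrt(sum(x^2));  m2 <- sqrt(sum(d1^2)); m4 <- sqrt(sum(d2^2))
  m0 <- max(m0, EPS)^0.1 / 0.1
  m2 <- max(m2, EPS)^0.1 / 0.1
  m4 <- max(m4, EPS)^0.1 / 0.1
  wl1 <- sum(abs(d1)); wl2 <- sum(abs(d2))
  c(clamp_log(m0),
    clamp_log(m0 - m2),
    clamp_log(m0 - m4),
    clamp_log(m0 / sqrt(max((m0 - m2) * (m0 - m4), EPS))),
    clamp_log(m2 / sqrt(max(m0 * m4, EPS))),
    clamp_log(wl1 / max(wl2, EPS)))
}

feat_TDPSD <- function(x, fused = TRUE, ...) {
  a <- tdpsd_descriptors(x)
  if (!fused) return(a)
  b <- tdpsd_descriptors(log(x^2 + EPS))
  denom <- a^2 + b^2
  f <- ifelse(denom < EPS, 0, -2 * a * b / denom)
  as.numeric(f)
}

# --- vectorized kernels (rows of W are windows) -----------------------------

vrow_diff <- function(W) W[, -1, drop = FALSE] - W[, -ncol(W), drop = FALSE]

vfeat <- list(
  MAV   = function(W, ...) rowMeans(abs(W)),
  IEMG  = function(W, ...) rowSums(abs(W)),
  RMS   = function(W, ...) sqrt(rowMeans(W^2)),
  VAR   = function(W, ...) apply(W, 1, stats::var),
  WL    = function(W, ...) rowSums(abs(vrow_diff(W))),
  DASDV = function(W, ...) sqrt(rowMeans(vrow_diff(W)^2)),
  MAVFD = function(W, ...) rowMeans(abs(vrow_diff(W))),
  MFL   = function(W, ...) log10(sqrt(pmax(rowSums(vrow_diff(W)^2), EPS))),
  MSR   = function(W, ...) rowMeans(sqrt(abs(W))),
  ZC    = function(W, threshold = 0, ...) {
    A <- W[, -ncol(W), drop = FALSE]; B <- W[, -1, drop = FALSE]
    rowSums(A * B < 0 & abs(A - B) > threshold)
  },
  SSC   = function(W, threshold = 0, ...) {
    n <- ncol(W)
    M <- W[, 2:(n - 1), drop = FALSE]
    rowSums((M - W[, 1:(n - 2), drop = FALSE]) *
              (M - W[, 3:n, drop = FALSE]) > threshold)
  },
  WAMP  = function(W, threshold = 0.02, ...) rowSums(abs(vrow_diff(W)) > threshold),
  ACT   = function(W, ...) apply(W, 1, stats::var)
)

# --- catalog ----------------------------------------------------------------

.feature_catalog <- list(
  MAV    = list(fn = feat_MAV,    n_out = 1, params = list()),
  IEMG   = list(fn = feat_IEMG,   n_out = 1, params = list()),
  RMS    = list(fn = feat_RMS,    n_out = 1, params = list()),
  VAR    = list(fn = feat_VAR,    n_out = 1, params = list()),
  WL     = list(fn = feat_WL,     n_out = 1, params = list()),
  DASDV  = list(fn = feat_DASDV,  n_out = 1, params = list()),
  MAVFD  = list(fn = feat_MAVFD,  n_out = 1, params = list()),
  MFL    = list(fn = feat_MFL,    n_out = 1, params = list()),
  MSR    = list(fn = feat_MSR,    n_out = 1, params = list()),
  LS     = list(fn = feat_LS,     n_out = 1, params = list()),
  ZC     = list(fn = feat_ZC,     n_out = 1, params = list(threshold = 0)),
  SSC    = list(fn = feat_SSC,    n_out = 1, params = list(threshold = 0)),
  WAMP   = list(fn = feat_WAMP,   n_out = 1, params = list(threshold = 0.02)),
  ACT    = list(fn = feat_ACT,    n_out = 1, params = list()),
  MOB    = list(fn = feat_MOB,    n_out = 1, params = list()),
  COMP   = list(fn = feat_COMP,   n_out = 1, params = list()),
  AR4    = list(fn = feat_AR4,    n_out = 4, params = list(order = 4)),
  SampEn = list(fn = feat_SampEn, n_out = 1,
                params = list(m = 2, r_factor = 0.2)),
  TDPSD  = list(fn = feat_TDPSD,  n_out = 6, params = list(fused = TRUE))
)

#' List the implemented feature catalog
#'
#' @return a data frame with one row per catalog feature: its name, the
#'   number of values it emits per channel, and its tunable parameters
#'   (as a comma-separated `name=default` string).
#' @examples
#' list_features()
#' @export
list_features <- function() {
  data.frame(
    name = names(.feature_catalog),
    n_out = vapply(.feature_catalog, function(f) as.integer(f$n_out), integer(1)),
    params = vapply(.feature_catalog, function(f) {
      if (length(f$params) == 0) return("")
      paste(names(f$params), unlist(f$params), sep = "=", collapse = ", ")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Extract one feature from a single-channel window
#'
#' Computes one catalog feature on a numeric sample sequence. Conventions:
#' MAV = mean rectified value; IEMG = sum of rectified values; RMS;
#' VAR = unbiased sample variance; WL = waveform length (sum |dx|);
#' DASDV = RMS of the first difference; MAVFD = MAV of the first
#' difference; MFL = log10 of the Euclidean norm of the first difference;
#' MSR = mean square root of rectified values; LS = L-scale (second
#' L-moment); ZC/SSC = threshold-gated zero-crossing / slope-sign-change
#' counts; WAMP = Willison amplitude (count |dx| > threshold, default
#' 0.02 mV); ACT/MOB/COMP = Hjorth activity, mobility, complexity (zero on
#' zero-variance windows); AR4 = order-4 Yule-Walker autoregressive
#' coefficients; SampEn = sample entropy (m = 2, r = 0.2 SD, natural log,
#' no self-matches; 0 on degenerate windows); TDPSD = six fused
#' spectral-moment descriptors (set `fused = FALSE` for the raw
#' descriptors).
#'
#' @param x numeric vector, one channel of one window (length >= 3).
#' @param feature_name a catalog name from [list_features()].
#' @param ... parameter overrides (e.g. `threshold`, `order`, `fused`).
#' @return numeric vector: length 1, or 4 for `AR4`, or 6 for `TDPSD`.
#' @examples
#' extract_feature(c(1, -1, 2, -2), "MAV")  # 1.5
#' extract_feature(c(0, 1, 0, 1), "WL")     # 3
#' @export
extract_feature <- function(x, feature_name, ...) {
  entry <- .feature_catalog[[feature_name]]
  stop_if_not(!is.null(entry), sprintf("unknown feature '%s'", feature_name),
              class = "emg_lookup_error")
  stop_if_not(is.numeric(x) && length(x) >= 2, "window must have length >= 2")
  args <- utils::modifyList(entry$params, list(...))
  val <- do.call(entry$fn, c(list(x), args))
  stop_if_not(all(is.finite(val)),
              sprintf("feature '%s' produced a non-finite value", feature_name))
  val
}
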