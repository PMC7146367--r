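# Independent brute-force oracles for features and metrics. These are
# written as direct transcriptions of the defining formulas (explicit
# loops, order statistics, pairwise enumerations) and share no code with
# the package implementations.

o_MAV   <- function(x) sum(abs(x)) / length(x)
o_IEMG  <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s }
o_RMS   <- function(x) sqrt(sum(x * x) / length(x))
o_VAR   <- function(x) sum((x - sum(x) / length(x))^2) / (length(x) - 1)
o_WL    <- function(x) { s <- 0; for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1]); s }
o_DASDV <- function(x) { s <- 0; for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
                         sqrt(s / (length(x) - 1)) }
o_MAVFD <- function(x) { s <- 0; for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
                         s / (length(x) - 1) }
o_MFL   <- function(x) { s <- 0; for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
                         log10(sqrt(s)) }
o_MSR   <- function(x) { s <- 0; for (v in x) s <- s + sqrt(abs(v)); s / length(x) }

# L-scale as half the Gini mean difference over all unordered pairs
o_LS <- function(x) {
  n <- length(x); s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + abs(x[i] - x[j])
  s / (n * (n - 1))
}

o_ZC <- function(x, threshold = 0) {
  s <- 0
  for (i in 1:(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) > threshold) s <- s + 1
  }
  s
}

o_SSC <- function(x, threshold = 0) {
  s <- 0
  for (i in 2:(length(x) - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > threshold) s <- s + 1
  }
  s
}

o_WAMP <- function(x, threshold = 0.02) {
  s <- 0
  for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > threshold) s <- s + 1
  s
}

o_ACT <- function(x) o_VAR(x)
o_MOB <- function(x) sqrt(o_VAR(diff(x)) / o_VAR(x))
o_COMP <- function(x) o_MOB(diff(x)) / o_MOB(x)

o_AR4 <- function(x) as.numeric(stats::ar.yw(x, aic = FALSE, order.max = 4)$ar)

o_SampEn <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * stats::sd(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dmax <- 0
      for (k in 0:(m - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
      if (dmax <= r) {
        B <- B + 1L
        if (max(dmax, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(0)
  -log(A / B)
}

# direct transcription of the six-descriptor construction with fusion
o_TDPSD <- function(x, eps = 1e-12) {
  desc <- function(y) {
    d1 <- y[-1] - y[-length(y)]
    d2 <- d1[-1] - d1[-length(d1)]
    m0 <- max(sqrt(sum(y^2)), eps)^0.1 / 0.1
    m2 <- max(sqrt(sum(d1^2)), eps)^0.1 / 0.1
    m4 <- max(sqrt(sum(d2^2)), eps)^0.1 / 0.1
    cl <- function(v) log(max(v, eps))
    c(cl(m0), cl(m0 - m2), cl(m0 - m4),
      cl(m0 / sqrt(max((m0 - m2) * (m0 - m4), eps))),
      cl(m2 / sqrt(max(m0 * m4, eps))),
      cl(sum(abs(d1)) / max(sum(abs(d2)), eps)))
  }
  a <- desc(x); b <- desc(log(x^2 + eps))
  out <- numeric(6)
  for (i in 1:6) {
    den <- a[i]^2 + b[i]^2
    out[i] <- if (den < eps) 0 else -2 * a[i] * b[i] / den
  }
  out
}

feature_oracles <- list(
  MAV = o_MAV, IEMG = o_IEMG, RMS = o_RMS, VAR = o_VAR, WL = o_WL,
  DASDV = o_DASDV, MAVFD = o_MAVFD, MFL = o_MFL, MSR = o_MSR, LS = o_LS,
  ZC = o_ZC, SSC = o_SSC, WAMP = o_WAMP, ACT = o_ACT, MOB = o_MOB,
  COMP = o_COMP, AR4 = o_AR4, SampEn = o_SampEn, TDPSD = o_TDPSD
)

# --- metric oracles ---------------------------------------------------------

# transcription of the defining formula: 100 x (1 - #correct / N)
o_ter <- function(p, l) {
  correct <- 0L
  for (i in seq_along(p)) if (p[i] == l[i]) correct <- correct + 1L
  100 * (1 - correct / length(p))
}

o_aer <- function(p, l, nm) {
  num <- 0L; den <- 0L
  for (i in seq_along(p)) {
    if (p[i] != nm) {
      den <- den + 1L
      if (p[i] != l[i]) num <- num + 1L
    }
  }
  if (den == 0L) return(NA_real_)
  100 * num / den
}

o_dbi <- function(X, labs) {
  cl <- unique(labs)
  K <- length(cl)
  mu <- list(); S <- numeric(K)
  for (i in 1:K) {
    Xi <- X[labs == cl[i], , drop = FALSE]
    mu[[i]] <- apply(Xi, 2, mean)
    tot <- 0
    for (r in seq_len(nrow(Xi))) tot <- tot + sum((Xi[r, ] - mu[[i]])^2)
    S[i] <- tot / nrow(Xi)
  }
  worst <- numeric(K)
  for (i in 1:K) {
    best <- -Inf
    for (j in 1:K) {
      if (j == i) next
      D <- sum((mu[[i]] - mu[[j]])^2)
      best <- max(best, (S[i] + S[j]) / D)
    }
    worst[i] <- best
  }
  mean(worst)
}

# brute-force window count: enumerate admissible start indices
o_window_count <- function(n, L, I) {
  count <- 0L; st <- 1L
  while (st + L - 1L <= n) { count <- count + 1L; st <- st + I }
  count
}

# small synthetic feature_matrix builder for evaluate-module tests
fake_feature_matrix <- function(n_per_cell, classes, conditions, trials,
                                subjects = 1, d = 3, sep = 5, sd = 1,
                                seed = 99) {
  set.seed(seed)
  rows <- expand.grid(class = classes, condition = conditions, trial = trials,
                      subject = subjects, rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  centers <- matrix(stats::rnorm(length(classes) * d, sd = sep), ncol = d,
                    dimnames = list(classes, NULL))
  values <- centers[rows$class, , drop = FALSE] +
    matrix(stats::rnorm(nrow(rows) * d, sd = sd), ncol = d)
  colnames(values) <- paste0("F", seq_len(d))
  structure(list(values = values, feature_names = colnames(values),
                 feature_set = "FAKE",
                 meta = data.frame(subject_id = rows$subject,
                                   motion_label = rows$class,
                                   condition_kind = "position",
                                   condition_value = rows$condition,
                                   trial_index = rows$trial,
                                   stringsAsFactors = FALSE)),
            class = "feature_matrix")
}
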