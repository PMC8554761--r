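# Linear slow collective modes (tICA) with VAMP-2 scoring.
#
# The estimator solves the symmetrized time-lagged generalized eigenvalue
# problem C_tau v = lambda C_0 v, with the instantaneous covariance C_0
# ridge-regularized. Symmetrization (averaging forward and time-reversed
# lagged covariances) enforces real eigenvalues on finite data, matching
# the reversible-dynamics assumption of the downstream MSM.

.as_series_list <- function(features) {
  if (is.matrix(features)) list(features)
  else if (is.list(features)) features
  else stop("features must be a matrix or a list of matrices")
}

.lag_steps <- function(lag, dt, where = "lag") {
  steps <- lag / dt
  if (abs(steps - round(steps)) > 1e-8)
    stop(where, " (", lag, " ns) must be a multiple of dt_save (", dt, " ns)")
  as.integer(round(steps))
}

# Accumulate symmetrized instantaneous and time-lagged second moments
# over series, mean-removed with the joint mean of heads and tails.
# Chunked so that million-frame series never force large copies; the
# mean is removed analytically from the raw moments.
.tica_covariances <- function(series, steps, chunk = 200000L) {
  p <- ncol(series[[1L]])
  sum_h <- numeric(p); sum_t <- numeric(p); n_pairs <- 0
  C0r <- matrix(0, p, p); Ctr <- matrix(0, p, p)
  for (X in series) {
    m <- nrow(X) - steps
    if (m < 1L)
      stop("every series must be longer than the lag (", steps, " frames)")
    for (from in seq(1L, m, by = chunk)) {
      to <- min(from + chunk - 1L, m)
      A <- X[from:to, , drop = FALSE]
      B <- X[(from:to) + steps, , drop = FALSE]
      sum_h <- sum_h + colSums(A)
      sum_t <- sum_t + colSums(B)
      C0r <- C0r + crossprod(A) + crossprod(B)
      Ctr <- Ctr + crossprod(A, B)
    }
    n_pairs <- n_pairs + m
  }
  n_tot <- 2 * n_pairs
  mu <- (sum_h + sum_t) / n_tot
  C0 <- (C0r - n_tot * tcrossprod(mu)) / n_tot
  Ct <- Ctr - outer(sum_h, mu) - outer(mu, sum_t) + n_pairs * tcrossprod(mu)
  Ct <- (Ct + t(Ct)) / n_tot
  list(C0 = C0, Ct = Ct, mean = mu, n = n_tot)
}

#' Fit linear slow collective modes (tICA)
#'
#' Learns the linear projections of the feature vectors with maximal
#' time-lagged autocorrelation at the given lag. Eigenvalues approximate
#' transfer-operator eigenvalues; the associated implied timescales are
#' `-lag / log(lambda)`. Zero-variance features are dropped with a
#' warning. The lag is a physical choice and must not be tuned by score.
#'
#' @param features a `feature_series` matrix or list of them (each with a
#'   `dt_save` attribute, or supply `dt`).
#' @param lag lag time in ns; must be a multiple of the frame interval.
#' @param n_modes number of modes to retain (>= 1).
#' @param reg ridge regularization added to the diagonal of the
#'   instantaneous covariance.
#' @param dt frame interval in ns if the series lack a `dt_save` attribute.
#' @return An object of class `slow_mode_model` with fields `lag`, `mean`,
#'   `components` (n_modes x n_features, rows orthonormal in the C0
#'   metric), `eigenvalues`, `n_modes`, `kept` (feature indices retained).
#' @export
fit_linear_slow_modes <- function(features, lag, n_modes = 5L, reg = 1e-6,
                                  dt = NULL) {
  series <- .as_series_list(features)
  if (is.null(dt)) dt <- attr(series[[1L]], "dt_save")
  if (is.null(dt)) stop("supply dt: series carry no dt_save attribute")
  stopifnot(n_modes >= 1)
  steps <- .lag_steps(lag, dt)
  cov <- .tica_covariances(series, steps)
  keep <- which(diag(cov$C0) > 1e-12)
  if (length(keep) == 0L) stop("all features are constant")
  if (length(keep) < ncol(cov$C0))
    warning("dropping ", ncol(cov$C0) - length(keep),
            " zero-variance feature(s)")
  C0 <- cov$C0[keep, keep, drop = FALSE]
  Ct <- cov$Ct[keep, keep, drop = FALSE]
  C0r <- C0 + diag(reg, nrow(C0))
  # whiten with the symmetric inverse square root of C0
  e0 <- eigen(C0r, symmetric = TRUE)
  pos <- e0$values > max(e0$values) * 1e-12
  W <- e0$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[pos]), sum(pos))
  M <- crossprod(W, Ct %*% W)
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  n_modes <- min(n_modes, length(em$values))
  ord <- order(em$values, decreasing = TRUE)[seq_len(n_modes)]
  comp_kept <- W %*% em$vectors[, ord, drop = FALSE]   # C0-orthonormal
  components <- matrix(0, n_modes, ncol(cov$C0))
  components[, keep] <- t(comp_kept)
  structure(list(lag = lag, mean = cov$mean, components = components,
                 eigenvalues = em$values[ord], n_modes = n_modes,
                 kept = keep, reg = reg, dt = dt),
            class = "slow_mode_model")
}

#' Project feature series onto fitted slow modes
#'
#' @param model a [slow_mode_model][fit_linear_slow_modes].
#' @param features matrix or list of feature matrices.
#' @return Projection matrix (or list), `n_frames x n_modes`; `dt_save`
#'   attributes are carried over.
#' @export
project_slow_modes <- function(model, features) {
  if (is.list(features) && !is.matrix(features))
    return(lapply(features, project_slow_modes, model = model))
  # (X - 1 mu') W' computed as X W' - 1 (W mu)' to avoid copying X
  Y <- features %*% t(model$components)
  Y <- sweep(Y, 2L, drop(model$components %*% model$mean))
  attr(Y, "dt_save") <- attr(features, "dt_save")
  Y
}

#' @export
print.slow_mode_model <- function(x, ...) {
  cat("<slow_mode_model> ", x$n_modes, " modes at lag ", x$lag, " ns\n",
      sep = "")
  ts <- -x$lag / log(pmin(pmax(abs(x$eigenvalues), 1e-12), 1 - 1e-12))
  cat("  eigenvalues:", sprintf("%.4f", x$eigenvalues), "\n")
  cat("  implied timescales (ns):", sprintf("%.2f", ts), "\n")
  invisible(x)
}

#' VAMP-2 score of a featurization
#'
#' Sum of squared estimated transfer-operator eigenvalues over the top
#' `k` modes, including the stationary mode (whose eigenvalue is 1), so
#' any stationary series scores at least ~1. Deterministic given input.
#'
#' @param features matrix or list of feature matrices.
#' @param lag lag time in ns.
#' @param k number of modes scored, including the stationary mode (>= 1).
#' @param dt frame interval in ns if the series lack a `dt_save` attribute.
#' @param reg ridge regularization passed to the mode estimator.
#' @return Scalar score in `[1, k]`.
#' @export
vamp2_score <- function(features, lag, k, dt = NULL, reg = 1e-6) {
  stopifnot(k >= 1)
  if (k == 1L) return(1)
  series <- .as_series_list(features)
  fit <- fit_linear_slow_modes(series, lag, n_modes = k - 1L, reg = reg,
                               dt = dt)
  if (fit$n_modes < k - 1L)
    warning("requested k = ", k, " exceeds available rank; scoring ",
            fit$n_modes + 1L, " modes")
  1 + sum(fit$eigenvalues^2)
}

#' Cross-validated VAMP-2 scoring
#'
#' Partitions whole trajectories (never frames) into `n_folds` random
#' folds, fits the slow modes on the training folds, and scores both
#' train and validation data by projecting onto the training modes and
#' computing the generalized time-lagged autocorrelation of each mode.
#'
#' @param features list of feature matrices (>= `n_folds` series).
#' @param lag lag time in ns.
#' @param k number of modes scored, including the stationary mode.
#' @param n_folds number of folds.
#' @param seed integer seed fixing the partition.
#' @param dt frame interval in ns if the series lack a `dt_save` attribute.
#' @return List with `train` and `validation` score vectors (length
#'   `n_folds`) and the fold assignment.
#' @export
cross_validated_vamp2 <- function(features, lag, k, n_folds = 5L, seed = 1L,
                                  dt = NULL) {
  series <- .as_series_list(features)
  if (length(series) < n_folds)
    stop("need at least as many independent series (", length(series),
         ") as folds (", n_folds, ")")
  if (is.null(dt)) dt <- attr(series[[1L]], "dt_save")
  folds <- .with_rng(seed, {
    sample(rep_len(seq_len(n_folds), length(series)))
  })
  steps <- .lag_steps(lag, dt)
  score_on <- function(model, subset) {
    cov <- .tica_covariances(subset, steps)
    C <- model$components[, model$kept, drop = FALSE]
    C0 <- cov$C0[model$kept, model$kept, drop = FALSE]
    Ct <- cov$Ct[model$kept, model$kept, drop = FALSE]
    num <- rowSums((C %*% Ct) * C)
    den <- rowSums((C %*% C0) * C)
    lam <- ifelse(den > 0, num / den, 0)
    1 + sum(lam^2)
  }
  train <- numeric(n_folds); validation <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- series[folds != f]
    va <- series[folds == f]
    model <- fit_linear_slow_modes(tr, lag, n_modes = k - 1L, dt = dt)
    train[f] <- score_on(model, tr)
    validation[f] <- score_on(model, va)
  }
  list(train = train, validation = validation, folds = folds)
}

#' Cumulative VAMP-2 knee table
#'
#' Utility for choosing the embedding dimensionality: reports the
#' cumulative VAMP-2 score and the implied timescale per mode count.
#' Modes whose implied timescale exceeds the lag are flagged as resolved.
#'
#' @param features matrix or list of feature matrices.
#' @param lag lag time in ns.
#' @param k_max largest mode count tabulated.
#' @param dt frame interval in ns if needed.
#' @return Data frame with columns `k`, `eigenvalue`, `timescale_ns`,
#'   `cumulative_vamp2`, `resolved`.
#' @export
vamp2_knee_table <- function(features, lag, k_max = 10L, dt = NULL) {
  fit <- fit_linear_slow_modes(.as_series_list(features), lag,
                               n_modes = k_max - 1L, dt = dt)
  lam <- c(1, fit$eigenvalues)
  lam_c <- pmin(pmax(abs(lam), 1e-12), 1 - 1e-12)
  data.frame(
    k = seq_along(lam),
    eigenvalue = lam,
    timescale_ns = c(Inf, -fit$lag / log(lam_c[-1L])),
    cumulative_vamp2 = cumsum(lam^2),
    resolved = c(TRUE, -fit$lag / log(lam_c[-1L]) > fit$lag)
  )
}
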