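# Microstate clustering, reversible MSM estimation, and Markovianity
# validation.

#' Cluster projected frames into microstates
#'
#' k-means with k-means++ seeding. For large data the centers are fitted
#' on a deterministic subsample (`max_fit_frames`) and every frame is then
#' assigned to its nearest center; with default settings this reproduces
#' plain k-means behaviour on small data while keeping the operation
#' tractable on millions of frames. Deterministic given `seed`.
#'
#' @param embedding projection matrix (`n x n_modes`) or list of such
#'   matrices, one per trajectory.
#' @param k number of microstates (>= 2).
#' @param seed integer seed.
#' @param max_fit_frames cap on the number of frames used to fit centers.
#' @param iter_max k-means iteration cap.
#' @return An object of class `microstate_assignment`: `labels` (list of
#'   integer vectors in `1..k`), `centers` (`k x n_modes`), `k`, `seed`,
#'   `dt_save`.
#' @export
cluster_microstates <- function(embedding, k, seed = 1L,
                                max_fit_frames = 1e5, iter_max = 100L) {
  series <- if (is.matrix(embedding)) list(embedding) else embedding
  dt <- attr(series[[1L]], "dt_save")
  X <- do.call(rbind, lapply(series, unclass))
  k <- as.integer(k)
  stopifnot(k >= 2, nrow(X) >= k)
  .with_rng(seed, {
    fit_idx <- if (nrow(X) > max_fit_frames)
      sort(sample.int(nrow(X), max_fit_frames)) else seq_len(nrow(X))
    Xf <- X[fit_idx, , drop = FALSE]
    if (nrow(unique(Xf)) < k)
      stop("k = ", k, " exceeds the number of distinct points")
    centers0 <- .kmeanspp_centers(Xf, k)
    km <- suppressWarnings(
      stats::kmeans(Xf, centers = centers0, iter.max = iter_max,
                    algorithm = "Lloyd"))
    centers <- km$centers
    lengths <- vapply(series, nrow, 1L)
    all_lab <- .assign_to_centers(X, centers)
    labels <- split(all_lab, rep(seq_along(series), lengths))
    names(labels) <- NULL
    structure(list(labels = labels, centers = centers, k = k, seed = seed,
                   dt_save = dt, withinss = sum(km$withinss)),
              class = "microstate_assignment")
  })
}

# k-means++ seeding: squared-distance-proportional sampling, which makes
# small, geometrically remote metastable clusters near-certain to receive
# a center even when they hold a tiny fraction of frames.
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (m in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[m, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[m, ])^2))
  }
  centers
}

# Nearest-center assignment, chunked; deterministic tie-break (first).
.assign_to_centers <- function(X, centers) {
  cn2 <- rowSums(centers^2)
  out <- integer(nrow(X))
  step <- 200000L
  for (from in seq(1L, nrow(X), by = step)) {
    to <- min(from + step - 1L, nrow(X))
    G <- X[from:to, , drop = FALSE] %*% t(centers)
    out[from:to] <- max.col(sweep(2 * G, 2L, cn2), ties.method = "first")
  }
  out
}

#' @export
print.microstate_assignment <- function(x, ...) {
  cat("<microstate_assignment> k = ", x$k, ", ",
      length(x$labels), " trajectorie(s), ",
      sum(vapply(x$labels, length, 1L)), " frames\n", sep = "")
  invisible(x)
}

# Sliding-window transition count matrix at `steps` lag, never counting
# across trajectory boundaries. Non-positive labels (frames outside the
# active set) are skipped.
transition_counts <- function(dtrajs, steps, k) {
  counts <- matrix(0, k, k)
  for (s in dtrajs) {
    if (length(s) <= steps) next
    from <- s[seq_len(length(s) - steps)]
    to <- s[seq_len(length(s) - steps) + steps]
    ok <- from >= 1L & to >= 1L
    counts <- counts +
      matrix(tabulate((from[ok] - 1L) * k + to[ok], nbins = k * k),
             k, k, byrow = TRUE)
  }
  counts
}

# Largest strongly connected set of the count graph, by total counts.
.largest_scc <- function(counts) {
  present <- which(rowSums(counts) + colSums(counts) > 0)
  adj <- (counts[present, present, drop = FALSE] > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  weight <- vapply(seq_len(comp$no), function(cc) {
    m <- comp$membership == cc
    sum(counts[present[m], present[m], drop = FALSE])
  }, numeric(1))
  sort(present[comp$membership == which.max(weight)])
}

# Reversible maximum-likelihood transition matrix: self-consistent fixed
# point on the symmetrized count variables x_ij (Bowman-style iteration),
# converged when the element-wise change of the normalized x falls below
# `tol`.
reversible_mle <- function(counts, tol = 1e-10, max_iter = 1e6) {
  Csym <- counts + t(counts)
  ci <- rowSums(counts)
  X <- Csym / sum(Csym)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    q <- ci / xi
    Xn <- Csym / outer(q, q, `+`)
    Xn <- Xn / sum(Xn)
    delta <- max(abs(Xn - X))
    X <- Xn
    if (delta < tol) break
  }
  pi <- rowSums(X)
  T <- X / pi
  list(T = T, pi = pi, iterations = it, delta = delta)
}

#' Estimate a reversible Markov state model
#'
#' Sliding-window transition counts at the lag (within trajectories
#' only), restriction to the largest strongly connected set, reversible
#' maximum-likelihood estimation of the transition matrix, and spectral
#' analysis with implied timescales `t_i = -lag / log|lambda_i|`.
#'
#' @param assignment a [microstate_assignment][cluster_microstates], or a
#'   list of integer label vectors (then supply `dt`).
#' @param lag lag time in ns, a positive multiple of the frame interval.
#' @param dt frame interval in ns when raw label vectors are given.
#' @param n_eigen number of eigenpairs reported (default all).
#' @return An object of class `reversible_msm` with fields `lag`, `T`,
#'   `pi`, `eigenvalues`, `implied_timescales`, `active_set`,
#'   `discarded_fraction`, `counts`, `dtrajs` (active-set-mapped label
#'   series with 0 = outside), `dt`.
#' @export
estimate_reversible_msm <- function(assignment, lag, dt = NULL,
                                    n_eigen = NULL) {
  if (inherits(assignment, "microstate_assignment")) {
    dtrajs <- assignment$labels
    if (is.null(dt)) dt <- assignment$dt_save
    k <- assignment$k
  } else {
    dtrajs <- assignment
    k <- max(unlist(dtrajs))
  }
  if (is.null(dt)) stop("frame interval dt unknown; supply dt")
  steps <- .lag_steps(lag, dt)
  if (steps < 1L) stop("lag must be positive")
  if (all(vapply(dtrajs, length, 1L) <= steps))
    stop("lag exceeds every trajectory length")
  counts <- transition_counts(dtrajs, steps, k)
  active <- .largest_scc(counts)
  if (length(active) == 0L) stop("empty connected set")
  total_frames <- sum(vapply(dtrajs, length, 1L))
  in_active <- sum(vapply(dtrajs, function(s) sum(s %in% active), 1L))
  mle <- reversible_mle(counts[active, active, drop = FALSE])
  ev <- .reversible_spectrum(mle$T, mle$pi)
  if (!is.null(n_eigen)) {
    ev$values <- ev$values[seq_len(min(n_eigen, length(ev$values)))]
  }
  lam <- ev$values
  its <- rep(NA_real_, length(lam))
  nz <- abs(lam) < 1 & abs(lam) > 0
  its[nz] <- -lag / log(abs(lam[nz]))
  map <- integer(k); map[active] <- seq_along(active)
  structure(list(lag = lag, T = mle$T, pi = mle$pi,
                 eigenvalues = lam, eigenvectors = ev$vectors,
                 implied_timescales = its[-1L],
                 active_set = active,
                 discarded_fraction = 1 - in_active / total_frames,
                 counts = counts,
                 dtrajs = lapply(dtrajs, function(s) map[s]),
                 dt = dt),
            class = "reversible_msm")
}

# Full spectrum of a reversible transition matrix via the symmetrized
# form D^(1/2) T D^(-1/2); right eigenvectors returned in original
# coordinates, first vector constant.
.reversible_spectrum <- function(T, pi) {
  s <- sqrt(pi)
  S <- T * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vec <- e$vectors[, ord, drop = FALSE] / s
  # normalize sign and scale: constant first vector == 1
  vec[, 1L] <- vec[, 1L] / vec[1L, 1L]
  list(values = e$values[ord], vectors = vec)
}

#' @export
print.reversible_msm <- function(x, ...) {
  cat("<reversible_msm> ", length(x$active_set), " active microstates, lag ",
      x$lag, " ns\n", sep = "")
  cat("  leading implied timescales (ns):",
      sprintf("%.1f", head(x$implied_timescales, 6L)), "\n")
  cat("  discarded frame fraction:",
      sprintf("%.3g", x$discarded_fraction), "\n")
  invisible(x)
}

#' Chapman-Kolmogorov test
#'
#' Compares `P^k(tau)` (the model propagated) against `P(k tau)`
#' (re-estimated from data at the longer lag) for `k = 1..k_max`.
#' Deviations are reported element-wise together with multinomial
#' standard errors of the re-estimated probabilities; an element passes
#' when its deviation is within `max(3 SE, tol)`.
#'
#' @param assignment a `microstate_assignment`, `reversible_msm` (its
#'   stored label series are used), or list of integer label vectors.
#' @param model transition model to propagate: a `reversible_msm`,
#'   `macrostate_model`, or row-stochastic matrix. Defaults to a model
#'   estimated at `lag` from the data.
#' @param k_max largest lag multiple tested (>= 2).
#' @param lag base lag in ns (taken from `model` when available).
#' @param dt frame interval in ns when raw label vectors are given.
#' @param tol absolute deviation floor below which an element always
#'   passes.
#' @return An object of class `ck_test` with per-k predicted and
#'   re-estimated matrices, deviations, standard errors and `passed`.
#' @export
ck_test <- function(assignment, model = NULL, k_max = 5L, lag = NULL,
                    dt = NULL, tol = 0.02) {
  stopifnot(k_max >= 2)
  if (inherits(assignment, "reversible_msm")) {
    dtrajs <- assignment$dtrajs
    dt <- assignment$dt
    if (is.null(model)) model <- assignment
  } else if (inherits(assignment, "microstate_assignment")) {
    dtrajs <- assignment$labels
    dt <- assignment$dt_save
  } else {
    dtrajs <- assignment
  }
  if (inherits(model, "reversible_msm")) {
    P <- model$T; lag <- model$lag
    if (inherits(assignment, "microstate_assignment")) {
      map <- integer(max(unlist(dtrajs))); map[model$active_set] <- seq_along(model$active_set)
      dtrajs <- lapply(dtrajs, function(s) map[s])
    }
  } else if (inherits(model, "macrostate_model")) {
    P <- model$P; lag <- model$lag
  } else if (is.matrix(model)) {
    P <- model
    if (is.null(lag)) stop("supply lag with a raw transition matrix")
  } else if (is.null(model)) {
    if (is.null(lag)) stop("supply lag")
    m <- estimate_reversible_msm(dtrajs, lag, dt = dt)
    P <- m$T; dtrajs <- m$dtrajs
  }
  if (is.null(dt)) stop("frame interval dt unknown; supply dt")
  steps <- .lag_steps(lag, dt)
  n <- nrow(P)
  res <- vector("list", k_max)
  ok <- TRUE
  Pk <- diag(n)
  for (k in seq_len(k_max)) {
    Pk <- Pk %*% P
    if (max(vapply(dtrajs, length, 1L)) <= k * steps)
      stop("insufficient data at lag multiple k = ", k)
    counts <- transition_counts(dtrajs, k * steps, n)
    ni <- rowSums(counts)
    est <- counts / ifelse(ni > 0, ni, 1)
    se <- sqrt(est * (1 - est) / ifelse(ni > 0, ni, 1))
    dev <- Pk - est
    pass <- abs(dev) <= pmax(3 * se, tol)
    pass[ni == 0, ] <- TRUE
    ok <- ok && all(pass)
    res[[k]] <- list(k = k, predicted = Pk, estimated = est,
                     deviation = dev, se = se, passed = all(pass))
  }
  structure(list(results = res, k_max = k_max, lag = lag, passed = ok,
                 tol = tol),
            class = "ck_test")
}

#' @export
print.ck_test <- function(x, ...) {
  cat("<ck_test> lag ", x$lag, " ns, k = 1..", x$k_max, ": ",
      if (x$passed) "PASS" else "FAIL", "\n", sep = "")
  for (r in x$results)
    cat(sprintf("  k = %d: max |dev| = %.4f (%s)\n", r$k,
                max(abs(r$deviation)), if (r$passed) "pass" else "fail"))
  invisible(x)
}
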