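# Relaxation-rate extraction from trajectory ensembles, two-state
# kinetic algebra for self-complementary oligomers, trace fitting, and
# simulation-to-experiment rate-curve calibration.

#' Extract first-passage times from a relaxation ensemble
#'
#' For `kind = "dissociation"`, the event time of a trajectory is the
#' first frame at which both central native pairs (strand-1 positions 5
#' and 6) exceed `dissoc_cutoff`; for `kind = "fraying"`, the first
#' frame at which either terminal native pair (positions 1 and 10)
#' exceeds `bound_cutoff` (complete breakage of the Watson-Crick
#' interaction). Trajectories with no event before `t_max` are censored.
#'
#' @param ensemble a [relaxation_ensemble][simulate_relaxation] (every
#'   trajectory must start hybridized).
#' @param kind `"dissociation"` or `"fraying"`.
#' @param bound_cutoff,dissoc_cutoff distance cutoffs in nm.
#' @return An object of class `first_passage_set` with `event_times`
#'   (ns, uncensored events), `censored` (logical per trajectory),
#'   `times` (per-trajectory event or censoring time), `t_max`,
#'   `event_kind`.
#' @export
extract_first_passage <- function(ensemble, kind = c("dissociation",
                                                     "fraying"),
                                  bound_cutoff = 1.3, dissoc_cutoff = 2.0) {
  kind <- match.arg(kind)
  trajs <- if (inherits(ensemble, "relaxation_ensemble"))
    ensemble$trajectories else ensemble
  t_max <- if (inherits(ensemble, "relaxation_ensemble")) ensemble$t_max
           else max(vapply(trajs, function(x) dim(x$frames)[1L] * x$dt_save,
                           numeric(1)))
  n <- length(trajs)
  times <- numeric(n); cens <- logical(n)
  for (m in seq_len(n)) {
    tr <- trajs[[m]]
    fr <- tr$frames
    if (kind == "dissociation") {
      d <- .native_pair_distance(fr, c(5L, 6L))
      if (min(d[1L, ]) > dissoc_cutoff)
        stop("trajectory ", m, " does not start hybridized")
      hit <- which(d[, 1L] > dissoc_cutoff & d[, 2L] > dissoc_cutoff)
    } else {
      d <- .native_pair_distance(fr, c(1L, 10L))
      hit <- which(d[, 1L] > bound_cutoff | d[, 2L] > bound_cutoff)
    }
    if (length(hit)) {
      # frame f samples the state over ((f-1) dt, f dt]; an event first
      # seen at frame f is assigned time f * dt_save
      times[m] <- hit[1L] * tr$dt_save
      cens[m] <- FALSE
    } else {
      times[m] <- t_max
      cens[m] <- TRUE
    }
  }
  structure(list(event_times = times[!cens], censored = cens,
                 times = times, t_max = t_max, event_kind = kind),
            class = "first_passage_set")
}

#' @export
print.first_passage_set <- function(x, ...) {
  cat("<first_passage_set> ", x$event_kind, ": ", length(x$event_times),
      " events, ", sum(x$censored), " censored, t_max = ", x$t_max,
      " ns\n", sep = "")
  invisible(x)
}

#' Fit an exponential rate to a first-passage survival curve
#'
#' Least-squares fit of `exp(-k t)` to the empirical survival fraction
#' evaluated at the event times, with censored trajectories kept in the
#' at-risk denominator throughout (administrative censoring at `t_max`).
#' A maximum-likelihood exponential fit (censoring-aware) is reported
#' alongside for comparison, and a trajectory bootstrap provides the
#' confidence interval.
#'
#' @param fps a [first_passage_set][extract_first_passage], or a numeric
#'   vector of uncensored event times.
#' @param n_boot bootstrap replicates for the CI (0 disables).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return List of class `survival_rate_fit`: `rate` (1/ns), `rate_ml`,
#'   `ci`, `n_events`, `n_censored`.
#' @export
fit_survival_rate <- function(fps, n_boot = 200L, conf = 0.95, seed = 1L) {
  if (is.numeric(fps))
    fps <- structure(list(event_times = fps, censored = logical(length(fps)),
                          times = fps, t_max = max(fps),
                          event_kind = "events"),
                     class = "first_passage_set")
  if (length(fps$event_times) < 1L)
    stop("no uncensored events: cannot fit a rate")
  fit_once <- function(times, censored) {
    n <- length(times)
    ev <- sort(times[!censored])
    surv <- 1 - seq_along(ev) / n      # survival just after each event
    # least squares on S(t) ~ exp(-k t); k > 0
    obj <- function(logk) sum((surv - exp(-exp(logk) * ev))^2)
    k0 <- 1 / mean(ev)
    opt <- optimize(obj, interval = log(k0) + c(-8, 8))
    exp(opt$minimum)
  }
  k <- fit_once(fps$times, fps$censored)
  # censoring-aware ML estimate: events / total observed time
  k_ml <- length(fps$event_times) / sum(fps$times)
  ci <- NULL
  if (n_boot > 0L) {
    ks <- .with_rng(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(fps$times), replace = TRUE)
      if (all(fps$censored[idx])) return(NA_real_)
      fit_once(fps$times[idx], fps$censored[idx])
    }, numeric(1)))
    a <- (1 - conf) / 2
    ci <- quantile(ks, probs = c(a, 1 - a), na.rm = TRUE)
  }
  structure(list(rate = k, rate_ml = k_ml, ci = ci,
                 n_events = length(fps$event_times),
                 n_censored = sum(fps$censored), conf = conf),
            class = "survival_rate_fit")
}

#' @export
print.survival_rate_fit <- function(x, ...) {
  cat(sprintf("<survival_rate_fit> k = %.4g 1/ns (ML %.4g), %d events, %d censored\n",
              x$rate, x$rate_ml, x$n_events, x$n_censored))
  if (!is.null(x$ci))
    cat(sprintf("  %g%% CI: [%.4g, %.4g]\n", 100 * x$conf, x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Two-state kinetic algebra for self-complementary oligomers
#'
#' For the duplex equilibrium `2S <-> D` of a self-complementary strand,
#' the observed slow relaxation rate is
#' `lambda_slow = k_d_slow + 4 k_a_slow [S]_Tf`. The equilibrium side is
#' fixed by the fraction of intact duplex `theta` at total strand
#' concentration `c_tot`: `[S]_Tf = c_tot (1 - theta)` and
#' `K_d = [S]^2 / [D] = 2 c_tot (1 - theta)^2 / theta`. Substituting
#' `k_a = k_d / K_d` gives
#' `k_d_slow = lambda_slow / (1 + 4 [S]_Tf / K_d)`.
#'
#' @param theta fraction of intact duplex, strictly inside (0, 1).
#' @param c_tot total single-strand concentration (mM).
#' @param lambda_slow observed slow relaxation rate (1/s).
#' @return List with `K_d` (mM), `S_Tf` (mM), `k_d_slow` (1/s),
#'   `k_a_slow` (1/(mM s)).
#' @export
two_state_rates <- function(theta, c_tot, lambda_slow) {
  stopifnot(c_tot > 0, lambda_slow >= 0)
  if (theta <= 0 || theta >= 1)
    stop("theta must lie strictly in (0, 1): K_d is degenerate at the ",
         "fully bound/unbound limits")
  S <- c_tot * (1 - theta)
  K_d <- 2 * c_tot * (1 - theta)^2 / theta
  k_d <- lambda_slow / (1 + 4 * S / K_d)
  k_a <- k_d / K_d
  list(K_d = K_d, S_Tf = S, k_d_slow = k_d, k_a_slow = k_a)
}

#' Fit a T-jump-style relaxation trace
#'
#' Nonlinear least squares for
#' `S(t) = A exp(-(t/tau_fast)^beta_fast) + B exp(-t/tau_slow) +
#' C exp(-t/tau_cool)` with `beta_fast` in (0, 1] and the identifiability
#' ordering `tau_fast < tau_slow < tau_cool`. The three amplitudes are
#' profiled out linearly (variable projection); the four nonlinear
#' parameters are optimized from `n_starts` seeded initializations and
#' the best residual is returned.
#'
#' @param times time grid (same units as the taus; strictly increasing,
#'   >= 8 samples spanning at least two decades).
#' @param signal observed trace.
#' @param init optional named list of starting values
#'   (`tau_fast`, `beta_fast`, `tau_slow`, `tau_cool`).
#' @param n_starts number of random multistarts.
#' @param seed integer seed.
#' @return List of class `tjump_trace_fit` with `A`, `B`, `C`,
#'   `tau_fast`, `beta_fast`, `tau_slow`, `tau_cool`, `rss`,
#'   `fitted`, `diagnostics` (per-start results).
#' @export
fit_tjump_trace <- function(times, signal, init = NULL, n_starts = 10L,
                            seed = 1L) {
  stopifnot(length(times) == length(signal))
  if (is.unsorted(times, strictly = TRUE))
    stop("time grid must be strictly increasing")
  if (length(times) < 8L)
    stop("need at least 8 samples")
  if (min(times) <= 0) stop("times must be positive")
  if (log10(max(times) / min(times)) < 2)
    stop("time grid must span at least two decades")
  # theta = (log tau_fast, logit beta, log(tau_slow/tau_fast - 1),
  #          log(tau_cool/tau_slow - 1))
  unpack <- function(th) {
    tf <- exp(th[1L])
    beta <- 1 / (1 + exp(-th[2L]))
    ts <- tf * (1 + exp(th[3L]))
    tc <- ts * (1 + exp(th[4L]))
    c(tau_fast = tf, beta_fast = beta, tau_slow = ts, tau_cool = tc)
  }
  design <- function(p)
    cbind(exp(-(times / p[["tau_fast"]])^p[["beta_fast"]]),
          exp(-times / p[["tau_slow"]]),
          exp(-times / p[["tau_cool"]]))
  rss_of <- function(th) {
    p <- unpack(th)
    X <- design(p)
    fit <- tryCatch(qr.coef(qr(X), signal), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) return(Inf)
    sum((signal - X %*% fit)^2)
  }
  lo <- log(min(times)); hi <- log(max(times))
  starts <- .with_rng(seed, {
    lapply(seq_len(n_starts), function(s) {
      c(runif(1, lo, hi - log(100)),
        runif(1, -1.5, 2.5),
        runif(1, 0, log(200)),
        runif(1, 0, log(200)))
    })
  })
  if (!is.null(init)) {
    th0 <- c(log(init$tau_fast),
             log(init$beta_fast / (1 - min(init$beta_fast, 0.999))),
             log(max(init$tau_slow / init$tau_fast - 1, 1e-3)),
             log(max(init$tau_cool / init$tau_slow - 1, 1e-3)))
    starts <- c(list(th0), starts)
  }
  diag_list <- vector("list", length(starts))
  best <- NULL
  for (s in seq_along(starts)) {
    opt <- tryCatch(
      optim(starts[[s]], rss_of, method = "Nelder-Mead",
            control = list(maxit = 4000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      # polish
      opt2 <- tryCatch(
        optim(opt$par, rss_of, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) opt)
      if (!is.null(opt2) && is.finite(opt2$value) &&
          opt2$value <= opt$value) opt <- opt2
    }
    diag_list[[s]] <- opt
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best))
    stop("all trace-fit starts failed; diagnostics: ",
         paste(vapply(diag_list, function(d)
           if (is.null(d)) "error" else format(d$value), character(1)),
           collapse = ", "))
  p <- unpack(best$par)
  X <- design(p)
  amps <- qr.coef(qr(X), signal)
  structure(c(as.list(p),
              list(A = amps[1L], B = amps[2L], C = amps[3L],
                   rss = best$value, fitted = as.vector(X %*% amps),
                   diagnostics = diag_list)),
            class = "tjump_trace_fit")
}

#' @export
print.tjump_trace_fit <- function(x, ...) {
  cat(sprintf("<tjump_trace_fit> beta_fast = %.3f\n", x$beta_fast))
  cat(sprintf("  tau_fast = %.4g, tau_slow = %.4g, tau_cool = %.4g\n",
              x$tau_fast, x$tau_slow, x$tau_cool))
  cat(sprintf("  amplitudes A = %.3g, B = %.3g, C = %.3g (rss %.3g)\n",
              x$A, x$B, x$C, x$rss))
  invisible(x)
}

#' Calibrate simulated rate-temperature curves to experiment
#'
#' Fits the two-parameter map under which experimental rates match
#' simulated ones: `rate_exp(T + dT) = s * rate_sim(T)`, i.e. `s`
#' multiplies simulated rates and `dT` is added to simulated
#' temperatures. A coarse-grained model whose dynamics are accelerated
#' 10x and whose transition sits 4 K low therefore calibrates to
#' `s = 0.1, dT = +4`. Least squares in log-rate, interpolating the
#' simulated curve linearly in log-rate between tabulated points.
#'
#' @param sim_curve,exp_curve data frames (or 2-column matrices) with
#'   temperature (K) and rate (1/s); >= 3 points each, >= 2 of them
#'   overlapping after the shift.
#' @param dT_range search bounds for the temperature shift (K).
#' @return List of class `rate_calibration`: `time_scale` (`s`),
#'   `temp_shift` (`dT`, K), `acceleration` (`1/s`), `residuals`,
#'   `n_matched`.
#' @export
calibrate_to_experiment <- function(sim_curve, exp_curve,
                                    dT_range = c(-25, 25)) {
  sim <- .as_curve(sim_curve); expc <- .as_curve(exp_curve)
  if (nrow(sim) < 3L || nrow(expc) < 3L)
    stop("curves must have at least 3 points each (under-determined)")
  sim <- sim[order(sim$temperature), ]
  logsim <- function(Tq) approx(sim$temperature, log(sim$rate), xout = Tq,
                                rule = 1)$y
  sse_of <- function(dT) {
    pred <- logsim(expc$temperature - dT)
    ok <- is.finite(pred)
    if (sum(ok) < 2L) return(list(sse = Inf))
    r <- log(expc$rate[ok]) - pred[ok]
    logs <- mean(r)
    list(sse = sum((r - logs)^2), logs = logs, n = sum(ok),
         residuals = r - logs)
  }
  grid <- seq(dT_range[1L], dT_range[2L], by = 0.25)
  sses <- vapply(grid, function(d) sse_of(d)$sse, numeric(1))
  if (all(!is.finite(sses)))
    stop("no overlap between curves for any shift in [",
         dT_range[1L], ", ", dT_range[2L], "] K")
  # ties (e.g. perfectly log-linear curves, where s and dT trade off)
  # resolve to the smallest |dT|
  near <- which(sses <= min(sses, na.rm = TRUE) + 1e-12)
  i <- near[which.min(abs(grid[near]))]
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- optimize(function(d) sse_of(d)$sse, interval = bracket)
  dT <- grid[i]
  fin <- sse_of(dT)
  if (is.finite(opt$objective) && opt$objective < fin$sse - 1e-12) {
    dT <- opt$minimum
    fin <- sse_of(dT)
  }
  s <- exp(fin$logs)
  structure(list(time_scale = s, temp_shift = dT, acceleration = 1 / s,
                 residuals = fin$residuals, n_matched = fin$n,
                 sse = fin$sse),
            class = "rate_calibration")
}

.as_curve <- function(x) {
  x <- as.data.frame(x)
  names(x)[1:2] <- c("temperature", "rate")
  stopifnot(all(x$rate > 0))
  x
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat(sprintf("<rate_calibration> time scale s = %.4g (acceleration %.3gx), temp shift dT = %+.2f K\n",
              x$time_scale, x$acceleration, x$temp_shift))
  invisible(x)
}
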