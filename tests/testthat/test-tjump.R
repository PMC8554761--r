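# First-passage extraction, survival fitting, two-state algebra, trace
# fitting, and rate-curve calibration.

hold_in_h <- function(n, dt = 1) {
  p <- pinned_preset("ATGATATCAT", "H")
  p$fray_toggle_rate <- 0
  p$jitter_sigma <- 1e-4
  simulate_equilibrium(p, n, dt_save = dt, seed = 2)
}

test_that("event detection: censoring and exact frame bookkeeping", {
  tr <- hold_in_h(200, dt = 0.5)
  ens <- structure(list(trajectories = list(tr), start_label = "H",
                        temperature_factor = 0, t_max = 100),
                   class = "relaxation_ensemble")
  fps <- extract_first_passage(ens, "dissociation")
  expect_identical(sum(fps$censored), 1L)
  expect_length(fps$event_times, 0L)
  expect_error(fit_survival_rate(fps), "no uncensored")
  # construct a crossing exactly at frame 137: move both central pairs
  tr2 <- tr
  tr2$frames[137:200, 1, 5:6, 2] <- 5
  ens2 <- ens; ens2$trajectories <- list(tr2)
  fps2 <- extract_first_passage(ens2, "dissociation")
  expect_equal(fps2$event_times, 137 * 0.5)
  # fraying triggers on either terminal pair at the 1.3 nm cutoff
  tr3 <- tr
  tr3$frames[50:200, 1, 1, 2] <- tr3$frames[50:200, 1, 1, 2] + 1.4
  ens3 <- ens; ens3$trajectories <- list(tr3)
  fps3 <- extract_first_passage(ens3, "fraying")
  expect_equal(fps3$event_times, 50 * 0.5)
  # a trajectory that starts dissociated is rejected
  tr4 <- tr
  tr4$frames[, 2, , 2] <- tr4$frames[, 2, , 2] - 10
  ens4 <- ens; ens4$trajectories <- list(tr4)
  expect_error(extract_first_passage(ens4, "dissociation"),
               "start hybridized")
})

test_that("survival-rate fitting recovers known exponentials", {
  times <- with_seed(61, rexp(1e4, rate = 1e-3))
  fit <- fit_survival_rate(times, n_boot = 0)
  expect_lt(abs(fit$rate - 1e-3) / 1e-3, 0.05)
  fit2 <- fit_survival_rate(times * 2, n_boot = 0)
  expect_equal(fit2$rate, fit$rate / 2, tolerance = 1e-6)
  # heavy administrative censoring (90%)
  t_max <- qexp(0.1, 1e-3)
  raw <- with_seed(62, rexp(1e4, 1e-3))
  fps <- structure(list(event_times = raw[raw <= t_max],
                        censored = raw > t_max,
                        times = pmin(raw, t_max), t_max = t_max,
                        event_kind = "dissociation"),
                   class = "first_passage_set")
  fit3 <- fit_survival_rate(fps, n_boot = 50, seed = 4)
  expect_lt(abs(fit3$rate - 1e-3) / 1e-3, 0.15)
  expect_true(fit3$ci[1] < 1e-3 && 1e-3 < fit3$ci[2])
})

test_that("two-state algebra satisfies the mass-action oracle and round trip", {
  out <- two_state_rates(theta = 0.5, c_tot = 2, lambda_slow = 1e5)
  ma <- oracle_mass_action(out$k_d_slow, out$k_a_slow, c_tot = 2)
  expect_lt(abs(ma$theta - 0.5), 1e-3 * 0.5)
  expect_lt(abs(ma$lambda - 1e5) / 1e5, 1e-3)
  expect_equal(ma$S_eq, out$S_Tf, tolerance = 1e-9)
  # round trip lambda = k_d + 4 k_a [S]
  for (theta in c(0.1, 0.3, 0.5, 0.8, 0.95)) {
    o <- two_state_rates(theta, c_tot = 2, lambda_slow = 3.3e4)
    lam <- o$k_d_slow + 4 * o$k_a_slow * o$S_Tf
    expect_lt(abs(lam - 3.3e4) / 3.3e4, 1e-10)
  }
})

test_that("two-state limits behave as the physics requires", {
  # fully bound limit: K_d -> 0
  expect_lt(two_state_rates(1 - 1e-9, 2, 1e5)$K_d, 1e-8)
  # negligible reassociation (4[S]/K_d -> 0, i.e. theta -> 0):
  # k_d_slow -> lambda_slow
  o <- two_state_rates(1e-9, 2, 1e5)
  expect_lt(abs(o$k_d_slow - 1e5) / 1e5, 1e-6)
  expect_error(two_state_rates(1, 2, 1e5), "theta")
  expect_error(two_state_rates(0, 2, 1e5), "theta")
})

test_that("trace fit recovers noiseless parameters within 1%", {
  tt <- 10^seq(log10(5), log10(5e7), length.out = 80)   # 5 ns .. 50 ms
  truth <- list(A = 1, B = -0.6, C = 0.8,
                tau_fast = 100, beta_fast = 0.3,
                tau_slow = 2e4, tau_cool = 5e6)
  sig <- truth$A * exp(-(tt / truth$tau_fast)^truth$beta_fast) +
    truth$B * exp(-tt / truth$tau_slow) +
    truth$C * exp(-tt / truth$tau_cool)
  fit <- fit_tjump_trace(tt, sig, seed = 3)
  expect_lt(abs(fit$beta_fast - 0.3) / 0.3, 0.01)
  expect_lt(abs(fit$tau_fast - 100) / 100, 0.01)
  expect_lt(abs(fit$tau_slow - 2e4) / 2e4, 0.01)
  expect_lt(abs(fit$tau_cool - 5e6) / 5e6, 0.01)
  expect_lt(abs(fit$A - 1), 0.01)
  expect_true(fit$tau_fast < fit$tau_slow &&
                fit$tau_slow < fit$tau_cool)
})

test_that("a plain exponential is recovered as beta ~ 1", {
  tt <- 10^seq(0, 4, length.out = 60)
  sig <- 2 * exp(-tt / 50) - 0.5 * exp(-tt / 2e3) + 0.3 * exp(-tt / 3e4)
  fit <- fit_tjump_trace(tt, sig, seed = 5)
  expect_gte(fit$beta_fast, 0.95)
})

test_that("beta separates stretched from compressed generators under noise", {
  tt <- 10^seq(log10(5), log10(5e7), length.out = 60)
  fit_beta <- function(beta, seed) {
    sig <- exp(-(tt / 100)^beta) - 0.6 * exp(-tt / 2e4) +
      0.8 * exp(-tt / 5e6)
    sig <- sig + with_seed(seed, rnorm(length(tt), sd = 0.01))
    fit_tjump_trace(tt, sig, n_starts = 4, seed = seed,
                    init = list(tau_fast = 300, beta_fast = 0.5,
                                tau_slow = 1e4, tau_cool = 1e6))$beta_fast
  }
  b03 <- vapply(1:12, function(s) fit_beta(0.3, s), numeric(1))
  b06 <- vapply(1:12, function(s) fit_beta(0.6, 100 + s), numeric(1))
  expect_lt(quantile(b03, 0.75), quantile(b06, 0.25))
})

test_that("trace-fit input validation", {
  expect_error(fit_tjump_trace(c(3, 2, 1, 4:9), rnorm(9)), "increasing")
  expect_error(fit_tjump_trace(1:9 / 1.0, rnorm(9)), "two decades")
  expect_error(fit_tjump_trace(c(1, 10, 100), rnorm(3)), "8 samples")
})

test_that("calibration recovers identity and a constructed distortion", {
  Ts <- seq(300, 330, by = 3)
  # curved in log-rate so the (s, dT) pair is identifiable
  rates <- 1e4 * exp(0.12 * (Ts - 300) + 0.004 * (Ts - 300)^2)
  sim <- data.frame(temperature = Ts, rate = rates)
  id <- calibrate_to_experiment(sim, sim)
  expect_lt(abs(id$time_scale - 1), 1e-6)
  expect_lt(abs(id$temp_shift), 1e-3)
  # experiment = simulation slowed 10x and transition moved +4 K
  exp_curve <- data.frame(temperature = Ts + 4, rate = 0.1 * rates)
  cal <- calibrate_to_experiment(sim, exp_curve)
  expect_lt(abs(cal$time_scale - 0.1) / 0.1, 1e-6)
  expect_lt(abs(cal$temp_shift - 4), 1e-3)
  expect_equal(cal$acceleration, 10, tolerance = 1e-6)
  expect_error(calibrate_to_experiment(sim[1, ], exp_curve),
               "at least 3 points")
  far <- data.frame(temperature = Ts + 500, rate = rates)
  expect_error(calibrate_to_experiment(sim, far), "no overlap")
})

test_that("fraying responds faster than dissociation on every preset", {
  for (nm in c("AT-all", "GC-end", "GC-core", "GC-mix")) {
    p <- build_preset(nm)
    ens_f <- simulate_relaxation(p, u = 0, n_traj = 60, t_max = 30,
                                 seed = 71, dt_save = 0.1)
    k_fray <- fit_survival_rate(extract_first_passage(ens_f, "fraying"),
                                n_boot = 0)$rate
    ens_d <- simulate_relaxation(p, u = 0, n_traj = 60, t_max = 4000,
                                 seed = 72, dt_save = 4)
    fps_d <- extract_first_passage(ens_d, "dissociation")
    k_diss <- if (length(fps_d$event_times) > 0)
      fit_survival_rate(fps_d, n_boot = 0)$rate
    else 1 / ens_d$t_max   # upper bound when nothing dissociates
    expect_gt(k_fray, 10 * k_diss, label = nm)
  }
})

test_that("dissociation rate rises monotonically with the temperature factor", {
  p <- build_preset("GC-mix")
  ks <- vapply(c(0.5, 1, 2), function(u) {
    tmax <- 4000 / exp(u)
    ens <- simulate_relaxation(p, u = u, n_traj = 100, t_max = tmax,
                               seed = 80 + round(10 * u), dt_save = tmax / 1000)
    fit_survival_rate(extract_first_passage(ens, "dissociation"),
                      n_boot = 0)$rate
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
})
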