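# Microstate clustering, reversible MSM estimation, CK validation,
# PCCA+ coarse-graining, and the bootstrap.

test_that("k-means recovers well-separated clouds and is deterministic", {
  set.seed(41)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  X <- centers[rep(1:4, each = 200), ] + matrix(rnorm(1600, sd = 0.2),
                                                800, 2)
  attr(X, "dt_save") <- 1
  a <- cluster_microstates(X, k = 4, seed = 2)
  expect_identical(a$k, 4L)
  truth <- rep(1:4, each = 200)
  tab <- table(truth, a$labels[[1]])
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
  b <- cluster_microstates(X, k = 4, seed = 2)
  expect_identical(a$centers, b$centers)
  expect_error(cluster_microstates(X[rep(1, 50), ], k = 4, seed = 1),
               "distinct")
})

test_that("k-means objective beats random center assignment", {
  set.seed(43)
  X <- matrix(rnorm(2000), 500, 4)
  attr(X, "dt_save") <- 1
  fit <- cluster_microstates(X, k = 10, seed = 3)
  rand <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    lab <- sample.int(10, 500, replace = TRUE)
    sum(vapply(1:10, function(g) {
      sub <- X[lab == g, , drop = FALSE]
      if (nrow(sub) < 1) return(0)
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(fit$withinss <= rand))
})

test_that("reversible MLE reproduces the symmetric-count closed form", {
  counts <- matrix(c(90, 10, 10, 90), 2, 2)
  m <- duplexmsm:::reversible_mle(counts)
  expect_equal(m$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), tolerance = 1e-9)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("implied timescales follow -lag/log(lambda)", {
  dtraj <- with_seed(7, oracle_sample_dtmc(
    matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), 2e4, 1L))
  msm <- estimate_reversible_msm(list(dtraj), lag = 1.2, dt = 1.2)
  lam2 <- msm$eigenvalues[2]
  expect_equal(msm$implied_timescales[1], -1.2 / log(lam2),
               tolerance = 1e-12)
  # frozen analytic value: lambda = 0.8 at lag 1.2 ns -> 5.38 ns
  expect_equal(-1.2 / log(0.8), 5.3777, tolerance = 1e-4)
  expect_lt(abs(msm$implied_timescales[1] - 5.38), 0.8)  # estimator noise
})

test_that("estimated MSMs satisfy detailed balance to 1e-10", {
  with_seed(8, {
    for (rep in 1:5) {
      n <- sample(3:6, 1)
      P <- oracle_random_reversible_P(n)$P
      dtraj <- oracle_sample_dtmc(P, 5000, 1L)
      msm <- estimate_reversible_msm(list(dtraj), lag = 1, dt = 1)
      db <- max(abs(msm$pi * msm$T - t(msm$pi * msm$T)))
      expect_lt(db, 1e-10)
      expect_lt(max(abs(rowSums(msm$T) - 1)), 1e-12)
      expect_lt(max(abs(msm$pi %*% msm$T - msm$pi)), 1e-10)
      expect_equal(msm$eigenvalues[1], 1, tolerance = 1e-10)
    }
  })
})

test_that("counts never cross trajectory boundaries and trimming reports", {
  # states 3 and 4 only touched in a second trajectory, disconnected
  d1 <- rep(c(1L, 2L), 50)
  d2 <- rep(c(3L, 4L), 10)
  msm <- estimate_reversible_msm(list(d1, d2), lag = 1, dt = 1)
  expect_identical(msm$active_set, c(1L, 2L))
  expect_equal(msm$discarded_fraction, 20 / 120, tolerance = 1e-12)
  expect_error(estimate_reversible_msm(list(d1), lag = 200, dt = 1),
               "lag exceeds")
})

test_that("CK test passes Markovian data out to k = 6", {
  P <- matrix(c(0.92, 0.06, 0.02,
                0.05, 0.90, 0.05,
                0.02, 0.08, 0.90), 3, 3, byrow = TRUE)
  dtrajs <- with_seed(10, lapply(1:4, function(i)
    oracle_sample_dtmc(P, 3e4, i %% 3L + 1L)))
  ck <- ck_test(dtrajs, k_max = 6, lag = 1, dt = 1)
  expect_true(ck$passed)
  expect_lt(max(abs(ck$results[[1]]$deviation)), 0.02)
})

test_that("CK test flags a constructed non-Markovian projection", {
  # hidden 3-state chain: states 2 and 3 merged in observation, with
  # state 3 much stickier -> merged state has memory
  Ph <- matrix(c(0.90, 0.10, 0.00,
                 0.20, 0.60, 0.20,
                 0.00, 0.02, 0.98), 3, 3, byrow = TRUE)
  hid <- with_seed(11, oracle_sample_dtmc(Ph, 1e5, 1L))
  obs <- ifelse(hid == 1L, 1L, 2L)
  ck <- ck_test(list(obs), k_max = 6, lag = 1, dt = 1, tol = 0.01)
  expect_false(ck$passed)
})

test_that("PCCA+ recovers block structure and respects constraints", {
  # two weakly-connected 2-blocks
  P <- matrix(c(0.88, 0.10, 0.02, 0.00,
                0.10, 0.88, 0.00, 0.02,
                0.02, 0.00, 0.88, 0.10,
                0.00, 0.02, 0.10, 0.88), 4, 4, byrow = TRUE)
  dtraj <- with_seed(12, oracle_sample_dtmc(P, 5e4, 1L))
  msm <- estimate_reversible_msm(list(dtraj), lag = 1, dt = 1)
  mm <- pcca_coarse_grain(msm, 2)
  expect_true(all(mm$memberships >= 0 & mm$memberships <= 1))
  expect_equal(rowSums(mm$memberships), rep(1, 4), tolerance = 1e-9)
  crisp <- mm$assignment[order(msm$active_set)]
  # blocks {1,2} and {3,4} exactly, up to label permutation; the sign
  # structure of the second eigenvector is the oracle
  ev2 <- msm$eigenvectors[, 2]
  expect_identical(crisp[1] == crisp[2], TRUE)
  expect_identical(crisp[3] == crisp[4], TRUE)
  expect_false(crisp[1] == crisp[3])
  # crisp blocks coincide with the sign structure of the lambda_2
  # eigenvector (the spectral oracle)
  expect_true(all(tapply(sign(ev2), crisp,
                         function(s) length(unique(s)) == 1L)))
  one <- pcca_coarse_grain(msm, 1)
  expect_equal(one$P, matrix(1, 1, 1))
  expect_error(pcca_coarse_grain(msm, 10), "n_macro")
})

test_that("macrostate-count rule follows the documented gap logic", {
  expect_identical(select_n_macrostates(c(5000, 40, 38, 35),
                                        gap_ratio = 3, lag = 1.2), 2L)
  expect_identical(select_n_macrostates(c(0.8, 0.5, 0.2), gap_ratio = 3,
                                        lag = 1.2), 1L)
  expect_identical(select_n_macrostates(c(800, 700, 600, 500, 400),
                                        gap_ratio = 3, lag = 1.2), 6L)
})

test_that("bootstrap gives zero-width intervals on identical data and is seeded", {
  d <- rep(c(1L, 1L, 2L, 2L, 1L), 200)
  dtrajs <- lapply(1:5, function(i) d)
  b <- bootstrap_uncertainty(dtrajs, lag = 1, n_boot = 20, seed = 3, dt = 1)
  expect_lt(max(b$ci_pi[, 2] - b$ci_pi[, 1]), 1e-12)
  b2 <- bootstrap_uncertainty(dtrajs, lag = 1, n_boot = 20, seed = 3, dt = 1)
  expect_identical(b$ci_pi, b2$ci_pi)
  expect_error(bootstrap_uncertainty(dtrajs[1], lag = 1, n_boot = 10,
                                     dt = 1), "2 trajectories")
})

test_that("bootstrap intervals cover the true stationary law", {
  pr <- with_seed(13, oracle_random_reversible_P(3))
  P <- pr$P; pi_true <- pr$pi
  # per-state coverage of the 95% intervals, trajectories started from
  # the stationary law (the estimand is the equilibrium occupancy)
  cover <- with_seed(14, {
    vapply(1:120, function(rep) {
      dtrajs <- lapply(1:20, function(i)
        oracle_sample_dtmc(P, 500, sample.int(3L, 1L, prob = pi_true)))
      b <- suppressWarnings(
        bootstrap_uncertainty(dtrajs, lag = 1, n_boot = 60,
                              seed = rep, dt = 1))
      pi_true >= b$ci_pi[, 1] - 1e-12 & pi_true <= b$ci_pi[, 2] + 1e-12
    }, logical(3))
  })
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 0.999)
})

test_that("implied timescales are stable under doubling the microstate count", {
  gm <- gcmix_run()
  emb <- project_slow_modes(gm$modes,
                            featurize_trajectory(gm$trajectory))
  a400 <- cluster_microstates(emb, k = 400, seed = 9)
  msm400 <- estimate_reversible_msm(a400, lag = 1.2)
  t1_200 <- gm$msm$implied_timescales[1]
  t1_400 <- msm400$implied_timescales[1]
  expect_lt(abs(t1_400 - t1_200) / t1_200, 0.10)
})
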