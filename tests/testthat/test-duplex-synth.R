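# Ground-truth presets and the synthetic trajectory generator.

test_that("named presets carry the published state sets and sequences", {
  expect_identical(build_preset("AT-all")$states,
                   c("H", "5S2", "3S2", "5S4", "3S4", "D"))
  expect_identical(build_preset("GC-end")$states,
                   c("H", "5S2", "3S2", "5S4", "D"))
  expect_identical(build_preset("GC-core")$states, c("H", "F4", "D"))
  expect_identical(build_preset("GC-mix")$states, c("H", "D"))
  expect_identical(build_preset("AT-all")$sequence$bases, "ATATATATAT")
  expect_identical(build_preset("GC-end")$sequence$bases, "GATATATATC")
  expect_identical(build_preset("GC-core")$sequence$bases, "ATATGCATAT")
  expect_identical(build_preset("GC-mix")$sequence$bases, "ATGATATCAT")
})

test_that("preset stationary laws satisfy the configured constraints", {
  for (nm in c("AT-all", "GC-end", "GC-core", "GC-mix")) {
    p <- build_preset(nm)
    expect_lt(abs(sum(p$stationary) - 1), 1e-12)
    expect_equal(p$stationary[["D"]], 0.5, tolerance = 1e-12)
  }
  at <- build_preset("AT-all")
  expect_equal(sum(at$stationary[c("5S2", "3S2", "5S4", "3S4")]), 0.100,
               tolerance = 1e-12)
  ge <- build_preset("GC-end")
  expect_equal(sum(ge$stationary[c("5S2", "3S2", "5S4")]), 0.0023,
               tolerance = 1e-12)
})

test_that("detailed balance holds for every preset at every temperature", {
  for (nm in c("AT-all", "GC-end", "GC-core", "GC-mix")) {
    for (u in c(0, 0.7, -1.3, 3)) {
      p <- build_preset(nm, overrides = list(temperature_factor = u))
      db <- max(abs(p$stationary * p$rate_matrix -
                      t(p$stationary * p$rate_matrix)))
      expect_lt(db, 1e-10)
      expect_lt(max(abs(as.vector(p$stationary %*% p$rate_matrix))), 1e-12)
    }
  }
})

test_that("preset validation names the violated invariant", {
  expect_error(build_preset("AT-everything"), "unknown preset")
  expect_error(build_preset("AT-all", overrides = list(
    pi = c(H = 0.6, `5S2` = 0.04, `3S2` = 0.03, `5S4` = 0.018,
           `3S4` = 0.012, D = 0.5))), "sum to 1")
  expect_error(build_preset("custom", overrides = list(
    sequence = "ATATATATAT", pi = c(H = 0.5, D = 0.5),
    flux = data.frame(i = "H", j = "X", f = 1e-4))), "outside the state set")
  expect_error(build_preset("custom", overrides = list(sequence = "ATAT")),
               "'sequence', 'pi' and 'flux'")
})

test_that("preset relaxation spectra share a ~microsecond leading timescale", {
  t1 <- vapply(c("AT-all", "GC-end", "GC-core", "GC-mix"), function(nm) {
    Q <- build_preset(nm)$rate_matrix
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    -1 / ev[2L]
  }, numeric(1))
  expect_true(all(t1 > 500), info = "microsecond-scale in generator units")
  expect_lt(max(t1) / min(t1), 1.2)
  # within factor 2 of the configured hybridization timescale (the
  # two-state exchange time implied by the H/D flux of GC-mix)
  expect_lt(max(t1) / (2 * 976.6), 1)
  expect_gt(min(t1) * 2 / 976.6, 1)
})

test_that("equilibrium simulation is bit-reproducible under a fixed seed", {
  p <- build_preset("GC-core")
  a <- simulate_equilibrium(p, 500, dt_save = 0.5, seed = 42)
  b <- simulate_equilibrium(p, 500, dt_save = 0.5, seed = 42)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth_labels, b$truth_labels)
  c <- simulate_equilibrium(p, 500, dt_save = 0.5, seed = 43)
  expect_false(identical(a$frames, c$frames))
})

test_that("equilibrium occupancy of D is ~0.5 at melting conditions", {
  p <- build_preset("GC-mix")
  tr <- simulate_equilibrium(p, 5e5, dt_save = 4, seed = 11)
  expect_lt(abs(mean(tr$truth_labels == "D") - 0.5), 0.02)
})

test_that("label frequencies match the stationary law within 3 MC SEs", {
  p <- build_preset("AT-all")
  jumps <- with_seed(5, simulate_jump_process(p$rate_matrix, 6e5,
                                              p$stationary))
  tf <- seq(0, 6e5 - 1, by = 0.6)
  labs <- jumps$states[findInterval(tf, jumps$times)]
  # batch-means MC standard error over 25 blocks
  blocks <- split(labs, cut(seq_along(labs), 25L))
  for (s in p$states) {
    est <- vapply(blocks, function(b) mean(b == s), numeric(1))
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - p$stationary[[s]]), 3 * se + 1e-12,
              label = paste("state", s))
  }
})

test_that("dwell times are exponential at the state's total exit rate", {
  p <- build_preset("AT-all")
  Q <- p$rate_matrix
  jumps <- with_seed(9, simulate_jump_process(Q, 3e6, p$stationary))
  dwell <- diff(jumps$times)
  st <- jumps$states[-length(jumps$states)]
  for (s in c("H", "5S2")) {
    d <- dwell[st == s]
    if (length(d) > 1e4) d <- d[seq_len(1e4)]
    ks <- suppressWarnings(ks.test(d, "pexp", rate = -Q[s, s]))
    expect_gt(ks$p.value, 0.01, label = paste("dwell KS", s))
  }
})

test_that("relaxation ensembles start in H and respect the temperature tilt", {
  p <- build_preset("GC-mix")
  ens <- simulate_relaxation(p, u = 0, n_traj = 12, t_max = 100,
                             seed = 3, dt_save = 0.5)
  expect_length(ens$trajectories, 12L)
  for (tr in ens$trajectories)
    expect_identical(tr$truth_labels[1L], "H")
  # u large: nearly every trajectory reaches D quickly
  ens_hot <- simulate_relaxation(p, u = 5, n_traj = 60, t_max = 200,
                                 seed = 4, dt_save = 0.5)
  reached <- vapply(ens_hot$trajectories,
                    function(tr) any(tr$truth_labels == "D"), logical(1))
  expect_gte(mean(reached), 0.99)
})

test_that("relaxation mean dissociation time matches the linear-solve oracle", {
  p <- build_preset("GC-mix")
  mod <- duplexmsm:::temperature_modified(p, 1)
  truth <- oracle_mfpt_ctmc(mod$Q, "H", "D")
  ens <- simulate_relaxation(p, u = 1, n_traj = 1000, t_max = 6 * truth,
                             seed = 13, dt_save = 5)
  fps <- extract_first_passage(ens, "dissociation")
  expect_lt(sum(fps$censored) / 1000, 0.02)
  # censoring-consistent mean: total observed time / number of events
  est <- sum(fps$times) / length(fps$event_times)
  expect_lt(abs(est - truth) / truth, 0.05)
})

test_that("find_melting_factor returns ~0 for balanced presets and matches a grid scan", {
  for (nm in c("AT-all", "GC-mix"))
    expect_lt(abs(find_melting_factor(build_preset(nm))), 1e-6)
  # custom preset with D-mass 0.3 at u = 0
  p <- build_preset("custom", overrides = list(
    sequence = "ATGATATCAT", pi = c(H = 0.7, D = 0.3),
    flux = data.frame(i = "H", j = "D", f = 2e-4)))
  u_star <- find_melting_factor(p)
  us <- seq(-3, 3, by = 1e-4)
  dmass <- vapply(us, function(u)
    duplexmsm:::temperature_modified(p, u)$pi[["D"]], numeric(1))
  expect_true(all(diff(dmass) > 0))  # strictly monotone in u
  u_grid <- us[which.min(abs(dmass - 0.5))]
  expect_lt(abs(u_star - u_grid), 1e-4)
  expect_error(find_melting_factor(build_preset("custom", overrides = list(
    sequence = "ATATATATAT", pi = c(H = 1),
    flux = data.frame(i = character(0), j = character(0),
                      f = numeric(0))))), "no dissociated state")
})

test_that("generator/classifier round trip is >= 99% per state", {
  # emitted frames of each state via single-state presets (1000 frames,
  # jitter and fraying active)
  cases <- list(
    c("ATATATATAT", "H"), c("ATATATATAT", "5S2"), c("ATATATATAT", "3S2"),
    c("ATATATATAT", "5S4"), c("ATATATATAT", "3S4"), c("ATATATATAT", "D"),
    c("ATATGCATAT", "F4"), c("ATATGCATAT", "H"), c("GATATATATC", "5S2"))
  for (cs in cases) {
    p <- pinned_preset(cs[1L], cs[2L])
    tr <- simulate_equilibrium(p, 1000, dt_save = 0.5, seed = 17)
    cls <- classify_trajectory(tr, p$sequence)
    expect_gte(mean(cls == cs[2L]), 0.99)
  }
})

test_that("XYZ trajectory files round-trip", {
  p <- build_preset("GC-core")
  tr <- simulate_equilibrium(p, 25, dt_save = 0.5, seed = 1)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, path)
  back <- read_xyz_trajectory(path)
  expect_equal(back$frames, tr$frames, tolerance = 1e-5)
  expect_identical(back$truth_labels, tr$truth_labels)
  expect_equal(back$dt_save, tr$dt_save)
})
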