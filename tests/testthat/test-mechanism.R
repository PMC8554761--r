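# Register classification and transition path theory.

test_that("templates of every preset classify to their own label", {
  for (nm in c("AT-all", "GC-end", "GC-core", "GC-mix")) {
    p <- build_preset(nm)
    for (s in p$states) {
      tpls <- if (s == "F4") p$templates[[s]] else list(p$templates[[s]])
      for (tpl in tpls) {
        d <- interbase_distance_matrix(tpl)
        expect_identical(classify_macrostate(d, p$sequence), s,
                         label = paste(nm, s))
      }
    }
  }
})

test_that("sign convention: strand-2 translation toward +x by two bases is 5S2", {
  p <- build_preset("AT-all")
  tpl <- p$templates$H
  tpl[2, , 1] <- tpl[2, , 1] + 2 * 0.34
  lab <- classify_macrostate(interbase_distance_matrix(tpl), p$sequence)
  expect_identical(lab, "5S2")
  tpl[2, , 1] <- tpl[2, , 1] - 4 * 0.34
  lab2 <- classify_macrostate(interbase_distance_matrix(tpl), p$sequence)
  expect_identical(lab2, "3S2")
})

test_that("all-distant frames are dissociated; half-broken frames are not H or D", {
  p <- build_preset("AT-all")
  d <- matrix(5, 10, 10)
  expect_identical(classify_macrostate(d, p$sequence), "D")
  # central native pairs beyond 2 nm but a register still engaged (a
  # six-base shift): not D; lands on the sentinel since 6-shifts are
  # outside the macrostate taxonomy
  d2 <- interbase_distance_matrix(duplexmsm:::.ladder_template(6))
  expect_gt(min(d2[5, 6], d2[6, 5]), 2.0)
  lab6 <- classify_macrostate(d2, p$sequence)
  expect_false(lab6 == "D")
  expect_identical(lab6, "unassigned")
  # nothing engaged but central pairs inside the dissociation cutoff
  d3 <- matrix(1.9, 10, 10)
  expect_identical(classify_macrostate(d3, p$sequence), "unassigned")
  expect_error(classify_macrostate(matrix(NA_real_, 10, 10), p$sequence),
               "malformed")
})

test_that("F4 requires the central core and one fully open terminal run", {
  p <- build_preset("GC-core")
  d <- interbase_distance_matrix(p$templates$F4[[1]])
  prof <- register_contact_profile(d, p$sequence)
  expect_identical(classify_macrostate(d, p$sequence), "F4")
  # same geometry on a sequence without a central G:C core stays H-ish
  at <- duplex_sequence("ATATATATAT")
  expect_false(classify_macrostate(d, at) == "F4")
  # both runs open is not F4 (that is far along dissociation)
  tpl2 <- p$templates$F4[[1]]
  tpl2[1, 1:4, 2] <- tpl2[1, 1:4, 2] + 2
  tpl2[2, 7:10, 2] <- tpl2[2, 7:10, 2] - 2
  expect_false(classify_macrostate(interbase_distance_matrix(tpl2),
                                   p$sequence) == "F4")
})

test_that("committor boundary conditions and symmetric midpoint are exact", {
  P <- matrix(c(0.8, 0.2, 0.0,
                0.1, 0.8, 0.1,
                0.0, 0.2, 0.8), 3, 3, byrow = TRUE)
  q <- committor(P, source = 1, sink = 3)
  expect_identical(q[1], 0)
  expect_identical(q[3], 1)
  expect_equal(q[2], 0.5)
  expect_error(committor(P, 1, 1), "disjoint")
})

test_that("committor matches brute-force trajectory sampling on a random chain", {
  pr <- with_seed(51, oracle_random_reversible_P(5))
  q <- committor(pr$P, source = 1, sink = 5)
  mc <- with_seed(52, oracle_committor_mc(pr$P, 1, 5, n_runs = 4000))
  for (i in 2:4)
    expect_lt(abs(q[i] - mc$q[i]), 3 * mc$se[i] + 1e-9)
})

test_that("pathway fractions: linear chain, empty via, and flux conservation", {
  P <- matrix(c(0.9, 0.1, 0.0,
                0.05, 0.9, 0.05,
                0.0, 0.1, 0.9), 3, 3, byrow = TRUE)
  expect_equal(pathway_fraction(P, 1, 3, via = 2), 1.0)
  expect_equal(pathway_fraction(P, 1, 3, via = integer(0)), 0.0)
  fl <- reactive_flux(P, 1, 3)
  out_src <- sum(fl$net_flux[1, ])
  into_snk <- sum(fl$net_flux[, 3])
  expect_lt(abs(out_src - into_snk), 1e-10)
  expect_error(pathway_fraction(P, 1, 3, via = 1), "disjoint")
})

test_that("pathway fraction matches reactive-trajectory counting on a parallel network", {
  # two parallel intermediates with asymmetric rates: A=1, I1=2, I2=3, B=4
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.30   # A - I1 exchange flux
  W[1, 3] <- W[3, 1] <- 0.06   # A - I2
  W[2, 4] <- W[4, 2] <- 0.10   # I1 - B
  W[3, 4] <- W[4, 3] <- 0.12   # I2 - B
  W[1, 4] <- W[4, 1] <- 0.04   # direct channel
  diag(W) <- 1.2
  P <- W / rowSums(W)
  pi <- rowSums(W) / sum(W)
  frac <- pathway_fraction(P, 1, 4, via = 2, pi = pi)
  traj <- with_seed(53, oracle_sample_dtmc(P, 3e6, 1L))
  segs <- oracle_reactive_segments(traj, 1, 4)
  expect_gt(length(segs), 1e4)
  hits <- vapply(segs, function(s) any(s == 2L), logical(1))
  emp <- mean(hits)
  se <- sd(hits) / sqrt(length(hits))
  expect_lt(abs(frac - emp), max(3 * se, 0.02 * emp))
})

test_that("MFPT: closed form, degenerate source, and simulation agreement", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_equal(mfpt(P, 1, 2, lag = 1.2), 12, tolerance = 1e-10)
  expect_equal(mfpt(P, 1, 1, lag = 1.2), 0)
  pr <- with_seed(54, oracle_random_reversible_P(6))
  m <- mfpt(pr$P, 2, 5, lag = 1, pi = pr$pi)
  steps <- with_seed(55, {
    vapply(1:4000, function(r) {
      s <- 2L; n <- 0L
      cum <- t(apply(pr$P, 1, cumsum))
      while (s != 5L) { s <- findInterval(runif(1), cum[s, ]) + 1L
                        n <- n + 1L }
      n
    }, numeric(1))
  })
  expect_lt(abs(m - mean(steps)), 3 * sd(steps) / sqrt(length(steps)))
})

test_that("MFPTs are near-symmetric at melting conditions on the fitted model", {
  gm <- gcmix_run()
  r <- gm$mechanism
  expect_false(is.null(r))
  ratio <- r$mfpt_DH_ns / r$mfpt_HD_ns
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("ground-truth chains also have near-symmetric melting MFPTs", {
  for (nm in c("AT-all", "GC-end", "GC-core", "GC-mix")) {
    Q <- build_preset(nm)$rate_matrix
    a <- oracle_mfpt_ctmc(Q, "D", "H")
    b <- oracle_mfpt_ctmc(Q, "H", "D")
    expect_gt(a / b, 1 / 1.5)
    expect_lt(a / b, 1.5)
  }
})
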