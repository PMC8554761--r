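# Independent oracles used to freeze expected values. These deliberately
# re-derive quantities by brute force (linear solves on ground-truth
# chains, trajectory counting, direct table summation) and never call the
# code paths they check.

# Stationary law of a rate matrix by dense null-space solve.
oracle_stationary <- function(Q) {
  n <- nrow(Q)
  pi <- qr.solve(rbind(t(Q), rep(1, n)), c(rep(0, n), 1))
  setNames(pi / sum(pi), rownames(Q))
}

# Mean first-passage time (continuous time) from `from` to set `to` on a
# rate matrix, by linear solve.
oracle_mfpt_ctmc <- function(Q, from, to) {
  states <- rownames(Q)
  keep <- setdiff(states, to)
  A <- -Q[keep, keep, drop = FALSE]
  m <- solve(A, rep(1, length(keep)))
  m[match(from, keep)]
}

# Mean first-passage steps (discrete) from `from` to set `to` on a
# row-stochastic matrix.
oracle_mfpt_dtmc <- function(P, from, to) {
  n <- nrow(P)
  keep <- setdiff(seq_len(n), to)
  A <- diag(length(keep)) - P[keep, keep, drop = FALSE]
  m <- solve(A, rep(1, length(keep)))
  m[match(from, keep)]
}

# Simulate a discrete-time Markov chain (integer states).
oracle_sample_dtmc <- function(P, n_steps, start) {
  n <- nrow(P)
  cum <- t(apply(P, 1L, cumsum))
  s <- integer(n_steps)
  s[1L] <- start
  u <- runif(n_steps)
  for (t in 2:n_steps)
    s[t] <- findInterval(u[t], cum[s[t - 1L], ]) + 1L
  s
}

# Reactive source->sink segments of a state sequence: each segment runs
# from the last visit to A before the first subsequent entry into B.
oracle_reactive_segments <- function(s, A, B) {
  segs <- list()
  last_a <- NA_integer_
  inside <- FALSE
  for (t in seq_along(s)) {
    if (s[t] %in% A) {
      last_a <- t
      inside <- TRUE
    } else if (s[t] %in% B) {
      if (inside && !is.na(last_a)) {
        segs[[length(segs) + 1L]] <- s[last_a:t]
        inside <- FALSE
      }
    }
  }
  segs
}

# Committor by direct trajectory sampling: fraction of runs from each
# state hitting B before A.
oracle_committor_mc <- function(P, A, B, n_runs = 2000L, max_steps = 1e5L) {
  n <- nrow(P)
  cum <- t(apply(P, 1L, cumsum))
  q <- numeric(n); se <- numeric(n)
  for (i in seq_len(n)) {
    if (i %in% A) { q[i] <- 0; next }
    if (i %in% B) { q[i] <- 1; next }
    hit <- logical(n_runs)
    for (r in seq_len(n_runs)) {
      s <- i
      for (step in seq_len(max_steps)) {
        s <- findInterval(runif(1L), cum[s, ]) + 1L
        if (s %in% A) { hit[r] <- FALSE; break }
        if (s %in% B) { hit[r] <- TRUE; break }
      }
    }
    q[i] <- mean(hit)
    se[i] <- sd(hit) / sqrt(n_runs)
  }
  list(q = q, se = se)
}

# Random reversible transition matrix from random symmetric fluxes.
oracle_random_reversible_P <- function(n, self_weight = 2) {
  W <- matrix(runif(n * n, 0.05, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- diag(W) * self_weight
  P <- W / rowSums(W)
  pi <- rowSums(W) / sum(W)
  list(P = P, pi = pi)
}

# Independent NN free-energy summation: reads the parameter TSVs itself
# and walks the duplex structure explicitly.
oracle_nn_dg <- function(bases, label, T) {
  stacks_path <- system.file("extdata", "nn_stacks_santalucia1998.tsv",
                             package = "duplexmsm")
  dang_path <- system.file("extdata", "nn_dangling_dg37_synthetic.tsv",
                           package = "duplexmsm")
  st <- read.table(stacks_path, header = TRUE, sep = "\t", comment.char = "#")
  dg <- read.table(dang_path, header = TRUE, sep = "\t", comment.char = "#")
  b <- strsplit(bases, "")[[1L]]
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  if (label == "D") return(0)
  k <- c(H = 0, `5S2` = 2, `3S2` = -2, `5S4` = 4, `3S4` = -4, F4 = 0)[[label]]
  # pairing mask: strand-1 position i pairs strand-2 base 11 - i + k
  paired <- vapply(1:10, function(i) {
    j <- 11 - i + k
    j >= 1 && j <= 10 && comp[[b[i]]] == b[j]
  }, logical(1))
  if (label == "F4") {
    stretch <- 1:6
  } else {
    r <- rle(paired); e <- cumsum(r$lengths); s0 <- e - r$lengths + 1
    runs <- which(r$values)
    w <- runs[which.max(r$lengths[runs])]
    stretch <- s0[w]:e[w]
  }
  val <- function(key) unlist(st[st$key == key, c("dH", "dS")])
  dH <- 0; dS <- 0
  for (m in stretch[-length(stretch)]) {
    v <- val(paste0(b[m], b[m + 1]))
    dH <- dH + v[[1]]; dS <- dS + v[[2]]
  }
  for (pos in c(stretch[1], stretch[length(stretch)])) {
    v <- if (b[pos] %in% c("G", "C")) val("init_GC") else val("init_AT")
    dH <- dH + v[[1]]; dS <- dS + v[[2]]
  }
  v <- val("symmetry"); dH <- dH + v[[1]]; dS <- dS + v[[2]]
  out <- dH - T * dS / 1000
  # dangling ends: first unpaired base adjacent to each duplex end,
  # longer overhang wins when both strands overhang
  i <- stretch[1]; j <- stretch[length(stretch)]
  dang <- function(side, x, y) {
    hit <- dg$side == side & dg$dangle_base == x & dg$pair_base == y
    dg$dG37[hit][1]
  }
  p <- 11 - i + k
  t1 <- i - 1; t2 <- 10 - p
  if (t1 >= t2 && t1 > 0) out <- out + dang("5p", b[i - 1], b[i])
  else if (t2 > 0) out <- out + dang("3p", b[p + 1], b[p])
  p2 <- 11 - j + k
  t1 <- 10 - j; t2 <- p2 - 1
  if (t1 >= t2 && t1 > 0) out <- out + dang("3p", b[j + 1], b[j])
  else if (t2 > 0) out <- out + dang("5p", b[p2 - 1], b[p2])
  out
}

# Mass-action oracle for the two-state algebra: integrate
# d[D]/dt = k_a [S]^2 - k_d [D] with [S] = c_tot - 2 [D], report the
# equilibrium duplex fraction and the linearized relaxation rate.
oracle_mass_action <- function(k_d, k_a, c_tot) {
  # equilibrium from the quadratic k_a (c - 2D)^2 = k_d D
  a <- 4 * k_a; bq <- -(4 * k_a * c_tot + k_d); cq <- k_a * c_tot^2
  D_eq <- (-bq - sqrt(bq^2 - 4 * a * cq)) / (2 * a)
  S_eq <- c_tot - 2 * D_eq
  theta_eq <- 2 * D_eq / c_tot
  # linearized rate: d(dD)/dt = -(k_d + 4 k_a S_eq) dD
  lambda <- k_d + 4 * k_a * S_eq
  list(theta = theta_eq, lambda = lambda, S_eq = S_eq)
}
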