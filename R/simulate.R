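# Synthetic trajectory generation: continuous-time Markov jump dynamics
# over the preset's macrostates, dressed with coordinate templates,
# mean-reverting jitter, and fast terminal-pair fraying.

# Evaluate `code` under a fresh L'Ecuyer-CMRG stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
.with_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based stream splitting: the k-th substream of a master seed.
.stream_seed <- function(master_seed, k) {
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(master_seed))
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(k)) s <- parallel::nextRNGStream(s)
  s
}

#' Simulate the macrostate jump process of a preset
#'
#' Direct (Gillespie) stochastic simulation of the continuous-time Markov
#' chain defined by the preset's rate matrix. This is the exact dynamics
#' the dressed coordinate trajectories are built on, and is exported so
#' that dwell-time and first-passage statistics can be checked against
#' the generator analytically.
#'
#' @param Q rate matrix (1/ns), rows summing to zero.
#' @param t_total total simulated time (ns).
#' @param start start state name, or a named probability vector to sample
#'   the start from.
#' @return A list with `times` (jump entry times, ns, starting at 0) and
#'   `states` (state name per dwell).
#' @export
simulate_jump_process <- function(Q, t_total, start) {
  states <- rownames(Q)
  exit <- -diag(Q)
  jump_prob <- Q
  diag(jump_prob) <- 0
  jump_prob <- jump_prob / ifelse(exit > 0, exit, 1)
  cur <- if (is.character(start)) match(start, states)
         else sample.int(length(states), 1L, prob = start)
  if (is.na(cur)) stop("unknown start state")
  cap <- 256L
  times <- numeric(cap); labs <- integer(cap)
  t <- 0; n <- 0L
  while (t < t_total) {
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(times) <- cap; length(labs) <- cap
    }
    times[n] <- t; labs[n] <- cur
    if (exit[cur] <= 0) break   # absorbing
    t <- t + rexp(1L, exit[cur])
    cur <- sample.int(length(states), 1L, prob = jump_prob[cur, ])
  }
  list(times = times[seq_len(n)], states = states[labs[seq_len(n)]])
}

# Frame labels on the save grid from a jump process.
.frames_from_jumps <- function(jumps, n_frames, dt_save) {
  tf <- (seq_len(n_frames) - 1L) * dt_save
  jumps$states[findInterval(tf, jumps$times)]
}

# Column index of coordinate (strand s, base b, axis c) in the flattened
# n x 60 coordinate matrix (strand fastest, then base, then axis), which
# reshapes to [n][2][10][3] without copying semantics changing.
.coord_col <- function(s, b, c) s + 2L * (b - 1L) + 20L * (c - 1L)

# Build dressed coordinates (n x 60) for a label sequence.
.dress_frames <- function(preset, labels, dt_save) {
  n <- length(labels)
  g <- .GEOM
  states <- preset$states
  # flat templates; F4 handled per dwell below
  flat <- matrix(0, length(states), 60L,
                 dimnames = list(states, NULL))
  for (s in states) {
    tpl <- preset$templates[[s]]
    flat[s, ] <- if (s == "F4") as.vector(tpl[[1L]]) else as.vector(tpl)
  }
  lab_idx <- match(labels, states)
  coords <- flat[lab_idx, , drop = FALSE]

  # randomization: dissociated strands get an independent random
  # orientation and separation direction every frame (free tumbling is
  # faster than the save cadence, so D carries no artificial slow
  # internal coordinate); F4 picks its open run per dwell
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  if ("D" %in% states) {
    idx_d <- which(labels == "D")
    if (length(idx_d)) {
      s2cols <- .coord_col(2L, 1:10, rep(1:3, each = 10L))
      d_tpl <- matrix(flat["D", s2cols], 10L, 3L)
      B <- sweep(d_tpl, 2L, colMeans(d_tpl))      # centered strand 2
      cent1 <- colMeans(matrix(
        flat["D", .coord_col(1L, 1:10, rep(1:3, each = 10L))], 10L, 3L))
      nd <- length(idx_d)
      q <- .random_quaternions(nd)                 # nd x 4 (x, y, z, w)
      dir <- .random_directions(nd)                # nd x 3
      origin <- sweep(g$d_sep * dir, 2L, cent1, `+`)
      for (bb in 1:10) {
        v <- B[bb, ]
        # v' = v + w*t + qv x t with t = 2 qv x v, vectorized over frames
        t1 <- 2 * (q[, 2L] * v[3L] - q[, 3L] * v[2L])
        t2 <- 2 * (q[, 3L] * v[1L] - q[, 1L] * v[3L])
        t3 <- 2 * (q[, 1L] * v[2L] - q[, 2L] * v[1L])
        vx <- v[1L] + q[, 4L] * t1 + q[, 2L] * t3 - q[, 3L] * t2
        vy <- v[2L] + q[, 4L] * t2 + q[, 3L] * t1 - q[, 1L] * t3
        vz <- v[3L] + q[, 4L] * t3 + q[, 1L] * t2 - q[, 2L] * t1
        coords[idx_d, .coord_col(2L, bb, 1L)] <- origin[, 1L] + vx
        coords[idx_d, .coord_col(2L, bb, 2L)] <- origin[, 2L] + vy
        coords[idx_d, .coord_col(2L, bb, 3L)] <- origin[, 3L] + vz
      }
    }
  }
  if ("F4" %in% states) {
    alt <- as.vector(preset$templates$F4[[2L]])
    for (r in which(runs$values == "F4")) {
      if (runif(1) < 0.5)
        coords[starts[r]:ends[r], ] <-
          matrix(alt, ends[r] - starts[r] + 1L, 60L, byrow = TRUE)
    }
  }

  # fast terminal-pair fraying: two free-running telegraph processes,
  # displacing the terminal native pairs only while the chain is in H
  if ("H" %in% states && preset$fray_toggle_rate > 0) {
    in_h <- labels == "H"
    if (any(in_h)) {
      fray_cols <- list(
        list(up = .coord_col(1L, 1L, 2L), dn = .coord_col(2L, 10L, 2L)),
        list(up = .coord_col(1L, 10L, 2L), dn = .coord_col(2L, 1L, 2L)))
      tf <- (seq_len(n) - 1L) * dt_save
      t_total <- n * dt_save
      for (p in 1:2) {
        toggles <- .telegraph_times(preset$fray_toggle_rate, t_total)
        frayed <- (findInterval(tf, toggles) %% 2L) == 1L
        on <- frayed & in_h
        coords[on, fray_cols[[p]]$up] <-
          coords[on, fray_cols[[p]]$up] + g$fray_disp
        coords[on, fray_cols[[p]]$dn] <-
          coords[on, fray_cols[[p]]$dn] - g$fray_disp
      }
    }
  }

  # mean-reverting jitter: stationary AR(1) per coordinate
  a <- exp(-dt_save / preset$jitter_corr_time)
  innov_sd <- preset$jitter_sigma * sqrt(1 - a^2)
  for (cc in seq_len(60L)) {
    z <- rnorm(n, sd = innov_sd)
    z[1L] <- rnorm(1L, sd = preset$jitter_sigma)
    coords[, cc] <- coords[, cc] +
      as.numeric(stats::filter(z, a, method = "recursive"))
  }
  coords
}

# Toggle times of a symmetric telegraph process with per-direction rate r.
.telegraph_times <- function(r, t_total) {
  if (r <= 0) return(numeric(0))
  m <- max(16L, ceiling(r * t_total * 1.5))
  tt <- cumsum(rexp(m, r))
  while (tt[length(tt)] < t_total)
    tt <- c(tt, tt[length(tt)] + cumsum(rexp(m, r)))
  tt
}

#' Simulate an equilibrium trajectory from a kinetic preset
#'
#' Samples the preset's continuous-time Markov jump process (initial state
#' drawn from the stationary law), discretizes it on the save grid, and
#' dresses every frame with the state's coordinate template plus
#' mean-reverting jitter. Fast terminal-pair fraying fluctuations toggle
#' the terminal base positions while the chain is hybridized without
#' changing the macrostate label; in the dissociated state the strands are
#' given a random relative orientation per dwell. Identical seeds give
#' bit-identical output.
#'
#' @param preset a [kinetic_preset][build_preset].
#' @param n_frames number of saved frames (>= 1).
#' @param dt_save save interval in ns (> 0); default 0.1 ns mirrors a
#'   100 ps save cadence.
#' @param seed integer master seed.
#' @return An object of class `duplex_trajectory` with fields `frames`
#'   (`[n_frames][2][10][3]` nm), `dt_save`, `seed` and `truth_labels`.
#' @export
simulate_equilibrium <- function(preset, n_frames, dt_save = 0.1, seed = 1L) {
  stopifnot(n_frames >= 1, dt_save > 0)
  if (length(preset$states) == 0L) stop("empty state set")
  .with_rng(seed, {
    jumps <- simulate_jump_process(preset$rate_matrix,
                                   t_total = n_frames * dt_save,
                                   start = preset$stationary)
    labels <- .frames_from_jumps(jumps, n_frames, dt_save)
    coords <- .dress_frames(preset, labels, dt_save)
    new_trajectory(coords, dt_save, seed, labels)
  })
}

new_trajectory <- function(coords, dt_save, seed, labels) {
  dim(coords) <- c(nrow(coords), 2L, 10L, 3L)
  structure(list(frames = coords, dt_save = dt_save, seed = seed,
                 truth_labels = labels),
            class = "duplex_trajectory")
}

#' @export
print.duplex_trajectory <- function(x, ...) {
  cat("<duplex_trajectory> ", dim(x$frames)[1L], " frames, dt_save = ",
      x$dt_save, " ns, seed = ", x$seed, "\n", sep = "")
  if (!is.null(x$truth_labels)) {
    tab <- table(x$truth_labels)
    cat("  truth labels:", paste(sprintf("%s=%d", names(tab), tab),
                                 collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a relaxation ensemble (temperature-jump analogue)
#'
#' Generates `n_traj` independent trajectories, each started in the fully
#' hybridized state `H`, under the preset's kinetics tilted by temperature
#' factor `u` (rates toward less-bound states sped up by `exp(+u)` per
#' unit of the unbinding coordinate and reverse rates slowed by `exp(-u)`,
#' preserving detailed balance at the tilted stationary law). Trajectory
#' randomness uses independent counter-derived RNG substreams of the
#' master seed.
#'
#' @param preset a [kinetic_preset][build_preset].
#' @param u temperature factor (>= 0 for a heating jump; 0 = melting
#'   conditions).
#' @param n_traj number of trajectories (>= 1).
#' @param t_max trajectory length in ns (> 0).
#' @param seed integer master seed.
#' @param dt_save save interval in ns.
#' @return An object of class `relaxation_ensemble`: list of
#'   `duplex_trajectory`, plus `start_label`, `temperature_factor`,
#'   `t_max`.
#' @export
simulate_relaxation <- function(preset, u, n_traj, t_max, seed = 1L,
                                dt_save = 0.1) {
  stopifnot(n_traj >= 1)
  if (t_max <= 0) stop("t_max must be positive")
  if (!"H" %in% preset$states) stop("preset has no hybridized state H")
  mod <- temperature_modified(preset, u)
  p_u <- preset
  p_u$rate_matrix <- mod$Q
  p_u$stationary <- mod$pi
  n_frames <- max(1L, floor(t_max / dt_save))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  s <- .stream_seed(seed, 0L)
  trajs <- vector("list", n_traj)
  for (k in seq_len(n_traj)) {
    assign(".Random.seed", s, envir = globalenv())
    jumps <- simulate_jump_process(p_u$rate_matrix, t_total = t_max,
                                   start = "H")
    labels <- .frames_from_jumps(jumps, n_frames, dt_save)
    coords <- .dress_frames(p_u, labels, dt_save)
    trajs[[k]] <- new_trajectory(coords, dt_save, seed, labels)
    s <- parallel::nextRNGStream(s)   # counter-based: advance the base stream
  }
  structure(list(trajectories = trajs, start_label = "H",
                 temperature_factor = u, t_max = t_max, seed = seed),
            class = "relaxation_ensemble")
}

#' @export
print.relaxation_ensemble <- function(x, ...) {
  cat("<relaxation_ensemble> ", length(x$trajectories),
      " trajectories from H, u = ", x$temperature_factor,
      ", t_max = ", x$t_max, " ns\n", sep = "")
  invisible(x)
}
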