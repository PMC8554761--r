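# Register-based configuration labeling and transition path theory on the
# macrostate model.

#' Register contact profile of a frame
#'
#' Counts intact Watson-Crick contacts for every register offset
#' `k = -8..+8`: strand-1 base `i` is paired with strand-2 base
#' `j = 11 - i + k` when that partner exists, the bases are
#' complementary, and the symmetrized distance is below `bound_cutoff`.
#' Each offset additionally gets a contact-quality score, the sum of
#' `(seating_scale - d)+` over its pairable positions: with a helical
#' rise much smaller than the contact cutoff, neighboring registers also
#' fall inside the cutoff (a two-base-off contact sits at ~0.91 nm for
#' the template geometry), so raw counts alone do not separate adjacent
#' shifts, whereas the quality score prefers the register whose contacts
#' are actually seated. The seating scale sits between the seated
#' contact distance (0.6 nm) and the breakage cutoff (1.3 nm) so that
#' off-register contacts score near zero. Positive offsets are 5' shifts, negative 3'
#' shifts (matching the geometric construction of the shifted-state
#' templates). Terminal fraying flags come from the raw per-pair
#' distances (the two terminal pairs are strand-swap images of one
#' another, so the symmetrized matrix cannot tell which one is open).
#'
#' @param d 10 x 10 interbase distance matrix (nm), rows strand 1.
#' @param seq a [duplex_sequence] (needed for complementarity).
#' @param bound_cutoff contact distance cutoff (nm).
#' @param seating_scale distance scale (nm) of the register-quality
#'   score.
#' @return List with `offsets` (-8..8), `counts`, `quality`, `possible`
#'   (WC-pairable positions per offset), `frayed` (length-2 logical,
#'   native terminal pairs 1 and 10 broken), `bound_cutoff`.
#' @export
register_contact_profile <- function(d, seq, bound_cutoff = 1.3,
                                     seating_scale = 1.0) {
  stopifnot(is.matrix(d), nrow(d) == 10L, ncol(d) == 10L)
  sym <- (d + t(d)) / 2
  nearest <- max.col(-sym, ties.method = "first")
  offsets <- -8:8
  counts <- integer(length(offsets))
  quality <- numeric(length(offsets))
  possible <- integer(length(offsets))
  for (m in seq_along(offsets)) {
    k <- offsets[m]
    ok <- register_pairing(seq, k)
    possible[m] <- sum(ok)
    if (possible[m] == 0L) next
    i <- which(ok)
    j <- 11L - i + k
    dd <- sym[cbind(i, j)]
    counts[m] <- sum(dd < bound_cutoff)
    # quality restricted to seated contacts whose partner is the nearest
    # strand-2 base; off-register positions then contribute ~nothing
    quality[m] <- sum(pmax(seating_scale - dd, 0) * (nearest[i] == j))
  }
  frayed <- c(d[1L, 10L] >= bound_cutoff, d[10L, 1L] >= bound_cutoff)
  list(offsets = offsets, counts = counts, quality = quality,
       possible = possible, frayed = frayed, bound_cutoff = bound_cutoff)
}

# Predicted symmetrized distance matrices of the ladder geometry per
# register offset, cached (geometry only, sequence independent).
.register_pred_env <- new.env(parent = emptyenv())
.register_template_sym <- function(k) {
  key <- as.character(k)
  if (!exists(key, envir = .register_pred_env)) {
    tpl <- .ladder_template(k)
    dd <- interbase_distance_matrix(tpl)
    assign(key, (dd + t(dd)) / 2, envir = .register_pred_env)
  }
  get(key, envir = .register_pred_env)
}

# Mean squared deviation from the register-k prediction over its
# informative entries (predicted distance below the non-interacting
# zone); large-distance entries carry no register information.
.register_template_sse <- function(sym, k, horizon = 2.0) {
  pred <- .register_template_sym(k)
  mask <- pred < horizon
  mean((sym[mask] - pred[mask])^2)
}

#' Classify a configuration into a macrostate label
#'
#' Rule set, applied in order: the frame is `D` when both central native
#' pairs (strand-1 positions 5 and 6) exceed `dissoc_cutoff` and no
#' register offset holds two or more intact contacts. Otherwise the
#' register is resolved by matching the symmetrized distance matrix
#' against the ladder-geometry prediction of each admissible offset
#' (least mean-square deviation over the informative entries; see
#' [register_contact_profile()] for the per-offset contact counts), and
#' the winning offset sets the label: 0 is `H`,
#' `+|k|` is `5S|k|`, `-|k|` is `3S|k|` (ties prefer offset 0, then the
#' smaller |k|, then the 5' side). A register-0 frame is `F4` instead of
#' `H` when the sequence has a central G:C core, both central contacts
#' are intact, and one terminal run of four native A:T contacts is
#' entirely broken. Frames matching no rule get the sentinel label
#' `"unassigned"`.
#'
#' @param d 10 x 10 interbase distance matrix (nm).
#' @param seq a [duplex_sequence].
#' @param bound_cutoff intact-contact cutoff (nm), the complete-breakage
#'   distance of a Watson-Crick pair.
#' @param dissoc_cutoff separation (nm) beyond which strands are
#'   non-interacting.
#' @return A macrostate label string.
#' @export
classify_macrostate <- function(d, seq, bound_cutoff = 1.3,
                                dissoc_cutoff = 2.0) {
  stopifnot(bound_cutoff > 0, dissoc_cutoff > 0,
            bound_cutoff < dissoc_cutoff)
  if (!all(is.finite(d))) stop("malformed distance matrix")
  prof <- register_contact_profile(d, seq, bound_cutoff)
  # raw distances for the physical native pairs: the central and terminal
  # pairs come in strand-swap image pairs that symmetrization would mix
  central_far <- d[5L, 6L] > dissoc_cutoff && d[6L, 5L] > dissoc_cutoff
  if (central_far && all(prof$counts < 2L)) return("D")
  if (all(prof$counts == 0L)) return("unassigned")
  # resolve the register against the full predicted distance matrix of
  # each admissible offset: the whole informative block of the matrix
  # (not just the contact diagonal) votes, which keeps the decision
  # stable under coordinated jitter excursions
  sym <- (d + t(d)) / 2
  adm <- prof$offsets[prof$possible > 0L]
  sse <- vapply(adm, function(kk) .register_template_sse(sym, kk),
                numeric(1))
  cand <- adm[sse <= min(sse) + 1e-12]
  # tie-break: offset 0, then smaller |k|, then positive (5') side
  cand <- cand[order(abs(cand), -sign(cand))]
  k <- cand[1L]
  if (k == 0L) {
    if (has_gc_core(seq) &&
        d[5L, 6L] < bound_cutoff && d[6L, 5L] < bound_cutoff) {
      run1 <- 1:4; run2 <- 7:10
      broken <- function(run)
        all(d[cbind(run, 11L - run)] >= bound_cutoff)
      if (xor(broken(run1), broken(run2))) return("F4")
    }
    return("H")
  }
  label <- paste0(if (k > 0) "5S" else "3S", abs(k))
  if (label %in% MACROSTATE_LABELS) label else "unassigned"
}

#' Classify every frame of a trajectory
#'
#' @param trajectory a `duplex_trajectory`.
#' @param seq a [duplex_sequence].
#' @param bound_cutoff,dissoc_cutoff see [classify_macrostate()].
#' @param frames optional integer vector of frame indices to classify.
#' @return Character vector of labels.
#' @export
classify_trajectory <- function(trajectory, seq, bound_cutoff = 1.3,
                                dissoc_cutoff = 2.0, frames = NULL) {
  fr <- trajectory$frames
  idx <- if (is.null(frames)) seq_len(dim(fr)[1L]) else frames
  vapply(idx, function(t)
    classify_macrostate(interbase_distance_matrix(fr[t, , , , drop = TRUE]),
                        seq, bound_cutoff, dissoc_cutoff),
    character(1))
}

#' Forward committor of a macrostate transition matrix
#'
#' Probability of reaching the sink set before the source set, from each
#' state, under the discrete chain `P`. Boundary conditions are exact:
#' 0 on the source, 1 on the sink.
#'
#' @param P row-stochastic transition matrix (optionally with
#'   `dimnames`).
#' @param source,sink disjoint nonempty state sets (indices or names).
#' @return Numeric committor vector `q+` with one entry per state.
#' @export
committor <- function(P, source, sink) {
  n <- nrow(P)
  src <- .state_idx(P, source); snk <- .state_idx(P, sink)
  if (length(intersect(src, snk)))
    stop("source and sink sets must be disjoint")
  if (!length(src) || !length(snk)) stop("source and sink must be nonempty")
  q <- numeric(n)
  q[snk] <- 1
  inter <- setdiff(seq_len(n), c(src, snk))
  if (length(inter)) {
    A <- diag(length(inter)) - P[inter, inter, drop = FALSE]
    b <- P[inter, snk, drop = FALSE] %*% rep(1, length(snk))
    sol <- tryCatch(solve(A, b), error = function(e) {
      warning("committor system singular (unreachable states); ",
              "using least-squares solution")
      qr.solve(A, b)
    })
    q[inter] <- pmin(pmax(as.vector(sol), 0), 1)
  }
  names(q) <- rownames(P)
  q
}

.state_idx <- function(P, states) {
  if (is.character(states)) {
    idx <- match(states, rownames(P))
    if (anyNA(idx)) stop("unknown state name(s): ",
                         paste(states[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(states)
}

# Stationary law of a row-stochastic matrix (leading left eigenvector).
.stationary_of_P <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v <- abs(v)
  v / sum(v)
}

#' Transition path theory reactive flux decomposition
#'
#' Computes forward/backward committors, the gross and net reactive flux
#' matrices, and the total source-to-sink flux (per lag step) for a
#' reversible macrostate chain at stationarity.
#'
#' @param P row-stochastic transition matrix.
#' @param source,sink disjoint state sets.
#' @param pi stationary distribution (computed from `P` when omitted).
#' @return List with `q_plus`, `q_minus`, `flux` (gross), `net_flux`,
#'   `total_flux`.
#' @export
reactive_flux <- function(P, source, sink, pi = NULL) {
  src <- .state_idx(P, source); snk <- .state_idx(P, sink)
  if (is.null(pi)) pi <- .stationary_of_P(P)
  qp <- committor(P, src, snk)
  qm <- 1 - qp   # backward committor of a reversible chain
  n <- nrow(P)
  F <- outer(pi * qm, qp) * P
  diag(F) <- 0
  F[, src] <- 0   # reactive flux never flows back into the source
  net <- pmax(F - t(F), 0)
  total <- sum(F[src, , drop = FALSE])
  list(q_plus = qp, q_minus = qm, flux = F, net_flux = net,
       total_flux = total)
}

#' Fraction of reactive flux passing through a state set
#'
#' Fraction of source-to-sink reactive trajectories (equivalently, of
#' reactive probability flux) that visit at least one state in `via`.
#' Computed exactly from committor theory: the flux avoiding `via` is
#' the source-to-sink flux of paths for which `via` is taboo, obtained
#' from the committors of the chain with `via` absorbed into the
#' boundary, and the fraction is `1 - F_avoid / F_total`.
#'
#' @param model a `macrostate_model`, or a row-stochastic matrix.
#' @param source,sink disjoint state sets.
#' @param via state set disjoint from both; empty set gives 0.
#' @param pi optional stationary distribution.
#' @return Scalar fraction in `[0, 1]`.
#' @export
pathway_fraction <- function(model, source, sink, via, pi = NULL) {
  P <- if (inherits(model, "macrostate_model")) model$P else model
  if (inherits(model, "macrostate_model") && is.null(pi))
    pi <- model$pi_macro
  if (is.null(pi)) pi <- .stationary_of_P(P)
  src <- .state_idx(P, source); snk <- .state_idx(P, sink)
  via_i <- if (length(via)) .state_idx(P, via) else integer(0)
  if (length(intersect(via_i, c(src, snk))))
    stop("via must be disjoint from source and sink")
  if (length(via_i) == 0L) return(0)
  total <- .first_exit_flux(P, pi, src, snk, taboo = integer(0))
  if (total <= 0) stop("zero total reactive flux between source and sink")
  avoid <- .first_exit_flux(P, pi, src, snk, taboo = via_i)
  1 - avoid / total
}

# Rate (per lag step) of reactive source->sink excursions avoiding the
# taboo set: sum over source exits weighted by the taboo-constrained
# commitment probability of the landing state.
.first_exit_flux <- function(P, pi, src, snk, taboo) {
  n <- nrow(P)
  # committor to the sink with source and taboo absorbing (q = 0 there)
  q <- numeric(n)
  q[snk] <- 1
  inter <- setdiff(seq_len(n), c(src, snk, taboo))
  if (length(inter)) {
    A <- diag(length(inter)) - P[inter, inter, drop = FALSE]
    b <- P[inter, snk, drop = FALSE] %*% rep(1, length(snk))
    q[inter] <- as.vector(solve(A, b))
  }
  sum(outer(pi[src], rep(1, n)) * P[src, , drop = FALSE] *
        matrix(q, length(src), n, byrow = TRUE))
}

#' Mean first-passage time on a macrostate model
#'
#' Expected time (ns) to first reach the sink set, starting from the
#' stationary distribution restricted to the source set, via the
#' fundamental-matrix linear system scaled by the lag.
#'
#' @param model a `macrostate_model`, or a row-stochastic matrix (then
#'   supply `lag`).
#' @param source,sink state sets; a source inside the sink returns 0.
#' @param lag lag time in ns for raw matrices.
#' @param pi optional stationary distribution for the source weighting.
#' @return MFPT in ns.
#' @export
mfpt <- function(model, source, sink, lag = NULL, pi = NULL) {
  P <- if (inherits(model, "macrostate_model")) model$P else model
  if (inherits(model, "macrostate_model")) {
    if (is.null(lag)) lag <- model$lag
    if (is.null(pi)) pi <- model$pi_macro
  }
  if (is.null(lag)) stop("supply lag with a raw transition matrix")
  if (is.null(pi)) pi <- .stationary_of_P(P)
  src <- .state_idx(P, source); snk <- .state_idx(P, sink)
  if (all(src %in% snk)) return(0)
  n <- nrow(P)
  m <- numeric(n)
  keep <- setdiff(seq_len(n), snk)
  A <- diag(length(keep)) - P[keep, keep, drop = FALSE]
  sol <- tryCatch(solve(A, rep(lag, length(keep))),
                  error = function(e) stop("sink unreachable from source"))
  if (any(sol < -1e-8)) stop("sink unreachable from source")
  m[keep] <- sol
  w <- pi[src] / sum(pi[src])
  sum(w * m[src])
}

#' Full pathway report for a macrostate model
#'
#' Committors, MFPT matrix, and via-state pathway fractions for the
#' hybridization (D to H) and dehybridization (H to D) transitions.
#'
#' @param model a labeled `macrostate_model` (see [label_macrostates()]).
#' @param shifted_labels labels counted as out-of-register states.
#' @return A list of class `pathway_report`.
#' @export
pathway_report <- function(model,
                           shifted_labels = c("5S2", "3S2", "5S4", "3S4")) {
  if (is.null(model$labels))
    stop("model has no macrostate labels; run label_macrostates() first")
  lab <- model$labels
  P <- model$P
  dimnames(P) <- list(lab, lab)
  pi <- setNames(model$pi_macro, lab)
  n <- length(lab)
  mf <- matrix(NA_real_, n, n, dimnames = list(lab, lab))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    mf[i, j] <- mfpt(P, i, j, lag = model$lag, pi = pi)
  diag(mf) <- 0
  out <- list(mfpt_ns = mf, labels = lab, pi = pi)
  if (all(c("H", "D") %in% lab)) {
    via_shift <- intersect(shifted_labels, lab)
    out$committor_DH <- committor(P, "D", "H")
    out$flux_DH <- reactive_flux(P, "D", "H", pi = pi)
    out$fraction_via_shifted_DH <- if (length(via_shift))
      pathway_fraction(P, "D", "H", via_shift, pi = pi) else 0
    out$fraction_via_shifted_HD <- if (length(via_shift))
      pathway_fraction(P, "H", "D", via_shift, pi = pi) else 0
    out$fraction_via_F4_DH <- if ("F4" %in% lab)
      pathway_fraction(P, "D", "H", "F4", pi = pi) else 0
    out$mfpt_DH_ns <- mf["D", "H"]
    out$mfpt_HD_ns <- mf["H", "D"]
  }
  class(out) <- "pathway_report"
  out
}

#' @export
print.pathway_report <- function(x, ...) {
  cat("<pathway_report>\n  MFPT matrix (ns):\n")
  print(round(x$mfpt_ns, 1))
  if (!is.null(x$mfpt_DH_ns)) {
    cat(sprintf("  MFPT D->H = %.1f ns, H->D = %.1f ns\n",
                x$mfpt_DH_ns, x$mfpt_HD_ns))
    cat(sprintf("  fraction via shifted states: D->H %.3f, H->D %.3f\n",
                x$fraction_via_shifted_DH, x$fraction_via_shifted_HD))
  }
  invisible(x)
}

#' Attach physical labels to PCCA+ macrostates
#'
#' Labels each macrostate by the majority [classify_macrostate()] label
#' over a sample of its member frames, tying the data-driven MSM states
#' to the register-based taxonomy.
#'
#' @param macro a `macrostate_model`.
#' @param msm the parent `reversible_msm` (for the active set).
#' @param assignment the `microstate_assignment` used to build the MSM.
#' @param trajectories the trajectory or list of trajectories.
#' @param seq a [duplex_sequence].
#' @param max_frames_per_state sample cap per macrostate.
#' @param bound_cutoff,dissoc_cutoff classifier cutoffs (nm).
#' @return The `macrostate_model` with `labels` filled (majority label,
#'   made unique with suffixes if duplicated) and `label_table` of
#'   per-state classifier label counts.
#' @export
label_macrostates <- function(macro, msm, assignment, trajectories, seq,
                              max_frames_per_state = 400L,
                              bound_cutoff = 1.3, dissoc_cutoff = 2.0) {
  if (inherits(trajectories, "duplex_trajectory"))
    trajectories <- list(trajectories)
  # macrostate label per frame, aligned with trajectory frames
  macro_of_frame <- lapply(macro$dtrajs, identity)
  labels <- character(macro$n_macro)
  tab_list <- vector("list", macro$n_macro)
  offsets <- cumsum(c(0L, vapply(macro_of_frame, length, 1L)))
  flat <- unlist(macro_of_frame)
  for (m in seq_len(macro$n_macro)) {
    idx <- which(flat == m)
    if (length(idx) > max_frames_per_state) {
      # deterministic thinning; which frames are checked is immaterial
      pick <- unique(round(seq(1L, length(idx),
                               length.out = max_frames_per_state)))
      idx <- idx[pick]
    }
    cls <- character(length(idx))
    for (r in seq_along(idx)) {
      tr <- findInterval(idx[r] - 1L, offsets, rightmost.closed = FALSE)
      t_local <- idx[r] - offsets[tr]
      fr <- trajectories[[tr]]$frames[t_local, , , , drop = TRUE]
      cls[r] <- classify_macrostate(interbase_distance_matrix(fr), seq,
                                    bound_cutoff, dissoc_cutoff)
    }
    tab <- sort(table(cls), decreasing = TRUE)
    tab_list[[m]] <- tab
    labels[m] <- names(tab)[1L]
  }
  labels <- make.unique(labels, sep = ".")
  macro$labels <- labels
  macro$label_table <- tab_list
  macro
}
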