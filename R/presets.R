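#' Build a ground-truth kinetic preset for the synthetic generator
#'
#' A preset bundles everything the generator needs: the duplex sequence,
#' its macrostate set, a reversible rate matrix (1/ns) with its stationary
#' law, per-state coordinate templates, and the fast-fluctuation
#' parameters (jitter and terminal-pair fraying). The four named presets
#' are fully deterministic; `"custom"` builds a preset from an explicit
#' parameter map.
#'
#' The stationary law of every named preset places probability 0.5 on the
#' dissociated state `D` (melting conditions at temperature factor
#' `u = 0`), and the AT-all preset places exactly 0.100 of stationary mass
#' in its four shifted states.
#'
#' @param name `"AT-all"`, `"GC-end"`, `"GC-core"`, `"GC-mix"`, or
#'   `"custom"`.
#' @param overrides optional named list overriding preset parameters. For
#'   named presets, `jitter_sigma`, `jitter_corr_time`, `fray_toggle_rate`
#'   and `temperature_factor` may be overridden, as may `pi` and `flux`
#'   (re-validated). For `"custom"`, the list must contain `sequence`
#'   (string or `duplex_sequence`), `pi` (named stationary vector) and
#'   `flux` (data frame with columns `i`, `j`, `f` of equilibrium exchange
#'   fluxes, 1/ns).
#' @return An object of class `kinetic_preset`.
#' @examples
#' p <- build_preset("GC-mix")
#' p$states
#' @export
build_preset <- function(name, overrides = NULL) {
  named <- names(.PRESET_SEQUENCES)
  if (name %in% named) {
    seq <- duplex_sequence(name)
    pi <- .PRESET_PI[[name]]
    flux <- .PRESET_FLUX[[name]]
    t_ref <- .PRESET_TM[[name]]
  } else if (identical(name, "custom")) {
    if (is.null(overrides$sequence) || is.null(overrides$pi) ||
        is.null(overrides$flux))
      stop("custom presets need 'sequence', 'pi' and 'flux' in overrides")
    seq <- if (inherits(overrides$sequence, "duplex_sequence"))
      overrides$sequence else duplex_sequence(overrides$sequence)
    pi <- overrides$pi
    flux <- overrides$flux
    t_ref <- if (!is.null(overrides$t_ref)) overrides$t_ref else 310
  } else {
    stop("unknown preset name: ", name,
         " (expected one of ", paste(c(named, "custom"), collapse = ", "), ")")
  }
  if (!is.null(overrides)) {
    for (fld in c("pi", "flux"))
      if (!is.null(overrides[[fld]])) assign(fld, overrides[[fld]])
  }
  noise <- .NOISE
  for (fld in c("jitter_sigma", "jitter_corr_time", "fray_toggle_rate"))
    if (!is.null(overrides[[fld]])) noise[[fld]] <- overrides[[fld]]
  u <- if (!is.null(overrides$temperature_factor))
    overrides$temperature_factor else 0

  states <- names(pi)
  bad <- setdiff(states, MACROSTATE_LABELS)
  if (length(bad))
    stop("unknown macrostate label(s): ", paste(bad, collapse = ", "))
  if (abs(sum(pi) - 1) > 1e-12)
    stop("invariant violated: stationary law must sum to 1 (got ",
         format(sum(pi), digits = 15), ")")
  if (any(pi <= 0)) stop("stationary probabilities must be positive")
  if (!all(c("i", "j", "f") %in% names(flux)))
    stop("flux table needs columns i, j, f")
  if (!all(c(flux$i, flux$j) %in% states))
    stop("flux table references states outside the state set")
  if (any(flux$f <= 0)) stop("exchange fluxes must be positive")
  if (nrow(flux) == 0L && length(states) > 1L)
    stop("multi-state presets need at least one exchange flux")

  Q <- flux_to_rates(pi, flux)
  db <- max(abs(pi * Q - t(pi * Q)))
  if (db > 1e-10)
    stop("invariant violated: detailed balance (max |pi_i q_ij - pi_j q_ji| = ",
         format(db), ")")

  preset <- structure(list(
    sequence = seq,
    states = states,
    rate_matrix = Q,
    stationary = pi,
    base_rate_matrix = Q,   # u = 0 network; temperature tilts start here
    base_stationary = pi,
    flux = flux,
    templates = state_templates(seq, states),
    jitter_sigma = noise$jitter_sigma,
    jitter_corr_time = noise$jitter_corr_time,
    fray_toggle_rate = noise$fray_toggle_rate,
    temperature_factor = u,
    t_ref = t_ref,
    name = if (name %in% named) name else "custom"
  ), class = "kinetic_preset")
  if (u != 0) {
    mod <- temperature_modified(preset, u)
    preset$rate_matrix <- mod$Q
    preset$stationary <- mod$pi
  }
  preset
}

# Rate matrix (1/ns) from stationary law and symmetric exchange fluxes.
flux_to_rates <- function(pi, flux) {
  n <- length(pi)
  Q <- matrix(0, n, n, dimnames = list(names(pi), names(pi)))
  for (r in seq_len(nrow(flux))) {
    i <- flux$i[r]; j <- flux$j[r]; f <- flux$f[r]
    Q[i, j] <- Q[i, j] + f / pi[[i]]
    Q[j, i] <- Q[j, i] + f / pi[[j]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Apply the temperature factor u: every u = 0 rate i -> j is scaled by
# exp(u * (level_j - level_i)), where the level is an unbinding coordinate
# (H = 0 ... D = 1): rates toward less-bound states speed up, reverse
# rates slow down. Because the scaling is the gradient of a state
# function, the Kolmogorov cycle criterion is preserved and the tilted
# chain is reversible with stationary law pi_u ~ pi * exp(2 u level).
temperature_modified <- function(preset, u) {
  lv <- .STATE_LEVEL[preset$states]
  Q0 <- if (!is.null(preset$base_rate_matrix)) preset$base_rate_matrix
        else preset$rate_matrix
  pi0 <- if (!is.null(preset$base_stationary)) preset$base_stationary
         else preset$stationary
  Q <- Q0 * exp(u * outer(lv, lv, function(a, b) b - a))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  pi <- pi0 * exp(2 * u * lv)
  pi <- pi / sum(pi)
  list(Q = Q, pi = pi)
}

#' Stationary law of a rate matrix
#'
#' Solves pi Q = 0, sum(pi) = 1 by the null space of t(Q).
#'
#' @param Q square rate matrix, rows summing to zero.
#' @return Named stationary probability vector.
#' @export
stationary_law <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- rownames(Q)
  pi
}

#' Find the temperature factor balancing hybridized and dissociated mass
#'
#' Returns the factor `u*` at which the stationary probability of the
#' dissociated state `D` equals 0.5 within `tol`, computed by bisection on
#' the analytic stationary law of the tilted chain (no sampling). Named
#' presets are balanced at `u = 0` by construction, so `u*` is ~0 there;
#' the operation matters for custom presets and as the analogue of tuning
#' simulation temperature to the melting point.
#'
#' @param preset a [kinetic_preset][build_preset].
#' @param tol tolerance on the D-mass (probability), > 0.
#' @return The scalar `u*`.
#' @export
find_melting_factor <- function(preset, tol = 1e-8) {
  stopifnot(tol > 0)
  if (!"D" %in% preset$states)
    stop("preset has no dissociated state D")
  dmass <- function(u) temperature_modified(preset, u)$pi[["D"]]
  # D-mass is strictly increasing in u (its level strictly dominates).
  lo <- -50; hi <- 50
  if (dmass(lo) > 0.5 || dmass(hi) < 0.5)
    stop("melting factor outside bracket [-50, 50]")
  while (TRUE) {
    mid <- (lo + hi) / 2
    d <- dmass(mid)
    if (abs(d - 0.5) < tol) return(mid)
    if (d < 0.5) lo <- mid else hi <- mid
    if (hi - lo < 1e-14) return(mid)
  }
}

#' @export
print.kinetic_preset <- function(x, ...) {
  cat("<kinetic_preset> ", x$name, " (", x$sequence$bases, ")\n", sep = "")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  stationary:", paste(sprintf("%s=%.4g", x$states, x$stationary),
                             collapse = ", "), "\n")
  cat("  temperature factor u =", x$temperature_factor, "\n")
  invisible(x)
}
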