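# Ground-truth constants for the synthetic duplex generator.
#
# Every number that defines a named kinetic preset lives in this one file.
# The networks are constrained by the published structural facts only:
#   * stationary mass on D is exactly 0.5 (melting condition, u = 0),
#   * AT-all places exactly 0.100 of stationary mass in shifted states,
#   * GC-end places 0.0023 total in its three shifted states (even split),
#   * the leading relaxation timescale is ~1 microsecond in generator
#     units and shared across presets to within ~10%,
#   * GC-core's frayed state F4 is short-lived relative to H and D.
# Exchange rates are parameterized by symmetric equilibrium fluxes
# f_ij = pi_i q_ij = pi_j q_ji (1/ns), which imposes detailed balance by
# construction. Resulting relaxation spectra (ns), from the rate-matrix
# eigenvalues: AT-all 1061, 113, 95, 36, 32; GC-end 1036, 85, 85, 70;
# GC-core 1026, 50; GC-mix 977.

#' @rdname macrostate_labels
#' @export
MACROSTATE_LABELS <- c("H", "5S2", "3S2", "5S4", "3S4", "F4", "D")

#' The seven admissible macrostate labels
#'
#' `H` is the fully hybridized duplex; `5S2`/`5S4` and `3S2`/`3S4` are
#' out-of-register states shifted by two or four bases in the 5' or 3'
#' direction; `F4` is the frayed state with one four-base terminal A:T run
#' fully open (possible only for a sequence with a central G:C core); `D`
#' is the fully dissociated pair of strands.
#'
#' `MACROSTATE_REGISTER` maps each bound label to its register offset in
#' bases (positive = 5' shift, negative = 3' shift); `F4` sits at offset 0
#' and `D` has no register (NA).
#'
#' @name macrostate_labels
#' @export
MACROSTATE_REGISTER <- c(H = 0L, `5S2` = 2L, `3S2` = -2L, `5S4` = 4L,
                         `3S4` = -4L, F4 = 0L, D = NA_integer_)

# Unbinding coordinate used for the temperature factor u: state weights are
# tilted as pi_u ~ pi * exp(2 * u * level), and each rate q_ij is scaled by
# exp(u * (level_j - level_i)). The level is a gradient over the network,
# so the scaled chain stays reversible for every u.
.STATE_LEVEL <- c(H = 0, `5S2` = 0.2, `3S2` = 0.2, `5S4` = 0.4, `3S4` = 0.4,
                  F4 = 0.4, D = 1)

# Named 10-base self-complementary sequences (5'->3').
.PRESET_SEQUENCES <- c(
  "AT-all"  = "ATATATATAT",
  "GC-end"  = "GATATATATC",
  "GC-core" = "ATATGCATAT",
  "GC-mix"  = "ATGATATCAT"
)

# Coarse-grained melting temperatures (K) used for thermodynamic reports.
.PRESET_TM <- c("AT-all" = 309, "GC-end" = 317, "GC-core" = 324,
                "GC-mix" = 324)

# Stationary laws at u = 0 (melting conditions).
.PRESET_PI <- list(
  "AT-all"  = c(H = 0.400, `5S2` = 0.040, `3S2` = 0.030,
                `5S4` = 0.018, `3S4` = 0.012, D = 0.500),
  "GC-end"  = c(H = 0.4977, `5S2` = 0.23 / 300, `3S2` = 0.23 / 300,
                `5S4` = 0.23 / 300, D = 0.500),
  "GC-core" = c(H = 0.450, F4 = 0.050, D = 0.500),
  "GC-mix"  = c(H = 0.500, D = 0.500)
)

# Equilibrium exchange fluxes f_ij (1/ns). Only listed pairs exchange.
.PRESET_FLUX <- list(
  "AT-all" = data.frame(
    i = c("H", "D",   "D",   "D",   "D",   "H",   "H",   "5S2", "3S2"),
    j = c("D", "5S2", "3S2", "5S4", "3S4", "5S2", "3S2", "5S4", "3S4"),
    f = c(0.80, 0.66, 0.50, 0.34, 0.26, 5.00, 4.00, 2.50, 2.00) * 1e-4,
    stringsAsFactors = FALSE),
  "GC-end" = data.frame(
    i = c("H", "D",   "H",   "D",   "H",   "D"),
    j = c("D", "5S2", "5S2", "3S2", "3S2", "5S4"),
    f = c(2.36, 0.06, 0.05, 0.05, 0.04, 0.09) * 1e-4,
    stringsAsFactors = FALSE),
  "GC-core" = data.frame(
    i = c("H", "F4"),
    j = c("F4", "D"),
    f = c(5.30, 4.10) * 1e-4,
    stringsAsFactors = FALSE),
  "GC-mix" = data.frame(
    i = "H", j = "D", f = 2.56e-4, stringsAsFactors = FALSE)
)

# Geometry of the coordinate templates (nm).
.GEOM <- list(
  rise       = 0.34,  # per-base rise along the ladder axis
  pair_gap   = 0.60,  # separation of paired base centers
  d_sep      = 6.20,  # centroid separation of dissociated strands
  fray_disp  = 0.60,  # per-base displacement of a frayed terminal base
  f4_disp0   = 0.70,  # displacement of the first base of the F4 open run
                      # (pair separation 2.0 nm, safely past the 1.3 nm
                      # breakage cutoff under jitter)
  f4_dispinc = 0.30   # per-base increment further into the open run
)

# Fast-fluctuation defaults.
.NOISE <- list(
  jitter_sigma     = 0.15, # nm, stationary sd of the mean-reverting jitter
  jitter_corr_time = 0.30, # ns
  fray_toggle_rate = 2.0   # 1/ns per direction, terminal-pair telegraph
)

# Distance cutoffs (nm): a Watson-Crick contact is intact below
# `bound`, and strands separated beyond `dissoc` are non-interacting.
.CUTOFFS <- c(bound = 1.3, dissoc = 2.0)

# Boltzmann constant in molar units, kJ/(mol K).
.KB_KJ <- 0.008314462618
# kcal -> kJ
.KCAL_TO_KJ <- 4.184
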