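# Nearest-neighbor (NN) thermodynamics of the macrostate registers, and
# the MSM-vs-NN free energy comparison.

#' Load the embedded nearest-neighbor parameter table
#'
#' Watson-Crick stack enthalpies/entropies and duplex initiation terms
#' from the unified oligonucleotide NN set, plus a dangling-end free
#' energy table. The dangling-end values shipped with the package are a
#' synthetic stand-in with the qualitative structure of the published
#' set (see the file header); their `version` field records this.
#'
#' @param stacks_file,dangling_file optional paths overriding the
#'   embedded tables (same TSV schema).
#' @return List of class `nn_parameter_table` with `stacks` (named list
#'   of `c(dH, dS)`), `init_GC`, `init_AT`, `symmetry`, `dangling`
#'   (data frame), `stack_version`, `dangling_version`.
#' @export
nn_parameter_table <- function(stacks_file = NULL, dangling_file = NULL) {
  if (is.null(stacks_file))
    stacks_file <- system.file("extdata", "nn_stacks_santalucia1998.tsv",
                               package = "duplexmsm")
  if (is.null(dangling_file))
    dangling_file <- system.file("extdata", "nn_dangling_dg37_synthetic.tsv",
                                 package = "duplexmsm")
  ver <- function(path) {
    v <- grep("^# version:", readLines(path, n = 20L), value = TRUE)
    if (length(v)) sub("^# version:\\s*", "", v[1L]) else "unknown"
  }
  st <- read.table(stacks_file, header = TRUE, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE)
  dg <- read.table(dangling_file, header = TRUE, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE)
  stacks <- setNames(lapply(seq_len(nrow(st)), function(r)
    c(dH = st$dH[r], dS = st$dS[r])), st$key)
  wc <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0))
  missing <- setdiff(wc, names(stacks))
  if (length(missing))
    stop("NN stack table incomplete; missing ", paste(missing, collapse = ", "))
  structure(list(
    stacks = stacks[wc],
    init_GC = stacks[["init_GC"]], init_AT = stacks[["init_AT"]],
    symmetry = stacks[["symmetry"]],
    dangling = dg,
    stack_version = ver(stacks_file), dangling_version = ver(dangling_file)
  ), class = "nn_parameter_table")
}

# Paired stretch (strand-1 positions, contiguous) implied by a macrostate
# label. Returns NULL for D.
.label_stretch <- function(seq, label) {
  if (label == "D") return(NULL)
  if (label == "F4") {
    if (!has_gc_core(seq))
      stop("label F4 requires a sequence with a central G:C core")
    # intact central core plus one intact terminal A:T run; the 5' run is
    # the documented convention for the NN column
    return(1:6)
  }
  k <- MACROSTATE_REGISTER[[label]]
  if (is.na(k)) stop("unknown macrostate label: ", label)
  ok <- register_pairing(seq, k)
  if (!any(ok)) stop("register ", k, " has no Watson-Crick pairs for ",
                     seq$bases)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  attr_k <- starts[best]:ends[best]
  attr(attr_k, "register") <- k
  attr_k
}

# First dangling base at each stretch end. When both strands overhang at
# the same end (possible when a register breaks a terminal pair) the
# longer overhang is used -- terminal-mismatch parameters are out of
# scope. Returns a data frame (side, dangle_base, pair_base).
.dangling_context <- function(seq, stretch, k) {
  b <- strsplit(seq$bases, "")[[1L]]
  i <- stretch[1L]; j <- stretch[length(stretch)]
  out <- list()
  add <- function(side, dangle_pos, pair_pos)
    out[[length(out) + 1L]] <<- data.frame(
      side = side, dangle_base = b[dangle_pos], pair_base = b[pair_pos],
      stringsAsFactors = FALSE)
  # start end (5' of strand 1): strand-1 tail 1..i-1, strand-2 tail
  # beyond partner p = 11 - i + k
  p <- 11L - i + k
  t1 <- i - 1L           # strand-1 tail length
  t2 <- 10L - p          # strand-2 tail length
  if (t1 > 0L || t2 > 0L) {
    if (t1 >= t2 && t1 > 0L) add("5p", i - 1L, i)
    else if (t2 > 0L) add("3p", p + 1L, p)
  }
  # far end (3' of strand 1)
  p2 <- 11L - j + k
  t1 <- 10L - j
  t2 <- p2 - 1L
  if (t1 > 0L || t2 > 0L) {
    if (t1 >= t2 && t1 > 0L) add("3p", j + 1L, j)
    else if (t2 > 0L) add("5p", p2 - 1L, p2)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Nearest-neighbor free energy of a macrostate's paired register
#'
#' Sums stack terms (`dH - T dS`) over dinucleotide steps wholly inside
#' the paired stretch implied by the macrostate's register (for `F4`,
#' the central G:C core plus the 5' intact A:T run), adds initiation
#' terms for the two terminal pair classes of the stretch, the
#' self-complementary symmetry correction, and one dangling-end term for
#' the first unpaired base adjacent to each duplex end (tail bases
#' beyond the first dangling base contribute nothing). `D` returns 0,
#' the unbound reference.
#'
#' @param seq a [duplex_sequence].
#' @param label a macrostate label.
#' @param T temperature in kelvin (> 0).
#' @param params a [nn_parameter_table()].
#' @return Free energy of duplex formation, kcal/mol.
#' @export
nn_free_energy <- function(seq, label, T = 310,
                           params = nn_parameter_table()) {
  stopifnot(T > 0)
  if (!label %in% MACROSTATE_LABELS)
    stop("unknown macrostate label: ", label)
  stretch <- .label_stretch(seq, label)
  if (is.null(stretch)) return(0)
  k <- if (label == "F4") 0L else MACROSTATE_REGISTER[[label]]
  b <- strsplit(seq$bases, "")[[1L]]
  dH <- 0; dS <- 0
  for (m in stretch[-length(stretch)]) {
    key <- paste0(b[m], b[m + 1L])
    v <- params$stacks[[key]]
    if (is.null(v)) stop("unknown stack in table: ", key)
    dH <- dH + v[["dH"]]; dS <- dS + v[["dS"]]
  }
  for (pos in c(stretch[1L], stretch[length(stretch)])) {
    v <- if (b[pos] %in% c("G", "C")) params$init_GC else params$init_AT
    dH <- dH + v[["dH"]]; dS <- dS + v[["dS"]]
  }
  dH <- dH + params$symmetry[["dH"]]
  dS <- dS + params$symmetry[["dS"]]
  dG <- dH - T * dS / 1000
  ctx <- .dangling_context(seq, stretch, k)
  if (!is.null(ctx)) {
    for (r in seq_len(nrow(ctx))) {
      hit <- params$dangling$side == ctx$side[r] &
        params$dangling$dangle_base == ctx$dangle_base[r] &
        params$dangling$pair_base == ctx$pair_base[r]
      if (!any(hit))
        stop("missing dangling-end entry: ", ctx$side[r], " ",
             ctx$dangle_base[r], " on ", ctx$pair_base[r])
      dG <- dG + params$dangling$dG37[hit][1L]
    }
  }
  dG
}

#' Relative free energies from macrostate populations
#'
#' Applies `F = -kB T ln P + C` with the hybridized state `H` as the
#' zero reference: `dF(s) = -kB T ln(pi_s / pi_H)`, reported in kJ/mol.
#' States with zero or missing population are omitted with a warning.
#'
#' @param pi_macro named stationary probabilities including `"H"`.
#' @param T temperature in kelvin.
#' @return Named vector of dF (kJ/mol); `dF["H"]` is exactly 0.
#' @export
free_energies_from_populations <- function(pi_macro, T = 310) {
  if (!"H" %in% names(pi_macro))
    stop("populations must include the reference state H")
  bad <- !is.finite(pi_macro) | pi_macro <= 0
  if (any(bad)) {
    warning("omitting state(s) with zero/missing population: ",
            paste(names(pi_macro)[bad], collapse = ", "))
    pi_macro <- pi_macro[!bad]
  }
  dF <- -.KB_KJ * T * log(pi_macro / pi_macro[["H"]])
  dF[["H"]] <- 0
  dF
}

#' Align MSM and NN free-energy columns and report their discrepancy
#'
#' Builds the comparison table `ddF = dF_MSM - dF_NN` over the shared
#' macrostate set, both columns referenced to `H` (so adding a constant
#' to either column leaves `ddF` unchanged). Inputs may be in kJ/mol
#' (default) or kcal/mol (`units_nn = "kcal"` converts by 4.184).
#'
#' @param msm_col named dF vector from
#'   [free_energies_from_populations()], kJ/mol.
#' @param nn_col named dF (or absolute G, see reference handling) vector
#'   from the NN model.
#' @param units_nn `"kJ"` or `"kcal"` for `nn_col`.
#' @param T temperature in kelvin, recorded in the output.
#' @return Data frame of class `macrostate_thermo` with columns `state`,
#'   `dF_msm`, `dF_nn`, `ddF` (kJ/mol) and attribute `temperature`.
#' @export
compare_msm_nn <- function(msm_col, nn_col, units_nn = c("kJ", "kcal"),
                           T = 310) {
  units_nn <- match.arg(units_nn)
  if (units_nn == "kcal") nn_col <- nn_col * .KCAL_TO_KJ
  shared <- intersect(names(msm_col), names(nn_col))
  dropped <- setdiff(union(names(msm_col), names(nn_col)), shared)
  if (length(dropped))
    warning("state sets differ; using intersection (dropped: ",
            paste(dropped, collapse = ", "), ")")
  if (!"H" %in% shared) stop("shared state set must include H")
  m <- msm_col[shared] - msm_col[["H"]]
  n <- nn_col[shared] - nn_col[["H"]]
  out <- data.frame(state = shared, dF_msm = as.numeric(m),
                    dF_nn = as.numeric(n),
                    ddF = as.numeric(m - n), stringsAsFactors = FALSE)
  attr(out, "temperature") <- T
  class(out) <- c("macrostate_thermo", class(out))
  out
}

#' Full MSM-vs-NN thermodynamic table for a labeled macrostate model
#'
#' @param pi_macro named macrostate populations (names = macrostate
#'   labels, including `H`).
#' @param seq a [duplex_sequence].
#' @param T temperature in kelvin (defaults to the preset melting
#'   temperature when `seq` is a named preset).
#' @param params a [nn_parameter_table()].
#' @return A `macrostate_thermo` data frame (see [compare_msm_nn()]).
#' @export
macrostate_thermo_table <- function(pi_macro, seq, T = NULL,
                                    params = nn_parameter_table()) {
  if (is.null(T))
    T <- if (seq$name %in% names(.PRESET_TM)) .PRESET_TM[[seq$name]] else 310
  states <- names(pi_macro)
  states <- states[states %in% MACROSTATE_LABELS]
  msm <- free_energies_from_populations(pi_macro[states], T)
  nn <- vapply(names(msm), function(s)
    nn_free_energy(seq, s, T, params), numeric(1))
  compare_msm_nn(msm, nn, units_nn = "kcal", T = T)
}
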