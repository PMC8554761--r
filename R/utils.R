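# Small bookkeeping helpers for simulation-campaign arithmetic.

#' Single-strand concentration of n strands in a cubic box
#'
#' @param n_strands number of strands in the box.
#' @param box_nm cubic box edge length (nm).
#' @return Concentration in mM.
#' @examples
#' strand_concentration(2, 7.8)  # ~7 mM
#' @export
strand_concentration <- function(n_strands, box_nm) {
  stopifnot(n_strands > 0, box_nm > 0)
  avogadro <- 6.02214076e23
  vol_l <- (box_nm * 1e-7)^3 / 1e3   # nm -> cm, cm^3 -> L
  n_strands / (avogadro * vol_l) * 1e3
}

#' Frame count of a simulation campaign
#'
#' @param n_sim number of independent simulations.
#' @param t_us production length per simulation (microseconds).
#' @param save_ps save cadence (picoseconds).
#' @return Total number of saved frames.
#' @examples
#' campaign_frames(40, 25, 100)  # 1e7
#' @export
campaign_frames <- function(n_sim, t_us, save_ps) {
  stopifnot(n_sim > 0, t_us > 0, save_ps > 0)
  n_sim * (t_us * 1e6 / save_ps)
}
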