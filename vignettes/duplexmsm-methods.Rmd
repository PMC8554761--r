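---
title: "Methods: sequence-dependent kinetic models of DNA duplex hybridization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-dependent kinetic models of DNA duplex hybridization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Short DNA oligomers associate and dissociate on microsecond time
scales, and the placement of G:C pairs within an otherwise repetitive
A:T tract reshapes the kinetic landscape qualitatively: a fully
repetitive self-complementary 10-mer can bind its partner in several
out-of-register alignments (the two strands shifted by two or four
bases toward the 5' or 3' end), a centrally placed G:C core stabilizes
a long-lived frayed state with one four-base A:T arm open, and a
maximally disruptive G:C placement yields clean two-state
("all-or-nothing") kinetics. `duplexmsm` implements the full inference
chain that turns two-strand trajectory data into such sequence-dependent
kinetic models: Markov state models (MSMs) over hybridized (H), shifted
(5S2, 3S2, 5S4, 3S4), frayed (F4) and dissociated (D) macrostates,
mechanism statistics from transition path theory, a nearest-neighbor
(NN) thermodynamic comparison, and temperature-jump style relaxation
rates.

Because the molecular-dynamics data behind such studies are far beyond
desk scale (the emulated campaign is 40 simulations x 25 us = 1e7
frames per sequence), the package ships a first-class synthetic
generator: explicit ground-truth continuous-time Markov networks over
the macrostates, dressed with coordinate templates and fast
fluctuations. Every downstream stage is tested against this stated
world.

## The synthetic world

### Kinetic networks

Each named preset (`AT-all` = ATATATATAT, `GC-end` = GATATATATC,
`GC-core` = ATATGCATAT, `GC-mix` = ATGATATCAT) carries a reversible
rate matrix built from symmetric equilibrium exchange fluxes
`f_ij = pi_i q_ij`, so detailed balance holds by construction. The
stationary laws and state sets are the published structural facts:

* state sets {H,5S2,3S2,5S4,3S4,D}, {H,5S2,3S2,5S4,D}, {H,F4,D},
  {H,D} for AT-all, GC-end, GC-core, GC-mix;
* dissociated mass exactly 0.5 (each system sits at its melting
  point, `u = 0`);
* AT-all shifted-state mass exactly 0.100; GC-end shifted mass 0.0023,
  split evenly over its three shifted states (the split itself is not
  a published number; the even split is our documented choice);
* GC-core routes all hybridization flux through F4 (no direct H-D
  edge), and F4 is short-lived (~50 ns dwell) relative to H and D
  (~1-2 us).

Rates are otherwise free choices, frozen once in `R/constants.R`. They
were set so that (i) the leading relaxation timescale is ~1 us in
generator units and shared across presets to within ~10% (all four
systems sit at their melting points at equal concentration, so their
hybridization/dehybridization timescale should match), and (ii) every
metastable sub-process relaxes at 40-110 ns, far above the 1.2 ns MSM
lag and far below the leading timescale, so the implied-timescale gap
structure is unambiguous. One published kinetic detail was deliberately
not imposed: a 25:1 bias of F4 -> H over F4 -> D would push the F4
relaxation time to ~6 ns, too close to the lag for reliable desk-scale
recovery of the three-state network; the preset uses ~1.3:1 and keeps
F4 short-lived.

### Temperature

Temperature enters as a single dimensionless factor `u`. Each state
has an unbinding level `L` (H = 0, two-base shifts 0.2, four-base
shifts and F4 0.4, D = 1) and every rate `i -> j` is scaled by
`exp(u (L_j - L_i))`. Because the scaling is the gradient of a state
function, the tilted chain remains reversible for every `u`, with
stationary law `pi_u ~ pi exp(2 u L)`; a literal per-edge
`exp(+/-u)` scaling would violate the cycle criterion on the triangle
H-S2-D and admit no equilibrium. `find_melting_factor()` inverts the
analytic tilted law by bisection; the melting semantics (D-mass 0.5)
are exact, and no kelvin scale is claimed — the rate-curve calibration
operation absorbs units.

### Coordinates

Antiparallel strands on a straight ladder: 0.34 nm rise, paired base
centers 0.6 nm apart, register offsets translating strand 2 along the
ladder axis (positive = 5' shift; with this convention a +2 template
has both 5' ends overhanging, which pins the 5S/3S naming). F4 fans
one four-base terminal run open to 2.0-3.8 nm pair separations.
Dissociated strands are placed 6.2 nm apart (every interbase distance
>= 3 nm) with an independently re-randomized relative orientation
*every frame*: free tumbling is much faster than the save cadence, and
per-dwell orientations would otherwise create an artificial slow
coordinate inside D that the MSM honestly resolves as a spurious
macrostate (we observed exactly this before the change).

Fast dynamics below the lag: mean-reverting (AR(1)) jitter with 0.15 nm
stationary spread and 0.3 ns correlation time on every coordinate, and
telegraph fraying of the two terminal native pairs at 2/ns per
direction (1.8 nm displaced separation) while the chain is hybridized.
Both relax well below the 1.2 ns lag and must not (and do not) appear
as MSM processes.

What the generator does *not* emulate: force-field energetics, helical
twist, sequence-dependent base geometry, diffusive encounter between
strands, partially zipped intermediates below the lag, or any kelvin
temperature scale. A green recovery test therefore establishes that
the inference chain recovers the stated kinetic truth from realistic
trajectory data volumes — not that it would recover the truth of any
particular force field.

## The inference chain

1. **Featurization.** Interstrand base-center distances d(i,j),
   strand-swap symmetrized (the 45 unordered off-diagonal pairs
   averaged), then reciprocal-transformed to emphasize near-duplex
   resolution. A 0.05 nm floor guards the reciprocal against degenerate
   input; templates never approach it. Intramolecular distances are
   excluded (an optional flag exists for experimentation).
2. **Slow modes.** Linear tICA at lag 1.2 ns: the symmetrized
   time-lagged generalized eigenproblem with a 1e-6 ridge on the
   instantaneous covariance (100 features contain collinear blocks).
   The lag is a physical choice, never optimized by score. VAMP-2
   scores (`1 + sum lambda_i^2`, the stationary mode counted) support
   cross-validation over whole trajectories; the embedding dimension
   keeps modes with implied timescale above the lag.
3. **Microstates.** k-means with k-means++ seeding (squared-distance
   seeding makes remote, rarely populated metastable clusters
   near-certain to receive centers — essential for the 0.08%-populated
   GC-end shifted states), fitted on a 1e5-frame subsample and applied
   to all frames; k = 200 by default.
4. **Reversible MSM.** Sliding-window counts at the lag (never across
   trajectory boundaries), ergodic trimming to the largest strongly
   connected set (discarded fraction reported), and the standard
   self-consistent fixed-point reversible maximum-likelihood estimator
   (element-wise convergence 1e-10). Implied timescales
   `t_i = -lag / log |lambda_i|`; Chapman-Kolmogorov validation
   compares `P^k(tau)` with `P(k tau)` under 3-sigma multinomial bands.
5. **Macrostates.** The number of macrostates follows a deterministic
   gap rule: among timescales above the lag, the candidate cut with the
   largest spectral gap (the floor `t -> lag` counts as the final gap)
   wins if it reaches `gap_ratio = 3`. PCCA+ (inner-simplex vertex
   construction on the leading eigenvectors, memberships clipped and
   renormalized, crisp assignment by maximal membership with
   lowest-index tie-break) yields macrostates; their transition matrix
   is re-counted from the projected trajectories and their stationary
   law aggregates the microstate one. Macrostates are tied to the
   physical taxonomy by majority vote of the geometric classifier over
   member frames.
6. **Mechanism.** Committors by linear solve with exact boundary
   conditions; reactive flux `f_ij = pi_i (1-q_i) P_ij q_j`; the
   fraction of reactive flux through a set S uses the taboo-committor
   construction (flux avoiding S = source->sink flux with S absorbed
   into the boundary), checked against brute-force reactive-segment
   counting; MFPTs by the fundamental-matrix solve, scaled by the lag,
   from the stationary law restricted to the source.
7. **Thermodynamics.** `F = -kB T ln P + C` with H as the zero
   reference converts populations to relative free energies; the NN
   column sums unified-parameter stacks over the register's paired
   stretch, initiation terms for the stretch-end pair classes, the
   self-complementary symmetry correction, and one dangling-end term
   per duplex end.
8. **T-jump analogues.** First-passage extraction (dissociation: both
   central native pairs beyond 2.0 nm; fraying: either terminal pair
   beyond 1.3 nm — raw per-pair distances, since the two terminal pairs
   are strand-swap images that symmetrization cannot distinguish),
   least-squares survival fits with censored trajectories kept in the
   at-risk denominator, the self-complementary two-state algebra
   (`lambda = k_d + 4 k_a [S]`, `K_d = 2 c_tot (1-theta)^2 / theta`),
   stretched-plus-two-exponential trace fitting with variable
   projection and ordered time constants, and rate-curve calibration
   under `rate_exp(T + dT) = s * rate_sim(T)` (so a 10x-accelerated,
   4 K-cold simulation calibrates to `s = 0.1`, `dT = +4 K`;
   `acceleration = 1/s` is reported alongside).

## Numerical and design choices worth knowing

* **Register classification.** The published cutoffs (1.3 nm contact
  breakage, 2.0 nm dissociation) drive the D/fraying/unassigned rules.
  Register resolution itself cannot use contact counts under this
  geometry: with a 0.34 nm rise, a two-base-off contact sits at
  0.91 nm — inside the 1.3 nm cutoff — so adjacent registers tie or
  even beat the true one on counts. The classifier instead matches the
  full symmetrized distance matrix against the ladder prediction of
  each admissible register (least mean-square deviation over entries
  predicted below 2 nm). This uses every informative matrix entry
  (~40 values rather than the 3-5 independent seated contacts of a
  four-shifted register) and holds the per-state round-trip accuracy at
  >= 99.5% under full jitter. It assumes the ladder geometry scale and
  is in that sense generator-facing; the physical cutoffs remain the
  interface for event detection.
* **F4 conventions.** Classification requires the central G:C contacts
  intact and exactly one terminal run of four native A:T contacts fully
  broken (raw distances). In the NN column, F4's intact stretch is the
  central core plus the 5' A:T run, with the frayed run's first base as
  a dangling end — the two runs are symmetry-equivalent, so the choice
  is a convention, not a claim.
* **Dangling ends.** When a register leaves both strands overhanging at
  the same duplex end, the longer overhang contributes the dangling
  term (terminal-mismatch parameters are out of scope). The stack,
  initiation and symmetry parameters are the unified oligonucleotide
  set; the 32 dangling-end values shipped with the package are an
  explicitly synthetic stand-in (the file and its header say so) with
  the published set's qualitative structure — replace
  `inst/extdata/nn_dangling_dg37_synthetic.tsv` with the published
  table for quantitative use. Tails beyond the first dangling base
  contribute nothing; no inert-tail penalty is applied, and no salt
  correction (relative dF between states cancels much of it).
* **Uncertainty.** A Bayesian transition-matrix posterior is replaced
  by a whole-trajectory bootstrap (percentile intervals, disconnected
  replicates skipped and counted). Coverage was checked against the
  generating chain: ~90% empirical coverage for nominal 95% intervals
  at small trajectory counts — adequate for error bars, slightly
  anticonservative, as percentile bootstraps are.
* **Two-state algebra limits.** In the self-complementary
  parameterization `4[S]/K_d = 2 theta / (1 - theta)` is independent of
  concentration, so the "no reassociation" limit `k_d -> lambda`
  corresponds to `theta -> 0` (mostly melted), and `theta -> 1` gives
  `K_d -> 0`.
* **Scale-downs (stated once, used everywhere).** The default save
  cadence emulates 100 ps; desk-scale runs use `dt_save = 0.6 ns` so
  that 1e6 frames span 600 us of chain time (~600 leading-timescale
  correlation times) within minutes of CPU. Recovery tests use 1e5-1e6
  frames instead of the emulated 1e7; survival and oracle studies use
  1e3-1e4 samples. Tolerances in tests derive from oracle standard
  errors (3 SE) or stated bands, never from observed outcomes.

## Worked example

```{r}
library(duplexmsm)
res <- run_pipeline(pipeline_config("AT-all", n_frames = 5e5,
                                    dt_save = 0.6, seed = 1))
print(res)
res$summary$shifted_percent        # ~10% in out-of-register states
res$mechanism$mfpt_DH_ns           # ~2 us hybridization MFPT
res$thermo                         # dF_MSM vs dF_NN vs ddF (kJ/mol)
```

## Known limitations

* The classifier's register matching presumes the generator's ladder
  scale; applying it to real coarse-grained MD frames would require
  re-deriving the template geometry from that model's helix.
* The linear tICA substitute resolves all preset processes but cannot
  claim the representational headroom of nonlinear slow-mode learners;
  the estimator interface (`fit`/`project`/score) is where one would
  slot in.
* No hidden-Markov or biased-sampling estimators; no mismatch or
  internal-loop NN terms (the studied registers produce none); no
  melting-temperature prediction in kelvin.
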