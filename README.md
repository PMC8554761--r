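# duplexmsm

Sequence-dependent kinetic models of DNA duplex hybridization and
dehybridization from two-strand trajectory data.

Short self-complementary DNA 10-mers do not simply snap together: a
repetitive A:T tract lets the two strands bind out of register
(shifted by two or four bases toward the 5' or 3' end), a central G:C
core stabilizes a long-lived frayed state, and a maximally disruptive
G:C placement gives clean two-state kinetics. `duplexmsm` is for
researchers who want to infer such kinetic landscapes from trajectory
data: it builds Markov state models (MSMs) over the macrostates
{H, 5S2, 3S2, 5S4, 3S4, F4, D}, extracts mechanism statistics, compares
the model's thermodynamics with the nearest-neighbor (NN) model, and
analyzes temperature-jump style relaxation.

At its core are:

* a **synthetic trajectory generator** — explicit ground-truth
  reversible rate matrices `Q` (detailed balance
  `pi_i q_ij = pi_j q_ji` by construction) over each sequence's
  macrostates, dressed with ladder-geometry coordinates, mean-reverting
  jitter, and terminal-pair fraying, so the whole inference chain is
  testable without MD data;
* **featurization** — the 100-element vector of reciprocal,
  strand-swap-symmetrized interstrand base-center distances;
* **tICA slow modes** scored by VAMP-2 (`sum_i lambda_i^2`);
* a **reversible maximum-likelihood MSM** with implied timescales
  `t_i = -tau / ln |lambda_i|`, Chapman-Kolmogorov validation
  (`P(k tau) = P^k(tau)`), and **PCCA+** coarse-graining;
* **transition path theory** — committors `q+`, reactive flux
  `f_ij = pi_i (1 - q_i) P_ij q_j`, via-state pathway fractions, and
  mean first-passage times;
* **NN thermodynamics** — `F = -kB T ln P + C` referenced to H versus
  the stack/initiation/symmetry/dangling-end sum, reported as
  `ddF = dF_MSM - dF_NN`;
* **T-jump analysis** — first-passage survival fits, the
  self-complementary two-state algebra
  (`lambda_slow = k_d + 4 k_a [S]`, `K_d = 2 c_tot (1-theta)^2/theta`),
  stretched-exponential trace fits
  `S(t) = A exp(-(t/tau_f)^beta) + B exp(-t/tau_s) + C exp(-t/tau_c)`,
  and rate-curve calibration between simulation and experiment.

## Worked example

```r
library(duplexmsm)
res <- run_pipeline(pipeline_config("AT-all", n_frames = 1e6,
                                    dt_save = 0.6, seed = 1))
print(res)
```

```
<pipeline_result> AT-all (ATATATATAT), 1e+06 frames
  macrostates ( 6 ): 3S4=0.01064, 5S4=0.01961, 3S2=0.03005, 5S2=0.04451, D=0.4311, H=0.4641
  shifted-state occupancy: 10.48%
  MFPT D->H = 1940 ns, H->D = 2385 ns
```

Reading the output: the pipeline simulated a million frames of
synthetic AT-all dynamics at melting conditions, learned slow modes,
clustered 200 microstates, and recovered all six ground-truth
macrostates by the implied-timescale gap rule plus PCCA+. The
estimated equilibrium occupancy of the four out-of-register shifted
states (10.48%) recovers the generator's configured 10.0%; the mean
first-passage times between the dissociated and hybridized states are
approximately equal, as they must be at the melting point. The run
also writes (with `outdir` set) the macrostate populations, transition
matrix, and an MSM-vs-NN free-energy table.

A command-line interface with `simulate`, `modes` and `all`
subcommands lives at `inst/scripts/duplexmsm-cli.R`.

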