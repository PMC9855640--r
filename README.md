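# crusim

Stochastic calcium-release-unit simulation of cardiac excitation–contraction
coupling, for studying how calmodulin (CaM) variants that weaken
Ca²⁺-dependent inactivation (CDI) of the L-type Ca²⁺ channel (LCC) drive a
rat ventricular myocyte toward calcium overload and arrhythmia.

Several CaM point mutations (D96V, N98S, D130G, F142L, N54I) lower CaM's
Ca²⁺-binding affinity and thereby blunt CDI — the main mechanism that shuts
the L-type channel during calcium-induced calcium release. crusim lets you
express any such variant as a multiplicative factor on the CDI rate constant
and rerun the pacing and beta-adrenergic experiments that connect that single
molecular deficit to cell-level phenotypes: SR calcium loading, prolonged
action potentials, altered calcium sparks, alternans and overload.

## The model in brief

* 20,000 (full scale) independent calcium release units, each with **49 RyR2
  channels and 7 LCCs** facing a dyadic subspace and a local junctional-SR
  compartment; desk-scale ensembles (e.g. 200 CRUs) rescale the CRU-to-bulk
  flux weights.
* **LCC**: six-state Markov model (C1, O2, O3, C4, C5, C6). CDI is the
  transition O2 → C4 with rate `cdi_factor · k24 · [Ca:CaM]`,
  `k24 = 8 s⁻¹µM⁻¹`.
* **CDI effector**: dyadic Ca:CaM from mass-action binding of two Ca²⁺,
  `d[Ca:CaM]/dt = k₊ Ca² (CaM_T − [Ca:CaM]) − k₋ [Ca:CaM]`
  (CaM_T = 24 µM, k₊ = 30, k₋ = 71.4). At steady state the bound fraction is
  `Ca²/(Ca² + K)`, so a variant with affinity K maps to the CDI factor
  `(Ca² + K_WT)/(Ca² + K)` at Ca = 10 µM, K_WT = 2.5 µM.
* **RyR2**: two-state channels with Hill activation in dyadic Ca²⁺, a
  saturating luminal (jSR) sensitisation and mean-field coupled gating;
  constant closing rate.
* Whole-cell layer: bulk myoplasm/NSR calcium with dynamic buffers, SERCA
  with a thermodynamic load ceiling, 3Na:1Ca exchanger, a rat-like
  sarcolemmal current set, current-clamp pacing, and beta-adrenergic scaling
  (LCC ×1.2, SERCA ×1.3).
* Analysis: spark detection (start above 25 µM, end below 5 µM), spark
  summaries, APD50/80/90 and alternans metrics, Welch t-tests.

The integrator is an adaptive explicit-Euler scheme with per-step stochastic
channel gating, per-release-site random streams and a rule limiting channel
state changes to at most 10% of CRUs per step. Fixed seeds give bit-identical
runs. See `vignettes/crusim-methods.Rmd` for the full model account,
numerical choices and calibration.

## Worked example

```r
library(crusim)

# variant CDI factors from published Ca2+ affinities
round(cdi_factor_from_affinity(c(N54I = 3.1, D96V = 38, N98S = 11,
                                 D130G = 150, F142L = 15)), 2)
#>  N54I  D96V  N98S D130G F142L
#>  0.99  0.74  0.92  0.41  0.89

# 3 s of 1 Hz pacing, 100 release units
ts <- simulate(protocol(pacing_hz = 1, duration = 3, n_cru = 100, seed = 1))
ts
#> <crusim_ts> 100 CRUs, 3 s, 1 Hz pacing, seed 1
#>   6001 samples; v range [-84.0, 65.1] mV; ca_myo range [0.0976, 1.09] uM
#>   steps 163875 (mean dt 1.83e-05 s), 753 rejected (10% rule), 5456 dt shrinks

# action-potential metrics per beat
apd <- apd_metrics(ts$data$t, ts$data$v, stim_times(ts$protocol))
round(apd$beats[, c("t_stim", "v_dia", "v_peak", "apd50", "apd80", "apd90")], 2)
#>   t_stim  v_dia v_peak apd50 apd80  apd90
#> 1   0.05 -83.96  65.10  5.26 82.62 101.42
#> 2   1.05 -83.94  64.58  5.33 69.59  91.29
#> 3   2.05 -83.87  64.73  5.20 67.15  89.64

# calcium sparks over the final second of the retained CRU traces
ev <- detect_sparks_ts(ts)
summarize_sparks(ev, window = 1, n_cru = length(ts$cru$ids))[,
  c("n_sparks", "freq_per_cru_s", "freq_cell_s", "duration_mean", "amplitude_mean")]
#>   n_sparks freq_per_cru_s freq_cell_s duration_mean amplitude_mean
#> 1       14            1.4       28000         24.71          128.8
```

The cell rests near −84 mV, fires brief rat-like action potentials
(APD90 ≈ 90 ms after the first beat), and its spontaneous sparks last
~25 ms with ~130 µM dyadic amplitudes. Variant runs just swap the parameter
set: `simulate(prot, default_params(variant = "mut75"))` scales the CDI rate
to 0.75·k24 (the D96V-like deficit); at fast pacing and under
beta-adrenergic stimulation this mutant loads its SR, prolongs the action
potential and degenerates into calcium overload while the wild type keeps a
regular train.

A full variant × frequency × beta grid with trend report:

```r
res <- reproduce_paper_grid("repro", preset = "desk-small", seeds = 1:6)
res$checks
```

A thin command-line driver with `run`, `grid`, `analyze`, `fixture` and
`reproduce` subcommands lives at `exec/crusim`.

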