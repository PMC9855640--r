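---
title: "crusim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crusim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crusim simulates excitation–contraction (EC) coupling in a rat ventricular
myocyte as a population of stochastic calcium release units (CRUs) coupled to
deterministic bulk compartments, and asks how calmodulin (CaM) variants that
weaken Ca²⁺-dependent inactivation (CDI) of the L-type Ca²⁺ channel (LCC)
push the cell toward arrhythmia. This vignette is the package's account of
the model, its numerical scheme, the calibration of every constant the
underlying publication record does not pin down, and what the reduced-scale
test suite does and does not demonstrate.

## The model

**Architecture.** A full-scale cell contains 20,000 independent CRUs; each
CRU couples a dyadic subspace (volume `v_ds_pl`, default 10⁻⁶ pL) to its own
junctional SR (jSR) compartment and holds a cluster of 49 RyR2 channels and
7 LCCs. CRUs interact only through the bulk variables (myoplasmic Ca²⁺,
network-SR Ca²⁺, membrane potential) — there is no spatial coupling and hence
no Ca²⁺ wave propagation. Desk-scale runs simulate `n_cru` units and weight
every CRU-to-bulk flux by `n_cru_full / n_cru`, so the bulk compartments see
a full-sized cell sampled by a smaller stochastic ensemble.

**LCC.** Six states C1, O2, O3, C4, C5, C6 (O2/O3 conduct). The channel
rests in C6 at −84 mV, is primed to C1 and opened to O2 by depolarisation,
and is pushed toward O3 by strong depolarisation. Closing during the action
potential is dominated by CDI, the transition O2 → C4 with rate

```
rate(O2 -> C4) = cdi_factor * k24 * [Ca:CaM]_dyad,   k24 = 8 s^-1 uM^-1
```

Voltage-dependent inactivation (O2 → C5) is slower, and the O2 → C1
deactivation rate is made voltage dependent: it is thermodynamically very
small at depolarised potentials (where inactivation does the closing) and
fast on repolarisation, which is what terminates the late window current.
All voltage-rate coefficients are exponentials `a·exp(±v/b)` with calibrated
constants (`lcc_params()`); the published anchors are the topology, `k24`,
the two-Ca²⁺ CDI stoichiometry and the channel counts.

**CDI effector.** Dyadic Ca:CaM is a dynamic state with mass-action kinetics
carrying the two-Ca²⁺ stoichiometry,

```
d[Ca:CaM]/dt = k_on * Ca_ds^2 * (CaM_T - [Ca:CaM]) - k_off * [Ca:CaM]
```

with the published constants CaM_T = 24 µM, k_on = 30, k_off = 71.4. The
O2 → C4 rate uses the instantaneous dyadic [Ca:CaM] in µM, so `k24`'s units
(s⁻¹µM⁻¹) are respected and the Ca²⁺ cooperativity lives entirely in the
binding step.

**Variants.** A CaM variant is expressed as a multiplicative factor on `k24`.
For a variant with Ca²⁺-binding affinity K (µM), the factor is the ratio of
variant to wild-type steady-state bound fractions at a dyadic Ca²⁺ of 10 µM:

```
factor = (Ca^2 + K_WT) / (Ca^2 + K),   Ca = 10 uM,  K_WT = 2.5 uM
```

Note the dimensional convention: the mass-action scheme above makes the
equilibrium constant carry µM², yet the printed variant factors are only
recovered when each affinity enters at its printed µM value against Ca² in
µM². The package adopts that numeric convention (`cdi_factor_from_affinity()`)
because it reproduces the published factor table exactly (e.g. 0.74 for the
D96V affinity of 38 µM, 0.41 for D130G at 150 µM); the inconsistency is
flagged here rather than silently resolved. The pacing experiments use the
rate-scaling mutants mut90 (0.90·k24) and mut75 (0.75·k24), which the source
work maps onto N98S/F142L- and D96V-like CDI deficits.

**RyR2.** Two states per channel. The opening rate is
`k_open_base · H(Ca_ds) · L(Ca_jsr) · (1 + c·f_open)` with a Hill activation
H (half-activation 25 µM, cooperativity 2), a saturating luminal factor L
(floor 0.05, half-saturation 700 µM, cooperativity 4) and mean-field coupled
gating in the cluster open fraction `f_open`; the closing rate (120 s⁻¹) is
Ca²⁺-independent. The luminal factor keeps rising well above the normal
diastolic jSR load, which is what lets an overloaded store sensitise
spontaneous release (the Ca²⁺-overload mechanism). The release flux is a
per-open-channel driving-force term `nu_ryr · (Ca_jsr − Ca_ds)`; the
per-channel (rather than cluster-lumped) conductance is a documented choice,
as the source record does not specify the law.

**Buffers.** The dyad carries three dynamic buffers: CaM (above, 2 Ca²⁺ per
complex), a sarcolemmal and an SR-membrane buffer (single-site mass action,
calibrated constants). The bulk myoplasm has a single lumped single-site
buffer sized to give a buffering ratio near 100 at diastolic Ca²⁺; jSR
calsequestrin is folded into a constant free fraction `beta_jsr = 0.1`.

**Membrane.** The sarcolemmal current set (fast Na⁺ current with
Hodgkin–Huxley gates, rat-like transient-outward and steady-state K⁺
currents, inward rectifier, Na/K pump, 3Na:1Ca electrogenic exchanger,
background leaks, sarcolemmal Ca²⁺ pump) is a functional stand-in with every
constant exposed in `default_params()$membrane`: the full parameterisation of
the parent whole-cell model is not printed in the source. It was calibrated
to (a) a stable resting potential near −84 mV, (b) a brief rat-like action
potential (APD90 ≈ 80 ms at 1 Hz), and (c) a stable 1 Hz wild-type transient
train. Positive exchanger current is Ca²⁺-entry (reverse) mode, so the early
AP shows the positive exchanger peak and diastole the negative (forward,
extruding) plateau. SERCA uptake carries a thermodynamic load ceiling
`(1 − (Ca_NSR/nsr_max)^4)`, which bounds SR loading and creates the
store-overload regime the variant experiments probe. Ito recovery from
inactivation is slow at negative potentials (τ ≈ 65 ms), as in rat.

**Non-junctional DHPR.** 15% of L-type channels sit outside the dyads and
feed the bulk directly; they are modelled as a deterministic influx
proportional to that fraction with a sigmoidal voltage activation
(`nonjunctional_dhpr_flux()`).

**Beta-adrenergic stimulation** scales the L-type (and non-junctional) Ca²⁺
flux by 1.2 and SERCA by 1.3 (published values; `protocol(beta_adrenergic =
TRUE)`).

## Numerics

The coupled system advances by explicit Euler with per-step stochastic
channel updates: each LCC transitions with probability `1 − exp(−rate·dt)`
(one uniform per channel per step), and RyR2 opening/closing counts are
exact binomial draws by CDF inversion. Two stiff subsystems use exact
exponential relaxation instead of a forward-Euler increment: the dyadic
Ca:CaM step (whose relaxation rate `k_on·Ca² + k_off` reaches ~10⁶ s⁻¹ inside
a spark, far beyond the Euler stability bound at practical step sizes) and
the Hodgkin–Huxley gates (Rush–Larsen update). Both are exact for the frozen
coefficients of one step and conserve mass to rounding; Ca²⁺ bound by CaM is
booked as two ions per complex, so total-calcium conservation closes to
floating-point accuracy (the engine records a running audit that the tests
check at 10⁻⁶ relative).

**Adaptive timestep.** The controller enforces the rule that at most 10% of
CRUs may change channel state in one step: a violating trial step is
discarded and redrawn at half the step (the random streams are deterministic,
so this is reproducible). Accuracy violations — a relative concentration
increment above 20% or a voltage step above 0.5 mV — do not reject the step
but halve the next one. This asymmetry is deliberate: rejecting on
increment would systematically censor the rare spontaneous channel openings
that cause the increment (the redraw at smaller dt usually "un-fires" the
event), visibly suppressing the spark rate. Steps that would drive any
concentration negative are rejected outright. Desk presets run between
`dt_min = 10⁻⁷ s` and `dt_max = 2·10⁻⁵ s` (the full-scale source scheme uses
10–100 ns; at a few hundred CRUs the binding control is the 10% rule, which
the engine audits — paced desk runs accept no step over the rule).

**Random numbers.** Each release site owns an independent splitmix64 stream
derived from the run seed, replacing the GPU-specific generator of the
full-scale implementation. Identical (protocol, parameters, seed) give
bit-identical trajectories; the repeat-seed protocol (6 seeds in the source
experiments) is exposed through `run_experiment_grid(seeds = 1:6)`.

## Analysis definitions

* **Sparks** (`detect_sparks()`): a spark starts when dyadic Ca²⁺ rises above
  25 µM and ends when it next falls below 5 µM (published thresholds), with
  linearly interpolated crossing times. Events in progress at either end of
  the analysis window are discarded, biasing mean durations slightly short.
  Time-to-peak is measured from the start-threshold crossing to the peak
  sample — the source's definition is not stated, and this reading is
  flagged. Spark analysis defaults to the retained 10% of CRUs and the final
  second of a run, as in the source protocol.
* **Spark frequency** is reported in three conventions (per CRU per second,
  whole-cell per second scaled to 20,000 CRUs, and pooled sparks per ms over
  the analysed subset) because the published table's unit is ambiguous.
* **APD** (`apd_metrics()`): per beat, the diastolic potential is taken just
  before the stimulus and APD at fraction f is the time between crossings of
  `v_dia + (1−f)·amplitude` (APD90 = 90% repolarisation), interpolated
  between samples; beats that never repolarise before the next stimulus are
  censored at the cycle length and flagged. The **alternans index** is the
  mean absolute successive APD difference over the mean APD (reported per
  fraction; APD80 is the headline number because fast-pacing APs do not
  always reach 90% repolarisation).
* **Welch's t-test** (`welch_ttest()`) implements the unequal-variance
  statistic and Welch–Satterthwaite dof directly and reports Cohen's d
  alongside the p-value: simulated spark counts are so large that tiny mean
  differences reach significance, so effect sizes carry the interpretive
  weight.

## Calibration and study conditions

Constants the source record does not print are `"calibrated"` in
`param_provenance()` and were fixed, once, against these targets:

* resting state: v ≈ −84 mV, myoplasmic Ca²⁺ ≈ 0.11 µM, NSR ≈ 1000 µM,
  dyadic Ca²⁺ roughly 100-fold above myoplasmic during release;
* spontaneous sparks at rest: duration on the ~22 ms scale (the regression
  test freezes a 14–35 ms band around the calibrated 23 ms mean), amplitudes
  on the ~130–150 µM scale, ~0.2–0.3 sparks CRU⁻¹s⁻¹;
* a stable 1 Hz wild-type train (diastolic 0.10 µM, systolic ≈ 0.9 µM) and a
  rat-like AP.

The reduced-scale study conditions used by the acceptance suite are fixed:
200-CRU ensembles, 10 s runs, final 4 s analysed, paired seeds {2, 5} (the
1 Hz contrasts, whose margins are wide, use seed 2 alone). The
alternans-positivity threshold is 0.1 on the APD80 index: the stochastic
jitter floor of a regular 200-CRU train sits near 0.05–0.08, and the severe
mutant's index during the 6 Hz overload transition sits above 0.15.

## What the desk-scale tests show — and what they do not

The quantitative outputs of the full-scale study (spark tables, trace
magnitudes) depend on a complete parent-model parameterisation and
20,000-CRU GPU ensembles and are out of reach here; the suite instead checks
directionality under the fixed study conditions: more spark activity with
pacing and with CDI severity; higher diastolic/systolic Ca²⁺ and NSR loading
with severity, amplified by pacing; longer APD50/APD90 with severity at
4 Hz; mutant-specific loss of normal EC coupling at high rate (6 Hz
alternans-index separation; diastolic Ca²⁺ failure under beta-adrenergic
4 Hz pacing while wild type retains a regular train); larger integrated
L-type current and slower exchanger recovery for the mutant under
beta-adrenergic stimulation.

Known limitations. The mutant's high-rate abnormality here manifests as a
Ca²⁺-overload transition (climbing diastolic Ca²⁺, depressed, drifting
transients) rather than the clean period-doubling APD alternans the
full-scale model shows at 6 Hz: restitution-driven period-2 dynamics did not
emerge at a 200-CRU scale for any explored combination of refill-limited
release, deeper release geometry or slow-Ito restitution, and the milder
mutant (0.90·k24) stays at the wild-type jitter floor at this ensemble size.
No bi-lobal (N/C-lobe) CDI decomposition, no CaM–RyR2 interaction, no
state-dependent CaM–channel binding, no spatial Ca²⁺ waves, no tissue-level
electrophysiology; the membrane current set is a calibrated stand-in, not a
parameter-faithful reproduction of the parent model. Conclusions about real
myocytes should lean on the directionality of the comparisons, not on any
absolute number this reduced model prints.

## Reproducing the experiment grid

```{r}
library(crusim)
res <- reproduce_paper_grid("repro", preset = "desk-small", seeds = 1:6)
res$checks          # pass/fail table of the trend properties
```

`desk-small` (200 CRUs, 6 s, 6 seeds) covers wild type and both rate-scaling
mutants at 1/2/4/6 Hz with and without beta-adrenergic scaling and writes
the tidy summary, a trend report and a reproducibility manifest. The same
grid is reachable from a shell via `exec/crusim reproduce`.
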