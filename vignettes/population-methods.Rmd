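---
title: "Populations of hiPSC-CM models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Populations of hiPSC-CM models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`hipscpop` simulates the spontaneous action potential (AP) of a
ventricular-like human induced pluripotent stem cell-derived cardiomyocyte
(hiPSC-CM) as a 20-state stiff ODE system. The equations follow the
published Paci-family hiPSC-CM model lineage (itself built on the
ten Tusscher human-ventricular formulations): Hodgkin–Huxley currents
I_Na (m³hj), I_CaL (GHK flux with d·f1·f2·fCa gating), I_Kr, I_Ks, I_K1,
I_f, I_to, the pumps/exchangers I_NaK, I_NCX, I_pCa, background Na⁺/Ca²⁺
leaks, and a two-compartment Ca²⁺ subsystem (cytosol + SR with uptake,
leak, and a gated release). There is no stimulus current: depolarisation is
intrinsic (I_f, window I_CaL, NCX), which is what makes quiescence — a cell
that stops producing APs — a meaningful, detectable outcome rather than a
protocol artefact. Voltage is carried internally in volts (the convention
of the source model family); every user-facing trace and biomarker is in mV
and ms.

Exact coefficients of the source models were reconstructed from the
published lineage; where a coefficient could not be recovered verbatim the
parent formulation was used and the assembled model was validated against
its observable behaviour: spontaneous rate ≈ 38 beats/min, MDP ≈ −76 mV,
peak ≈ +23 mV, V_Max ≈ 21 V/s, APD90 ≈ 456 ms for the baseline control
cell — squarely inside reported hiPSC-CM ranges.

### The late sodium current and the V1763M variant

I_NaL is deliberately simple (the alternative Markov-chain channel models
are out of scope): one activation gate `mL` (sharing the fast-Na activation
time constant) and one slow inactivation gate `hL` (τ = 200 ms), with

    I_NaL = g_NaL · mL · hL · (V − E_Na),  g_NaL = 58 S/F (baseline).

The LQT3 V1763M gain-of-function variant is expressed through three named
parameters (`mut_gNaL_scale = 1.33`, `mut_hL_shift_mV = +2`,
`mut_tau_hL_factor = 10`). A pure conductance scaling or availability shift
cannot reproduce the mutation's phenotype in this model family: a current
that still inactivates with τ = 200 ms has largely vanished by the late
plateau, where APD90 is decided. Slowed inactivation — the canonical LQT3
kinetic lesion, i.e. a persistent current component — is therefore the
third knob. The three values were calibrated against the two observable
constraints the mutation must satisfy (they are *not* free parameters): a
4.86-fold persistent I_NaL, sampled 200 ms after the instant of maximum
upstroke velocity of a steady spontaneous AP, and ≈ +43 % APD90
prolongation of the baseline cell. The 200-ms measurement is implemented as
a configurable protocol (`persistent_inal(result, delay_ms)`); because the
cells are unstimulated, the upstroke (max dV/dt) serves as the reference
instant that a paced protocol would take from the stimulus.

## Numerical method

No ODE-solver package is available to this package, so the integrator is
built in C++: gates advance by the Rush–Larsen exponential update (exact
for frozen voltage, unconditionally stable — this removes the microsecond
gate stiffness), voltage and concentrations by forward Euler, with
step-doubling (Richardson) local-error control and local extrapolation.
Error weights mix a relative tolerance with per-state typical magnitudes
(default `rtol = atol = 1e-5`); steps are capped at 1 ms so diastolic
depolarisation is never jumped over. Gates are clamped to [0, 1] and
concentrations to positive values after each step; a step-size collapse or
non-finite state yields an explicit `failed` status, distinct from
quiescence. Determinism is absolute: no randomness enters the integration,
and identical settings reproduce traces bit-for-bit. Self-convergence is
asserted in the test suite: halving both tolerances moves steady-state
APD90 by well under 1 ms.

Steady state: every simulation runs `duration_s` (default 800 s) and
analyses only the final `window_s` (default 30 s); convergence is declared
when the last three beats' APD90 spread is below 5 ms. The initial state
shipped with the package is the baseline control cell frozen after a
2000-s pre-run, so the default protocol starts essentially converged; the
residual slow drift (minutes-scale Na⁺ loading) is why the calibration of
the mutant knobs was done against the exact production protocol.

## Biomarkers

Per beat: MDP (minimum Vm), Peak, APA = Peak − MDP, V_Max (max dV/dt), and
APD_x measured from the instant of V_Max to the downward crossing of
`Peak − x/100·APA` (linear interpolation between samples). The V_Max
reference (rather than a threshold crossing) is the standard choice for
unstimulated APs and is configurable; APD levels are relative to the
per-beat APA, matching the MDP/Peak/APA definitions. The per-model summary
averages the last three beats to smooth residual beat-to-beat drift. Rate
is 60 over the mean upstroke-to-upstroke interval and requires at least two
detected cycles. Cycle detection requires an upward crossing of 0 mV with
a ≥ 40 mV excursion (both configurable); the amplitude floor is what
operationalises "stopped producing APs" against sub-threshold oscillations.

## Populations, calibration, transfection, classification

- **Sampling**: the 11 maximal conductances/permeabilities are scaled by
  independent factors drawn from [0.5, 2] (uniform, or Latin hypercube),
  the conventional ±2-fold variability interval of population-of-models
  studies; the interval is configurable.
- **Calibration**: a candidate is accepted iff it beats spontaneously and
  every biomarker named in the range table lies inside its inclusive
  [lower, upper] window. Inclusive bounds mean borderline models cannot
  flip under round-off. The shipped control ranges
  (`ranges_synthetic_control.csv`) are *synthetic stand-ins*: plausible
  spans assembled from the published hiPSC-CM literature, not the
  experimental tables the original study used (those live in its
  supplement). Quantitative acceptance fractions therefore differ from the
  study's 1,463/10,000.
- **Transfection**: the mutant population re-simulates every accepted
  control model with the V1763M I_NaL and *identical* scale factors; no
  re-calibration, preserving the 1:1 ancestry map. Models that fall silent
  are excluded but logged by id, so |control| = |mutant| + |quiescent| +
  |failed| always holds.
- **Classification**: symptomatic iff APD90 exceeds the upper control
  calibration bound (i.e. repolarisation leaves the normal range); an
  explicit ms threshold can be supplied instead.

## Drug trials

Single pore block: factor `1/(1 + (dose/IC50)^h)` per targeted channel
(I_Na, I_NaL, I_Kr, I_CaL), constant in time (no use-dependent binding),
with per-genotype IC50 overrides (the mexiletine-like spec blocks mutant
I_Na harder than control). Hill defaults to 1 when a table gives only an
IC50. Every model re-runs from the shipped initial state at every dose;
stopped models are flagged by the quiescence detector and excluded from
ΔAPD90 aggregates (mean ± SD and medians, overall and per phenotype
label). The shipped mexiletine/ranolazine tables are labelled synthetic:
IC50s are literature-plausible, chosen before any trial was run, and stand
in for the supplement's assay-derived values. The fictitious `testdrug`
(pure I_NaL block, IC50 20 µM) exists so every drug-module test runs
without pharmacological claims.

## What the synthetic world does and does not establish

A green suite establishes: the baseline mutation effect (+43 % APD90,
4.86-fold persistent I_NaL — both computed, not asserted constants), exact
closed-form behaviour of the block model and biomarker extractor,
conservation/idempotence/anti-monotonicity of the population bookkeeping,
bit-exact seeded reproducibility, ODE self-convergence, and the
direction of the population-level effects (mutation prolongs APs across
the population; late-Na block shortens mutant APs dose-dependently and
most in high-g_NaL models; symptomatic models carry more I_NaL, less I_Kr
and less I_pCa). It does *not* establish the study-scale quantitative
aggregates (acceptance counts, ΔAPD90 milliseconds per dose, stopped
fractions), which depend on the experimental range tables and assay IC50s
that only exist in the original supplement.

Known limitations: with synthetic calibration the symptomatic/asymptomatic
contrast reproduces the I_NaL, I_Kr and I_pCa directions but not the
reported I_CaL (+27 %) and I_K1 (+14 %) contrasts (the I_CaL sign is
unstable across seeds here, I_K1 tends negative); the reconstructed base
model also weights I_NaK variability more heavily than the source study
reports. Scaled-down populations (tens of models, 100–120-s pre-runs) are
used in the tests for budget reasons and inherit extra beat-to-beat drift;
all assertions at that scale are ordering properties, not absolute values.
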