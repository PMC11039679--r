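---
title: "redoxtf: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{redoxtf: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(redoxtf)
```

## The biological problem

Cells discriminate between mild ("eustress") and severe ("distress")
hydrogen-peroxide exposure by activating different transcription-factor
programs: at low H2O2 the p53 group (p53, NRF2, JUN) accumulates, while at
high H2O2 the FOXO1 group (FOXO1, NF-kB, NFAT1) translocates to the nucleus
and p53 accumulation is blocked. In single-cell time-lapse data this
produces mutually exclusive activation at fixed timepoints, a two-phase
temporal response to acute (bolus) H2O2 — FOXO1 first, p53 only after FOXO1
exits the nucleus — and the reversed order under continuous enzymatic
production (glucose oxidase, GOX). `redoxtf` packages (a) a mechanistic
simulator that formalizes the peroxiredoxin-hyperoxidation explanation of
this switch, and (b) the trace-analysis pipeline (event detection,
event-aligned aggregation, windowed autocorrelation, quadrant
classification) needed to quantify those behaviors in simulated — or
schema-compatible real — single-cell traces.

## Model

Each cell carries six states: intracellular H2O2 `H`, hyperoxidized
2-Cys-peroxiredoxin fraction `P`, oxidative damage `D`, FOXO1 nuclear
fraction `F`, and a p53/MDM2 pair `(p, m)`.

**Exposure.** Bolus: `H` jumps to the dose at treatment time and decays,
`dH/dt = -k_clear * H`. Continuous: `dH/dt = v - k_clear * H` with
`v = k_gox * dose` (dose in mU/mL GOX; `k_gox` converts to
uM-equivalents/h). An optional production dip after the first hour
(`gox_dip`) is off by default because its magnitude is not constrained by
any measurement we reproduce.

**Hyperoxidation.** `dP/dt = k_hyp * H * (1 - P) - k_srx * s * P`, where
`s` is the SRXN1 activity multiplier (1 control, 0 J14 inhibition, > 1
overexpression). `P` is the two-threshold switch: while `P > theta_F` the
redox relay is collapsed — FOXO1 relaxes toward its nuclear plateau
(`dF/dt = (f_target - F)/tau_f`), p53 accumulation is frozen
(`dp/dt = 0`), and damage repair is suspended. A PRDX
capacity multiplier below 1 (knockout/knockdown) scales both `k_clear` and
`theta_F` down: less enzyme scavenges less H2O2 and constitutes a smaller
buffer that must be hyperoxidized.

**Damage and p53 drive.** `dD/dt = k_dmg * H + k_dmg_P * 1(P > theta_F)
- k_rep * D * 1(P < theta_F)`. The `k_dmg_P` term makes damage accrue while
the antioxidant relay is lost even after exogenous H2O2 is gone; the
repair gate ties damage resolution to relay recovery. Both choices are the
minimal coupling that lets SRXN1 inhibition convert a mildly lethal bolus
into a highly lethal one while leaving the unperturbed dose-response
intact. p53 production is driven when
`u = D * 1(P < theta_F) + k_srx * P > theta_p`; the repair-flux term
`k_srx * P` means SRXN1 overexpression (which keeps `P` low) also reduces
drive at low dose. Drive acts after a dead time `tau_act` (~0.7-1.2 h),
representing the signaling delay between relay reactivation and p53
stabilization; this is what produces the ~1 h lag between FOXO1 nuclear
exit and detectable p53 accumulation.

**p53/MDM2 oscillator.** `dp/dt = beta_p * (p_basal + a(t - tau_act)) -
alpha_p * m * p` and `dm/dt = gamma_m * (m_basal + hill(p(t - tau_delay)))
- delta_m * m`, with `hill(x) = x^4 / (K_m^4 + x^4)`. The Hill nonlinearity
in delayed MDM2 induction is required for a sustained limit cycle (a linear
delayed feedback of this form is unconditionally stable because the
delayed-gain and decay terms are pinned to each other at the fixed point).
Defaults give a period of about 5.5 h and a 2-5x peak-to-baseline
excursion, matching the canonical p53 pulsing phenotype.

**Death.** Hazard `lambda(t) = lambda_0 + lambda_d * max(0, D - D_c)`;
each cell draws an Exp(1) quantile and dies when the integrated hazard
crosses it. `lambda_0` is a small treatment-independent background hazard
(~1% per 24 h), the rate seen in otherwise healthy imaged cohorts. Because
damage accrues mostly while `P > theta_F`, death risk is governed by how
long FOXO1 stays nuclear — which is also why simulated death fractions rise
steeply with bolus dose and why blocking SRXN1 (FOXO1 nuclear until movie
end) is so lethal.

**Heterogeneity and noise.** Per-cell lognormal multipliers (unit mean,
CV `cv_cell`) are applied to `k_hyp`, `k_clear`, `theta_F` and `D_c`.
`theta_F` receives half weight (CV `cv_cell / 2`): the hyperoxidation
threshold reflects PRDX/SRXN1 stoichiometry, which we take to be less
variable than kinetic rates; with full weight the low-dose activator pool
is dominated by low-threshold cells whose long residence times would break
the observed monotone duration-dose relation. Measured channels get
multiplicative lognormal noise (SD `sigma_meas`), and the nuclear fraction
is clipped to [0, 1].

## Numerical choices

* Fixed-step RK4 at `dt = 1` min for cell simulations; the two delay terms
  use sample-and-hold lookups into per-step history buffers. A fixed step
  keeps populations bitwise reproducible and the system is not stiff at
  this resolution. The standalone linear-subsystem operations
  (`simulate_h2o2()`, `simulate_prdx()`) use substeps of at most 0.5 min so
  they agree with closed forms to better than 1e-6 relative error.
* Per-cell RNG streams are derived from `(seed, cell_index)` by a fixed
  affine counter map, so cell `i` is identical no matter the population
  size and populations are order-independent.
* The basal p53/MDM2 state is computed by fixed-point iteration and used as
  the initial condition and the delay-history value before t = 0.
* `P` is clipped to [0, 1] and all states floored at 0 after each step;
  non-finite states abort with the offending parameter set named.

## Detection conventions

FOXO1 episodes use hysteresis thresholds on the running-median-smoothed
nuclear fraction: entry at the first of `persistence = 2` consecutive
frames at or above `foxo_hi = 0.55`, exit at the first of 2 consecutive
frames at or below `foxo_lo = 0.45`. The numeric values are not dictated by
any published gating rule (the study's figures show dashed thresholds
without printing them); these defaults cleanly separate the simulator's
bimodal populations and are configurable. p53 onset uses
baseline + max(3 x MAD, 15% of baseline) sustained for 3 frames (1 h at
20-min sampling). The relative floor is ours: a MAD estimated from three
frames collapses to near zero often enough that the pure MAD rule calls
onsets on measurement noise. Events are detected on pre-death samples only;
an episode still open at death is counted to the death frame.

Autocorrelation windows follow the FOXO1-conditioned rule: first 10 h for
cells that never accumulated FOXO1, the 10 h after FOXO1 exit otherwise;
open episodes exclude the cell, and windows clipped by death or movie end
are flagged truncated. The sample ACF normalizes by the window variance
(`r(0) = 1`). A linear detrend is applied before correlating (on by
default, toggleable): post-exit p53 rises monotonically in many cells and
would otherwise masquerade as long-lag structure. The oscillation score is
the maximum autocorrelation in the 3-8 h lag band; the call threshold is
`max(0.2, 2/sqrt(n))`, with 0.2 chosen against simulated oscillatory vs
sustained-rise traces.

## Calibration

Dose units are a labeling convention: bolus dose 100 means the condition
labeled 100 uM. Fixed kinetic constants (`k_clear = 2.3`/h for sub-2-h
clearance; `k_hyp`, `theta_F`, `k_srx` placing the FOXO1 activation
threshold between 50 and 80 uM with a within-1-h entry at 100-300 uM and
repair on the hours scale; `tau_act` reproducing the ~1 h exit-to-onset
lag) were set from the timing constraints. The death submodel —
`lambda_d`, `D_c`, `k_dmg`, `cv_cell` — was then fitted with
`calibrate_death_model()` (Nelder-Mead on probit-scale squared error)
against six cohort death fractions: bolus 50/80/100/300 uM-equivalent at
1/11/34/97% and continuous 0.5/2 mU/mL at 27/97%; `k_dmg_P` and `k_gox`
were chosen alongside so that the SRXN1-inhibition death shift and the
continuous-mode fractions are reproduced simultaneously. The shipped
defaults of `kinetic_params()` are the result. Two systematic residuals are
acknowledged: at the highest bolus and GOX settings the model kills
essentially every cell (printed values: 97%), because the surviving few
percent in the data presumably reflect exposure outliers the model does not
represent; and the 1% death printed at 50 uM corresponds to an expected
~1 in 100 cells, so individual simulated cohorts of n = 188 fluctuate
between 0 and 3 dead cells.

## What the generator does and does not emulate

Emulated: 20-min sampling over 24 h; dose-dependent bimodal activation at a
5-h snapshot; bolus two-phase dynamics with duration-sorted heatmap
structure; GOX entry-time-sorted dynamics with p53-first ordering and the
p53 plateau (zero derivative) while FOXO1 is nuclear; perturbation
directions for SRXN1-OE (activation threshold up), J14 (prolonged FOXO1,
delayed p53, increased death), PRDX1-KO/PRDX2-KD (threshold down);
dose-dependent death with duration-linked risk; lognormal measurement
noise. An optional cell-density dose attenuation
(`density_coupling`) is off by default.

Not emulated: segmentation/tracking artifacts, photobleaching and focus
drift, cell division and lineage effects, spatial H2O2 gradients, explicit
thioredoxin/NADPH pools (lumped into `k_srx` and the relay terms), and any
transcriptome-level readout. Passing tests therefore demonstrate that the
pipeline recovers the statistics of an idealized population with the
study's qualitative structure — not that it is robust to the full artifact
spectrum of real imaging data.

## Problem sizes

The test suite simulates populations of tens to a few hundred cells per
condition, which resolves the cohort statistics it asserts (death
fractions, medians, ordering fractions) at binomial noise of a few percent.
The acceptance script uses the printed cohort sizes where the study prints
them (n = 186-288 per bolus dose, 176/195 for GOX) and 500-2000 cells
where it states only "n >= 2000" or no size.

## Known limitations

* The activation dose-response saturates: essentially every simulated cell
  activates FOXO1 at 300 uM-equivalent, so the model cannot produce the
  ~3% survivor tail printed at the top doses.
* All ODE forms are the simplest consistent formalization of the proposed
  mechanism, not fitted biochemistry; rate constants are effective, not
  measured.
* The quadrant classifier's control-quantile gate implies a ~5% per-channel
  false-positive rate by construction. At a dose where one channel is
  active in essentially every cell, the expected both-active fraction is
  therefore very close to 5% (and slightly above it at intermediate doses,
  where the two activated subpopulations each contribute their
  opposite-channel false positives). A reported maximum both-active
  fraction of 5.0-5.5% is thus the faithful output of this gating rule,
  not evidence of genuine co-activation; gates drawn conservatively in
  the bimodal gap, as in manual practice, would report lower values.
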