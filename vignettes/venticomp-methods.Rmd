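---
title: "Simulated versus real newborn ventilation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated versus real newborn ventilation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venticomp)
```

## The problem

Positive-pressure ventilation (PPV) of a non-breathing newborn is usually
delivered with a flow-driven T-piece resuscitator through a face mask, and a
respiratory function monitor (RFM) at the mask records airway pressure and
gas flow breath by breath. Training manikins aim to reproduce the conditions
a provider meets clinically: a lung whose compliance changes as functional
residual capacity (FRC) is established, large and variable mask leak, and
occasional upper-airway obstruction. `venticomp` implements the full
comparison pipeline for evaluating such a manikin against real newborn
ventilation when both are ventilated at standard settings (set PIP 30 mbar,
PEEP 5 mbar, 8 L/min): a waveform simulator for both recipients, the RFM-style
per-inflation measurement chain, the duration-matched pairing design, and the
longitudinal statistics used to compare the four groups
(manikin/baby x short/long).

Because the clinical recordings behind such comparisons are not public, the
simulator is a first-class component here: it generates waveforms with the
statistical structure the analysis assumes, together with ground-truth logs
(injected leak fractions, compliance trajectories, obstruction windows) so
that every measurement operation can be scored against what was injected.

## The waveform model

Each inflation is a single-compartment linear lung with compliance $C$
(mL/mbar) and resistance $R$ (mbar/(mL/s)), driven by a square airway
pressure wave that moves between the delivered PEEP and PIP with short
exponential transitions ($\tau_\text{rise}=35$ ms, $\tau_\text{fall}=50$ ms;
chosen so the flow discontinuities at phase switches are resolved by the
100 Hz grid and trapezoidal volume integration is accurate to well under 1%).
Lung volume above the end-expiratory equilibrium follows
$\dot V = (P_\text{drive} - V/C)/R$, solved exactly per sample for
piecewise-constant drive.

Mask leak is modelled with two coupled mechanisms:

* a **leak flow** component during inspiration, sized so that the standard
  leak formula $100\,(V_{T,\text{insp}} - V_{T,\text{exp}})/V_{T,\text{insp}}$
  recovers the injected per-breath leak fraction exactly (leak occurs mainly
  during inflation, so expired volume estimates the true tidal volume);
* a **droop** of the lung-driving pressure amplitude, proportional to the
  leak fraction (coefficient 0.5 by default). The airway pressure recorded at
  the sensor still reaches set PIP — consistent with the observation that a
  T-piece achieves its set pressure independent of leak unless the leak is
  extreme — but the volume actually delivered falls as leak grows. The
  coefficient was set so that the extracted leak-versus-eV$_T$ relationship is
  strongly negative (Pearson $r \approx -0.9$ in manikin short sequences),
  matching the strong negative coupling reported for such data; without it
  the generator fails to emulate the documented relationship.

Per-breath parameters jitter around their targets. Achieved PIP jitters
one-sidedly below the set value (a T-piece caps delivered pressure), with a
baseline SD of 0.3 mbar scaled by a subject-level factor (1 for the manikin,
5 for babies), reproducing the much larger dispersion of clinical PIP and
eV$_T$. PEEP jitter (SD 0.8 mbar) is deliberately not scaled: PEEP spread is
similar in manikin and baby ventilation. Gaussian sensor noise (pressure
0.1 mbar, flow 1.5 mL/s) is added to every sample.

The **manikin** lung hides its compliance behind a valve: while closed the
effective compliance is near zero, so inflations reach target PIP with almost
no tidal volume and no chest rise; the valve opens abruptly once a threshold
number of adequate inflations (achieved PIP at least 0.9 x set PIP; the
adequacy criterion is not specified by the device, so it is a configuration
key) has accrued — 10 for the hardest scenario, 0 for the easiest. Scenario
S1 (normal compliance 0.5 mL/mbar, compensated heart rate 120 bpm) requires
30 s of optimal PPV to reach baby-cry; S4 (valve-gated, post-opening
compliance 0.65 mL/mbar, decompensated heart rate 60 bpm) requires 90 s. The
scenario clock credits only adequate inflations and accrues continuously, so
under optimal PPV success lands on the scenario constant exactly, while
suboptimal PPV (a configurable fraction of inflations rendered ineffective)
takes strictly longer. The heart rate rises logistically toward 160 bpm with
cumulative effective PPV — only this qualitative behaviour is modelled; the
real device's heart-rate algorithm is proprietary.

The **baby** lung establishes FRC: effective compliance ramps as
$1 - e^{-0.15\,(i-1)}$ over breath index $i$ from 25% of its plateau
(0.55 mL/mbar, subject-jittered), putting ~95% of the plateau at breath 20 to
match the reported progressive eV$_T$ rise over the first twenty ventilations.
Babies also carry occasional spontaneous-effort flow artefacts
(2 events/min, brief sine-shaped blips, which can push expired above inspired
volume and exercise the negative-leak clamp), probabilistic pauses over 5 s,
and a gradual end transition: over the final three inflations delivered PIP
and PEEP fade (x0.85, 0.75, 0.65) while the leak fraction rises (+0.15,
+0.25, +0.35), reproducing the loosely-held mask while spontaneous breathing
is assessed. The manikin's transition is abrupt: pressures are maintained to
the last inflation.

Mask leak per breath is `mean + drift x (i-1) + N(0, sd)` clamped to
[0, 0.95]: manikin mean 0.35, baby mean 0.50 (SD 0.25/0.28), both with drift
-0.002 per breath, modelling leak-reducing adjustments; this yields the lower
median leak in long versus short sequences. Defaults were fixed once, from
the qualitative description of the data (large and variable leak, medians
of roughly 20-50%), and are exposed as configuration.

Simulated studies use 18 providers by default, each contributing one S1 and
one S4 manikin episode plus duration-shadowed baby episodes (target duration
within +/-6% of the manikin episode, comfortably inside the +/-15% pairing
tolerance). Obstructions are injected per sequence with probability 4/36
(manikin) and 7/36 (baby) — the observed per-sequence occurrence rates in the
study design being emulated — as 3-5 consecutive inflations whose flow is
attenuated to 2% while pressure is untouched.

## The measurement chain

Segmentation thresholds the pressure trace at a baseline-PEEP estimate (10th
percentile) plus `min_rise` (5 mbar); each window runs from one onset to the
next, containing one inspiration and its expiration. Per window: PIP is the
maximum pressure; PEEP is the median of the last 20% of the expiratory
segment, flagged if the decay has not settled into a plateau (the commercial
monitor's extraction algorithms are undocumented, so these estimators are
defined here and validated by parameter recovery); volumes are trapezoidal
integrals of positive/negative flow after converting mL/min to mL/s; leak is
the clamped percentage formula, with expired-exceeds-inspired clamped to zero
and flagged (raw value retained) and zero inspired volume flagged as
undefined rather than an error; eV$_T$ is expired volume over weight, with
manikin sequences normalised by 3.14 kg, the median birth weight of the
newborns behind the manikin's heart-rate algorithm.

Pauses are onset-to-onset gaps exceeding the typical (median) cycle by more
than 5 s; total PPV time is the ventilated span minus pause durations. The
pause anchor (onset-to-onset) is a definition made here; the source design
only states that pauses over 5 s are excluded.

Obstruction calls require at least three consecutive inflations with eV$_T$
below 1 mL/kg despite achieved PIP at least 0.9 x target, with at least one
adjacent inflation achieving at least half the sequence-median eV$_T$. Both
thresholds are configuration keys ("minimal" flow and "target" PIP are not
quantified in the design). A qualifying run that starts at the very first
inflation is attributed to the not-yet-aerated lung — the manikin's closed
valve produces exactly this signature during the S4 run-in — and is not
reported as obstruction by default (`ignore_leading = TRUE`), because no
preceding typical inflation exists.

## Pairing and groups

Each manikin sequence is paired with the first not-yet-used pool sequence
whose total PPV time is within 15% (relative to the manikin duration; the
referent is not specified in the source design, so the manikin denominator is
a documented choice). Greedy first-fit in pool order operationalises
consecutive allocation and makes the pairing deterministic given input order.
Duration class is assigned by scenario (S1 short, S4 long), not by realised
duration, since suboptimal PPV lengthens realised times by design.

## Statistics

**Median/IQR** summaries pool all per-breath values per group.

**Panel comparison.** `value_it = alpha + beta * group_i + u_i + e_it` is
fitted by feasible GLS with Swamy-Arora variance components (one-way random
effects): the idiosyncratic variance from within-subject residuals, the
subject-level variance from the between regression, quasi-demeaning by
`theta_i = 1 - sqrt(s2_e / (T_i s2_u + s2_e))`. The group contrast's variance
uses a Newey-West HAC estimator (Bartlett weights, autocovariances
accumulated within subjects only) on the quasi-demeaned residuals, with the
standard bandwidth `floor(4 (T/100)^(2/9))`; p-values use a t reference with
`n_subjects - 2` degrees of freedom. Degenerate (non-positive) subject-level
variance falls back to pooled OLS with a warning — also the exact limit of
the transformation. Monte-Carlo checks in the test suite show nominal size
(~0.05) under the model's own null. A known limitation, measured during
development: under strongly serially correlated errors (AR(1),
$\phi = 0.5$) the truncated-lag HAC on quasi-demeaned data *over*-estimates
the contrast variance (demeaning induces negative autocovariance at long
lags), making the test conservative rather than anti-conservative; power for
a 5 mbar offset at 18 subjects per arm still exceeds 0.8. An augmented
Dickey-Fuller screen (`adf_screen`) is available as an optional stationarity
diagnostic; it warns rather than gates, since no action on failure is
prescribed by the design being implemented.

**LOESS trends** use local linear fits with tricube weights and span 0.5
(`surface = "direct"`, so data on an exact line are reproduced exactly),
restricted to breath indices contributed by at least 5 of the group's
subjects; pointwise standard errors come from the local weighted residual
variance.

**Dynamical correlation.** Per subject, both curves are truncated to the
index range shared by all subjects (interior gaps linearly interpolated),
centred by their time average and scaled to unit L2 norm; the cross-subject
mean trend of the *standardised* curves is then removed and the curves
renormalised before taking the inner product; the population estimate is the
mean over subjects. Standardising before removing the mean trend is a
deliberate ordering: it makes the estimate exactly invariant to per-subject
positive-slope affine rescaling of the curves while keeping it in [-1, 1]
and equal to +/-1 for identical/negated curves; removing the trend first
would break that invariance. Subjects with a zero-variance curve (or a curve
coinciding with the mean trend) are excluded with a warning. Inference is by
bootstrap over subjects (1000 resamples by default; the mean trend is
recomputed inside each resample): percentile 95% CI, and a two-sided p-value
equal to twice the proportion of resampled estimates with sign opposite to
the point estimate, floored at `1/n_boot` — the design being implemented
does not state its bootstrap p-value convention, so this standard one is
used. Pearson correlations on pooled breath pairs are reported alongside for
comparability with the literature, with the caveat that repeated-measures
autocorrelation biases them.

**Obstruction occurrence** is compared with a Pearson chi-square on the 2x2
sequences-with/without-obstruction table, without continuity correction
(Yates correction available by flag).

## Worked example

```{r example, eval = FALSE}
res <- run_full_study(default_run_config(seed = 1, n_providers = 18,
                                         n_boot = 1000,
                                         out_dir = "venticomp_run"))
res$summary_table      # median (IQR) per parameter per group
res$correlations       # dynamical rho, bootstrap CI/p, Pearson r
res$obstruction        # 2x2 counts and chi-square
```

The run directory contains `breaths.csv` (every extracted inflation),
`pairs.csv`, `groups.json`, the two results tables, LOESS trend curves,
boxplot/trend/scatter figures and a `manifest.json` with the config hash —
reruns with the same config are byte-identical.

## Problem sizes, tolerances, degenerate inputs

The default study (18 providers, 72 episodes, ~3600 inflations at 100 Hz)
simulates and analyses in well under a minute; test-suite Monte-Carlo checks
use 300-500 replicates of 36-subject panels and bootstrap sizes of 200-300,
sizes at which the checked properties are stable. Numerical choices: exact
exponential state updates per sample; trapezoidal integration on the native
grid; breath windows backed up 5 samples before the threshold crossing to
catch the first instants of the rise; leak clamped to [0, 100] with flags
rather than errors; scenario S2/S3 parameters are nominal stubs (the study
design only exercises S1 and S4).

## What passing tests do and do not show

The generator reproduces the *structure* the analysis relies on — square
pressure delivery, flow-integrated volumes consistent with the leak formula,
FRC establishment, valve gating, pauses, obstruction signatures, and the
qualitative group contrasts (greater baby dispersion; higher eV$_T$ and lower
leak in long sequences). It does not reproduce real newborn physiology:
there is no airway-resistance heterogeneity, no genuine spontaneous
breathing interaction with the ventilator beyond flow artefacts, heart rate
is a nominal logistic curve, and the published clinical medians/correlations
derive from non-public recordings, so agreement with them beyond direction
and rough magnitude is not claimed — and the S4 closed-valve run-in visibly
attenuates pooled correlations for long manikin sequences, mirroring the
fidelity limitation noted for the physical manikin itself.
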