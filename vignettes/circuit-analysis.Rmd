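---
title: "Analyzing stress-circuit experiments: behavior, photometry, patch clamp"
author: "circuitphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing stress-circuit experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitphys)
```

# The problem this package addresses

Chronic social defeat stress (CSDS) splits defeated mice into two
phenotypes: *susceptible* animals that combine social avoidance with
anxiety-like behavior (AD), and *resilient* animals that show only the
anxiety-like component (A). Circuit studies of this paradigm combine four
very different data streams — video-tracked behavior, two-channel fiber
photometry of projection-specific dopamine activity, ex vivo patch-clamp
recordings, and cross-mouse correlation statistics. `circuitphys`
implements that full analysis chain as tested, reusable functions, together
with seeded synthetic-data generators whose latent structure is known, so
every stage can be validated against ground truth.

The scientific core the pipeline must reproduce is a *dissociation*:
dopamine-neuron firing covaries with anxiety-like behavior (time in the
open arms of an elevated plus maze) but not with the social-interaction
phenotype. The synthetic cohort is built with exactly that structure — a
single latent anxiety trait drives both open-arm occupancy and firing,
while the social-interaction ratio is drawn independently — and the
statistics stage is expected to recover it blind.

# Behavioral scoring

Trajectories are uniformly sampled center-point tracks inside an arena
whose named zones are unions of axis-aligned rectangles:

* elevated plus maze: 70 cm arms, 5 cm wide (`arena_epm()`), zones
  `open`, `closed`, `center`;
* open field: 44 × 44 cm with a 10 × 10 cm `center` (`arena_oft()`);
* social-interaction box: 44 × 44 cm with an interaction zone abutting the
  mesh-cage wall (`arena_si()`); the zone's 14 × 9 cm default is a
  configuration knob because no standard dimension exists;
* three-chamber apparatus: 44 × 17 cm chambers with 3 × 5 cm sniffing
  zones (`arena_three_chamber()`).

`zone_occupancy()` counts member samples per zone (closed boundaries;
when zones share an edge the first zone in the arena's declaration order
wins, which makes zone times exactly additive over a partition). An
*entry* is an outside-to-inside transition persisting at least 0.2 s —
a hysteresis against boundary jitter, since tracking software rules are
proprietary; initial placement inside a zone counts as one entry. Distance
is the summed Euclidean step length.

The indices follow the field's formulas: `si_ratio()` is
$100 \times t_{\text{target}}/t_{\text{no-target}}$ (undefined, not
fabricated, when the no-target time is zero), `sucrose_preference()` is the
consumed-fraction percentage, `fust_preference()` the urine/water zone-time
ratio. `classify_mouse()` maps stressed mice with SI ratio $\ge 100$ to A
and $< 100$ to AD; the boundary is inclusive on the resilient side.

# Fiber photometry

Recordings hold a calcium-dependent 490 nm channel and an isosbestic
405 nm control, decimated to 381 Hz. Processing follows the standard
isosbestic-regression chain:

1. `fit_control()` — ordinary least squares of the 490 signal on the 405
   control over the whole session; the fitted control absorbs bleaching and
   motion artifacts common to both channels. A constant control makes the
   fit singular; the function falls back to an intercept-only fit with a
   warning rather than failing silently.
2. `dff()` — $\Delta F/F = (F_{490} - F_{405,\text{fit}})/F_{405,\text{fit}}$
   per sample, then z-scored over the entire session for cross-mouse
   comparability.
3. `compartment_auc()` — trapezoidal integral of the z-scored signal over
   contiguous visits to each arena compartment. Because total AUC scales
   with the time spent in a zone, the per-second mean (`auc_per_s`) is
   reported alongside and is the default input to the correlation stage.
4. `detect_events()` — a sample is event-eligible when $\Delta F/F$ exceeds
   the session median by $2.91 \times$ the **raw** median absolute
   deviation. The multiplier only reproduces the intended approximate 95%
   Gaussian band if the MAD is unscaled: $2.91 \times 0.6745\,\sigma
   \approx 1.96\,\sigma$, which is why no 1.4826 consistency factor is
   applied, and why the threshold is centered on the median (the
   MAD-consistent center). Each supra-threshold excursion contributes one
   event at its maximum; a 0.5 s minimum inter-event interval (configurable)
   suppresses noise re-crossings within one transient.
5. `peri_event()` — epochs from −5 to +5 s around behavior onsets, z-scored
   *within the window*, then offset so each epoch's −5…−4 s mean is exactly
   zero; at most five epochs per mouse per onset label are kept (the first
   five chronologically — the selection rule is not standardized, and
   chronological order avoids any outcome-dependent choice). Onsets closer
   than 5 s to a record edge are skipped with a message.
6. `sliding_slope()` and `summary_bin()` — the 0.5 s sliding least-squares
   slope of the averaged trace, and the mean z in the −0.5…+0.5 s bin.

Event detection operates on $\Delta F/F$ before session z-scoring: the
threshold rule is stated in $\Delta F/F$ units, and z-scoring is a
monotone affine map so the detected set would be identical either way;
keeping the pre-z scale makes the stored threshold interpretable.

The synthetic generator (`gen_photometry()`) writes
$F_{490} = (B_{490} + \textstyle\sum_k k(t - t_k))\,b(t) + m(t) + \epsilon$
and $F_{405} = B_{405}\, b(t) + g\, m(t) + \epsilon'$, with a
double-exponential bleach $b(t)$, an AR(1) motion artifact $m(t)$ shared
between channels, and transient kernels
$k(t) = A (1 - e^{-t/\tau_r}) e^{-t/\tau_d}$ with $(\tau_r, \tau_d)$ =
(0.18, 1.4) s for GCaMP6s and (0.05, 0.40) s for GCaMP6f — typical sensor
kinetics; both are processed identically and are poolable. Transients
arrive as an inhomogeneous Poisson process whose rate rises during
open-arm occupancy, which is what couples photometry to behavior. With
default baselines ($B_{490} = 100$, $B_{405} = 80$, $g = 0.8$) the two
channels are affinely related up to noise, so the control fit genuinely
removes the artifacts (residual variance below 5% of the raw variance with
transients off) — the generator emulates the *correctable* artifact
regime; channel-specific bleaching that the linear fit cannot absorb is
representable (per-channel options) but is not the default condition, so
passing tests say nothing about sessions with severe wavelength-dependent
bleaching.

# Patch-clamp analysis

`detect_spikes()` high-pass filters (100 Hz Butterworth, zero-phase),
thresholds at 4 robust SDs (1.4826 × MAD) on the negative-going side,
requires a 0.2 ms minimum excursion width (single-sample crossings at
10 kHz are Gaussian-tail noise at this threshold), timestamps each
excursion at its extremum, and enforces a 2 ms refractory period.
`spike_trough_latency()` measures the onset-to-trough duration of the
average waveform; `classify_putative_da()` accepts units firing between 1
and 10 Hz with trough latency strictly greater than 1.1 ms.

Step protocols follow the recording conventions: excitability as 1-s
current steps from −100 to 280 pA in 20 pA increments
(`excitability_curve()`, `rheobase()` = smallest spiking step), Ih as 3-s
voltage steps from −120 to −60 mV in 10 mV increments from a −60 mV hold.
`ih_amplitude()` is the steady-state minus instantaneous current; the
measurement windows are not standardized, so the defaults — the final 10%
of the step versus a 20–60 ms post-transient window — are explicit,
configurable parameters. `sag_metrics()` reports both the sag amplitude
($V_{ss} - V_{peak}$ during a step hyperpolarizing the cell to about
−80 mV) and a normalized sag ratio
$(V_{ss} - V_{peak})/(V_{base} - V_{peak})$, since "sag ratio" lacks a
universal definition; a peak outside −90…−70 mV warns but does not abort.
`per_mouse_mean()` averages neuron features per mouse (unweighted), after
excluding units that fail the putative-dopamine criteria (overridable) —
correlations against behavior are computed at mouse level.

The simulator behind these protocols (`gen_step_protocols()`) is a
single-compartment spike-and-reset membrane with one Ih gating variable —
deliberately the *minimal* model exhibiting every measured feature:
$C\dot V = -g_L(V - E_L) - g_h x (V - E_h) + I$,
$\dot x = (x_\infty(V) - x)/\tau_h$,
$x_\infty(V) = (1 + e^{(V - V_{1/2})/k})^{-1}$, forward-Euler at 0.05 ms.
Defaults ($g_L = 5$ nS, $E_L = -60$ mV, $V_{th} = -40$ mV, $g_h = 2$ nS,
$E_h = -30$ mV, $V_{1/2} = -85$ mV, $k = 6$ mV, $\tau_h = 300$ ms) give a
120 pA rheobase for the passive cell (first step strictly above
$g_L(V_{th} - E_L) = 100$ pA), Ih of order −150 pA at −120 mV, and a
few-mV sag — the right orders of magnitude for midbrain dopamine neurons.
Spike threshold crossing uses strict inequality, so a cell driven exactly
to threshold asymptotically never spikes spuriously. Cell-attached traces
(`gen_cell_attached()`) use gamma-renewal intervals (shape 4, pacemaker-like
regularity) and a biphasic waveform with configurable trough latency;
ground-truth spike times are recorded at the trough, which is also where
the detector timestamps.

# Statistics stage

`normality_gate()` routes each sample by a Kolmogorov–Smirnov test of the
standardized values against the standard normal at $\alpha = 0.05$. The KS
test with estimated moments is conservative (the Lilliefors effect), so
the parametric route is favored; the plain KS test is nevertheless the
default because it is the stated convention in this literature, and the
threshold is configurable. `correlate()` uses Pearson when both variables
pass, Spearman otherwise; `compare_groups()` uses one-way ANOVA when all
groups pass the gate and Levene's test finds homogeneous variances,
Kruskal–Wallis otherwise, with matching pairwise post hocs
(pooled-variance t or Wilcoxon) under Bonferroni correction. Bonferroni
replaces exact Dunnett-style multivariate-t post hocs: it preserves
family-wise control without the multivariate machinery, at a known cost in
power. All tests are two-sided. When the omnibus route is rank-based there
is no correlation CI; the recovery checks then fall back to the two-sided
p-value, which answers the same null question.

`run_pipeline()` wires the stages together: cohort generation, per-mouse
trials, feature extraction, and `analyze_cohort()` — which by construction
receives only the assembled per-mouse metrics table. The generator's
ground truth travels in the report object for recovery testing but is
never an input to any analysis function.

# The synthetic cohort as study conditions

Defaults mirror the reference cohort: 28 stress-naive controls and 60
defeated mice with susceptibility probability 0.59 (the observed AD
fraction among defeated animals). Each mouse draws an anxiety trait
$a \sim \mathrm{Beta}(2, 4)$; defeat adds 0.25 (clipped to $[0,1]$).
Open-arm occupancy targets $0.35 - 0.35a$ (noise SD 0.04) and true firing
$6 - 4a$ Hz (noise SD 0.7) both decrease in the trait, so firing and
open-arm time covary positively; the true SI ratio is drawn independently
(susceptible: normal(55, 15) clipped below 100; resilient: normal(145, 25)
clipped above), so firing and SI ratio are independent by construction.
Group-level firing depression follows from the trait shift
($\approx 1$ Hz); individual stressed mice can still exceed the control
mean, as real resilient animals do.

Trial geometry: 150 s per social-interaction phase, 300 s EPM and OFT
trials at 30 Hz tracking (the frame rate is unreported in the source
conventions; 30 Hz is standard commercial-tracker output). Trajectories are
reflected random walks confined to one zone at a time, with dwell segments
scheduled greedily against the running target-versus-realized occupancy
deficit — the simplest process that provably converges to prescribed zone
fractions (within ±0.05 at 3000 s in the test suite). Between-zone transits
run through the arena center, which keeps plus-maze paths on the maze; the
scheduler absorbs the occupancy that transits deposit in intervening zones.
Entry/exit microstructure, thigmotaxis and velocity profiles are *not*
modeled, so tests passing on these tracks validate zone accounting, not
naturalistic locomotion.

Per mouse, 3–7 cell-attached neurons are simulated for 30 s each at 5 kHz
(neuron count per the reference convention; duration and rate chosen to
keep a full 10-seed recovery run within minutes on one CPU while leaving
the firing-rate standard error well below the programmed 1 Hz group
effect). Six mice per cohort receive a photometry session during the EPM
trial.

# Numerical choices and degenerate inputs

* Seeds: every stochastic stage draws a sub-seed from one master seed via
  `split_seed()` (an exact integer hash), so any mouse or stage regenerates
  in isolation; all outputs are bit-identical given `(config, seed)`.
* Zone boundaries are closed; partition ties resolve to the first declared
  zone. Nearest-sample alignment between time bases breaks ties toward the
  earlier sample.
* Undefined ratios (zero denominators) raise errors so mice are flagged
  rather than silently imputed; a constant photometry control warns and
  falls back to an intercept-only fit; a constant signal yields zero events
  with a degenerate flag; `rheobase()` returns `NA` when no step spikes.
* Euler integration at 0.05 ms conserves the analytic subthreshold fixed
  point to well under 0.5 mV, and voltage-clamp currents match the
  closed-form gating relaxation to 2%.

# Known limitations

* The trajectory model optimizes occupancy realism only; entry *counts*
  are emergent, not calibrated.
* The membrane model is not a biophysical dopamine-neuron model: no
  spike-frequency adaptation, no SK/Kv dynamics; excitability curves are
  therefore steeper than real neurons' at high currents.
* Event-rate estimates from MAD-threshold detection are a relative index,
  not an inferred transient rate: the ≈1.96-σ band admits a noise floor of
  excursions (limited mainly by the minimum inter-event interval), and the
  session-adaptive MAD means larger transients *raise* the threshold. The
  raw event count is therefore not monotone in transient amplitude; the
  count of events matching injected transients is, and that is what the
  test suite checks.
* The Kruskal–Wallis route reports no correlation CIs; recovery checks use
  p-values there.
* Repeated-measures designs (e.g., excitability group × step curves) are
  summarized per step with Bonferroni control rather than a
  sphericity-corrected RM-ANOVA.

# A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(cohort_config(seed = 3), stages = c("behavior", "ephys"))
report <- run_pipeline(cfg)
report$correlations
```

On seed 3 this prints a firing × open-arm-time Pearson r of 0.54
(p = 9.3e-6, n = 60) next to a firing × SI-ratio Spearman rho of −0.07
(p = 0.58): the programmed dissociation, recovered blind by the statistics
stage.
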