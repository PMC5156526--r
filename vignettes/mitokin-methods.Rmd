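---
title: "Models and methods behind mitokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mitokin quantifies how transcription factors (TFs) interact with mitotic
chromosomes from live-cell imaging data, and simulates the formaldehyde
fixation artifact that makes dynamically bound TFs appear excluded from
chromosomes in fixed-cell images. This vignette explains the models, their
assumptions, the tunable parameters, and the numerical and design choices
made where several reasonable options existed. Every empirical statement
here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is quoted from external data.

```{r setup}
library(mitokin)
```

## The two-state kinetic picture

All single-particle-tracking (SPT) stages share one model: a TF molecule is
either **bound** to chromatin (diffusion coefficient $D_{\mathrm{bound}}$,
typically $\sim 0.01\ \mu m^2/s$) or **free** ($D_{\mathrm{free}}$,
typically $\sim 1$–$3\ \mu m^2/s$), switching with exponential waiting
times: binding at rate $k^*_{\mathrm{on}}$ while free, unbinding at rate
$k_{\mathrm{off}}$ while bound. The stationary bound fraction is
$F_{\mathrm{bound}} = k^*_{\mathrm{on}} / (k^*_{\mathrm{on}} +
k_{\mathrm{off}})$, and the mean duration of a specific binding event — the
*residence time* — is $\tau_s = 1/k_{\mathrm{off},s}$.

Two imaging regimes probe different parts of this model:

* **Slow tracking** (2 Hz, 500 ms exposures): fast-moving molecules blur
  into the background, so only bound molecules are detected, and the data
  reduce to *dwell times* — how long each spot persists. These estimate
  residence times.
* **Fast tracking** (~222 fps, stroboscopic): individual displacements
  ("jump lengths") between frames are resolved; their distribution over
  several lag times estimates $F_{\mathrm{bound}}$, $D_{\mathrm{free}}$ and
  $D_{\mathrm{bound}}$.

## Synthetic data generator

`simulate_two_state_tracks()` is a Brownian-dynamics simulator of fast
tracking. State switching is simulated in continuous time and displacements
are integrated piecewise, so a frame containing a switch contributes
$2\sum_i D_i t_i$ of variance per axis — there is no one-switch-per-frame
approximation. The axial ($z$) position diffuses with the state's
coefficient and reflects at $\pm$ `cell_half_depth` (default 4 µm; a
bounded axial domain keeps the out-of-focus pool finite and gives a proper
stationary distribution). A localization is emitted only while $|z| \le$
`slice_half_width` (default 0.35 µm, i.e. a ~0.7 µm detection slice);
emitted positions carry Gaussian localization error ($\sigma = 35$ nm by
default) and molecules photobleach with a per-frame hazard. Detections
separated by at most `blink_max_gap` (default 1) missed frames share a
trajectory id, emulating tracker blinking re-connection.

Slow-tracking data are generated directly as dwell samples
(`simulate_slow_tracking_dwells()`): a binding duration drawn from the
mixture $f_{ns}\,\mathrm{Exp}(k_{ns}) + (1-f_{ns})\,\mathrm{Exp}(k_s)$
(non-specific and specific events), an independent bleaching time from
$\mathrm{Exp}(k_{\mathrm{photobleach}})$, and the observed dwell is the
minimum, floored to whole frames with a one-frame minimum. Rendering
motion-blurred movies would add nothing: the analysis consumes dwell times.

What the generator deliberately does **not** emulate: point-spread-function
rendering, localization algorithms, camera noise beyond Poisson/Gaussian,
spatially heterogeneous binding sites, and anomalous diffusion. Passing
recovery tests therefore demonstrates correctness of the estimators under
the model's own assumptions, not robustness to all features of real data.

Presets (`spt_preset()`) encode an interphase-like TF (stationary bound
fraction 0.309, specific off-rate 0.08 s$^{-1}$) and a mitosis-like TF
(bound fraction 0.183, off-rate scaled by $1/0.54$ so the mitotic residence
time is 54% of interphase). Diffusion coefficients (2 and 0.01 µm²/s) are
plausible for a nuclear TF, not measurements. The fast-tracking
photobleaching rate is 8 s$^{-1}$: under stroboscopic maximal-intensity
illumination of photoactivatable dyes, tracks survive tens of frames, and
this matters statistically — each surviving molecule contributes many
correlated jumps, so the effective sample size of a jump-length data set is
closer to the number of molecules than to the number of jumps. The
slow-tracking preset uses 0.05 s$^{-1}$ (low-intensity 2 Hz imaging).

## Residence time from dwell-time survival

`dwell_survival()` computes $S(t) = \#\{\text{dwell} \ge t\}/n$ on the
frame grid. `fit_two_exponential()` fits

$$S(t) = F e^{-k_{\mathrm{off,emp,ns}} t} + (1-F) e^{-k_{\mathrm{off,emp,s}} t}$$

by unweighted nonlinear least squares (Levenberg–Marquardt with box
constraints). Choices worth stating:

* **Fit target.** The survival curve is fitted directly, unweighted, not a
  likelihood on raw dwells. For frame-quantized data the survival values at
  grid points $j \ge 2$ follow the continuous mixture exactly, so nothing
  is lost by the quantization.
* **The first grid point is excluded.** $S$ at one frame is 1 by
  construction — any detected event lasts at least one frame, including
  sub-frame events floored up — so that point carries no decay information
  and, if fitted, drags both rates low; the recovery tests hold only with
  it excluded.
* **Component ordering is structural.** The fast rate is parameterized as
  the slow rate plus a non-negative increment, so the slower ("specific")
  component is identified by construction, not by initialization luck.
* **Initialization** comes from the curve: log-linear slopes of the last
  and first thirds for the slow and fast rates, the extrapolated slow-tail
  intercept for $F$, plus a few fixed perturbed restarts.

Photobleaching inflates the empirical off-rate additively:
$k_{\mathrm{off,emp,s}} = k_{\mathrm{photobleach}} + k_{\mathrm{off},s}$.
`photobleach_rate()` estimates the bleach rate as the slow component of a
histone (H2B) control — a species with negligible true unbinding — and
`correct_residence()` subtracts it; $\tau_s = 1/k_{\mathrm{off},s}$. If the
empirical rate does not exceed the bleach rate the residence time is
unidentifiable and the function refuses rather than extrapolates. The
uncorrected estimate $1/k_{\mathrm{off,emp,s}}$ is predictably biased low
by the factor $k_s/(k_s + k_{\mathrm{photobleach}})$, which the test suite
verifies.

## Bound fraction from jump-length distributions

`jump_histogram()` pools Euclidean displacements at lags of 1–7 frames
(4.5–31.5 ms at the default 4.5 ms frame interval; the frame interval is
data metadata, since published hardware rates differ slightly between 222
and 225 Hz). Pairs spanning a blink gap are skipped, so only uninterrupted
runs contribute. Bins are 10 nm wide from 0 to 1.2 µm and each lag is
normalized to a probability density.

The model density at lag $\Delta\tau$ is a two-component Rayleigh mixture:

$$P(r, \Delta\tau) = F_B\, \frac{r}{2(D_B\Delta\tau + \sigma^2)}
  e^{-r^2/4(D_B\Delta\tau+\sigma^2)} \;+\;
  Z(\Delta\tau)\,(1-F_B)\, \frac{r}{2(D_F\Delta\tau + \sigma^2)}
  e^{-r^2/4(D_F\Delta\tau+\sigma^2)}$$

with localization error $\sigma$ fixed at 35 nm by default (optionally
fitted in [20, 60] nm). $Z(\Delta\tau)$ corrects for free molecules
diffusing out of the ~0.7 µm axial detection slice between frames: without
it, the loss of fast molecules at long lags masquerades as extra bound
fraction. Because the defocus weight multiplies only part of the mixture,
the model is renormalized per lag before comparison — both sides of the
least-squares objective are proper densities.

Two defocus models are provided:

* `z_corr()` — the classical closed form: the slice-average survival of
  Brownian motion between absorbing boundaries (alternating erfc image
  series, Gauss–Legendre quadrature over the slice, series truncated at
  $10^{-10}$). Absorbing boundaries overestimate the loss (molecules that
  leave and return are counted as lost), which is conventionally
  compensated by an *effective* slice thickness
  $\Delta z_{\mathrm{eff}} = 0.700 + 0.15716\sqrt{D} + 0.20811$ µm
  (`corrected_dz()`; constants are configuration). The form of this
  published calibration is ambiguous in its source ($\sqrt D$ vs $D$); the
  $\sqrt D$ reading is used since it matches the diffusion length scaling.
  One consequence: because $\Delta z_{\mathrm{eff}}$ grows like $\sqrt D$,
  the corrected factor tends to a small constant (~0.13) rather than 0 as
  $D \to \infty$; the uncorrected form (`corrected = FALSE`) has the
  classical limit.
* `defocus_survival()` — the exact quantity for frame-sampled data: the
  probability of being inside the slice at every one of $k$ successive
  frame checks, free diffusion in between, computed by iterating the
  Gaussian transfer operator restricted to the slice. The test suite
  checks this against the simulator's per-lag survival directly, whereas
  a single effective-thickness absorbing model cannot match all lags at
  once — it under-predicts survival at short lags and over-predicts at
  long ones, which surfaces as a small spurious addition to the fitted
  bound fraction.

`fit_two_state()` therefore defaults to the discrete-survival weight
(applied to both components; the bound component also loses a small
fraction), with `defocus = "corrected_dz"` available for strict
side-by-side comparison with the classical analysis. `z_corr()` itself is
validated against an independent Monte-Carlo absorption oracle
(`z_corr_mc()`, Brownian-bridge-corrected so step discretization does not
bias absorption) to within 1%.

Optimization is box-constrained L-BFGS-B over
$(F_B, D_F, D_B)$ — bounds $[0,1]$, $[0.15, 20]$ and $[5\times10^{-4},
0.1]$ µm²/s, the upper free bound matching the tracker's maximal expected
diffusion constant — from at least five Latin-hypercube starting points
with fixed sub-seeds. The parameters span two orders of magnitude, so the
search is scaled per-parameter (`parscale`); a fit is reported converged
when the best run terminates cleanly or two independent restarts agree on
the optimum. The discrete-survival weights are precomputed on a log grid
of $D$ and interpolated inside the objective.

## FRAP

`normalize_frap()` applies double normalization:
$(\mathrm{spot}-\mathrm{bg})/(\mathrm{cell}-\mathrm{bg})$, scaled so the
pre-bleach mean is exactly 1 — this cancels acquisition bleaching and
background. The exact published recipe is available only by citation, so
this standard choice is stated explicitly. The bleach frame must show a
drop exceeding 3 SD of pre-bleach noise.

`time_to_recovery()` reports $t_{90}$: the first time the curve reaches 90%
of the recovered plateau *measured from the bleach floor*, linearly
interpolated between frames. Measuring from the floor (rather than from
the pre-bleach level) keeps the statistic defined for partial recoveries
and makes it invariant under affine intensity transforms; this
interpretation is a documented choice. The plateau is the mean of the final
10% of post-bleach frames (at least 5). No model fitting is involved;
`fit_frap_exponential()` exists for diagnostics only. On a noiseless
saturating exponential $1-e^{-kt}$, $t_{90} = \ln(10)/k$; the tests verify
recovery within one frame interval across $k$ from 0.05 to 2.5 s$^{-1}$,
with and without noise.

## Chromosome-enrichment imaging statistic

For a two-channel image (H2B chromosome marker + TF),
`log2_enrichment()` computes

$$E = \log_2 \frac{\overline{TF}_{\mathrm{chromosomes}} - bg}
                 {\overline{TF}_{\mathrm{whole\ cell}} - bg}$$

where the whole-cell mean **includes** the chromosome pixels (this follows
the statistic's "over the whole cell intensity" definition and changes the
value relative to an on/off-chromosome ratio; `true_log2_enrichment()`
gives the implied ground truth $\log_2[\rho / (\alpha\rho + 1 - \alpha)]$
for a region covering a fraction $\alpha$ of the cell with intensity ratio
$\rho$). Masks: the cell is segmented by Otsu's threshold on the
log-transformed summed channels (the log keeps the threshold between
background and cell body rather than between cell body and the much
brighter chromosomes), largest component, holes filled; chromosomes by Otsu
within the cell mask on H2B, holes filled, components under 20 px removed,
with a bimodality guard (above/below mean ratio ≥ 1.5) that rejects images
without chromosome signal. Background defaults to the median intensity
outside the cell mask; a constant override and manual ROIs are accepted.
The thresholding method and background rule are not specified in the
source analyses beyond "thresholded", so Otsu + median background are
documented choices.

`timelapse_enrichment()` applies the same per-frame (chromosomes move; no
registration) to a fixative-addition movie and reports the normalized
chromosome intensity at a query time (default 60 s) after addition,
linearly interpolated between frames.

`render_cell_image_pair()` generates elliptical two-channel test images
with Poisson noise at a configurable photon budget, providing exact
ground-truth masks and enrichment for estimator validation (bias measured
≤ 0.1 log2 units at a 1000-photon budget across $\rho$ from 0.5 to 4).

## The fixation-artifact model

`simulate_fixation()` implements a stochastic particle rendering of the
fixation-artifact mechanism: a 2D cell disc (radius 8 µm) with a
concentric chromosome disc (4 µm); free particles diffuse and reflect at
the membrane, bind inside the chromosome disc with hazard
$k^*_{\mathrm{on}}$, unbind with $k_{\mathrm{off}}$; from $t=0$ fixative
enters through the membrane and diffuses inward, giving the front
$C(r,t) = C_0\,\mathrm{erfc}\!\big[(R_{\mathrm{cell}}-r)/\sqrt{4 D_{pfa}
t}\big]$; every non-crosslinked particle is immobilized ("crosslinked")
with hazard $k_x C(r,t)$, frozen at its current position and state forever
(chromatin-bound particles crosslink at the same hazard — whether they
differ is unknown, so equal hazards is the neutral choice). The apparent
enrichment is the particle-density analogue of the imaging statistic: mean
density inside the chromosome disc over mean density in the cell. Mode
`uniform_instant` freezes everything at $t=0$, the analogue of
high-pressure freezing / freeze substitution, and preserves the initial
enrichment exactly.

The mechanism is verbal in its source, so geometry and constants are this
package's modelling choices. Two regimes exist, and only one produces the
artifact: if fixative transport is fast relative to crosslinking
(free-solution diffusivity, tens of µm²/s), fixation is effectively
uniform and slow — the dose response at 60 s is flat or even inverted,
because higher dose then just freezes the equilibrium sooner. The artifact
requires the **front-limited** regime: effective penetration slowed by the
membrane and crowded cytoplasm ($D_{pfa} = 0.3$ µm²/s default) with
moderate crosslinking ($k_x = 0.05$ s$^{-1}$ per unit dose), so that the
cytoplasmic pool near the membrane is captured while the chromosome
interior is still unfixed — bound molecules keep unbinding into a
crosslinked, non-rebinding cytoplasm — and at low dose fixation is still
incomplete after a minute. In this regime the model reproduces all three
directional predictions, each checked in the test suite: enrichment at
60 s decreases monotonically with dose (0.25–4 units), a slowly
exchanging TF ($k_{\mathrm{off}} = 0.05$ s$^{-1}$) retains far more
enrichment than a dynamic one (1 s$^{-1}$), and instantaneous uniform
fixation preserves enrichment exactly. The time step obeys
$\Delta t \le 0.1/\max(k_{\mathrm{off}}, k^*_{\mathrm{on}}, k_x C_0)$ and
is validated at construction and again at run time.

## Numerical choices and degenerate inputs

* Gauss–Legendre order 64 and series tolerance $10^{-10}$ for `z_corr()`;
  the normalized model density integrates to 1 within $10^{-6}$.
* The discrete-survival transfer operator uses a trapezoid grid whose
  resolution adapts to the one-frame diffusion length (at least 4 nodes
  per standard deviation, 151–901 nodes).
* Degenerate inputs fail loudly: empty dwell samples, curves without a
  bleach event or without recovery, uniform H2B, non-positive
  background-subtracted means, unidentifiable residence times, fixation
  time steps violating the stability bound.
* All generators take explicit integer seeds and are byte-reproducible;
  fitting multi-starts use fixed sub-seeds and restore the RNG state.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the pipelines at the scales
the analyses are designed for, chosen once: 24 cells × ~2000 lag-1 jumps
for bound-fraction recovery (tolerance ±0.03, three seeds); 5000 dwell
events for residence recovery (±15%, plus the analytic uncorrected-bias
check); $10^5$ Monte-Carlo paths for the defocus oracle (1% agreement);
photon budgets of $10^3$–$10^4$ for imaging (bias ≤ 0.1 log2); 2000
particles × 70 s × 20 replicates per dose for the fixation predictions.

## Known limitations

* The greedy nearest-neighbour linker (`link_localizations()`) is plumbing
  for simulated, well-separated data (≤ 0.1 particles/µm²), not a
  replacement for a multi-hypothesis tracker.
* Two-state models only: no three-state kinetics, no state-lifetime
  correction of $F_{\mathrm{bound}}$, no anomalous diffusion.
* FRAP is summarized by $t_{90}$ only; no reaction–diffusion FRAP fitting.
* The fixation model is directional: its constants are not calibrated to
  any measured dose–response values, and it makes no chemistry claims
  (irreversible crosslinks, no epitope masking).
* Enrichment imaging handles single 2D planes; no z-stacks, no cell
  tracking through mitosis.
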