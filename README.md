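# mitokin

Kinetic analysis of transcription-factor (TF) binding to mitotic
chromosomes from live-cell imaging — and a simulator of the formaldehyde
fixation artifact that hides it.

## The scientific problem

Most TFs were long believed to be excluded from mitotic chromosomes,
largely on the evidence of fixed-cell immunofluorescence. Live-cell
imaging tells a different story: many TFs coat mitotic chromosomes, but
bind them *dynamically* — with shorter residence times and lower bound
fractions than in interphase — and chemical fixation itself can evict a
dynamically bound TF from chromosomes before it is immobilized, creating
an artifactual "exclusion". Quantifying this requires a set of
complementary measurements, each with its own estimator:

* **Residence time** from slow single-particle tracking (2 Hz, long
  exposures): the dwell-time survival curve is fitted with a
  two-exponential decay,
  `S(t) = F exp(-k_off,emp,ns t) + (1-F) exp(-k_off,emp,s t)`,
  and the specific (slow) rate is corrected for photobleaching measured on
  a histone control: `k_off,emp,s = k_photobleach + k_off,s`, residence
  time `tau_s = 1 / k_off,s`.
* **Bound fraction** from fast tracking (~222 fps): jump-length
  distributions at lags of 4.5–31.5 ms are fitted with a two-state
  (bound/free) Rayleigh mixture whose free component is weighted by an
  axial defocus-loss factor — molecules diffusing out of the ~0.7 µm
  detection slice would otherwise masquerade as bound molecules.
* **FRAP**: time to reach 90% of the recovered plateau (t90), model-free.
* **Chromosome enrichment** in two-channel images:
  `E = log2(mean TF on chromosomes / mean TF over the whole cell)` with an
  H2B-marker-derived chromosome mask, plus a time-lapse variant for
  fixative-addition movies.
* **Fixation artifact model**: a stochastic particle simulation of an
  inward-moving crosslinking gradient superimposed on TF binding kinetics,
  reproducing the dose dependence and off-rate dependence of the artifact
  and the uniform-fixation (cryofixation) rescue.

A synthetic-data module simulates every input — two-state Brownian
switching with localization error, an axial detection slice and blinking;
censored dwell-time mixtures; FRAP tables; two-channel cell images — so
each estimator is verified by parameter recovery against known ground
truth. See the methods vignette (`vignettes/mitokin-methods.Rmd`) for the
models, assumptions and design choices.

## Worked example

Simulate a fast-tracking experiment for a mitosis-like TF (true bound
fraction 18.3%), build jump-length histograms, and fit the two-state
model:

```r
library(mitokin)

preset <- spt_preset("mitosis")
acq <- acquisition_settings(n_frames = 120)          # 4.5 ms frames
trk <- simulate_fast_tracking_cells(preset$kinetics, acq,
                                    n_cells = 24, particles_per_cell = 900,
                                    seed = 1)
fit <- fit_two_state(jump_histogram(trk, lags = 1:7))
fit
#> Two-state jump-length model fit
#>   F_bound = 0.202
#>   D_free  = 1.99 um^2/s   D_bound = 0.0107 um^2/s   sigma = 0.035 um (fixed)
#>   residual = 2.377 (converged), 7 lags, defocus model: discrete
```

The fitted bound fraction (here 0.202 against a simulated truth of 0.183)
is the steady-state fraction of molecules in the slow, chromatin-bound
state; `D_free` and `D_bound` are the two diffusion coefficients, and the
defocus model is the correction without which the out-of-focus loss of
fast molecules at long lags would inflate the bound fraction.

Residence time with photobleaching correction:

```r
acq2 <- acquisition_settings(frame_interval = 0.5, n_frames = 400)  # 2 Hz
d <- spt_preset("interphase")$dwell
dw <- simulate_slow_tracking_dwells(d$f_ns, d$k_ns, d$k_s, d$k_photobleach,
                                    acq2, n_events = 5000, seed = 1)
res <- correct_residence(fit_two_exponential(dwell_survival(dw)),
                         k_photobleach = d$k_photobleach)
res
#> Photobleaching-corrected residence time
#>   k_photobleach = 0.05 1/s   k_off,s = 0.07302 1/s
#>   tau_s = 13.7 s
```

The simulated truth is `1/0.08 = 12.5` s; the uncorrected estimate
`1/k_off,emp,s` would be biased low by `k_s/(k_s + k_photobleach) = 0.615`.

A command-line wrapper over the same functions is installed at
`system.file("cli", "mitokin", package = "mitokin")`, with subcommands
`simulate`, `fit-residence`, `fit-jumps`, `fit-frap`, `enrich` and
`simulate-fixation`; every run writes a JSON run record alongside its
outputs.

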