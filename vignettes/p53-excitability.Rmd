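---
title: "Excitable p53 dynamics driven by stochastic DNA damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitable p53 dynamics driven by stochastic DNA damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(p53dyn)
```

p53dyn simulates and analyzes pulsatile p53 signaling in single cells. The
package couples three layers: an exact stochastic simulation of DNA
double-strand-break (DSB) induction and repair, a deterministic excitable
model of the ATM--p53--Mdm2--Wip1 network forced by the break count, and a
trajectory-statistics layer (wavelet pulse detection, inter-pulse-interval
and divergence statistics) that treats simulated cells exactly like
measured reporter trajectories. This vignette explains the models, the
parameter choices, and what the package's tests do and do not establish.

## The stochastic DSB process

Breaks are born at a zero-order rate and repaired independently (first
order). To mimic a radiomimetic drug pulse, the birth rate is a step
function: `b_s` breaks/h while the drug is active (`t < T_s`, default 0.5
h), then the basal rate `b_b`. Waiting times are drawn by analytic
inversion of the piecewise-linear integrated hazard, so the step is crossed
exactly, without thinning; event types are chosen from the propensities at
the jump time. Two break classes are carried: isolated breaks repair at `r
= 0.35`/h, complex (clustered) breaks at `r_c = log(2)/20`/h (a 20 h
half-life), and a birth during the drug window is complex with probability
`f_c = 0.1`.

Two modeling choices deserve comment. First, doses are parameterized by the
target maximal number of inflicted breaks `N_s`, with `b_s = N_s / T_s`,
because dose--response analyses bin cells by maximal inflicted DSBs.
Second, complex breaks arise only during the drug window: spontaneous
background breaks are isolated. With a uniformly applied `f_c` the
stationary background level would be `b_b(1-f_c)/r + b_b f_c/r_c`, about
3.8 breaks, contradicting the background level `b_b/r = 2` that the
single-class theory states and that the basal regime is calibrated to;
restricting clustered lesions to the radiomimetic burst keeps the
background at 2 while preserving biphasic repair after stimulation.

The closed-form population mean `(N_s - N_b) e^{-rt} + N_b` and the
repair-time approximation `log(N_s)/r` are implemented alongside the
simulator and cross-checked against ensemble means in the tests.
`estimate_rates()` inverts the model: in basal (stationary) mode the repair
rate comes from the lag-2/lag-1 autocovariance ratio, which is exact for
the linear immigration--death process and insensitive to white detection
noise (which inflates the lag-0 variance only), and the break rate follows
from the stationary mean; in decay mode the mean-decay law is fit by
nonlinear least squares.

## Abstract feedback circuits

Two toy circuits reproduce the qualitative dichotomy between negative-only
and mixed-feedback pulse generators.

The NF model is a three-stage delayed repression loop in which the input
scales production. A small repression-independent leak makes the loop gain
fall again at high input, so the oscillatory regime is closed by a second
supercritical Hopf: amplitudes grow from zero at both boundaries and the
response to transient inputs is graded. These are the signatures the
package's onset classifier calls `hopf_like`.

The NPF model is a cubic autocatalytic activator (a FitzHugh--Nagumo-type
nonlinearity, with the positive self-interaction carrying an activation
threshold) under a slow inhibitor whose sigmoidal activation saturates
*below* the upper knee of the cubic. That geometric detail is load-bearing:
it removes the stable excited state that plainer activator--inhibitor
variants possess, so the only attractor above onset is the full relaxation
loop. The rest state is then destroyed by a saddle-node on the loop itself,
and oscillations appear at full amplitude with a diverging period -- type I
excitability, classified `homoclinic_like`. Numerically the model shows a
constant-amplitude oscillation window with the period rising steeply toward
both ends, an all-or-none response to transient inputs (sub- to
supra-threshold amplitude ratio about 0.16), and the inhibition asymmetry
expected of an excitation loop: quenching the input *after* ignition does
not change the outcome, quenching the self-interaction truncates the pulse
in a graded, time-dependent way.

`bifurcation_scan()` is deliberately a direct-simulation engine, not a
continuation package: each grid point is integrated long enough to pass its
transient (the first 40% of the run is discarded), oscillation is declared
when the post-transient peak-to-trough span exceeds 1% of the rest-state
magnitude and at least two maxima recur, and periods are measured between
successive maxima by local quadratic interpolation. `classify_onset()`
compares the period at the oscillating point nearest the onset with the
period at the middle of the oscillatory parameter range; a ratio above two
is called `homoclinic_like`. Grids clustered near an onset are therefore
fine to use -- the mid-regime reference is taken at the centre of the
parameter range, not at the median grid index.

## The six-species p53 core

The deterministic core tracks active ATM (a conserved kinase pool, so
`ATM_a` is a fraction), p53, mdm2 mRNA, Mdm2, wip1 mRNA and Wip1, in
arbitrary concentration units and hours. Its structure:

* ATM activation has a seeded part proportional to the break count (MRN
  recruitment at damage foci) and a cooperative self-interaction
  (condensing autophosphorylation and gammaH2AX spreading) that saturates
  once breaks are present (`D/(K_D + D)`). Wip1 opposes activation twice:
  by mass-action dephosphorylation of ATM* (`k4`) and by cooperative
  interference with the activation step (`K5`, Hill 4), capturing its
  action on ATM itself and on the phosphorylated scaffold that sustains
  self-activation.
* ATM* stabilizes p53 by attenuating Mdm2-mediated degradation and by
  enhancing Mdm2 turnover.
* p53 transactivates mdm2 and wip1 with a steep, high-midpoint Hill
  function (`K_TP = 3.2`, Hill 8), so transcription is essentially off at
  the rest level of p53 and strongly on at pulse levels.

The steep transactivation is not cosmetic. If rest-level p53 drives
appreciable wip1 transcription, the post-pulse p53 undershoot (caused by
the Mdm2 overhang) propagates into a Wip1 undershoot below its rest level,
which makes re-ignition during a pulse train systematically easier than
first ignition from rest. That widens the hysteresis between the oscillatory
and excitable regimes and turns basal dynamics into long locked pulse
trains. With transcription flat below rest p53, the re-ignition and
first-ignition thresholds nearly coincide, and basal cells produce the
observed phenomenology: long silent stretches, occasional isolated pulses
or short trains, wide inter-pulse intervals.

Under constant damage the model rests stably at the background level (2
breaks), oscillates with a ~5 h period for sustained damage above roughly
5--10 breaks, and is excitable in between and below: instantaneous ATM*
kicks from rest give an all-or-none p53 response (under 5% of a fine kick
grid lands between 20% and 80% of the full amplitude), the threshold is
insensitive to +-50% changes in p53 or Mdm2 but moves strongly with the
cell's Wip1 production scale, and the local sensitivity ranking of the
threshold is dominated by Wip1-associated parameters.

One property deliberately reported as it is: approached along the
oscillating branch (downward continuation in the damage level), the limit
cycle of this parameterization disappears at a fold of cycles with the
period still bounded (about 6.2 h at the fold versus 4.7--5.8 h
mid-regime), i.e. the onset is a *hard* subcritical one rather than a clean
saddle-homoclinic: oscillations do appear and vanish at close to full
amplitude -- the observable that matters for amplitude conservation -- but
the diverging-period signature that `classify_onset()` demands for
`homoclinic_like` is not met, and the corresponding assertion in the test
suite fails by design rather than being weakened. Several structural
variants (faster Wip1 arm, leak-free transactivation, sharper
self-activation, a single-slow-variable limit) moved the system toward but
not across that boundary; documenting the hard onset honestly was
preferred over contorting the model further, since every downstream claim
(all-or-none pulses, conserved amplitudes, Wip1-set thresholds, regime
statistics) holds as tested.

## Hybrid simulation and populations

`simulate_cell()` integrates the ODE with the pre-computed break count
entering as a zero-order-hold forcing; integration restarts at every jump
and at every intervention time, so the discontinuities are handled exactly
(tolerances 1e-8/1e-10, `lsoda`). Interventions are instantaneous
multiplicative parameter changes -- `k_dsb`+`v_s` scaling emulates a kinase
inhibitor, `wip1_scale` scaling emulates over- or under-expression.

`run_ensemble()` adds the two cell-to-cell variability sources the study
names: each cell gets its own DSB realization (child seeds derived
deterministically from one root seed) and its own lognormal Wip1 production
rate. The lognormal log-SD default (0.49) was calibrated once so that the
simulated steady-state wip1 mRNA CV across a basal population is about
0.52, the printed calibration point; the measured mRNA CV sits slightly
below the rate CV because high-Wip1 cells pulse less and transcription
feedback partially compensates. A cell is a *responder* if a detected pulse
peaks within the first six hours.

Scenario doses were fixed once from the regime phenomenology: medium = 50
inflicted breaks (isolated breaks clear within ~11 h, the few complex ones
within the recording, so cells drift back from coherent oscillation to
basal-like irregular pulsing), high = 400 breaks (enough complex damage
persists through 48 h to keep cells oscillating coherently).

## Trajectory analysis

Pulse detection follows the mass-spectrometry ridge-line strategy: a Ricker
CWT over ten log-spaced scales (0.5--6 h), local coefficient maxima linked
across adjacent scales (gap tolerance one scale), ridges kept if they span
at least three scales and their best coefficient exceeds three times the
MAD of the smallest-scale coefficients. Amplitudes and widths are then
refined with a localized smoothing spline (GCV-chosen smoothness) in a
window of +-1.5 detection scales; the amplitude baseline is the smaller of
the spline values at the window edges, and the width is the FWHM of the
baseline-subtracted spline. On noiseless synthetic Gaussian pulses this
recovers amplitude within 3% and FWHM within 5%; at an amplitude-to-noise
ratio of 5 the detector's recall stays at or above 0.95 with at most 0.05
false positives per trajectory.

Noiseless ODE output is a special case: subthreshold ripples of amplitude
~0.01 are smooth and the CWT noise floor is numerically tiny, so the SNR
criterion alone cannot reject them. Ensemble analyses therefore apply an
amplitude floor (`min_amplitude = 0.5`, about a quarter of the full pulse
amplitude); the all-or-none property makes results insensitive to the
exact cut.

IPI bookkeeping: a cell contributes first/last IPIs only with at least two
pulses (with exactly two they coincide). The Kullback--Leibler divergence
uses shared equal-width bins spanning the pooled range of the compared
samples, each histogram regularized with `1/(2n)` pseudo-mass per bin;
comparisons across several groups should pass one shared set of `edges`.
KLD estimates from a few dozen IPIs carry upward small-sample bias, which
is why the regime-comparison tests use the largest ensemble for the
reference distribution and read the divergences comparatively, not as
absolute numbers.

## Problem sizes and limitations

The test suite runs ensembles of 40--100 cells per damage regime, 500-track
DSB ensembles, and a 1000-cell population for the heterogeneity
calibration; these sizes were chosen so that every asserted ordering is
stable under the fixed seeds while the whole suite stays comfortably
runnable on a laptop. The synthetic-data generator emulates the statistical
structure the analysis relies on -- pulse trains with known ground truth,
multiplicative+additive Gaussian measurement noise, 15--20 min sampling,
48 h recordings, binomial focus miscounting -- but not segmentation
artifacts, photobleaching trends, cell division, or heteroscedastic noise;
passing tests demonstrate correctness of the pipeline on data satisfying
the model's assumptions, not robustness to every failure mode of real
microscopy. The bifurcation engine detects attractors reachable from the
rest state (plus downward continuation where used) and cannot see unstable
objects or exotic coexisting attractors; onset classification is therefore
operational, in the spirit of the observable claims it supports.
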