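---
title: "Models and methods behind arraycrit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arraycrit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arraycrit)
```

# The conformational-spread model

The bacterial chemosensory array is modelled as an $L \times L$ lattice of
allosteric units with free boundary conditions. Each unit is active
($\sigma_i = +1$, $a_i = 1$) or inactive ($\sigma_i = -1$, $a_i = 0$), and
the lattice energy in units of $k_BT$ is

$$\mathcal H = -J \sum_{\langle ij\rangle} \sigma_i \sigma_j
  + \left(\tfrac{H_b}{2} + \tfrac{H_L}{2}\right) \sum_i \sigma_i ,$$

with nearest-neighbour coupling $J$, a biasing field $H_b$ (possibly
per-site) and a ligand field $H_L$. The sign convention makes a *positive*
field penalize activity, so a positive ligand step mimics attractant
(kinase shut-off). A unit flips with rate

$$\omega(\sigma_i \to -\sigma_i) = \omega_0
  \exp\!\left[-J\sigma_i \textstyle\sum_j \sigma_j
  + \left(\tfrac{H_b}{2}+\tfrac{H_L}{2}\right)\sigma_i\right],$$

which satisfies detailed balance against $e^{-\mathcal H}$ exactly (the
test suite checks the flip-rate ratio against the energy difference to
machine precision, and compares long-run kinetic Monte Carlo occupancies on
$2\times2$ and $3\times3$ lattices against exact Boltzmann enumeration).
$\omega_0$ is the fundamental flip frequency of a single unit; simulations
use $\omega_0 = 1$, so all simulated times are in units of $1/\omega_0$.
The finite-size scaling analysis later calibrates $1/\omega_0$ to tens of
milliseconds, and a sampling interval of $33/\omega_0$ then corresponds to
1 Hz acquisition.

## Kinetic Monte Carlo scheme

The dynamics are simulated rejection-free: one exponential waiting time is
drawn from the total event rate and one uniform draw selects the event,
with per-event cost $O(\log N)$ through a binary sum tree over all event
channels. After a spin flip only the flipped site and its at most four
neighbours are re-rated. For the homogeneous, non-adapting model the flip
rate depends only on $(\sigma_i, \sum_j \sigma_j)$ and is served from a
pre-computed table. All randomness comes from R's RNG, so `set.seed()`
makes whole trajectories bit-reproducible.

## Adaptation feedback

Methylation enters as a per-site biasing field. Each unit carries an
integer methylation level $m_i \in [0, M]$ with $M = 64$ (about eight
receptor dimers of eight methylation sites each) and offset $m_0 = M/8$.
Active units demethylate at rate $k_B$, inactive units methylate at rate
$k_R$; these events share the continuous-time event queue with the spin
flips, and moves that would leave $[0, M]$ are suppressed (saturation).
The calibrated magnitude is $k_R = k_B = (n_R/L^2)\,V_R/\omega_0 =
0.0015\,\omega_0$ for $n_R = 200$ adaptation enzymes at $V_R = 0.1\,
\mathrm{s^{-1}}$ on a $20\times20$ array.

We set the field to $H_{b,i} = \alpha\,(m_0 - m_i)$, i.e. methylation
*favours* activity. Combined with the activity-dependent (de)methylation
rule this is a negative feedback: an active unit demethylates, its field
rises, and it is pushed toward inactivity. The opposite sign (field
$\alpha(m_i - m_0)$ under this Hamiltonian's field convention) would make
the feedback positive and destroy the adaptive fixed point; the
steady-state activity $a_0 = k_R/(k_R + k_B)$ and perfect re-adaptation
after ligand steps of either sign are verified by simulation tests, so the
negative-feedback sign is the one the model's own stated behaviour
requires. Adaptation is implemented in $\pm\alpha$ steps per methylation
event via the integer $m_i$; a continuous-field variant would differ only
at $O(\alpha)$ resolution in the local field.

# FRET preprocessing

Per cell, the acceptor/donor ratio $R(t) = A(t)/D(t)$ is corrected for
photobleaching by dividing a fitted exponential trend, converted to the
ratiometric index $\mathrm{FRET}(t) = (R - R_0)/(R + \alpha)$ with setup
constant $\alpha = 0.3$ and $R_0$ the mean ratio during
saturating-attractant windows, and normalized by the mean index during
saturating-repellent windows, so activity is pinned to 0 and 1 by the two
stimulus classes. Window edges are trimmed by two samples to avoid
flow-exchange transients, and negative activities are retained (clipping
would bias dwell statistics near $a = 0$).

The bleach trend deserves care: the kinase telegraph rides on the ratio,
so a naive exponential regression through the buffer samples absorbs
whichever state happens to dominate early or late in the recording. The
first-pass fit therefore alternates a two-level classification of the
detrended log-ratio with a shared-slope/two-intercept regression on the
plateau samples; it is exact for noise-free two-level traces and robust
otherwise. Two-state cells additionally get the second-pass refinement:
residual drift is re-fitted on dwell segments of the dominant state only,
and the trace is renormalized by the upper histogram peak before events
are re-extracted.

Receptor-cluster intensity from 1D profiles is summarized as
$\Delta I = I_{\max} - \langle I\rangle$ with $\langle I\rangle$ the
arithmetic mean over the sampled profile; $\Delta I$ is non-negative and
invariant under constant offsets.

# Switching statistics

## Experimental-trace pipeline

Activity traces are low-pass filtered with a centred 3-s moving average
and switching events are detected as local peaks of the per-sample
derivative of the filtered signal. Defaults: derivative threshold 0.10
activity units per sample, minimum separation 5 s, amplitude from the
difference of 4-s flanking medians offset by a 2-s gap (so the windows sit
on the plateaus, not the ramp), and a minimum amplitude of 0.3. The
threshold pair was chosen so that pure Gaussian noise of $\sigma = 0.1$
produces fewer than one false event per 1000 s trace, which the suite
verifies over 30 seeds; a derivative threshold low enough to fire inside
such noise (e.g. 0.05/sample, where the filtered noise derivative has
s.d. $\approx 0.047$) cannot satisfy that null property, which is why the
amplitude veto exists. Candidates whose amplitude sign contradicts the
derivative sign are discarded, and of two same-direction events in close
succession (echoes of one transition) only the stronger is kept - a
two-state signal must alternate.

Each event's transition time $\tau$ is the time constant of a saturating
exponential $a(t) = a_{\rm pre} + \Delta a\,(1 - e^{-(t-t_0)/\tau})$
fitted around the event. The fit compares the *filter-convolved* model
against the filtered trace (removing the widening bias a moving average
would otherwise introduce), anchors the plateaus on flanking medians that
iteratively exclude the fitted ramp extent, and optimizes $(t_0, \log\tau)$
by a coarse grid followed by bounded quasi-Newton refinement. Events whose
neighbour-truncated context is shorter than a third of the fit window keep
$\tau$ flagged missing rather than biased. On mock traces with the
experimental signal-to-noise ratio ($\sigma = 0.15$ at 1 Hz, residences of
50 s, ramps of 5 s), the detector recovers dwell and transition means
within 10%.

Residence times are the gaps between consecutive events, with the interval
before the first event and the censored terminal interval dropped. A cell
is two-state when at least 65% of its transitions have amplitude at least
0.7; raising the thresholds to 80%/0.8 moves the summary statistics by
less than 5%. Per-cell outputs include the activity bias
$\langle a\rangle$, the well free-energy difference $\Delta G =
\ln[(1-\langle a\rangle)/\langle a\rangle]$, Arrhenius fits $\langle\Delta
t_{\rm up,down}\rangle(\Delta G) = \langle\Delta t\rangle
e^{-\gamma_{\rm up,down}\Delta G}$ (unweighted least squares in log space;
the characteristic $\langle\Delta t\rangle$ is read at the crossing of the
two lines), maximum-likelihood exponential dwell fits with
Kolmogorov-Smirnov diagnostics, energy landscapes $-\ln p(a)$, the
timescale ratio $r = \langle\Delta t\rangle / \langle\tau\rangle$ with
$\langle\tau\rangle = (\langle\tau_+\rangle + \langle\tau_-\rangle)/2$,
and the noise strength $\eta = \sigma_a / a_0$.

## Simulation-trace pipeline

Noise-free simulated traces admit a more robust event definition, used by
the finite-size sweeps: the two state levels are located from the activity
histogram peaks and events are complete alternating crossings between the
10% and 90% amplitude bands. The residence time is the gap between
consecutive mid-amplitude crossings and the transition time is the
band-to-band traversal duration - the duration of the activity transient.
This duration convention (rather than the fitted exponential time
constant, which is about $\ln 9 \approx 2.2$ times smaller for an
exponential ramp) is what makes the simulated timescale ratio
commensurable with the experimentally printed residence and transition
times: with it, the simulated residence time at $(L = 20, J = J^*(L))$ is
about $1.6 \times 10^3/\omega_0$ (47 s at $1/\omega_0 = 30$ ms) with
$r \approx 10$, matching the measured two-state statistics, and the
$r = 9$ and $r = 12$ isolines hug the finite-size critical coupling.
Because comparisons of transition-time *shapes* are made on
mean-normalized distributions, they are insensitive to this convention
factor. The extractor cannot see dwells shorter than the traversal itself;
by memorylessness this truncation only shifts the dwell distribution, so
exponentiality checks subtract the observed floor first.

# Finite-size scaling

The timescale ratio $r$ cancels $\omega_0$ and obeys
$r \approx L^{(z-b)} \exp(c_0\,\epsilon L)$ with reduced temperature
$\epsilon = |J^* - J|/J$ (referenced to $J^*(\infty) = \ln(1+\sqrt2)/2
\approx 0.4407$ by default, configurable). The finite-size critical
coupling is $J^*(L) = J^*(\infty)/(1 - c\,L^{-1})$ with $c = 1.25$ for
free boundaries. Scaling constants are fitted in two stages: $b$ and
$c_\tau$ from a log-log regression of $\langle\tau\rangle$ on $L$ (the
residual $J$-dependence of $\tau$ near criticality is weak and treated as
noise), then $z - b$ and $c_0$ jointly from a regression of $\ln r$ on
$\ln L$ and $\epsilon L$; on synthetic tables generated from the law with
5% noise all four constants are recovered within 10%. Isolines
$J_r^{\rm iso}(L)$ invert the swept $r(J)$ per lattice size by a local
linear fit of $J$ against $\ln r$ around the target (robust to sampling
noise, and avoiding curvature over wide $J$ ranges), and are reported as
percent deviations from $J^*(L)$. The polarized/non-polarized phase
diagram uses the peak-valley ratio of the activity histogram with a
default threshold of 3, sanity-checked by the requirement that the phase
boundary tracks $J^*(L)$. Calibration of the fundamental frequency along
an isoline uses $\omega_0 = r\,c_\tau L^b / \Delta t_{\rm exp}$.

Sweeps grow each $(L, J)$ run adaptively until a target number of
switching events is banked (100 per point for the isoline grids used in
the tests, over $L \in \{12, 16, 20, 24\}$ and five couplings within
$\pm3\%$ of $J^*(L)$), with deterministic per-point sub-seeds.

# Step-response analysis

Non-adapting responses start from an all-active array and apply a ligand
step $\Delta H$ at $t = 0$; the response time is the mean first crossing
of $a = 0.5$ across replicates (replicates that never cross are censored
at the window end and flagged), and the response amplitude is
$1 - \langle a\rangle_{\rm post}/0.5$ with the post-response level read
from the late-time plateau. Adapting responses pre-equilibrate one
feedback chain and branch replicates off decorrelated snapshots; the
response time and trough come from an exponential fit restricted to the
decay segment before re-adaptation, since the mean trace recovers to
$a_0$ afterwards. Saturating responses are summarized by a logistic
(sigmoidal) midpoint fit. All response fits are bounded least squares -
degenerate inputs (a response completed within a single sample, or a
trace with no decaying structure) raise an error rather than returning a
spurious time constant. The speed-amplitude scan tabulates amplitude and
speed $1/t_R$ over a $(J, \Delta H)$ grid and marks the rows nearest
$J^*(L)$ as the critical isoline.

# Synthetic data

The generator produces two-state telegraph activity with alternating
exponential dwells, deterministic saturating-exponential transition ramps
(optionally with per-event ramp constants resampled from an empirical
distribution), clamping to attractant/repellent windows, and additive
Gaussian noise; fluorescence channels are built by inverting the
ratiometric index with per-channel exponential bleaching and
multiplicative intensity noise. Defaults mirror the measured switching
phenotype: residences of order 50 s, ramps of 5 s, 1 Hz sampling, activity
noise $\sigma = 0.15$ (the published signal-to-noise figure is not
reproducible from the text, so recovery tests treat $\sigma$ as a knob),
bleach constants of 500-800 s. Every generator returns a machine-readable
ground-truth record.

What the generator does *not* emulate: camera shot noise and photophysics
(channel noise is Gaussian), drift and segmentation artefacts, multi-array
cells with more than two output levels, and any correlation between
transition and residence times. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to every artefact of real recordings.

# Problem sizes and numerical choices

The test suite and acceptance checks run at deliberately reduced
statistics chosen to keep each check to minutes on one core: occupancy
oracles use $4{-}6 \times 10^6$ events per parameter set; the two-state
statistics use $8 \times 10^5/\omega_0$ runs at $L = 12$; the isoline grid
uses 100 events per $(L, J)$ point; response scans use 16-24 replicates.
These sizes give sampling errors comfortably inside the stated tolerances
(e.g. total-variation distance below 0.01 against exact enumeration, and
isoline deviations within $\pm3\%$ of $J^*(L)$ with roughly $2\%$ Monte
Carlo wobble). Tolerances on closed-form checks are exact to machine
precision; stochastic checks use fixed seeds throughout.

# Known limitations

- The dynamics are strictly equilibrium (detailed balance); the measured
  asymmetry between upward and downward transition times in real arrays
  is a non-equilibrium signature outside this model's scope, as are
  cluster-update or three-state schemes.
- The transition-time convention for simulated sweeps (transient duration)
  and for per-event experimental fits (exponential time constant) differ
  by a factor of about $\ln 9$ for exponential ramps; mean-normalized
  shape comparisons are unaffected, but absolute cross-pipeline ratios
  should use one convention consistently.
- Bond disorder is limited to i.i.d. two-species site labels with a single
  cross-coupling; spatially correlated receptor patches are not modelled.
- `exact_equilibrium()` enumerates at most $3\times3$ lattices; it is an
  oracle for tests, not an analysis tool.
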