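---
title: "Methods: trial-aligned photometry and single-unit analysis"
author: "habpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-aligned photometry and single-unit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habpipe)
```

habpipe analyses trial-aligned recordings from behaving animals: continuous
fiber-photometry calcium signals (GCaMP fluorescence digitized at 500 Hz) and
spike-sorted single units, both aligned to behavioural events such as cue
onsets, intra-oral infusions, footshocks, or attack bouts. This vignette
documents the statistical procedures, their assumptions, the tunable
parameters, and the design decisions taken where the methods left genuine
freedom. It also describes exactly what the synthetic-session generators
emulate, because they are the ground-truth test bed against which every stage
of the pipeline is validated.

## Event-related fluorescence

Raw traces are smoothed with a centred moving-average filter (span 0.020 s;
edge windows shrink so the output length is preserved), then segmented and
aligned to event onsets. The fractional fluorescence change is computed per
trial as

$$\Delta F/F = \frac{F - F_0}{F_0},$$

where $F_0$ is the mean raw fluorescence over a baseline window belonging to
that trial. The default baseline is the 1.5 s window ending 0.5 s before
onset, i.e. $[-2.0, -0.5]$ s; for social-interaction bouts the window ends
3.5 s before onset ($[-5.0, -3.5]$ s) so that chasing immediately before an
attack does not contaminate the baseline. Both are configurable. Two
properties follow directly from the definition and are enforced by tests:
$\Delta F/F$ is invariant to rescaling the raw trace by any positive
constant, and alignment is invariant to a common time shift of trace and
events. Trials whose baseline mean is not positive are excluded with a
warning rather than silently repaired; if every trial is excluded the
computation errors.

One interpretive choice deserves a flag: the phrase "a 1.5 s-long control
window (typically set 0.5 s) prior to a trigger event" is ambiguous between
a window of length 1.5 s separated by a 0.5 s gap and other readings. We
treat 1.5 s as the length and 0.5 s as the gap; both numbers are exposed as
arguments.

Response summaries are taken from the trial-averaged trace: the peak
$\Delta F/F$ and its latency inside a response window, the AUC as the plain
sum of samples over a window (so it is additive over any partition of the
window), and the decay time constant from a least-squares fit of
$A e^{-t/\tau}$ to the mean trace from its peak to the window end
(Levenberg–Marquardt via minpack.lm, $\tau$ initialized at the $1/e$
crossing, bounded positive). When the peak is not positive the fit is
skipped and flagged. We deliberately fit only the two-parameter
mono-exponential: adding an offset or linear-trend term makes the model
practically non-identifiable over a 10 s window when $\tau$ is 5–8 s, and
in synthetic experiments such terms *increased* the error on the known
decay constant. The residual photobleaching trend inside a trial biases the
fitted $\tau$ by only a few percent at the default drift rate (see below).

## The max-|T| multivariate permutation test

To decide where a response differs from baseline without parametric
assumptions, and with family-wise control over the thousands of timepoints
in a trial, we use a sign-flip permutation test with the maximum-statistic
correction:

1. Subtract each trial's own baseline-window mean from that trial.
2. Observed statistic: the pointwise one-sample t across trials, $T(t)$.
3. Null: random sign flips of whole baseline-subtracted trial traces
   (default 1000 permutations). For each permutation record
   $\max_t |T^*(t)|$.
4. Corrected pointwise p-values:
   $p(t) = \frac{1 + \#\{\max_t|T^*| \ge |T(t)|\}}{n_\text{perm} + 1}$,
   with ties counted as exceedances (conservative) and the add-one
   convention so $p \ge 1/(n_\text{perm}+1)$.
5. Significant segments are the maximal runs of $p(t) < \alpha$ (default
   0.05, two-tailed), split by the sign of $T$.

Sign-flipping whole trials preserves within-trial autocorrelation, which is
essential for smoothed photometry data; the exchangeability assumption is
symmetry of the per-trial deviations around zero under the null. When
$2^{n}\le 4096$ the test can enumerate all sign patterns (`exact = TRUE`,
automatic when `n_perm` covers the full set), in which case p-values are
exact and the unit tests verify them against independent brute-force
enumeration. For speed, the implementation uses the fact that sign flips
leave the per-timepoint sum of squares invariant, so the permutation
distribution needs only one matrix product per draw; the observed and null
statistics go through the identical transform, so this is an algebraic
rewrite, not an approximation.

Scalar response strengths are compared between conditions with a label-
shuffling permutation test on the difference of means (two-tailed, add-one,
exhaustive when there are at most 4096 splits), and distributions with the
two-sample Kolmogorov–Smirnov test (`stats::ks.test`).

Trial-level permutation is implemented; for group plots across animals the
same functions apply after per-animal averaging (one row per animal), which
is how the package expects animal-level inference to be done.

## Sliding-window ROC profiles

Activation/inhibition profiles come from receiver-operating-characteristic
analysis of per-trial responses: a 200 ms test window advanced in 50 ms
steps is compared against a fixed 200 ms control window just before trial
onset ($-2$ to $-1.8$ s). Each trial is summarised by its mean
$\Delta F/F$ inside the window (summarising first keeps the observations
exchangeable across trials; pooling raw samples would not be), and

$$\mathrm{AUC} = P(A > B) + \tfrac{1}{2} P(A = B)$$

is computed by the rank method, identical to the Mann–Whitney statistic
divided by $n_A n_B$. AUC $> 0.5$ means activation relative to the control
period, $< 0.5$ inhibition. Between-condition selectivity uses the same
sliding windows on two conditions' per-trial means: 1 is complete
selectivity for condition 1, 0 for condition 2; raw window means are
compared without control-window normalization. Windows are selected
half-open $[s, s+0.2)$ on the sample grid, and the control window uses the
same rule, so a test window at the control position yields AUC exactly 0.5;
windows that would extend past the time axis are dropped, not padded.
Optional per-window p-values come from shuffling the test/control labels.

## Peri-event time histograms and standard scores

Spike trains are binned in 50 ms bins around each event and divided by the
bin width; before smoothing, summed counts exactly equal the number of
spikes inside the windows, and this integer identity is tested. Smoothing
is per-trial convolution with a normalized Gaussian ($\sigma$ = 50 ms)
truncated at $\pm 4\sigma$ with reflected edges, preserving rate mass away
from (and largely at) the boundaries. Standard scores are computed from the
trial-averaged profile: $z = (\bar r - \mu_c)/\sigma_c$ with $\mu_c,
\sigma_c$ the mean and standard deviation over the bins of a control period,
by default the 2 s before cue onset. Whether that dispersion should be taken
across control bins or across trials is not dictated by the method
description we follow; we use across-bins of the trial-averaged profile,
which makes the z-profile a deterministic function of the mean PETH and is
flagged in the documentation. A zero control-period dispersion flags the
unit rather than producing infinities.

## Optogenetic tagging

Units are identified as opsin-expressing by three joint criteria, applied
with strict inequalities:

* waveform correlation: Pearson correlation $C$ of the concatenated
  per-channel mean waveforms of spontaneous versus light-evoked spikes must
  exceed 0.85;
* evoked spiking: per 5 ms, 10 Hz light pulse, the first spike within 10 ms
  of pulse onset defines the latency, and the fraction of pulses with such
  a spike is the reliability $R$;
* bootstrap p-value: the observed statistic is ranked against surrogate
  pulse trains placed uniformly at random in the stimulation-free epoch
  preceding the real train (which must span at least 10x the train length).
  Each surrogate shifts the entire train, preserving the 10 Hz inter-pulse
  structure and hence within-train dependence.
  $p = (1 + \#\{\text{surrogate} \ge \text{observed}\})/(n_\text{boot}+1)$;
  units with $p < 0.001$ (requiring $n_\text{boot} \ge 1000$) and
  $C > 0.85$ are tagged.

The published criterion compares evoked and bootstrapped spontaneous latency
distributions without fixing the statistic. We rank the within-window
reliability by default, because at low spontaneous rates many surrogates
have no first-spike latency at all and a reliability rank remains well
defined; a median-latency variant is available via
`statistic = "latency"` and both are documented. The bootstrap is invariant
to shifting all timestamps by a constant, which the tests check.

## Response-profile clustering

The unbiased classification of reward responses into the pure-inhibition and
inhibition-then-excitation types proceeds exactly in three steps: PCA on the
per-timepoint mean-centred matrix of standardized profiles; Euclidean
distances on the first three principal components; complete-linkage
agglomeration cut at $k = 2$. Input profiles are already z-scores, so they
are centred but not variance-scaled before PCA (scaling again would distort
relative response magnitudes). Clusters are then sorted in descending order
of the total z-score between 5 and 10 s after cue onset — the post-reward
evaluation period where the rebound lives — computed per cluster as the mean
over its units of the per-unit summed z (a per-unit mean rather than a raw
sum, so the ordering cannot be dominated by cluster size). Cluster 1 is
therefore the rebound (type II) cluster and the other is type I; ties are
broken deterministically by cluster size and flagged, as is a low contrast
between the two ordering statistics, and a profile matrix of rank below
three falls back to the available components with a warning. The procedure
contains no randomness and is invariant to input order; "minor adjustments"
are interpreted strictly as label ordering, never reassignment. The merge
heights are verified in tests against a hand-rolled maximum-linkage
agglomeration, and the dendrogram can be exported as Newick text.

## Locomotion

Speed is the rate of body-position change: Euclidean displacement over the
time step for adjacent video frames. Conditioned locomotor suppression is
scored as the mean speed in the 4 s window after cue onset, per trial, block-
averaged over 5 consecutive trials for aversive sessions and 10 for
appetitive sessions. Positions are not smoothed by default — the synthetic
tracking noise is controlled — but a running-median filter is available.
Learning onset, for both photometry and behaviour, is defined as the first
block from which a blockwise significance flag stays true for every
subsequent block.

## The synthetic-session generators

Because the original recordings are not deposited, the generators are the
package's ground truth, and their defaults are the study conditions rather
than free dials.

**Calcium transients.** The event-locked kernel is a difference of
exponentials $k(t) = c\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ with $\tau_r$
solved numerically so the peak falls at the stated time-to-peak and $c$
normalizing the peak to 1 — the minimal smooth kernel matching the two
reported quantities (time to peak and mono-exponential decay constant).
Presets: quinine (peak 0.278 dF/F, 0.68 s, 5.88 s; inter-trial intervals
110–130 s), footshock (0.488, 0.26 s, 1.89 s; 20–40 s), social attack
(0.329, 0.57 s, 7.80 s). The trace is assembled as
$F(t) = B(t)\,(1 + \sum_i A_i k(t - t_i)) + \varepsilon(t)$ with
photobleaching drift $B(t) = e^{-t/2000\,\mathrm{s}}$ and white sample noise
$\varepsilon$ (sd 0.01 dF/F). The transients enter *multiplicatively* on the
drifting baseline: only then is the fractional amplitude recovered by
$\Delta F/F$ independent of drift, which is what makes exact noiseless
parameter recovery a meaningful invariant (amplitude and time-to-peak to a
sample, $\tau$ within 1% when drift is disabled; with the default drift the
fitted $\tau$ is biased low by about 4%, well inside the 15% recovery
tolerance).

**Trial amplitude variability.** Per-trial amplitudes are lognormal with
CV 0.3 (strictly positive, magnitudes preserved for inhibitory components)
plus an additive kernel-shaped noise term with sd 0.05 dF/F emulating
spontaneous transients that coincide with the analysis windows. The additive
term is what limits detectability of small conditioned responses: a purely
multiplicative noise model makes blockwise significance scale-invariant, so
a learned response would be "significant" from the first nonzero trial gain
no matter how small. The value 0.05 was fixed once from two study
conditions: blockwise (10-trial) detection of the conditioned cue component
(−0.10 dF/F) must begin near the logistic half-point (threshold
$\approx 2.26 \cdot 0.05/\sqrt{10} \approx 0.036$ dF/F, i.e. gain
$\approx 0.4$), and single 10-trial unconditioned sessions must reliably
show significant post-onset segments under the max-|T| test, as the recorded
sessions do.

**Learning.** The cue-locked component is scaled by a logistic gain in trial
number with half-point $h$ and scale $h/10$, anchored so the gain is exactly
0 on trial 1 and saturates at 1. Defaults $h = 7$ for aversive conditioning
(detectable within 5–10 trials) and $h = 135$ for appetitive conditioning
(detectable around 120–150 trials). The reward-probability task preset
delivers the US with 75% or 25% probability per cue.

**Spiking.** Conditioned units are inhomogeneous Poisson trains (thinning of
a homogeneous train at the peak rate) whose intensity steps from a 30
spikes/s baseline to 25 during cue and delay and 20 during reward delivery,
then relaxes exponentially back to baseline — from below for type 1 (pure
inhibition; never exceeds baseline) or from a 40 spikes/s rebound for type 2
(inhibition-then-excitation), with a 1.5 s relaxation constant. The rate
function itself is exported as the noiseless oracle for the PETH stages.
Population ensembles share one trial schedule; each member's seed is derived
from the master seed and its index, so member data are independent of
generation order. The default mixture is 37 type 1 + 33 type 2 units (the
recorded single-unit composition) and 9 + 9 for the photometry-site
ensemble, whose site presets stack cue inhibition (−0.10), reward inhibition
(−0.15) and, for type 2 only, a +0.20 rebound transient after reward offset
— site-level magnitudes are generator choices since none are reported, with
the rebound set well above profile noise so the ensemble is separable the
way the recorded one was.

**Tagging.** A tagging epoch is spontaneous Poisson firing (30 spikes/s)
over a long stimulation-free stretch followed by 600 pulses of 5 ms at
10 Hz; each pulse evokes a spike with probability 0.9 at a 3 ms latency
(1 ms jitter), and the evoked mean waveform is the spontaneous one plus a 2%
perturbation.

**Locomotion.** A planar Gaussian random walk at the 25 Hz frame rate whose
step size in the 0–4 s post-cue window is scaled by a per-trial suppression
gain.

What the generators do **not** emulate: biophysical GCaMP kinetics
(saturation, nonlinearity), hemodynamic or movement artifacts, isosbestic
control channels, bursting or refractory structure in spike trains,
electrode drift, or correlated noise across simultaneously recorded units.
Passing the recovery tests therefore shows that the pipeline's estimators
are correct for the declared signal model at realistic noise levels — it
does not certify robustness to artifact classes the generators do not
produce.

## Determinism and seeds

Every stochastic stage takes an explicit integer seed; a fixed seed gives
byte-identical output, and composite generators derive member seeds from the
master seed by index. The sampled permutation and bootstrap tests are
deterministic given their seed; the exhaustive variants are deterministic
outright and invariant to trial order.

## Problem sizes used by the test suite and acceptance script

The validation suite runs at the study's scales where that is what is being
claimed, and at reduced scales where only calibration is being spot-checked:
group transient recovery uses 7 quinine, 8 footshock and 7 social sessions
of 10 trials; the population analyses use 70 units (or 18 photometry sites)
with 100 trials each; null calibration of the max-|T| test uses 1000
signal-free sessions at 1000 permutations in the acceptance script and a
200 x 200 spot-check in the unit suite; the null ROC calibration uses 100
signal-free sessions; tagging calibration uses 200 unmodulated units at
1000 surrogates each. These sizes are the package's validation design and
are stated here so results are reproducible exactly.

## Known limitations

* The decay-constant estimator assumes an isolated mono-exponential tail;
  heavily overlapping transients (inter-event intervals much shorter than
  $\tau$) bias it, and the generators' quinine preset with 110–130 s
  intervals does not exercise that regime.
* The max-|T| test controls the family-wise error at the trial level; it
  does not model between-animal variance components. Animal-level inference
  requires pre-averaging, as noted above.
* With fewer than ~8 trials the sign-flip null is coarse
  ($p \ge 2^{-n}$), and segments at $\alpha = 0.05$ are only attainable at
  all for $n \ge 6$.
* The tagging p-value floor is $1/(n_\text{boot}+1)$, so the 0.001
  threshold requires at least 1000 surrogates.
* The z-profile convention (dispersion across control bins of the mean
  PETH) makes z-magnitudes grow with trial count; comparisons across
  datasets should hold trial counts fixed or rescale.
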