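---
title: "Decomposing spike-count variability into spiking irregularity and rate variability"
author: "spikevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing spike-count variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikevar)
```

## The model

Trial-to-trial variability of neural spike counts is usually summarized by
the Fano factor, $FF(T) = \mathrm{Var}(N_T)/E[N_T]$ for counts $N_T$ in a
window of width $T$. For a doubly stochastic point process -- one whose
interspike-interval (ISI) parameters $\gamma_i$ are themselves drawn per
trial -- the law of total variance splits the count variance into the
expected conditional variance (EVC, produced by the irregularity of spike
generation within a trial) and the variance of the conditional expectation
(VEC, produced by parameter variation between trials):

$$\mathrm{Var}(N_T) =
  \underbrace{E[\mathrm{Var}(N_T \mid \gamma_i)]}_{EVC} +
  \underbrace{\mathrm{Var}(E[N_T \mid \gamma_i])}_{VEC}.$$

Normalizing by $E[N_T]$ gives the working identity of this package,

$$FF(T) = n\Psi + T \cdot nRV,$$

with $n\Psi = EVC/E[N_T]$ the *normalized spiking irregularity*
(dimensionless) and $nRV = VEC/(T\,E[N_T])$ the *normalized rate
variability* (1/s). For renewal ISIs with per-trial rate $\lambda_i$ and
ISI variance $\sigma_i^2$, the large-$T$ limits are
$n\Psi = E[\lambda_i^3\sigma_i^2]/E[\lambda_i]$ -- the ISI $CV^2$, equal to
$1/\kappa$ for a gamma ISI of shape $\kappa$, independent of the ISI family
otherwise -- and $nRV = \mathrm{Var}(\lambda_i)/E[\lambda_i]$
([`theoreticalDecomposition()`]). FF is therefore asymptotically linear in
$T$: the intercept isolates how *irregularly* spikes are placed within
trials, the slope how much the *intensity* varies across trials. The two
components respond to entirely different biological mechanisms, which is
why estimating them separately, and in time, is worth the trouble.

## Estimators

**FF-asymptote (FFA).** [`fanoVsBinsize()`] computes $FF(T)$ over nested
windows and [`ffaFit()`] fits a weighted least-squares line over the
*linear zone*, defined as the largest contiguous upper range of the width
grid with mean count $\ge$ 5 spikes per window (below roughly 5 spikes the
pre-asymptotic transient visibly bends the curve). Weights are $1/sem^2$
with bootstrap-over-trials standard errors. The intercept estimates
$n\Psi$, the slope $nRV$; negative values are floored at 0 with a warning,
since both are variances in origin.

**Sub-bin (Vinci-style) estimator.** The line fit is noisy: small changes
in slope swing the intercept. [`vinciNpsi()`] instead estimates EVC
directly from one realization per trial by splitting the counting window
into $m$ equal sub-bins and using the variance of sub-bin counts *within*
each trial, which is blind to between-trial rate variability. Two
refinements matter:

* sub-bin counts are column-centered (the across-trial mean of every
  sub-bin is subtracted) so that a rate modulation shared across trials
  does not masquerade as irregularity; and
* the statistic is computed at $m$ and $2m$ sub-bins and extrapolated
  linearly in the reciprocal sub-bin width. For an equilibrium renewal
  process $FF(w) = CV^2 + C/(\lambda w) + o(1/w)$, so the two-scale
  extrapolation cancels the leading short-window bias -- the raw sub-bin
  statistic is simply $FF$ at the sub-bin width, which can be off by
  15--30% at realistic counts (positively for $\kappa > 1$, negatively for
  $\kappa < 1$).

The default sub-bin count is $m = \max(2, \min(10, \lfloor \bar N/4
\rfloor))$ so the coarse scale keeps roughly 4 spikes per sub-bin; on
gamma benchmarks with $\kappa \in \{0.5, 2, 4\}$ the estimator is then
unbiased to within a few percent at 1000--2000 trials. Given $n\Psi$, the
rate variability follows from the identity as
$nRV = (FF - n\Psi)/T$ ([`nrvFromFano()`]), so the reported triple always
satisfies $FF = n\Psi + T \cdot nRV$ exactly before flooring.

**CV2 and the nPPV.** The local irregularity statistic
$CV2_j = 2|I_{j+1}-I_j|/(I_{j+1}+I_j)$ of adjacent ISI pairs is robust to
slow rate changes. For a gamma renewal process the ratio
$I_j/(I_j+I_{j+1})$ is Beta$(\kappa, \kappa)$, which gives the calibration
curve in closed form,
$g(\kappa) = E[CV2] = 4\,(1 - B_{1/2}(\kappa+1, \kappa)) - 2$
(regularized incomplete beta), exactly 1 for a Poisson process.
[`cvLocal2()`] pools CV2 across trials and returns $1/g^{-1}(\overline{CV2})$,
the normalized point-process variability (nPPV) on the same $1/\kappa$
scale as $n\Psi$. For a renewal process $n\Psi =$ nPPV; history-dependent
violations such as bursting inflate $n\Psi$ *beyond* nPPV, which is what
makes the pair diagnostic.

**Empirical oracle.** For simulated schedules,
[`empiricalDecomposition()`] draws $K$ parameter sets and $R$ realizations
of each and computes EVC and VEC literally from the law of total variance.
It is the benchmark all single-realization estimators are compared against
in the test suite. Realized within-trial rate paths (noise increments,
switching times) count as parameters: realizations of a draw share the
path. This matters for interpreting the comparisons below.

**VarCE.** The comparator method [`varce()`] assumes a *constant*
irregularity coefficient $\phi$ over time, chooses the largest constant
keeping $\mathrm{Var}(N) - \phi E[N]$ non-negative across windows (the
smallest windowed FF; the minimum attains exactly 0), and reports the
remainder as rate variability. Two failure modes follow from the
construction and are reproduced in the acceptance tests: VarCE tracks VEC
only up to an additive offset even when $\phi$ truly is constant, and when
$n\Psi$ varies in time with no rate variability at all, VarCE reports the
$n\Psi$ fluctuations as spurious VEC.

## Simulators

Homogeneous renewal trains ([`sampleRenewal()`], exponential, gamma,
inverse Gaussian families) are started in equilibrium: the first event is a
uniform fraction of a length-biased ISI (for gamma $\kappa$ that is gamma
$\kappa+1$), so counts are stationary from the window start -- visible in
the FF-vs-binsize curves, which would otherwise show a small-$T$ artifact.
The inverse Gaussian family has no similarly convenient residual sampler
and uses a 10-mean-ISI burn-in instead.

Inhomogeneous trains ([`sampleInhomogeneousRenewal()`]) use operational
time rescaling: unit-mean gamma ISIs accumulated in
$\Lambda(t) = \int \lambda$, inverted on a 1 ms grid, with the shape taken
as $\kappa$ at the previous spike and a 5-mean-ISI burn-in before the
window. With constant schedules this reduces to the homogeneous sampler
(property-tested on ISI moments). A consequence of the shape-at-previous-
spike rule worth knowing: at an abrupt $\kappa$ step the ISI already in
progress belongs to the old regime and is length-biased, so estimates in
windows overlapping a step are smeared over roughly 100 ms; the benchmark
analyses exclude such windows.

[`sampleDoublyStochastic()`] draws per-trial parameters from a
[`makeSchedule()`] object, applies rate perturbations (noise, switching)
before generation and burst injection ([`injectBursts()`]) after, and
records *every* per-trial random quantity -- rate draws, noise increments,
switch times, burst-replaced spike indices -- in the ensemble's ground
truth, so simulations are fully replayable and estimators can always be
scored against what actually generated the data.

### The doubly stochastic gamma benchmark

The central validation schedule (`makeSchedule("benchmark")`) superimposes two
independently scheduled sources of variability on a 50 Hz gamma process
over the trial window $[-0.5, 1.5)$ s:

* **Rate variability**: $\lambda_i(t) = 50 + n_i\,m(t)$ Hz with
  $n_i \sim N(0, 30^2)$ and $m(t) = (1 - 5t_+ + e^{-2t_+})_+$, clamped at
  zero. $m$ equals 2 before the alignment event and decays to 0 by
  $t \approx 0.3$ s: the between-trial rate spread collapses after the
  event. A mirrored copy of $m$ at `tRec` = 1.4 s restores the spread
  towards the trial end, so the benchmark exhibits a transient collapse of
  rate variability with a later recovery rather than a one-way change. The
  $N(0, 30)$ spread is read as sd = 30 Hz; the variance reading is a
  configuration option (`nIsVariance`).
* **Spiking irregularity**: $1/\kappa$ steps from 2 to 0.25 at
  `tOn` = 0.3 s and back at `tOff` = 0.8 s. The shape change is
  deliberately placed *after* the rate-variability collapse has completed:
  the two onsets are asynchronous, so the sliding decomposition must
  recover two changes that do not coincide -- the point of the benchmark.

Running `slidingDecomposition()` (300 ms bins, 50 ms steps, sub-bin
estimator) on 2000--3000 trials of this schedule recovers the baseline
$n\Psi \approx 2$, the plateau $n\Psi \approx 0.25$, the collapse of nRV
from $\approx 44$/s to $\approx 0$ and its late recovery, with CVlocal2
tracking $1/\kappa$ throughout -- the package's headline acceptance
computation (`scripts/acceptance.R`).

### Perturbation defaults and what they emulate

* **Bursting**: each spike is replaced with probability 0.05 by 5 spikes at
  3 ms spacing -- a deliberate violation of the renewal assumption.
  $n\Psi$ inflates beyond CVlocal2, which is exactly how the package
  separates burst-driven irregularity from point-process variability.
* **Rate noise**: per-trial piecewise-constant white noise, variance
  3 Hz$^2$ per 50 ms step on a 10 Hz base. The $N(0,3)$ notation is read
  as a variance (the $N(\mu, \sigma^2)$ convention; pass `sd` for the
  other reading). The choice matters: a single-realization estimator
  necessarily absorbs the within-trial rate autocovariance
  $2\,\mathrm{Var}\,\tau/\bar\lambda$ into its intercept, which is +3% of
  $n\Psi$ under the variance reading but +9--10% under the sd reading --
  only the former is consistent with the estimators' documented tolerance
  of rate noise, so it is the default.
* **Rate switching**: two-state telegraph rate (0.25 and 1.75 times the
  base) with exponential dwells of mean 10 ms. Switching is rapid relative
  to any counting window; in this regime the estimators overestimate
  $n\Psi$ only slightly (one-sidedly), while slow switching (100 ms
  dwells) would push the entire switching variance into the intercept and
  make the decomposition ill-posed for single realizations -- a regime the
  estimators are documented not to handle.

## Burst detection

[`calibrateBursts()`] pools ISIs from a spontaneous epoch across a pool of
units and places the burst ISI threshold at their 5th percentile, floored
at 4 ms; [`detectBursts()`] then flags maximal runs of $\ge$ 3 spikes with
all consecutive ISIs at or below threshold. Detection is deterministic
given the calibration. "Bursts per spike" is burst *events* divided by
total spikes in the window (documented unit, used consistently); the
spontaneous-epoch baseline is recorded for optional adjustment. The
detector is validated by recovery, not by absolute agreement with any
published number: detected bursts/spike is monotone in the injected burst
probability over $\{0, 0.02, 0.05, 0.1, 0.2\}$, flat in time for renewal
controls, and localized to the epoch where bursts are injected.

## The balanced E/I network experiments

A current-based leaky integrate-and-fire neuron receives 50 excitatory and
50 inhibitory Poisson inputs through the same single-exponential synaptic
kernel (5 ms), with membrane time constant 20 ms, threshold 20 units above
rest, 2 ms refractory period, and 0.1 ms exact exponential-update
integration (compiled core). The synaptic weight (14 per spike, both
signs) was calibrated once by scanning the balanced default network for an
output rate near 10 Hz, so the default operates at 5--20 Hz in the
fluctuation-driven regime; only trend directions across experiment grids
are claimed, never absolute output values, because the LIF constants have
no published counterpart.

Per-trial pool rates are bivariate normal $N(40, 4^2)$ Hz (sd reading of
$N(40,4)$; the variance reading is a configuration option) with
correlation $\rho$, clamped at 0. Correlated spiking uses the
dichotomized-Gaussian construction: per 1 ms bin, an equicorrelated latent
Gaussian vector is thresholded to match the marginal rate exactly and the
pairwise count correlation via a solved latent correlation; heterogeneous
rates keep per-neuron thresholds. Laplace jitter (sd 2 ms) is added to
*spike times* -- not literal ISIs, a documented divergence chosen because
it preserves each train's rate -- and the E$\to$I delay shifts inhibitory
spikes by its mean. [`runNetworkExperiment()`] sweeps one manipulated
variable per experiment and tabulates the single-window decomposition of
the output (the first 100 ms are excluded as integration onset transient):

* trial-to-trial E/I *rate* correlation lowers the output nRV steeply
  (to $\approx 0$ at $\rho = 1$, and below the $\rho = 0$ level for
  deterministic rates) while leaving $n\Psi$ and CVlocal2 nearly flat;
* between-pool *spike* correlation at a 2--4 ms E$\to$I delay lowers
  $n\Psi$ and raises the rate (each excitatory volley is followed by a
  cancelling inhibitory one);
* within-pool spike correlation raises $n\Psi$ and the rate (uncancelled
  excitatory bouts produce burst-like output);
* shifting the E/I ratio above 0.5 raises the rate and regularizes output
  spiking (lower $n\Psi$);
* splitting the pools into more, smaller correlated sub-pools weakens the
  between-pool correlation effects.

## Numerical choices and degenerate inputs

* Half-open $[t, t+T)$ windows everywhere; spike times in seconds; trial
  indices 0-based on disk.
* Windows with mean count below 3 spikes (configurable) are reported
  missing, never interpolated; FFA needs $\ge$ 3 usable grid points or is
  flagged unavailable.
* Negative $n\Psi$/$nRV$ estimates are floored at 0 with a warning; the
  sliding decomposition aggregates flooring warnings per run.
* All uncertainty is bootstrap over trials (default 200--500 resamples);
  "sem" always means that bootstrap standard error.
* Every stochastic operation takes an explicit seed; ensembles record it.
  Seeds derived internally stay below $2^{31}$.
* CV2 calibration is clipped to $\kappa \in [0.02, 200]$ with a warning;
  fewer than 10 pooled CV2 pairs give a missing value.
* VarCE excludes zero-mean-count windows from the $\phi$ minimum (ties
  break to the earliest window).

## Test problem sizes

The suite validates estimator accuracy at 1000--2000 trials (2 s at 10 Hz
for the validation generators, matching their published configuration),
empirical oracles at $K \times R \approx 10^4$ simulated trains,
equilibrium properties at $10^4$ trains, ISI-moment reductions at
$\ge 10^5$ ISIs, and the network trends at 500 trials per grid point over
4-point grids. Near-tolerance stochastic comparisons are asserted on means
over replicate ensembles with a 2-sem allowance, so a test fails only when
there is statistical evidence that the true error exceeds the stated
tolerance.

## Limitations

The synthetic generators emulate renewal and doubly stochastic structure,
rate noise, switching, and stereotyped bursting; they do not emulate slow
nonstationarities across a session, refractory-driven short-ISI structure,
adaptation, or cross-neuron correlations within simultaneously recorded
populations (the network module drives one output neuron). Passing tests
therefore certify the estimators under the stated generative assumptions,
not on any particular recorded dataset. $n\Psi$ estimation degrades below
roughly 5 spikes per counting window and 100--200 trials (under- and
over-estimation of nRV and $n\Psi$ respectively); the missing-data policy
makes that regime visible rather than silently wrong. The Vinci-style
estimator is specified here by its contract (sub-bin conditional-variance
with the refinements above) and validated against the empirical oracle,
not as a bit-exact port of any external implementation; likewise the burst
detector and the mean-matching procedure
([`meanMatch()`]: greedy per-bin histogram matching to the pointwise
minimum target, 2 Hz cells, 10 repeats) are documented reimplementations
of their cited ideas.
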