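---
title: "Methods: neural-mass DCM and exponential ranking of signed connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-mass DCM and exponential ranking of signed connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmrank)
```

# Overview

`dcmrank` implements a two-stage analysis for locating differentially
active brain regions in two-group resting EEG studies:

1. **Effective connectivity estimation.** Per subject and frequency band,
   a generative neural-mass model of a fixed set of cortical sources is
   inverted against sensor data with a variational Laplace /
   expectation-maximization scheme. The result is a *signed* network of
   log-gain deviations: positive edges are couplings estimated above their
   prior gain of 1, negative edges below it.
2. **Exponential ranking.** Each signed network is summarized by a trust
   probability per region via the exponential-ranking fixed point, a
   PageRank-style method built on discrete-choice theory that treats
   negative links as recursive distrust rather than discarding them.
   Group-mean rankings are then compared band by band.

Because resting EEG of the kind this method targets is rarely shareable,
the package carries a first-class synthetic-cohort generator with known
ground-truth connectivity; every pipeline stage is tested against it.

# The generative model

## Source dynamics

Each source contains three neuronal subpopulations — spiny stellate cells,
pyramidal cells and inhibitory interneurons — linked by four intrinsic
connections with strengths $\gamma_1,\dots,\gamma_4$. Synaptic dynamics
are second-order kernels $H\kappa t e^{-\kappa t}$ parameterized by the
maximum postsynaptic potentials $H_e, H_i$ (mV) and lumped rate constants
$\kappa = 1/\tau$; the defaults ($H_e=4$, $H_i=32$, $\tau_e=4$ ms,
$\tau_i=16$ ms, $\gamma = 128, 128, 64, 64$) are the standard prior means
of the ERP neural-mass literature. Rate constants enter the equations in
s$^{-1}$ (i.e. $\kappa_e = 1000/\tau_e$): with the printed contact counts
this puts every intrinsic loop gain below unity at the resting point, so
the unforced system is asymptotically stable — in the millisecond
convention the same constants would put loop gains in the hundreds and the
model would saturate into a large-amplitude limit cycle.

Population output is the baseline-centred sigmoid firing rate
$$S(v) = \frac{1}{1+e^{-\rho_1 (v-\rho_2)}} - \frac{1}{1+e^{\rho_1\rho_2}},$$
with $\rho_1 = 2$, $\rho_2 = 1$; centring makes the all-zero state an
exact equilibrium, which the tests rely on. Between sources, forward
connections target the spiny stellate population, backward connections the
pyramidal and inhibitory populations, and lateral connections all three;
the default model for the 16-region auditory resting-state ROI set uses
lateral connections between all pairs.

Two printed constants have no canonical slot in this state layout: the
fifth contact count (16) and the adaptation time constant
$\tau_a = 512$ ms. We use them together as the *input pathway*: exogenous
input is low-pass filtered by a first-order adaptation kernel with rate
$1/\tau_a$ and steady-state gain $\gamma_5 = 16$ before driving the
stellate population (`adapt_input()`). Both are configurable and the
filter can be bypassed.

The state vector has 9 components per source (four second-order synaptic
pairs plus the pyramidal depolarization $x_0$, the observation target).
Integration is fixed-step classic Runge-Kutta at 1 ms, which passes a
step-halving convergence contract of 1% relative RMS with a wide margin.

## Observation model and inversion

Sensors see $y = L\,\mathrm{diag}(K)\,x_0(t)$ through a lead field $L$.
Estimated parameters are log-scale multipliers with prior mean 0 and
prior variance $1/16$ (so the prior multiplicative gain is exactly 1):
lateral coupling deviations, input gains, and per-source contribution
gains $K$; the intrinsic synaptic constants stay frozen at their priors
by default to keep a 16-source model identifiable. Inversion maximizes
the Gaussian (Laplace) free energy
$$F = \mathbb{E}_q[\ln p(y\mid\theta)] - \mathrm{KL}(q \,\|\, p(\theta)),$$
alternating a Levenberg-damped Gauss-Newton update of $q(\theta)$
(E-step, finite-difference Jacobians) with the closed-form update of a
scalar noise precision (M-step). Steps that decrease $F$ are rejected
with increased damping, and the iteration stops — restoring the last
recorded state — if re-linearization can no longer improve the recorded
optimum, so the reported $F$ trace is non-decreasing by construction.
Note the bound we maximize includes the entropy of $q$ through the KL
term; a "free energy" lacking that term would be unbounded in $q$ and
could not define the E-step. On a one-parameter linear-Gaussian fixture
the scheme reproduces the conjugate closed-form posterior to $10^{-6}$
and $F$ equals the exact log evidence.

## Band-wise windowing

The full-scale workflow fits one DCM per subject, band and candidate
"response time" (the modeled window length: 60, 100 or 2000 ms). How a
resting recording becomes a fit target at that length is genuinely open;
we segment the band-filtered recording into consecutive non-overlapping
windows of the response-time length and average them into one
representative window. The averaged window keeps the sensor SNR of a
single window while shrinking in scale; its spatio-temporal covariance
still reflects the source network, which is what the planted-effect
recovery test exercises end to end. This windowed-average convention is a
documented stand-in, not a claim about how any particular study fitted
its models; anything that yields a channels-by-samples window can be
substituted.

The DCM's own input is a deterministic Gaussian bump per driven source.
Staggered onsets (defaults 25 ms apart in the recovery fixtures) matter:
with a single shared input all driven sources respond nearly identically
and incoming couplings become collinear; separating the activations in
time restores identifiability, which is clearly visible in
parameter-recovery rank correlations.

# Exponential ranking

For a signed weighted adjacency $A$ ($A_{ij}$ = edge $i \to j$), node
reputations and trust probabilities are
$$k = A^\top p, \qquad
  p_i = \frac{e^{k_i/\mu}}{\sum_j e^{k_j/\mu}},$$
iterated to a fixed point (tolerance $10^{-10}$ on
$\max_i |\Delta p_i|$, max 10 000 iterations, softmax computed with
max-subtraction so large reputations cannot overflow). A period-2
oscillation, possible for small $\mu$, is detected by a stalled step size
and damped by averaging successive iterates. The noise parameter $\mu$ is
meaningful only relative to the edge-weight scale; it defaults to 1 and
is always reported alongside group results. Real-valued weights are a
strict generalization of the $\pm 1$ case since reputation is linear in
$A$. In the $\mu \to \infty$ limit $p$ is uniform; permutation
equivariance and normalization are tested on seeded random networks, and
on all 729 three-node sign matrices the returned point satisfies the
fixed-point equations to $10^{-8}$.

# Group analysis

Trust probabilities are averaged over subjects within (group, band, ROI).
For each candidate response time the package computes, per band, the
variance over ROIs of the absolute difference between the two group
means, and averages the five band variances; the response time with the
largest average variance separates the groups best and is selected.
*Population* variance (divide by $N$) is the default convention — the
statistic only ranks response times, so the convention cancels; sample
variance is available as an option.

Regions are flagged "increased" when the patient-group mean exceeds the
control mean in at least `min_bands` of the five bands (default: all
five; four reproduces an "all except one band" pattern). This replaces
reading differences off bar plots with an explicit, testable rule. A
derived left/right asymmetry column (differences between homologous ROI
pairs) is reported but not tested against.

# The synthetic cohort

`generate_cohort()` emulates the recording conditions the pipeline
assumes: two groups of 14 subjects, 128 channels at 1000 Hz, 300 s of
resting EEG. Shared ground truth is a full lateral deviation matrix
(Gaussian, sd 0.3) on top of a total lateral prior gain of 32 per source
split over incoming edges; each subject adds Gaussian jitter (sd 0.1) on
the deviation scale, and the patient group adds the configured
`group_effect` shift to the couplings *into* each affected region.
Input is an independent smooth stochastic drive per auditory-cortex
source (white noise through a one-pole low-pass at 30 Hz — resting data
has no event structure to model), passed through the adaptation pathway.
The drive amplitude (150 a.u.) was chosen so pyramidal depolarizations
sit in the 0.1-0.5 mV quasi-linear range of the sigmoid, where couplings
actually transmit; the sensor noise sd default (0.01) then corresponds to
roughly 10 dB channel SNR under the default lead field. The lead field
is a seeded random Gaussian matrix with unit-norm columns — there is no
head model here, and none is claimed; supply a real lead field for real
data. Control and patient subject $j$ share their subject-level draws,
so a null cohort with zero noise yields bit-identical paired recordings,
which pins down the group-effect machinery in tests.

What the generator does *not* emulate: volume-conduction geometry,
artifacts (ocular, muscular, cardiac), non-stationarity, and
between-subject anatomical variability. Passing recovery tests therefore
demonstrates that the estimation and ranking machinery is correct and
sensitive under the model's own assumptions — not that the method is
validated on real patient EEG.

# Test problem sizes and numerical choices

The test suite runs the full stack at desk scale: parameter recovery
uses 3 sources, 16 channels, 20 windows at 10 dB SNR and 10 seeded
replicates; the end-to-end planted-effect check uses 5 sources, 16
channels, 14 + 14 subjects, 12 s recordings at 250 Hz, and ten planted
plus ten null replicates, with a +1 log-unit shift (roughly a tripled
gain — an unmistakably abnormal region, as a positive control should be)
on the couplings into one region. In the recovery fixture "deviations of
$\pm 0.5$" perturb half the couplings, leaving the rest at the prior:
with every true magnitude equal, a rank correlation between true and
estimated magnitudes would be undefined; the half-and-half design gives
the statistic a meaningful (tie-limited) ceiling of about 0.88.

Other numerical choices: finite-difference steps of $10^{-3}$ (Jacobian
of the prediction) and $10^{-4}$ (bilinear operators); Levenberg damping
multiplied by 10 on rejection and 0.3 on acceptance; the noise variance
floored at $10^{-12}$; singular Gauss-Newton systems regularized with a
$10^{-8}$ jitter and reported through the convergence flag. Zero-phase
filtering uses forward-backward elliptic designs (order 5, 0.2 dB
ripple, 40 dB stop band) for band-pass stages — their sharp transitions
let the five analysis bands tile 0.5-45 Hz to within a few percent of
broadband power, where Butterworth cascades of practical order lose over
20% at the crossovers — plus a second-order Butterworth band-stop notch
and an eighth-order anti-alias low-pass before decimation.

# Known limitations

* The windowed-average fit target for resting data is a pragmatic
  convention; spectral (cross-spectral-density) fitting would be the
  principled alternative and is out of scope.
* The lead field used for synthetic inversions is the generator's own
  (an intentional inverse crime): recovery results quantify estimator
  correctness, not robustness to head-model error.
* Manual artifact rejection and independent-component denoising are
  interactive steps; the chain exposes a pass-through hook where they
  would sit.
* With 16 sources and full lateral structure the per-window inverse
  problem is strongly regularized by the priors; absolute deviation
  magnitudes shrink accordingly, and only relative (rank, sign, group
  difference) statements are supported.
* EDF support is minimal (16-bit, uniform rate, one continuous
  recording) — enough to exchange data with standard tools, not a full
  implementation of the format's annexes.
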