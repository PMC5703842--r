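---
title: "Models and methods behind stnbart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stnbart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stnbart` implements an analysis pipeline for intracranial recordings
(single units and multichannel local field potentials, LFPs) collected
while a subject performs a self-paced, continuous-time balloon analog
risk task (BART), together with a synthetic-data generator that makes
every stage of the pipeline testable without access to intraoperative
recordings. This vignette explains the models, their assumptions, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The task and its generator

In the continuous BART, a balloon inflates from the moment the subject
starts a trial, its value growing at 30 points/s. The subject may stop
(bank) at any time; a hidden pop time is drawn per trial from a Gaussian
whose parameters depend on the balloon colour — red 3 ± 0.9 s, orange
6.5 ± 1.95 s, yellow 10 ± 3 s (standard deviation 30% of the mean). A
popped balloon earns nothing. Two control conditions exist: *forced*
trials (25% of balloons) display a pre-drawn ring at a radius sampled
from the balloon's own pop distribution and bank automatically when the
balloon reaches it, and *gray* no-reward balloons behave like forced
trials with ring radii drawn from the intermediate (orange) distribution
but earn no points.

`generate_trials()` reproduces exactly this structure. Two choices were
open:

* **Truncation.** A Gaussian pop time can be negative; negative draws
  are redrawn rather than clipped. For the task's parameterizations
  (mean/sd ratio above 3.3) the truncated mass is below 0.05%, so the
  realized moments match the nominal ones almost exactly.
* **Quota assignment.** Trial types are assigned by exact quota with a
  seeded shuffle rather than independent Bernoulli draws, so a 1,000
  trial session contains exactly 250 forced trials. This makes the
  control fractions deterministic test targets rather than noisy ones.

The task description does not state the inter-trial interval, the
outcome-epoch duration or the number of trials per session; these are
configuration parameters (defaults 2 s, 1 s, and 100) documented in
`task_config()` and not inferred from anything.

Subject behaviour is emulated by `agent_policy()`: intended stop times
are drawn per risk level from a truncated normal plus motor jitter. The
default policy stops near 85% of each colour's mean pop time, a mildly
risk-averse profile of the kind real subjects display; it exists to give
the downstream analyses realistic event streams, not to model human
learning (subjects are told the risk ordering in advance, so no
within-session learning is modelled).

## Optimal stopping

With pop time $\tau \sim N(\mu, \sigma^2)$ and reward $R = \alpha t$,
the expected reward of planning to stop at $t$ is
$\alpha t (1 - \Phi((t-\mu)/\sigma))$. `optimal_stop_time()` maximizes
this on $(0, \mu + 6\sigma]$ — beyond that range the objective is
numerically zero — by a dense 1 ms grid followed by golden-section
refinement. The objective is cheap and one-dimensional, so the grid
avoids any dependence on optimizer tolerances; a brute-force grid oracle
in the test suite agrees to within 1 ms. Because $\alpha$ only scales
the objective, the search runs internally at unit rate, which makes
invariance of the maximizer to the reward rate exact rather than
approximate.

## The spiking model

Spike counts $N$ in $\Delta t = 50$ ms bins are modelled as
$N \sim \text{Poisson}(f\,\Delta t)$ with

$$\log f = \beta_0 + \beta X + \gamma \log(t - t_0 + 1),$$

where $X$ contains an indicator for the whole trial period, separate
indicators for the inflation and outcome epochs, an indicator for
no-point outcomes (reference level: banked), and trial-type indicators
(risk high / medium / low, control) with the inter-trial baseline as
reference. The last term makes the rate grow as a power law
$f \propto (t - t_0 + 1)^\gamma$ of elapsed trial time. Elapsed time is
measured at bin centers and the natural log is used (the exponent
algebra is base-free). The regressors are intentionally not
orthogonalized; the multicollinearity between, e.g., the trial indicator
and the risk indicators is handled by regularization.

Fitting uses elastic-net penalized Poisson regression (glmnet) with
10-fold cross-validation over both the penalty $\lambda$ and the mixing
parameter (grid 0.1–1 in steps of 0.1). The reported model uses the
one-standard-error rule: the largest $\lambda$ whose cross-validated
Poisson deviance is within one standard error of the minimum — the most
parsimonious model statistically indistinguishable from the best.
`rule = "min"` (best-performing $\lambda$) and `rule = "none"` (smallest
$\lambda$ on the path) support comparison fits. Folds are seeded random
partitions of bins; random partitioning ignores temporal autocorrelation
of the counts, a known caveat that mirrors common practice and is why
the shuffle control exists. An offset of $\log \Delta t$ puts
$\exp(\beta_0)$ directly on the spikes-per-second scale. The intercept is
never penalized; unit filtering retains units with session-average rates
in $[5, 100]$ spikes/s, bounds inclusive.

Effect sizes are reported as percent change from baseline:
$(e^{\beta_i} - 1) \times 100$ for binary/categorical terms and
$((t+1)^\gamma - 1) \times 100$ at a representative elapsed time of 5 s
for the time term. The shuffle control permutes the bin order of the
counts — destroying all temporal alignment while preserving the count
distribution — and refits the parsimonious model; on simulated data it
produces zero surviving effects.

Degenerate inputs are handled explicitly: constant design columns are
dropped with a warning, an all-constant design falls back to the
closed-form intercept-only MLE, and all-zero spike trains floor the
baseline rate at $10^{-3}$ spikes/s rather than returning $-\infty$.

## LFP band power and time-frequency maps

Preprocessing follows the standard chain: common-average referencing
(subtract the cross-channel mean at every sample; exactly removes
artifacts shared by all channels), band-pass filtering into delta
(0.1–4 Hz), theta (4–8), alpha (8–13), beta (13–30) and gamma
(30–80 Hz), anti-aliased downsampling to 200 Hz, and instantaneous power
as the squared magnitude of the analytic (Hilbert) signal. Open choices:

* **Filter design.** The bands are named without a filter specification;
  zero-phase (forward–backward) Butterworth filters of order 4 per pass
  are used. The delta band's 0.1 Hz low edge is implemented as a
  cascade of a 0.1 Hz high-pass and a 4 Hz low-pass, which is
  numerically far better conditioned than a band-pass with a relative
  edge of $10^{-4}$.
* **Processing order.** Band-pass at the native rate, then downsample,
  then the analytic signal — matching the order in which the steps are
  usually described. For in-band tones the alternative order agrees to
  within a few percent.

Artifact censoring flags "railing" (samples at ≥ 99.9% of the channel's
absolute maximum sustained for ≥ 50 ms) and aberrant broadband power
(rolling 100 ms mean of the squared signal exceeding the channel median
by more than 10 robust SDs), each padded by a 100 ms guard. All
thresholds are arguments.

Peri-event traces take the median across events of log power at each
time point, with each channel's log-power series standardized to zero
mean and unit variance over the whole session (not just the peri-event
epochs; the choice is documented here because either is defensible, and
whole-session statistics are better estimated). z-scoring before any
cross-channel averaging gives every channel equal weight; the package
also provides the raw-scale average (power averaged across channels,
then logged), which high-power channels dominate — on constructed
fixtures the two can disagree in sign, which is why the default is the
equal-weight version.

Time-frequency maps use a complex Morlet wavelet with $w = 9$ cycles on
40 log-spaced frequencies from 2.5 to 50 Hz (the count is a default, not
a claim), computed by FFT convolution with reflection padding;
unit-energy normalization is used, an arbitrary choice that cancels in
every normalized output. Power maps aligned to an event are normalized
per frequency by the mean power across all trials in the baseline
interval $B = (-1.5, -0.5)$ s before the event:
$I = 10 \log_{10}(P(f,t) / P_0(f))$. Condition contrasts are
$10 \log_{10}(P_1 / P_2)$ with no baseline normalization, hence exactly
antisymmetric under condition swap.

## Cluster-mass permutation statistics

Contrasts of per-trial dB maps are tested pixelwise with a two-sample
F statistic — the square of the pooled-variance t — whose pooled
variance is replaced by its mean over a 5 × 5 pixel neighbourhood
(truncated at the map edges) to stabilize the estimate; a variance floor
guards exactly constant maps. The smoother is applied to the variance,
and the neighbourhood mean is used; the alternative readings (median
smoothing, smoothing F itself) are close cousins, and this one keeps the
statistic's null an $F(1, n_a + n_b - 2)$ law, which the decile
thresholds require.

Pixels in the uppermost and lowermost deciles of that null law
(CDF ≥ 0.9 or ≤ 0.1) are grouped into clusters under 4-connectivity
(configurable to 8), with cluster mass the summed $|\log F|$ over member
pixels — log F is positive throughout the upper-decile region and
negative throughout the lower, so the mass is positive in both tails.
Significance comes from a label-shuffling null: each permutation
reassigns trials to conditions, re-runs the entire pipeline (smoothed F,
thresholding, clustering) and records the maximum cluster mass per tail.
Observed clusters are scored
$p = (1 + \#\{\text{null max} \ge \text{mass}\}) / (1 + n_{perm})$ — the
add-one correction avoids $p = 0$ — and retained at $p < 0.05$. The null
maximum is taken over both tails of the same permutation: treating each
tail as its own family at the full $\alpha$ empirically doubles the
family-wise error rate (we measured 0.10 over 500 null datasets), while
the across-tails maximum restores it to the nominal 0.05, which the test
suite verifies directly. The
default $n_{perm}$ is 1,000 (no count is prescribed anywhere); the test
suite uses 200 to keep the 500-dataset calibration experiment, which
verifies the family-wise error rate empirically, inside a practical run
time. Inside the permutation loop the decile thresholds are applied as
fixed F quantiles computed once — mathematically identical to
thresholding the per-pixel CDF.

## The hazard model of voluntary stopping

The prediction model asks whether channel-by-band LFP power carries
single-trial information about upcoming stops. Time within each trial is
discretized to a 40 Hz grid; the event indicator is 1 in the bin
containing the voluntary stop of a successfully banked trial and 0
elsewhere; popped trials are censored (all-zero bins ending at the pop).
Within-bin counts are Poisson with mean $\lambda_i(t)\,\Delta t$ and

$$\lambda_i(t) = h_i(t)\, e^{\mu + X(t)\cdot\beta},$$

where $h_i$ is the hazard function of a normal event-time distribution
with per-risk-level parameters $(m_i, s_i)$, and $X(t)$ holds, per
(channel, band), the mean of standardized log power over the trailing
0.5 s. The normal hazard $h(t) = \phi(z)/(s(1-\Phi(z)))$ is evaluated
through the log survival function, so it remains finite, accurate and
monotone far into the upper tail where the naive ratio overflows.

Open questions resolved here:

* Only within-trial bins enter the likelihood — $h_i(t)$ is defined in
  trial time, so inter-trial samples have no hazard to modulate.
* Control (forced/gray) trials carry no voluntary stop and are excluded.
* The trailing-window regressor is the mean of standardized log power
  (rather than the log of mean power); columns are re-standardized over
  the retained bins so coefficients read per regressor SD.
* Bins whose trailing window precedes the trial start or touches masked
  artifact samples are dropped and counted.

Priors: the coefficients get a horseshoe — $\beta_j \sim
N(0, \tau^2\lambda_j^2)$ with half-Cauchy(0, 1) local scales $\lambda_j$
and global scale $\tau$ — which shrinks irrelevant channels and bands to
zero while leaving genuine effects nearly unshrunk, playing the same
model-selection role the elastic net plays for the spiking model.
Hazard locations $m_i$ get a broad normal truncated to (0, 15) s, scales
$s_i$ a half-normal, and the intercept $\mu$ a normal(0, 2²); no prior
specification is inherited from anywhere, so weakly-informative defaults
are documented here.

Sampling runs in JAGS with, by default, four chains of 2,000 iterations,
the first half discarded and a thinning fraction of five. Convergence is
checked per reported parameter (Gelman–Rubin R-hat < 1.01, effective
sample size > 400) and failures are flagged in the returned summary —
never hidden. Internally the whole Poisson log-likelihood is collapsed
into a single node with the hazard term computed once per unique
(risk level, grid time) pair; this is an exact reformulation chosen
purely for sampling speed. The survival factor is floored at $10^{-12}$,
which caps the log hazard in a region of parameter space visited only
transiently. Coefficient effects are reported as
$(e^{\beta} - 1)\times 100$ percent hazard change per regressor SD;
"overlaps zero" is judged on the central 95% equal-tailed interval.

Simulated stop times for testing come from `simulate_hazard_stops()`,
the model's generative inverse: per-bin Bernoulli thinning with
probability $\min(1, \lambda_i(t)\Delta t)$ on the same 40 Hz grid. If
more than 1% of traversed bins saturate the simulator aborts with
guidance rather than silently distorting the event-time law. With
$\beta = 0$ the generated stop times follow the normal event-time law
(verified by a Kolmogorov–Smirnov check against the closed form).

## What the synthetic generator does and does not emulate

The LFP generator produces 1/f background noise (spectrally shaped white
noise, exponent 1 by default) plus band-limited sinusoids whose
amplitude ramps linearly before voluntary stops — the structure the
peri-event and time-frequency analyses are designed to detect. It does
not emulate Parkinsonian beta bursting, cross-frequency coupling,
non-sinusoidal waveform shape, volume conduction, or realistic artifact
morphologies. Passing tests therefore demonstrate that the pipeline
recovers known structure of exactly these kinds under realistic noise,
not that it would detect every phenomenon in real recordings.

## Problem sizes and numerical choices in the test suite

The tests exercise every stage at sizes chosen to give stable
statistical verdicts: 10,000 trials for pop-time moments; 20 replicates
of a 200-trial session for spiking-model recovery (a single elastic-net
mixing value of 0.5 is used there, since the mixing search affects
selection, not the accuracy of recovered coefficients); 500 null
datasets of 20-vs-20 maps at 40 × 80 pixels with 200 permutations for
the family-wise error calibration; and hazard-model fits on 60-trial
sessions with four chains of 500 iterations. At that reduced iteration
count the effective-sample-size convergence flags typically trip — the
posterior medians and interval checks are stable regardless, and the
flags are part of the verified output rather than silenced. The
package-default MCMC settings (4 × 2,000, thin 5) are the recommended
analysis configuration.
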