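---
title: "Modeling the integration of affective cues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the integration of affective cues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectcue)
```

## The problem

When observers judge how another person feels, they can draw on two
partially independent sources of information: the person's face and body
(the *character* cue) and the surrounding scene (the *context* cue).
`affectcue` models how continuous valence and arousal ratings, bounded on
$[-1, 1]$, arise from combining these two cues, and asks *which
combination rule* observers use. Each cue's momentary reliability is
operationalized as the across-observer spread of ratings collected under
cue-isolating conditions (`context_only`, `character_only`); the
`ground_truth` condition, in which both cues are visible, supplies the
ratings every candidate rule tries to predict.

## The candidate strategies

At each trial or timepoint $t$, let $\mu_c, \sigma_c$ and $\mu_f,
\sigma_f$ be the mean and standard deviation of the context and character
ratings. The battery contains seven rules:

* **bayes** — reliability-weighted integration. Cue rating distributions
  are combined multiplicatively,
  $P(a \mid c, f) \propto P(a \mid c)\, P(a \mid f) / P(a)$,
  on a discretized affect axis. With a flat prior the normalization is
  performed entirely in log space: the posterior log mass is
  $\log P(a\mid c) + \log P(a\mid f) - \mathrm{LSE}(x)$, where
  $\mathrm{LSE}(x) = \log \sum_i e^{x_i}$ is computed with
  max-subtraction so that products of near-underflowing densities remain
  finite. For Gaussian cues this reduces to the precision-weighted
  average $\mu^* = (\mu_c/\sigma_c^2 + \mu_f/\sigma_f^2) /
  (1/\sigma_c^2 + 1/\sigma_f^2)$ with variance
  $1/(1/\sigma_c^2 + 1/\sigma_f^2)$, which is never larger than either
  cue's variance — the reliability gain that distinguishes this rule
  from all the others.
* **heuristic** — the unweighted average $(\mu_c + \mu_f)/2$; its
  variance prediction is the mean of the cue variances.
* **context75 / character75** — stable-weight integration,
  $0.75\mu_c + 0.25\mu_f$ and $0.25\mu_c + 0.75\mu_f$.
* **all_in** — no integration: commit to whichever cue has the lower
  across-observer variance at each timepoint (ties go to context).
* **random_switch** — follow one cue per timepoint, chosen by a fair
  coin.
* **correlated_switch** — a two-state Markov chain over the cues with a
  10% per-step switch probability, producing long runs on one cue.

Strategies are scored against ground-truth ratings with Pearson *r*,
RMSE, and the Gaussian-residual AIC $n \ln(\mathrm{SSE}/n) + 2k$.
Bootstrap percentile intervals (5000 iterations by default), chi-squared
sign tests on per-observer AIC differences, two-tailed paired tests, and
protected exceedance probabilities complete the comparison battery.

## Distributional backends and the affect grid

All grid computations use `affect_grid()`: 201 points spanning
$[-1, 1]$ (step 0.01), uniform prior. Valence and arousal are treated as
two independent one-dimensional problems; per-dimension metrics are
always retained and their average is reported, matching the convention
of pooling the two dimensions.

Cue distributions are Gaussian by default, built from the
across-observer mean and standard deviation at each timepoint. A kernel
density backend (`build_kde_cue()`, Gaussian kernels, Silverman's
rule-of-thumb bandwidth) is available for ratings whose across-observer
distribution is not well summarized by two moments; it is applied
per-timepoint across observers. Numerical choices:

* Densities are renormalized after truncation to $[-1, 1]$, since
  ratings cannot leave the response box.
* `sigma_floor = 1e-3` prevents delta functions when all observers
  agree; undefined spreads (a single contributing observer) also fall to
  the floor, which makes the two cues equally reliable there.
* Log masses are floored at the log of the smallest positive normal
  double, so sums of log masses never produce `-Inf`.
* The point prediction of the Bayesian rule is the posterior **mean**.
  For Gaussian cues mean and mode coincide; for KDE posteriors they can
  differ, and the mean was chosen because squared-error metrics are
  minimized by it.

A closed-form Gaussian fast path (`bayes_integrate_closed()`) backs the
bulk fitting loops; the grid path is authoritative for KDE cues and near
the bounds. The two agree to better than $10^{-3}$ in the mean and
$2\times10^{-4}$ in the variance whenever the posterior keeps negligible
mass beyond $\pm 1$ (cue means within $\pm 0.7$ and spreads up to
$\approx 0.12$ put the boundary more than $3.5$ posterior standard
deviations away); outside that regime the truncated grid answer is the
correct one and the fast path is not used for reporting.

## Rating tables and resampling

The canonical exchange format is a tidy CSV with columns
`observer_id, video_id, condition, time_s, valence, arousal`. Continuous
ratings are step functions between input-device updates, so resampling
onto a uniform grid (500 ms, 100 ms, or 40 ms are the conventional
choices) carries the most recent rating forward (`hold_last`). How to
score grid points before an observer's first movement is genuinely
underdetermined; both back-filling with the first rating (`hold_last`)
and dropping the leading gap (`drop_leading`) are implemented, and the
choice is an explicit argument rather than an inference. Numbers are
serialized with round-trip precision so that write-then-read is
bit-exact.

## The synthetic cohort generator

`generate_dataset()` produces cohorts with the statistical structure the
analysis assumes, so every stage is testable without any behavioral
data:

* a smooth latent affect trajectory per video and dimension (band-limited
  sum of five harmonics, peak 0.6, slowest period 30 s);
* two cue channels whose means deviate from the latent trajectory by
  smooth biases (peak 0.25) — the cues carry partial, not identical,
  information;
* ambiguity schedules $\sigma_c(t), \sigma_f(t)$, by default antiphase
  sinusoids sweeping $0.06$–$0.50$ so the reliability ratio repeatedly
  exceeds 3 in both directions (constant and piecewise schedules are
  available);
* 50 observers per condition rating 12 videos of 90 s at 100 ms — the
  default study scale — with per-observer Gaussian rating noise at the
  scheduled spread, clipped to the bounds;
* a ground-truth channel produced by a *known* strategy plus observer
  noise (sd 0.1). A static mode generates independent trials instead of
  trajectories, mimicking frame-based designs sampled at 2 Hz.

Two generator decisions deserve emphasis. First, each ground-truth
observer applies the generating strategy to **their own** cue-channel
ratings (`gt_from = "own_ratings"`), with the reliability weights taken
from the true ambiguity schedules. This is the within-subject reading
that the individual-level analysis presupposes: if instead all observers
shared the strategy's prediction from the true cue means, an observer's
fitted predictions would be built from cue percepts that are pure noise
with respect to their ground truth, and the reliability-weighted rule
would win for every observer regardless of the generator — individual
strategies would be unrecoverable in principle. Fitting still estimates
the spreads from the data, so recovery tests include estimation noise.
Second, ground-truth noise has a fixed sd by default, which makes
Bayes- and Heuristic-generated cohorts *distributionally identical*
whenever $\sigma_c(t) = \sigma_f(t)$ — the identifiability boundary used
as a negative control. The optional `gt_noise = "strategy_variance"`
mode instead lets each rating sample from the strategy's own integrated
distribution, so the ground-truth rating spread carries the generator's
variance signature; this is the setting under which the
variance-prediction comparison is diagnostic.

What passing recovery tests does **not** show about real data: real
observers lag their ratings, share correlated errors, drift in
attention, and may mix strategies over time; none of these are emulated
beyond additive independent noise. Recovery on this generator
establishes that the *pipeline* identifies the generating rule under the
assumed structure, not that human data satisfy that structure.

## Group- and individual-level analyses

Three run modes mirror the common designs: `static_group` (independent
trials, between-subject), `dynamic_group` (continuous ratings,
between-subject), and `dynamic_individual` (continuous, within-subject —
every observer must have all three conditions).

At the group level the consensus (across-observer mean) of each cue
condition predicts the consensus ground truth; metrics pool timepoints
across videos within each dimension, and bootstrap CIs resample pooled
trials/timepoints. At the individual level each observer's own cue
ratings are the distribution means, combined with group-level
per-timepoint spreads (individual spreads are unobservable from a single
rating); bootstrap CIs resample observers, and the per-observer AIC
matrix feeds the winner tallies, the sign tests, the paired tests, and
the PXP.

Design choices that were genuinely open:

* **AIC parameter counts.** No parameter in the battery is fit to the
  ground-truth data, so counts are a charging convention: the Bayesian
  rule is charged $k = 2$ for its use of the two reliability channels,
  all other rules $k = 1$. The counts are configurable and echoed in
  every report. With $n$ in the tens of thousands the $2k$ term is
  negligible next to the SSE term, so conclusions are insensitive to the
  convention.
* **Chi-squared construction.** The AIC-difference test is a
  goodness-of-fit test of the sign counts of nonzero per-observer
  differences against a 50/50 split, the simplest reading of "is the
  difference distribution shifted away from zero"; zeros are excluded.
* **PXP.** Log model evidence is approximated as $-\mathrm{AIC}/2$;
  population frequencies get a symmetric Dirichlet prior
  ($\alpha_0 = 1$), updated variationally; exceedance probabilities are
  estimated from $10^5$ Dirichlet draws; protection mixes with the
  uniform distribution by the Bayesian omnibus risk, computed from the
  variational free energy against the equal-frequency null.
* **AIC pooling.** Timepoints are pooled across videos within an
  observer and dimension before the AIC is computed (per-video AICs can
  be obtained by running videos separately).
* **Switch realizations.** The two switch strategies are stochastic;
  each series gets one realization from a seed derived deterministically
  from the run seed, so reports are exactly reproducible and a
  re-realization is an explicit seed change.

## Problem sizes and determinism

The recovery study runs 20 replicates per generating strategy at the
default scale (50 observers, 12 videos, 90 s at 100 ms); a full
five-strategy study completes in about a minute on one core because all
fitting is closed-form and vectorized. Bootstrap CIs default to 5000
iterations; the PXP Monte Carlo to $10^5$ draws; the Bayes
variance-prediction Monte Carlo to 1000 draws per timepoint. Every
stochastic step draws its seed deterministically from the run seed via a
string-tagged hash, so `simulate → fit → compare` is byte-reproducible.

## Known limitations

* Valence and arousal are modeled independently; a joint 2-D affect
  grid is out of scope.
* Only a flat prior over affect is implemented (the log-sum-exp
  normalization is exact only in that case).
* No temporal filtering or lagged integration: cues are combined
  instantaneously at each timepoint.
* Free per-observer integration weights are not fit by optimization;
  the battery is a fixed set of named rules.
* The optional loader for externally deposited datasets is a thin
  convenience and is not exercised by the test suite.
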