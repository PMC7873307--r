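---
title: "Models and methods: decoded information flow across prefrontal arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: decoded information flow across prefrontal arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpfcflow)
```

This vignette is the package's account of its science: the models it fits,
the conventions and numerical choices behind them, what the synthetic-data
generator does and does not emulate, and the design decisions that were
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The experimental setting

The pipeline targets sessions from a two-armed bandit reversal-learning task
recorded on multi-electrode arrays in lateral prefrontal cortex (LPFC). Each
session contains about 24 blocks of 80 trials. A block is either a *What*
block, in which reward probability attaches to one of two novel objects, or
a *Where* block, in which it attaches to a saccade direction (left/right).
The better option is rewarded 70% of the time, the other 30%, and on an
unsignalled trial drawn uniformly from 30..50 the mapping reverses. Spiking
activity comes from eight 96-electrode arrays (768 electrodes), four per
hemisphere, at positions numbered 1-4 along the caudo-rostral/ventral axis:
rdlPFC (1), mdlPFC (2), cdlPFC (3), vlPFC (4).

Four analysis stages build on each other:

1. **Behaviour** — a Rescorla-Wagner (RW) model with asymmetric learning
   rates, fit per block type, whose value trace feeds the encoding model.
2. **Encoding** — a sliding-window fixed-effect ANOVA per neuron, giving
   percentage-significant time courses and response latencies.
3. **Decoding** — a leave-one-trial-out linear Gaussian decoder per array,
   giving accuracy time courses and posterior-probability series.
4. **Information flow** — a Granger-style lagged regression predicting each
   array's posterior series from the other arrays', quantifying directed
   flow via nested-model variance drops (fVar).

## Behavioural model

Values update only for the chosen option $i$:

$$v_i(k+1) = v_i(k) + \delta_f\,\bigl(R - v_i(k)\bigr),$$

with $\delta_f = \delta_{pos}$ after reward ($R=1$) and $\delta_{neg}$
otherwise. Choice probabilities pass through a logistic with inverse
temperature $\beta$:

$$d_1(k) = \bigl(1 + e^{\beta (v_2(k) - v_1(k))}\bigr)^{-1},
  \qquad d_2(k) = 1 - d_1(k),$$

and the likelihood of the observed choices is
$\prod_k [\,d_1(k)c_1(k) + d_2(k)c_2(k)\,]$ with $c_i(k)$ the indicator of
choosing option $i$.

Design choices, with rationale:

* **Options follow the block's domain**: objects (A/B) in What blocks,
  actions (left/right) in Where blocks; parameters are fit separately per
  block type.
* **Initial values** $v_i = 0.5$ at each block start: an uninformative prior
  between two options; values are not carried across blocks because each
  block introduces novel objects.
* **No reset at the reversal**: the reversal is unsignalled, so the model
  must discover it through prediction errors, as the subject does.
* **Bounds and multistart**: $\delta \in [0,1]$, $\beta \in [0,50]$, one
  central plus nine random starts of `optim(method = "L-BFGS-B")` under a
  fixed seed. A fit where no start converges is returned flagged, never
  silently.
* **Probability floor** $10^{-12}$ inside the log, so a single surprising
  choice cannot produce `-Inf`.

Parameter recovery at the generator's agent settings
($\beta = 5, \delta_{pos} = 0.6, \delta_{neg} = 0.3$, 200 blocks) is part of
the acceptance suite: median absolute error below 0.1 for the learning
rates and relative error below 30% for $\beta$ across 50 replicates.

## Encoding analysis

Spike counts in 50-ms windows advanced by 10 ms (half-open
$[t, t+\mathrm{width})$, labelled by bin center, cue-locked, window
$-1.5..1.5$ s) are regressed, per neuron and bin, on chosen object, chosen
action, reward (nominal) and value (continuous). Each factor's p-value is
the drop-one-term F test against the full model; the design matrix is shared
across neurons and bins, so one QR factorisation per (reduced) model serves
the whole population. Per-bin significance uses $\alpha = 0.05$ with **no
multiple-testing correction** — the time courses are descriptive, and
correcting across bins would change what "percentage of significant
neurons" means.

Open choices resolved here:

* **Value covariate** = the fitted value of the chosen option on each trial.
  The alternative (value difference) is available by supplying a different
  column; the chosen-option value is the quantity the update rule actually
  moves, which is what "value updating" tracks.
* **"Task-related" neuron** (the denominator of percentage curves) =
  significant for any factor in any post-cue bin; configurable, since no
  operational definition is standard.
* **Constant factors** (e.g. reward in a window where every trial was
  rewarded) yield missing p-values, never $p = 1$.
* **Interactions** are not included per bin; per-bin models are main-effects
  only, keeping one df per factor.

**Latency rule.** A paired t-test compares each bin of a population time
course against the mean of the $-1.5..-0.5$ s baseline, paired across
replicates (sessions, or session-array combinations); the first significant
bin is the latency. The literal first-significant-bin rule is noise-limited:
over ~300 bins at $\alpha = 0.05$, false positives arrive early essentially
by construction. The detector therefore offers a consecutive-bins guard
(`min_consecutive`), default **off** to keep the literal rule. When the
guard is used with overlapping windows it should outlast the overlap factor
(50-ms windows stepped by 10 ms share 80% of their data, so 6 consecutive
bins ≈ one independent confirmation); the recovery tests use exactly that.

## Population decoding

For each array, trial and 20-ms bin (window $-0.5..1.5$ s for flow input,
wider when latencies are needed), raw spike counts $x$ are compared with
per-class mean templates $\bar{X}_i$:

$$p_i = \frac{\exp(-\lVert x - \bar{X}_i \rVert^2)}
             {\sum_j \exp(-\lVert x - \bar{X}_j \rVert^2)},$$

a linear Gaussian decoder with spherical covariance, evaluated in log space.
The squared distance is used exactly as written — no variance scaling and no
1/2 factor. Cross-validation is leave-one-trial-out; the hold-one-out
templates are computed in closed form (the excluded trial shifts its own
class mean by a factor $n_c/(n_c-1)$), which the tests verify against a
naive per-fold loop to machine precision.

Conventions: accuracy per bin is the fraction of trials whose true-class
posterior exceeds 0.5, exact ties credited 0.5 (deterministic and unbiased);
accuracy is pooled over trials per bin, not averaged over folds (identical
here, since each fold holds one trial); folds whose training set lacks a
class are skipped and counted; all simultaneously recorded neurons of one
array enter together; binary domains only, so chance is 50%, which the
acceptance suite confirms under label shuffling.

## Information flow

The chosen-option posterior of output array $i$ at bin $t$ is regressed on
its own lags and on the current-plus-lagged posteriors of the other arrays:

$$p_i(t) = a_0 + \sum_{j=1}^{10} a_{(i,j)}\, p_i(t-j)
         + \sum_{k \ne i}\; \sum_{l=0}^{10} a_{(k,l)}\, p_k(t-l),$$

by ordinary least squares pooled over trials. Lags never cross trial
boundaries: within each trial the first $\max(\mathrm{lag})$ bins serve only
as predictors. A strictly lagged variant ($l = 1..10$) is available and is
exercised in the tests.

* **Partial models** drop one array *number* bilaterally: refit without the
  left-hemisphere instance, refit without the right, and average the two
  predicted series and variance-explained values (a simultaneous-drop mode
  exists as an option). Dropping the output's own number is rejected.
* **Variance explained** is in-sample $1 - SSE/SS_{tot}$ pooled over all
  predicted bins; each partial refit is nested in the full model, so
  $\mathrm{Var}_{partial} \le \mathrm{Var}_{full}$ and
  $\mathrm{fVar} = (\mathrm{Var}_{full} - \mathrm{Var}_{partial}) /
  \mathrm{Var}_{full} \in [0,1]$. A cross-validated variant was considered
  and not adopted as the default, to keep the nestedness guarantee exact.
* **ΔPosterior** is the per-bin mean over trials of (full − partial)
  prediction.
* **Ordinal distance** between dropped (input) and output array numbers is
  signed so that positive distances mean caudal-to-rostral flow (the input
  lies caudal/ventral of the output): distance = input number − output
  number, hemisphere ignored.
* **Fits are per session × block type × output array** (and domain pair);
  the group summaries then span sessions, hemispheres and pairs. With four
  numbers, |distance| 1/2/3 corresponds to 3/2/1 ordered number pairs per
  direction — the tests check these counts.
* **Cross-domain flow** keeps the output array's own-domain self-lags and
  uses the other arrays' series of the other domain; the 3↔4
  (cdlPFC↔vlPFC) contrast has its own summary helper.
* **Learning trajectories** slide a 10-trial window (step 1) over the
  within-block trial index, compute per-session mean fVar per block type in
  each window, and compare What vs Where with a two-sided paired t-test
  across sessions.
* Rank-deficient designs are resolved by pivoted least squares (aliased
  coefficients set to zero) with a warning — this arises naturally, e.g.
  when one series is an exact lagged copy of another.

## The synthetic-data generator

The generator exists so that every stage can be tested for *recovery of
planted structure* without any recorded data. Per session it produces the
task schedule, an RW agent playing it, and Poisson spike counts on a 10-ms
base grid for the full eight-array layout, together with a ground-truth
record of every planted effect.

Each (array, domain) pair carries a latent information signal per trial:

$$z(k, t) = \mathrm{ramp}(t - \mathrm{onset}_a)\, x_{dom}(k)
          + \mathrm{hold}(k, t) + \eta(k, t),$$

where $x_{dom}(k) \in \{-1, +1\}$ is the signed trial variable (chosen
action side, chosen object identity, reward; value uses the agent's chosen
option value rescaled to $[-1,1]$), the ramp rises linearly over 150 ms and
sustains, the hold component carries the sign of the agent's value
difference during the half-second before cue onset in the block-relevant
domain (object in What, action in Where), and $\eta$ is trial-wise AR(1)
noise. A neuron tuned to a domain with preference $\sigma = \pm 1$ fires
Poisson with rate $b\,(1 + g\,\sigma\, z)$ — modulation proportional to its
own baseline $b$ (gain modulation), which keeps negative-rate clipping rare;
negative rates are clipped at zero and counted, with a warning above 1%.

Directed coupling entries add a lag-shifted, gain-scaled copy of the source
array's **stochastic** latent component to the target's latent, same
hemisphere. Transferring only the stochastic part (not the full latent) is
deliberate: copying the ramp as well would let targets inherit the source's
earlier onset, corrupting the planted latency gradient, and would double the
deterministic drive on coupled arrays.

Default study conditions (all overridable through `session_config()`):

| parameter | default | rationale |
|---|---|---|
| blocks × trials | 24 × 80 | session scale of the task |
| reversal | uniform 30..50 | task design |
| reward schedule | 70% / 30% | task design |
| agent | $\beta=5, \delta_{pos}=0.6, \delta_{neg}=0.3$ | sharp but imperfect learner; also the recovery target |
| neurons/array | 20 | desk scale; study scale is reachable by override |
| baseline rate | log-normal, median 5 Hz, sdlog 0.5 | typical cortical distribution; caudal arrays scaled up ~10-25% |
| tuned fraction by array 1-4 | 0.4/0.6/0.8/0.9 | caudo-rostral prevalence gradient |
| modulation gain | 0.5 × baseline, scaled 0.5/0.7/0.85/1.0 | strength gradient; keeps clipping < 1% |
| onsets by array 1-4 | 250/200/150/100 ms | caudo-rostral latency gradient |
| hold gain | 0.3 | weak pre-cue planned-choice signal |
| latent noise | sd 0.6, AR $\rho = 0.4$ per 10-ms bin | fluctuation time constant ≈ 11 ms, fast relative to the planted 40-60-ms lags (see identifiability below) |
| coupling | caudal→rostral chains 4→3→2→1, lag 2 bins, gain 0.8, per domain; object→action 4→3, lag 3 bins, gain 0.5, What blocks | the directed structure the flow stage is meant to detect |
| reaction times | Gaussian 210 ± 15 ms | fills the field; no claim of matching real RT statistics |

What the generator does **not** emulate: biophysical spiking dynamics,
LFPs, eye movements, neuron-count differences between arrays, session
non-stationarities, or realistic reaction-time distributions. Passing
recovery tests therefore show that the estimators detect the *kind* of
structure they target at realistic noise levels — not that real LPFC data
contain that structure.

## Identifiability of flow direction, and how it is tested

A latent-copy coupling observed through noisy decoders creates a known
Granger pitfall: the target's decoded series embeds a relatively clean copy
of the source's past latent, so when the source's own decoded series is
noisy and its latent is temporally persistent, the *target* can spuriously
help predict the *source's* future. Two package choices respond to this:

* The default latent fluctuations are fast ($\rho = 0.4$ per 10-ms bin)
  relative to the planted lags, which suppresses the reverse artifact (it
  scales with the latent autocorrelation across the lag) while leaving the
  true-direction signal untouched.
* Direction-recovery validation of the estimator runs on posterior-level
  series from `simulate_posterior_network()` — coupled logistic-AR series on
  the decoder's output scale — where the planted direction is recovered in
  ≥95 of 100 seeded replicates and zero-gain coupling is indistinguishable
  from a trial-permutation null.

At desk scale (a handful of blocks, ~20 neurons per array), spike-level
single-session direction contrasts are underpowered: 20-ms spike counts of
~0.1-0.3 expected spikes make the decoded posteriors very noisy observers of
the latent, and the task ramp shared by all arrays lets any array partially
substitute for any other in the regression. This mirrors the scale of the
real effect, which is resolved only across many sessions, arrays and pairs.
The spike-level tests therefore assert the robust properties — nestedness,
ΔPosterior behaviour, the permutation null at zero gain, latency-gradient
recovery, chance-level decoding — and leave quantitative direction recovery
to the posterior-level suite.

## Numerical conventions

* Time bins are half-open $[t, t + \mathrm{width})$, labelled by center,
  seconds relative to cue onset.
* Posterior and likelihood computations run in log space; the softmax
  subtracts the maximum before exponentiating.
* Degenerate inputs produce *missing* values, not fabricated ones: empty
  groups, constant factors, folds without a training class, and aligned
  trial positions covered by fewer than two blocks are all `NA` with a
  count, never zero.
* All randomness flows from one seeded generator per entry point; session
  generation restores the caller's RNG state.

## Problem sizes

The shipped test and acceptance suites choose sizes that exercise each
property at adequate power: 200 blocks × 50 replicates for parameter
recovery; 10 seeds × 200 trials for the chance level; 10,000 blocks for the
task constants; 100 posterior-level replicates for direction recovery; four
sessions of eight 80-trial blocks with 24 neurons per array for the latency
gradients. Larger, study-scale runs use the same code paths through
configuration overrides.

## Known limitations

* In-sample fVar is biased upward by overfitting (dropping predictors
  always costs variance); conclusions should rest on contrasts (direction,
  distance, domain pairs) or permutation nulls, both provided, not on raw
  fVar magnitudes.
* The latency rule inherits the sensitivity of its inputs; with few
  replicates the paired t-test at each bin is low-powered, and with many
  bins the literal rule needs the consecutive-bin guard.
* The encoding ANOVA treats counts as Gaussian; at 50-ms windows and
  hundreds of trials this is a standard, well-behaved approximation, but
  p-values for very sparse neurons are conservative at best.
* The pipeline operates on one session at a time; cross-session stages
  (latencies, learning trajectories) take lists of per-session results.
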