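---
title: "Belief-state reinforcement learning models of dopamine reward prediction errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-state reinforcement learning models of dopamine reward prediction errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefrl)
library(dplyr)
```

## The scientific problem

In a blocked Pavlovian task, a mouse receives one of two reward sizes —
small (1 µL) or big (10 µL) of sucrose water — in blocks of five identical
trials. The same odor cue precedes every reward and a tone marks each block
start, so nothing perceptual distinguishes the two block types before the
reward arrives: the *state* (small-reward block $s_1$ vs big-reward block
$s_2$) is hidden. After extended training, rare probe blocks deliver
intermediate volumes (2, 4, 6, 8 µL).

Two model classes make sharply different predictions about the dopamine
reward response, which is taken to encode a reward prediction error (RPE):

* **Standard trial-level RL.** With a single observable state, the value
  $V$ tracks the average experienced reward and
  $\delta_t = r_t - V(s_t)$ is *linear* in reward on every trial.
* **RL on belief states.** If the animal maintains two hypothesis states
  distinguished by their reward distributions, Bayes' rule converts the
  observed reward into a posterior (the *belief*)
  $b(s) = P(r \mid s)P(s)/P(r)$, with Gaussian likelihood
  $P(r \mid s) = \mathcal{N}(r;\, \bar r_s, \sigma^2)$. The value is
  belief-weighted, $V(b_t) = w_1 b_t(s_1) + w_2 b_t(s_2)$, the RPE is
  $\delta_t = r_t - V(b_t)$, and the weights learn by
  $\Delta w = \alpha\, \delta_t\, b_t$. On the *second* trial of a probe
  block the belief has already absorbed the first reward, so a small
  intermediate reward (likely $s_1$) beats a low expectation — positive
  RPE — while a large intermediate reward (likely $s_2$) falls short of a
  high expectation — negative RPE. The trial-2 RPE is therefore
  *non-monotonic* in reward, while trial-1 responses stay linear under both
  models.

This package simulates the task, runs both model families, generates
synthetic per-mouse datasets (dopamine responses, anticipatory licking, raw
photometry traces), fits the models by maximum likelihood, and compares
them with BIC and random-effects Bayesian model selection.

```{r}
plot_rpe_curves(reproduce_predictions(sigma2 = 0.05))
```

## Rewards, states and the task simulator

Reward volumes map linearly onto the model scale via
$r = (v - 1)/9$, so the training anchors are exactly 0 and 1. (The
intermediate volumes 2, 4, 6, 8 µL map to 1/9, 3/9, 5/9, 7/9.)

`generate_task_history()` reproduces the three training phases: a
deterministic phase with strictly alternating blocks, a probabilistic phase
(block type switches with probability 0.5 at each block start), and a probe
phase in which every other day 3 of the 30 blocks (10%) are swapped for
intermediate-reward blocks of distinct volumes, each volume at most once
per day. The default day counts (10 + 20 + 24) were chosen so one simulated
mouse experiences close to 3,980 trials of each training block and roughly
42 trials per intermediate volume — the exposure regime the analysis
assumes. Probe positions within a day are uniform among non-first blocks;
the defaults put ≈45 trials on each intermediate volume, inside the
reported spread.

One choice is ours: the previous-block context of a block that follows an
*intermediate* block must still be a training-state label, so we assign the
nearest training state by volume (2, 4 µL → $s_1$; 6, 8 µL → $s_2$) — the
last experienced reward is what plausibly sets the animal's prior.

## Model variants and parameters

Six variants are compared (`model_variants()`), all sharing a learning rate
$\alpha \in [0, 0.3]$ and a gain $\beta \in [0, 100]$ that maps model RPEs
linearly to dF/F-scale responses:

| variant | free parameters | block-start expectation |
|---|---|---|
| `std_single` | $\alpha, V_0, \beta$ | one initial value |
| `std_dual` | $\alpha, V_{s_1}, V_{s_2}, \beta$ | initial value set by previous block |
| `bs_fixed` | $\alpha, \sigma^2, \beta$ | flat prior 0.5/0.5 |
| `bs_one_prior` | $\alpha, \sigma^2, \beta, p_1$ | one context-independent prior |
| `bs_two_prior` | $\alpha, \sigma^2, \beta, p_1, p_2$ | $p_1 = P(s_1)$ after $s_1$, $p_2 = P(s_2)$ after $s_2$ |
| `bs_three_state` | $+\, p_3$ | adds an intermediate state with mean 0.5 |

Sensory noise $\sigma^2 \in [0.01, 0.5]$ (variance on the normalized reward
scale), initial values in $[0, 1]$, priors in $[0.001, 0.999]$. For
`bs_two_prior` we parameterise the two priors as *stay* probabilities; the
first block of a history (context "none") uses the average of the two
context-conditioned priors. For `bs_three_state` the third state's reward
mean is fixed at 0.5 (the centre of the scale) and its prior mass $p_3$ is
shared across contexts, with the remaining $1 - p_3$ split by the
two-prior rule.

### Timing conventions

Two conventions are not fixed by the update equations themselves and we had
to decide them:

* **Value timing.** The value entering $\delta_t$ uses the *pre-outcome*
  belief: the prior on trial 1, thereafter the posterior given the rewards
  of trials $1..t{-}1$ of the current block. This is the only convention
  that yields the linear-trial-1 / non-monotonic-trial-2 pattern the models
  exist to explain.
* **Credit timing.** The weight update $\Delta w = \alpha \delta_t b_t$ may
  credit the *post-outcome* belief (default: the reward has just
  disambiguated the state) or the pre-outcome belief
  (`credit_belief = "prior"`). Both are available; all qualitative
  signatures hold under either.

The credit choice has one measurable consequence worth recording. Under
posterior credit, at the 50% switch rate the stationary time-averaged
weights do not settle exactly on the anchors $(0, 1)$: block-start
transition kicks ($\delta_1 \approx \pm 0.5$ credited to the inferred
state) balance the within-block decay four trials long, leaving an
$\alpha$-independent offset of roughly $\delta_1/4 \approx 0.1$ beyond each
anchor. Under pre-outcome credit the kicks cancel by symmetry and the
weights sit within 0.05 of $(0, 1)$ for fitted learning rates
($\alpha \lesssim 0.15$), drifting to ≈0.08 at the bound $\alpha = 0.3$.
The tests assert exactly these behaviours. Beliefs reset at every block
start (the tone signals a fresh latent draw); weights carry across blocks.

Weight initialisation is explicit: `"asymptotic"` ($w =$ state means,
i.e. $(0,1)$) when a history starts after extended training — the default,
and what fitting uses on probe-phase histories — or `"naive"`
($(0.5, 0.5)$) when simulating from scratch.

$\beta$ is implemented as a pure gain, `predicted_da = gain * rpe`, with an
optional additive `offset` (default 0) for the shifted-response
parameterisation; the offset is off because the fitted quantity here is the
baseline-corrected reward response.

## Fitting

Following the analysis design, models are fitted not to single trials but
to **condition averages**: the mean dopamine response for each (reward
volume, trial-in-block, previous-block type) cell
(`condition_average()`). The likelihood is Gaussian on these cell means
with the residual variance profiled at its MLE, so the criterion is
monotone in the residual sum of squares — maximum likelihood without a
separate noise parameter (the variance is floored at $10^{-12}$ so perfect
fits remain finite). Each cell counts once; cells never observed are
absent, not imputed.

`fit_model()` runs 5 random interior starts (gain log-spaced) of bounded
L-BFGS-B (NLL tolerance ~1e-8; `nlminb` as a gradient-free bounded
fallback), reports the best start and records all of them. The forward pass
is compiled (Rcpp) so a full six-variant, 11-mouse comparison runs in about
a minute.

## Model comparison

BIC is $k \ln n + 2\,\mathrm{NLL}$ with $n$ the number of condition cells.
Per-mouse log evidence is approximated as $-\mathrm{BIC}/2$ and fed to
random-effects Bayesian model selection (`bms_random_effects()`): a
variational Dirichlet scheme over population model frequencies
($\alpha_0 = 1$, flat), Monte-Carlo exceedance probabilities ($10^6$
Dirichlet draws by default, ties split uniformly), and the protected
version $\mathrm{pxp} = (1-\mathrm{BOR})\,\mathrm{xp} + \mathrm{BOR}/K$,
where the Bayes omnibus risk compares the variational free energy of the
random-effects model against the equal-frequency null. The two-model case
is verified against direct Beta-posterior integration in the tests.

## What the synthetic data emulate — and what they do not

`generate_mouse()` draws per-trial observables from a known model:
dopamine responses as `predicted_da` plus homoscedastic Gaussian noise, and
anticipatory licking as an affine, floor-clipped function of the
pre-outcome value (`max(0, 1 + 6 V + noise)` licks/s by default — the lick
scale is not constrained by any reported quantity and is documented as
arbitrary). Cohort generation draws each mouse's true parameters from
ranges chosen to be realistic and identifiable: $\alpha \sim U(0.05,
0.25)$, $\sigma^2 \sim U(0.03, 0.15)$, $\beta \sim U(1, 5)$, stay-priors
$\sim U(0.55, 0.8)$ (context dependence is precisely the winning model's
signature), standard-model initial values low after $s_1$ and high after
$s_2$; per-trial DA noise sd is $0.2\beta$.

`generate_raw_trace()` renders raw 1 kHz-style fluorescence for the
photometry pipeline: a multiplicative baseline (optionally bleaching with a
single slow exponential) modulated by difference-of-exponentials calcium
transients at cue and reward onsets (US amplitude = the model's predicted
response), plus white noise; timing follows the task (1 s odor, 1 s delay,
ITI = fixed 4 s + Exponential(mean 4.7 s), tone ending 3 s before a
block's first odor). Event timestamps live on the acquisition clock (sample
grid). These fixtures exercise the dF/F pipeline; they are *not*
biophysical: no indicator nonlinearity, no motion artefacts, no spectral
bleed-through, no lick-DA interaction. Passing tests therefore show the
*pipeline* recovers what was injected, not that real signals are this
clean.

## Photometry conventions

dF/F $= (F - F_0)/F_0$ with three baselines: per-trial mean over the 1 s
before odor onset; per-block mean over the 1 s before the tone; or a
running median over a 60 s window centered on each sample. Windows are
half-open $[t, t+1\,\mathrm{s})$; the running-median window truncates at
trace edges; windows that cross a boundary truncate with a warning, never
silently. US responses subtract the mean dF/F over the 100 ms centered on
reward onset, then take the mean (and single-sample max, `us_peak`) over
the following second. Min–max normalization against trial-1 responses is
provided for display only — models are never fitted to normalized values.

## Numerical choices and test problem sizes

Posteriors are computed in log space (no underflow; a degenerate prior is
absorbing). Beliefs renormalize to machine precision. Non-finite
predictions inside the optimizer incur a large finite penalty. All
randomness flows from explicit integer seeds; schedules, cohorts, fits and
Monte-Carlo draws are bit-reproducible given the seed.

The test-suite problem sizes are the package's own choices: fitting tests
use probe-phase-only histories (24 days, 3,600 trials, the full probe
exposure) with asymptotic weight initialisation; parameter recovery uses 20
mice; the six-variant comparison uses 11-mouse cohorts, mirroring the
cohort the analysis design targets.

## Known limitations

* Trial-level modeling only: no intra-trial temporal-difference dynamics,
  cue-onset responses are reported (as $V(b)$ at trial start) but not
  fitted.
* The fitted $\alpha$ is the least identified parameter from condition
  averages at realistic noise (its signature — within-block transients and
  weight drift — is small); recovery tests report its bias alongside the
  error.
* `bs_three_state` fixes the intermediate state's mean at 0.5 rather than
  learning it.
* Local optimization with 5 starts carries no global guarantee; fits are
  per-mouse, with no hierarchical pooling.
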