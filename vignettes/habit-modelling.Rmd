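---
title: "Modelling frequency-based habit formation with habitkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frequency-based habit formation with habitkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitkit)
```

## The scientific problem

Habits are stimulus-triggered behaviors that persist even when they no longer
serve the agent's goals. A long-standing idea is that habit strength grows
with *behavioral frequency*: the more often an action is repeated, the more
it is emitted automatically, independent of outcome value. `habitkit`
implements the computational machinery needed to study this idea in a
multi-task laboratory battery: seeded generators for the tasks' trial
schedules, generative choice models whose likelihoods can be fit to
trial-level data, group-level model selection, the per-participant habit
scores used across paradigms, questionnaire scoring, a synthetic-cohort
generator, and analytic power utilities. Everything is reproducible from
seeds; no participant data are required.

## Task designs

**Rewarded stimulus-pair task.** Eight abstract stimuli deterministically
yield 1, 3, 3, 5, 5, 7, 7 or 9 points. At each intermediate value there is a
*frequent* stimulus (paired 30 times per session with its 2-point-cheaper
neighbour and 10 times with its 2-point-dearer neighbour) and a *rare*
stimulus with the reversed pairing. A reward maximiser therefore chooses the
frequent member often and the rare member seldom, while both have identical
value — choice frequency and value are decoupled. Each of five training
sessions has 160 trials, every stimulus appears 40 times, and the obtainable
points are bounded between 640 (always choose the worse option) and 960
(always the better). The test phase shows every pair four times plus eight
extra presentations of the three same-reward pairs, 136 trials, with no
outcomes. The exact cross-level pairing table is fixed to the canonical
solution in which frequent(v) meets rare(v+2); all printed totals are
invariant across the admissible family of tables. One published figure we do
*not* use as a check is the test-phase earnings range (248–424 points): no
enumeration of the stated 136-trial structure reproduces it (an always-max
chooser earns 856), so the package records the structure, not that range.

**Unrewarded instructed-choice task.** Two stimulus pairs; a cue instructs
the choice on every training trial, 80/20 in one pair and 50/50 in the
other, six 20-trial blocks per pair per session (blocks alternating between
pairs from a seeded starting pair; the interleaving order is not fixed by
the design), five sessions, 600 trials per pair, 500 ms response window.
The cue counts are exact per block (16/4 and 10/10). The free-choice test
phase opens with ten trials per trained pair in the trained screen
locations, followed by a random interleaving of all pairings (four each,
locations balanced) with ten switched-location presentations of each
trained pair — 64 trials. Because the balanced block contributes two
switched-location presentations per trained pair, switched-location trials
total twelve; the tests count the dedicated ten-trial block separately.

**Two-stage sequential task.** Two equivalent initial states contain two
spaceships each; spaceships A and C fly deterministically to alien 1, B and
D to alien 2. Alien point values follow independent Gaussian random walks
(mean-zero steps, sd 2 points) with reflecting boundaries at −4 and +5,
rounded to integers. Because the outcome values are described in integer
points we round the emitted values; the underlying walk stays continuous so
reflection is exact.

## Choice models

Rewards are rescaled to $[0,1]$ by dividing points by 9 so that
reinforcement values $q$ and choice-kernel values $ck$ share a scale. On
every completed trial the probability of choosing the left stimulus is

$$P(\text{left}) = \sigma\!\big(\beta_q (q_L - q_R) + \beta_h (ck_L - ck_R)\big),$$

with $\sigma$ the logistic function. After feedback, $q_s \leftarrow q_s +
\alpha_q (r_s - q_s)$ for each displayed outcome (both outcomes are shown in
training; none in test), and on every completed trial the choice kernel
moves the chosen stimulus toward 1 and the unchosen toward 0 with rate
$\alpha_h$ — the kernel is a recency-weighted choice-frequency trace, the
formal counterpart of "habit strength is proportional to choice frequency".
The candidate set is: `random` (no parameters, $P = 0.5$), `rl`
($\alpha_q, \beta_q$), `ck` ($\alpha_h, \beta_h$), `rl_ck` (all four), and
`rl_ck_reduced` ($\alpha_q, \alpha_h, \beta_h$ with the constraint
$\beta_q = 10 - \beta_h$). Under the shared $[0,1]$ value scale that
constraint makes $\beta_h = 5$ the point of equal weighting of value and
frequency, which is why the rescaling is not optional plumbing. Learning
rates live in $[0,1]$ and temperatures in $[0,10]$.

Defaults that were genuinely open and how they were fixed:

* initial values $q_0 = ck_0 = 0.5$ (the unbiased midpoint; 0 is exposed as
  an argument),
* training feedback updates both displayed stimuli (`"chosen_only"` and
  `"none"` are exposed for sensitivity analyses),
* the kernel updates only the two stimuli on screen — habit accrues to acted-on
  cues — and keeps updating during the test phase, where choices still occur,
* missed trials contribute nothing to the likelihood and advance no update:
  no action was taken, so neither controller has anything to learn from.

The two-stage hybrid learner mixes model-based values ($Q_{mb}(s,a) =
V(\text{alien}(a))$) and cached model-free values with weight $w$:
$Q = w\,Q_{mb} + (1-w)\,Q_{mf}$, plus a perseveration bonus $\pi$ for
repeating the previously visited alien and a key-stickiness bonus $\rho$ for
repeating the previous response key (spaceship screen positions are
randomised per trial, which is what keeps $\pi$ and $\rho$ identifiable).
Updates: $\delta_1 = V - Q_{mf}$ into $Q_{mf}$ with rate $\alpha$, then
$\delta_2 = r - V$ into $V$ and, weighted by the eligibility trace
$\lambda$, into $Q_{mf}$. The habit index reported from a fit is $1 - w$, so
larger values mean more model-free (presumed habitual) control.

## Fitting and model selection

`fit_mle()` evaluates the replayed likelihood — learning states are driven
by the *observed* choices and outcomes, never by model samples — and runs
L-BFGS-B from `n_starts` seeded uniform draws within bounds
(`maxit` 500, `factr` 1e7, ties resolved to the earliest start). The
likelihood kernel for the value/kernel family is compiled (C++): per-trial
replay loops dominate recovery studies otherwise. All five training
sessions and the test phase are fit jointly with learning carried across
sessions, matching the multi-day training; test-only fitting simply means
passing the test log. The trial count entering the BIC is the number of
completed trials, because the likelihood is defined only over them. Logs
with fewer than 30 completed trials are refused with a distinct condition
class so that refusal is never confused with convergence failure.

Group-level inference uses random-effects Bayesian model selection: subjects
are allowed different generating models, model frequencies get a uniform
Dirichlet prior (concentration 1 per model), and a variational loop
estimates the posterior concentration from per-subject log evidence
(−AIC/2 by default, −BIC/2 as an option). Exceedance probabilities are
analytic (Beta CDF) for two models and Monte Carlo (default $10^5$ seeded
Dirichlet draws) otherwise. Individual-level evidence uses the conventional
absolute-BIC bands: below 6 insufficient, 6–10 strong, above 10 very
strong. `model_recovery()` closes the loop: simulate from each model, fit
all, tabulate lowest-BIC attributions.

## Habit scores

Every printed per-participant score is implemented as a pure formula plus a
log-level helper that applies the trial filters: responses faster than
50 ms are discarded, RT cell medians need at least three valid trials (the
source design is silent on a minimum; three is the smallest count for which
a median is not just a midpoint of two), and any missing input yields `NA`,
never a silent zero. RTs are stored as integer milliseconds in files and
converted to seconds inside the formulas, whose printed bounds (±0.8 s,
±0.5 s) are in seconds. The same-reward choice proportions use exactly the
twelve test presentations of each pair — the conditioning set of the
formula. All scores are antisymmetric under swapping their condition labels
(frequent/rare, valued/devalued, degraded/contingent), which the property
suite verifies on random inputs. Questionnaire scoring implements the
habit instruments: the per-behavior self-report index (item sum / 72, a
frequency filter requiring at least three frequently-performed behaviors),
the two creature-of-habit subscale means, and the habitual-tendencies total
and 4/4/3 subscale sums. Which items belong to which subscale is
configurable, since only the counts are fixed by the instruments'
published structure.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws, per participant, a generating model from the
mixture (default: the combined model), learning rates from Beta(2, 2),
temperatures from Uniform(1, 9), and instructed-choice compliance from
Beta(20, 2) — settings chosen once to span the qualitative regimes from
value-dominated to habit-dominated behavior. Response times are log-normal
(`exp` of a Gaussian around `log(420)` ms) sped up by the scaled value
difference and the kernel difference of the chosen option (slopes 0.25,
residual sd 0.2 on the log scale), truncated to (50 ms, response window];
this matches the *analysis* model for RTs (log-linear), with no claim to
model the human RT mechanism. Misses occur with probability 0.05 per trial.
Post ratings carry the pre rating plus value and kernel effects (weights
20 rating points per unit) with rounding and clipping to 0–100, two
ratings per timepoint. Questionnaire items load on a single latent habit
trait; setting the loading to zero emulates a null association between
questionnaires and task behavior. What the generator does *not* emulate:
planned-missing designs, demographic covariates, sequential effects in RTs,
or any drift-diffusion-style process.

Problem sizes used by the shipped test suite were chosen to exercise the
full pipeline at the scale of the study design where the property demands
it (50 subjects at the full 5 × 160 + 136 trial length for the
learning-rate recovery check) and at reduced scale (one or two training
days) where the property is scale-free, such as schema round-trips and
score symmetries.

## A known limitation: kernel lock-in dilutes the rewarded-pair effect

The package's own cohort simulations reveal a structural property worth
understanding before interpreting the rewarded-pair choice score. In the
combined model the kernel difference can reach 1 while the value difference
of the 2-point-apart training pairs is at most $2/9$; with $\beta_q \le 10$
the value signal contributes at most a logit of 2.2. A fast kernel
($\alpha_h$ in the upper half of its prior) therefore amplifies whatever
the agent happened to choose early — a positive-feedback "lock-in" that can
attach the habit to the *rare* member of a pair. Across a cohort drawn from
the full priors this randomizes the sign of some participants'
frequent-vs-rare preference: the cohort mean rewarded-pair choice score
stays positive (value-coherent agents dominate it) but a sign test at
n = 50 is underpowered, while the instructed-choice task — where training
frequency is imposed by the cue rather than emergent — shows the effect
robustly. The corresponding acceptance check on the rewarded-pair side is
accordingly expected to be marginal under these generating conditions; the
suite keeps it at its original settings rather than narrowing the priors,
because the dilution is a finding about the model family, not a bug.
Agents with slow kernels ($\alpha_h \approx 0.05$) show the rewarded-pair
effect strongly and deterministically, which the unit suite verifies.

## Numerical choices

* Seeded RNG is always scoped: `with_seed()` restores the caller's RNG
  state, and child seeds are derived with a fixed 32-bit congruential map so
  they stay valid R integers.
* Optimizer tolerance: `factr = 1e7` (≈ 1e-9 relative on the objective),
  500 iterations per start; the grid-oracle test bounds the optimizer's
  suboptimality at 1e-3 nats on short logs.
* Likelihoods floor choice probabilities at 1e-12 before taking logs; the
  compiled kernel uses the numerically stable `log1p(exp(·))` form.
* The variational model-selection loop stops when the concentration changes
  by less than 1e-6, or after 1e4 iterations with `converged = FALSE`.
* Random-walk reflection folds excursions back as often as needed, so the
  boundaries hold for any step size.
* Exact noncentral-t power, never the normal approximation: the
  approximation moves the required-n boundary cases.

## Worked example

```{r example, eval = FALSE}
p <- model_params("rl_ck", alpha_q = 0.3, beta_q = 8,
                  alpha_h = 0.05, beta_h = 5)
sim <- simulate_reward_pairs_participant(p, days = 5, seed = 12)
reward_pairs_scores_from_log(sim$log[sim$log$phase == "test", ])$choice
fit <- fit_mle("rl_ck", sim$log, n_starts = 10, seed = 1)
fit$estimates

cohort <- generate_cohort(cohort_config(n_participants = 20, seed = 1))
scores <- score_cohort(cohort$trial_logs, cohort$ratings)
colMeans(scores[-1], na.rm = TRUE)

required_n_two_sample_t(d = 0.912, alpha = 0.05, target_power = 0.95)
```
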