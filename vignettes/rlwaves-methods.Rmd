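---
title: "Models and methods behind rlwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rlwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlwaves)
```

# The task and the data

`rlwaves` models a two-choice probabilistic feedback task learned by the
same subjects at two longitudinal waves roughly two years apart.  Four
cues are interleaved over 128 trials in four blocks; for each cue one
option (the *contingent* option) is rewarded on 87.5% of its 32
presentations and the other on the remaining 12.5%.  Two cues give
feedback immediately after the response, two after a short delay — the
*feedback-timing* conditions by which some model parameters may be
split.  Trial records are long-format rows (subject, wave, trial, cue,
condition, choice, reward); non-response trials carry no update and no
likelihood term and are excluded before fitting.

Outcome schedules are exact rather than i.i.d.: each cue rewards the
contingent option on exactly 28 of its 32 presentations, in shuffled
order, and the schedule attaches to the choice identity, so either
choice on a trial has a well-defined outcome.  This fixes the learning
environment across agents and removes one source of Monte-Carlo
variance from every simulation in the package.

# Candidate learning models

Two heuristic strategy models describe strategy use rather than value
learning.  Each cue carries a weight pair $(w_A, w_B)$, initialized at
$(0.5, 0.5)$.  After a reward the chosen option's weight becomes 1 and
the other 0 (win-stay); after a punishment the `wsls` model flips the
weights (lose-shift) while the `ws` model returns to indifference — the
win-stay rule alone prescribes nothing after losses, and the
indifferent reset is the package's reading of that silence.  A single
strategy weight $\tau_{ws}$ or $\tau_{wsls} \in (0, 20)$ scales the
weights in a softmax, so larger values mean more deterministic strategy
use.

Eight value-based variants follow the Rescorla–Wagner delta rule.  The
chosen option's value is updated by the reward prediction error,
$v \leftarrow v + \alpha\,(\rho\, o - v)$ with learning rate
$\alpha \in (0,1)$, and the probability of choosing option $A$ is the
pairwise softmax $p(A) = 1/(1 + e^{-\tau (v_A - v_B)})$ with inverse
temperature $\tau$.  Because $\rho$ and $\tau$ are not jointly
identifiable, the *inverse-temperature family* (`vbm1`–`vbm4`) fixes
$\rho = 1$ and estimates $\tau \in (0,20)$, while the
*outcome-sensitivity family* (`vbm5`–`vbm8`) fixes $\tau = 1$ and
estimates $\rho \in (0,20)$.  Within each family, $\alpha$ and the
second parameter are each either shared or split by feedback timing,
giving the variants (1α,1τ), (2α,1τ), (1α,2τ), (2α,2τ) and their
$\rho$-family counterparts.

Two coding choices deserve emphasis because they are consequential and
easy to get wrong:

* **Outcome valence.** The inverse-temperature family updates values
  toward a signed outcome, $o = +1$ for reward and $o = -1$ for
  punishment, with initial values $v_0 = 0$.  This is the coding under
  which the task's simulated optimum (learning score ≈ 96.5% near
  $\tau$'s upper range) reproduces; coding punishments as 0 instead
  moves the optimum to a much higher learning rate and a visibly lower
  score, and changes the meaning of every fitted parameter.
* **Family distinctness.** Under signed valence with $v_0 = 0$, a free
  $\rho$ with $\tau = 1$ would be an exact reparameterization of a free
  $\tau$ (value differences scale linearly in $\rho$), collapsing the
  two families into one.  The outcome-sensitivity family therefore
  follows its update equation literally: the value target is
  $\rho\,r$ with the reward event $r \in \{0, 1\}$, so punishments
  drive values toward zero rather than below it.  The two families then
  make genuinely different predictions after losses, which is what lets
  model comparison distinguish them.

# Hierarchical estimation over two waves

Every free parameter $\theta$ is estimated for each subject and wave
through a probit link on an unconstrained scale:
$\theta_{iw} = lb + (ub - lb)\,\Phi(\mu_w + \sigma_w\, e_{iw})$.  The
subject effect vector $(e_{i1}, e_{i2})$ is standard bivariate normal
with a per-parameter cross-wave correlation $R_p$, expressed through
its Cholesky factor in a non-centered parameterization; this is what
ties the waves together and lets wave-2 data inform wave-1 estimates
and vice versa.  Priors: locations $\mu_w \sim \mathcal N(0, 0.5)$,
scales $\sigma_w \sim$ half-$\mathcal N(0, 0.5)$ (scales must be
positive; the half-normal is the convention in this model family), and
$R_p \sim$ LKJ(2) on each 2×2 block, one independent block per
parameter rather than one joint matrix across different parameters.
Subjects lost to wave-2 attrition contribute likelihood at wave 1 only;
their wave-2 effects remain latent draws from the hierarchical prior.

## The sampler

The posterior is explored by an adaptive Metropolis-within-Gibbs
sampler written for this model's structure (it is the package's own
sampler, implemented in C++):

* **Subject effects.** Each subject × parameter pair is updated by
  random-walk proposals with separately adapted scales for the wave-1
  coordinate and the wave-2 innovation — identification can be very
  different across waves — followed by an independence proposal from
  the $\mathcal N(0, I_2)$ prior whose acceptance is pure likelihood.
  The independence move matters: when a subject's data barely constrain
  a parameter (small learning rates make $\tau$ weakly identified), it
  decorrelates that subject's effect in a single step.
* **Group parameters, data side.** $\mu$, $\log\sigma$ and
  $\mathrm{atanh}\,r$ get adapted random-walk updates holding the raw
  effects fixed, so the whole cloud of subject parameters moves with
  the group parameter through the likelihood.
* **Group parameters, prior side (interweaving).** The same quantities
  are then redrawn holding every subject's *unconstrained effect*
  $x_{iw} = \mu_w + \sigma_w e_{iw}$ fixed — likelihood-invariant moves
  whose 1-D conditionals cost $O(n)$ and are drawn exactly by slice
  sampling.  Alternating the two parameterizations (an
  ancillarity–sufficiency interweaving scheme) keeps mixing acceptable
  both when the data are weak and when they are strong.

Defaults: 4 chains × 3000 iterations with the
first half as warmup, 6000 saved draws.  Convergence is judged by
split-Rhat < 1.1 on every monitored quantity (group parameters and all
bounded individual parameters); a failing fit is returned but flagged,
and flagged fits are excluded from model-averaging weights.  A
random-walk sampler has no divergence diagnostic, so the convergence
report lists divergences as `NA`.  Two regimes deserve mention: with
very small learning rates (the wave-1 regime of the reference
descriptives, mean α ≈ 0.02) individual inverse temperatures are only
weakly identified, the posterior is broad and prior-influenced, and
small cohorts (n ≲ 20) can need more than the default run length to
pass the Rhat criterion; cohorts of n ≳ 30–40 with clearly identified
parameters converge comfortably within it.  The package's correctness
checks on the sampler are an exact prior-recovery test on an empty
dataset (posterior equals prior analytically) and a prior-drawn
credible-interval calibration (simulation-based-calibration style
coverage).

# Model comparison

The pointwise unit is the trial.  PSIS-LOO is computed from the saved
per-trial log-likelihood draws: raw importance ratios are the inverse
likelihoods, the largest `min(0.2 S, 3 sqrt(S))` ratios are replaced by
expected order statistics of a generalized Pareto distribution fitted
to the tail (empirical-Bayes fit), weights are truncated at the raw
maximum, and trials with tail index k > 0.7 are counted and reported.
No moment-matching refits are attempted.  The comparison table reports
each model's elpd sum and per-trial mean, the difference to the best
model with a paired pointwise SE, and pseudo-BMA+ weights: Bayesian
bootstrap (Dirichlet(1,…,1) trial weights, default 100,000 draws) over
the pointwise elpd vectors, log-sum-exp-safe softmax per draw, averaged.
The two-step study workflow (`run_two_step_comparison()`) first pits
the baseline value model against the heuristics, then compares the
eight value-based variants.

# Validation

One-step-ahead predictions roll the latent states forward on the
observed history per posterior draw, so each trial's prediction uses
only earlier trials; predictive accuracy counts a trial as correct when
the posterior-mean probability of the observed choice exceeds one half
(exact ties score one half — the simplest argmax rule, chosen because
no sharper definition is standard).  Parameter recovery simulates a
cohort with known parameters, refits, and correlates generating with
posterior-mean values.  Model recovery refits every candidate to each
simulated dataset and selects at the group level by total elpd and at
the individual level by per-subject pointwise-elpd sums.

# The synthetic cohort generator

Real behavioral records of this kind are rarely redistributable, so
the generator is the package's stand-in for them and defines the
conditions every empirical check runs under.  Defaults: 140 subjects at
wave 1 with 90% retained at wave 2 (attrition completely at random); per-wave non-response rates 2.41%
and 0.97% injected uniformly over trials; 13/140 of subjects are
"poor-learner" agents generated from `wsls` with a low strategy weight
(τ_wsls ≈ 0.35, so they hover near chance and a realistic minority
fail the 50%-in-the-last-20-trials criterion); all other subjects are
`vbm3` agents (shared α, condition-split τ).  Group moments target the
reference descriptives — α means 0.02 (wave 1) and 0.05 (wave 2) with
SDs 0.02/0.04, τ means 14.6–16.5 with SDs ≈ 2.0–2.4 — and the
unconstrained-scale moments are solved numerically so the induced
bounded means and SDs match those targets exactly (a delta-method
inversion would misstate the small-α mean by almost half).  The
cross-wave correlation of unconstrained effects defaults to 0.5, a
moderate two-year stability chosen once since the source does not print
a test–retest value.  τ_immediate and τ_delayed are drawn
independently, giving a within-person condition difference with mean
≈ 0 and SD ≈ 3, close to the reported spread.

What the generator does not emulate: reaction times, age and sex
structure, practice or fatigue effects within a session, any
systematic attrition, and recognition-memory or imaging outcomes.
Passing tests on these cohorts therefore demonstrates that the
estimation and selection machinery behaves correctly under the assumed generative structure, not that the models describe real
children.

# The learning-score map and optimality

The model-derived *learning score* is the mean per-trial latent
probability of the contingent option — latent probability, not the
realized 0/1 choice, which has the same expectation but more
Monte-Carlo variance.  `learning_score_map()` tiles α ∈ (0.005, 0.995)
× τ ∈ (0.1, 19.9) with a 100 × 100 grid (10,000 combinations over the
open ranges) and simulates 200 replicate agents per cell by default;
`find_optimum()` reports the argmax before and after a 3×3 mean filter
(edge-renormalized) that suppresses Monte-Carlo jitter, breaking exact
ties lexicographically with a warning.  `fitted_learning_scores()`
computes the same score on observed histories at posterior-mean
parameters (full-posterior averaging is available behind the
`posterior = "draws"` flag), split by feedback-timing condition, as
input for downstream longitudinal analyses.

A practical caveat: at high τ the score surface is nearly flat in α
over roughly 0.1–0.3 (within a few tenths of a percentage point), so
the argmax *coordinate* along α is intrinsically noisy at any realistic
replicate count even though the score at the optimum is stable.
Comparisons against an externally reported optimum should therefore weight the
score and the τ coordinate more heavily than the exact α coordinate.

# Numerical and design notes

* Softmax probabilities are computed in the overflow-safe difference
  form and clamped to $[10^{-12}, 1 - 10^{-12}]$, so log-likelihoods
  are always finite.
* Values and weights are maintained per cue and never reset within a
  wave; wave 2 uses new cues, so states never carry across waves.
* The pseudo-randomized cue order resamples each block until no cue
  repeats more than three times consecutively (a design assumption).
* Every source of randomness flows from one master seed through named
  sub-seeds per stage (task, cohort parameters, choices, each MCMC
  chain, bootstrap), so any stage can be reproduced alone.
* Draws live in memory as iteration × chain × quantity arrays;
  persistent outputs are flat CSVs (posterior summaries, comparison
  tables, learning scores, trial records).
* Desk-scale problem sizes used by the test suite: recovery cohorts of
  40 subjects × 2 waves with two short chains, model recovery over 5
  cohorts of 32 subjects, calibration fits of 12 subjects with 64-trial
  tasks.  These sizes were chosen to make every check informative at
  interactive runtimes; the defaults users get are the full study-scale
  settings.

# Known limitations

* The random-walk/slice sampler is slower per effective draw than a
  gradient-based sampler would be on this posterior; heavily
  prior-dominated regimes (tiny cohorts with tiny learning rates) mix
  slowly and are flagged by Rhat rather than silently accepted.
* Individual inverse temperatures recover only moderately when
  learning rates are very small — an identifiability property of the
  design, visible in the recovery reports, not a fitting defect.
* The outcome-sensitivity family's loss coding is an interpretation
  (see above); fits of `vbm5`–`vbm8` should be read with that
  definition in mind.
* No reaction-time modeling, no eligibility traces or forgetting
  variants, and no structural models of brain–behavior coupling: the
  package produces the learning scores such analyses consume, nothing
  downstream of them.
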