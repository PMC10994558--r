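---
title: "Modelling explore-exploit behaviour on the four-armed restless bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling explore-exploit behaviour on the four-armed restless bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and its generative model

In the four-armed restless bandit task a participant chooses one of
four options ("bandits") on each of 300 trials and wins between 0 and
100 points. Each bandit's expected payout drifts from trial to trial,
so good performance requires continual re-learning: persisting with a
previously good option (exploitation) must be balanced against
sampling options whose value is uncertain (exploration). The task is
administered in six 50-trial blocks, with a 1.5-s response deadline;
trials without a response in time are *missed* and give no feedback.

`restlessbandit` implements the complete behavioural-modelling chain
for this task: payout-schedule generation, agent simulation, model
fitting, choice-type classification, model-free behavioural summaries,
and synthetic cohorts for recovery validation.

## The payout walk

The latent mean payout of bandit $i$ follows a decaying Gaussian
random walk (a mean-reverting AR(1) process),

$$\mu_{i,t+1} = \lambda\,\mu_{i,t} + (1-\lambda)\,\theta + \nu_t,
  \qquad \nu_t \sim N(0, \sigma_d^2),$$

and the payout shown on a trial is $\mathrm{round}\!\big(N(\mu_{i,t},
\sigma_o^2)\big)$ clipped to $[0, 100]$. The defaults are
$\lambda = 0.9836$, $\theta = 50$, $\sigma_d = 2.8$, $\sigma_o = 4$ —
the classic published instantiation values for this task family. The
exact payout sequences used in the original experiments are not
published as numbers, so the package ships two canonical fixed-seed
instantiations, `builtin_schedule("session_out")` and
`builtin_schedule("session_in")`, drawn from the same walk; they are
synthetic stand-ins, clearly labelled as such. Initial means are drawn
from the walk's stationary distribution
$N(\theta, \sigma_d^2/(1-\lambda^2))$ (a fixed start at $\theta$ is a
config option). Whether payouts clip at 0 or 1 differs between
conventions; we clip at $[0, 100]$, matching the "win between 0 and
100 points" task instruction, and expose both bounds in
`walk_params()`.

## Learning rules

Two learners track each bandit's value $Q_i$:

* **Delta rule** — $Q_c \leftarrow Q_c + \alpha\,(r - Q_c)$ for the
  chosen bandit $c$, with a constant learning rate
  $\alpha \in (0,1)$. Unchosen values do not change between trials
  (adding decay would introduce a parameter the model family does not
  have).
* **Bayesian (Kalman-filter) learner** — tracks a mean $Q_i$ and a
  variance $s_i^2$ per bandit. Observation step for the chosen bandit:
  $\kappa = s_c^2/(s_c^2+\sigma_o^2)$, $Q_c \leftarrow Q_c +
  \kappa\,(r - Q_c)$, $s_c^2 \leftarrow (1-\kappa)\,s_c^2$. Between
  *every* pair of trials (missed ones included) the prediction step
  tracks the walk: $Q_i \leftarrow \lambda Q_i + (1-\lambda)\theta$,
  $s_i^2 \leftarrow \lambda^2 s_i^2 + \sigma_d^2$. An unchosen
  bandit's variance therefore rises monotonically toward
  $\sigma_d^2/(1-\lambda^2)$, which is why the bandit unchosen longest
  is also the most uncertain one.

Beliefs start symmetric: all $Q_i$ at the prior mean (50) and, for the
Bayesian learner, all $s_i^2$ at the stationary walk variance; both
are config-exposed because the original initialization is unstated.

## Choice rules

Choice probabilities are softmax in a logit that combines value with
up to two bonuses:

$$P(c) \propto \exp\big(\beta\,Q_c \;+\; \phi\,u_c\,[\text{SME/SMEP}]
  \;+\; \rho\,\mathbb{1}[c = \text{last choice}]\,[\text{SMP/SMEP}]\big).$$

$\beta$ (inverse temperature, also called reward sensitivity; units
1/points) multiplies only the value term. The bonuses enter the logit
additively *outside* $\beta$: the reported magnitudes of the
parameters ($\beta$ on the $10^{-2}$ scale, $\rho \approx 3$-$4$) are
only dimensionally coherent if $\rho$ is in logit units, and $\phi$ is
then points-per-uncertainty-unit. The perseveration indicator compares
to the last *made* choice; a missed trial leaves it unchanged, because
no action occurred.

Two genuinely open choices are resolved as follows, both as config
switches with stated defaults:

* **Uncertainty term $u_c$** — the model family is described with
  $\phi$ multiplying the estimated *variance*, while the classical
  formulation of the exploration bonus uses the standard deviation.
  Default `bonus_on = "sd"` for comparability with that lineage;
  `"variance"` is one flag away.
* **Delta-rule exploration bonus** — eight variants arise from
  crossing both learning rules with all four choice rules, so the
  delta-rule SME/SMEP variants need an uncertainty proxy even though
  the delta rule tracks no variance. We use the recency count (trials
  since the bandit was last chosen), the natural delta-rule analogue:
  under the shared walk dynamics, "least recently chosen" and "most
  uncertain" coincide for the Bayesian learner, so recency is the
  common currency of the two learners' directed-exploration targets.

`choice_probabilities()` is computed via log-sum-exp and is exact in
the $\beta \to 0$ (uniform) and $\beta \to \infty$ (greedy) limits.

# Likelihood, fitting and model comparison

`session_log_likelihood()` evolves beliefs along the *recorded*
history and sums $\log P(\text{observed choice})$ over non-missed
trials. Missed trials contribute nothing to the likelihood and trigger
no observation update (behavioural probabilities in this task family
are likewise computed over correctly executed trials), but the
Bayesian diffusion step still runs across them. The sequential kernel
is implemented in C++ because fitting and the recovery harness
evaluate it on the order of $10^5$-$10^6$ times.

`fit_map()` maximizes log-likelihood plus log-prior on a transformed
scale ($\alpha$ logit; $\beta$, $\phi$ log, unless negative $\phi$ —
uncertainty aversion — is enabled, in which case $\phi$ is identity;
$\rho$ identity), from 10 starts by default: one fixed central start
plus Latin-hypercube points over the transformed box, keeping the best
optimum (ties to the lowest start index). The default priors are
weakly informative — $\alpha$ flat on $(0,1)$, $\beta$ and $\phi$
half-normal (scales 1 and 5), $\rho$ normal with sd 5 — and
`prior = "flat"` turns the same machinery into maximum likelihood.
Posterior summaries come from a Laplace approximation at the optimum
(multivariate-normal draws on the transformed scale, summarized on the
natural scale); if the Hessian is singular — e.g. a single-trial
session — a diagonal fallback keeps the fit usable, with wide
intervals. `fit_posterior()` provides full MCMC (adaptive random-walk
Metropolis initialized at the MAP, split-$\widehat{R}$ and effective
sample size diagnostics, WAIC); it exists because per-subject
posterior distributions are the reference analysis style for this
task, while MAP+Laplace is the fast default. Fits are per-subject;
hierarchical pooling across subjects is deliberately out of scope in
this version.

`compare_models()` reports log-likelihood, parameter count, AIC and
BIC per variant and ranks by BIC by default (the original
model-selection criterion is unstated; BIC's stronger complexity
penalty is the conservative default for nested families, and AIC and
the raw likelihood are always reported alongside). `group_contrast()`
forms the difference of group means of per-subject posterior means,
with a seeded bootstrap over subjects for the 95% interval.

# Choice-type classification

Every valid trial is labelled with exactly one of three types, from
the beliefs *before* the trial's outcome:

* **exploit** — the chosen bandit's $Q$ is the maximum (any argmax
  counts; exact ties are measure-zero after the first outcome);
* **directed** exploration — among non-best bandits, exactly one is
  the directed target: the most uncertain (largest $s_i^2$) for
  Bayesian learners, the longest-unchosen for delta learners (the two
  criteria coincide for the Bayesian learner under shared dynamics);
  ties break to the lowest bandit index;
* **random** exploration — any other lower-valued choice.

Missed trials are labelled `missed` without inspecting beliefs.
`behavioural_summary()` computes the model-free metrics with valid
trials as denominators: P(best bandit) — against the bandit with the
highest scheduled *latent mean* that trial by default, because "best"
is a property of the generative schedule rather than of one noisy
realized payout (the realized-payout ranking is the `best_by`
alternative) — mean points, the three label proportions, P(stay)
(repeating the previous *valid* choice, so a missed trial is skipped
over, not counted as a switch), P(missed) over all trials, mean
decision time, and all of these per 50-trial block (trials 1-50,
51-100, ...).

# The synthetic cohort generator

`sample_cohort()` emulates the study's structure so the whole chain is
testable without any data download: 22 healthy controls, 28 PD
without apathy, 25 PD with apathy. Only the *between-group contrasts*
of the decision parameters are anchored to reported values
($\beta$ shifted by $-0.02$, $\phi$ by $-0.40$, $\rho$ by $-3.57$ in
the apathy group); the absolute levels are not published, so the
generator anchors the PD-no-apathy group at $\beta = 0.10$,
$\phi = 0.8$, $\rho = 4.0$, $\alpha = 0.4$ — plausible magnitudes for
0-100-point payouts — and places healthy controls at the same level,
consistent with the near-identical task performance of those two
groups. Between-subject spreads (sd 0.03, 0.25, 1.2, 0.10
respectively) are a declared modelling choice. LARS apathy scores are
Gaussian per group (centres $-28.1$, $-28.0$, $-14.0$; sds 3.6, 2.9,
5.2), truncated to $[-36, 36]$, with a loading (default 0.5) of the
subject's standardized $\beta{+}\rho$ deficit so that within-group
behaviour-score correlations are non-trivial rather than purely
group-driven; scores above $-22$ are flagged apathetic. Sessions are
simulated with a 3% missed-trial rate on the `session_out` schedule
(a second session on `session_in` is an option).

What the generator does *not* emulate: reaction-time dynamics
(decision times are plausible log-normal metadata, not a model),
learning effects across blocks beyond what the agents produce, any
joint distribution of parameters beyond independent Gaussians, and
clinical covariates other than a scalar LARS. Tests that pass on this
cohort therefore validate the *pipeline* — that known group structure
propagates through simulation, fitting and classification — not any
claim about real patients.

# Validation experiments and problem sizes

The package's own validation chain, run by the test suite and
`scripts/acceptance.R`:

* **Likelihood oracle** — the compiled kernel agrees with a
  straight-line R trace to $10^{-10}$ over all $4^5 = 1024$ possible
  5-trial choice sequences (whose probabilities also sum to 1), and
  the uniform policy has the closed form $300\ln(1/4)$.
* **Parameter recovery** — 40 agents per learner, 300 trials,
  Latin-hypercube-dispersed generating parameters
  ($\alpha \in (0.15, 0.85)$, $\beta \in (0.02, 0.30)$,
  $\rho \in (0, 8)$, $\phi \in (0.1, 2)$ Bayesian / $(0.05, 0.5)$
  delta), 10-start MAP refits. Spearman true-vs-recovered exceeds 0.7
  for $\beta$ and $\rho$ and 0.5 for $\phi$; in practice all exceed
  0.95, and the $\alpha$ bias is well inside $\pm 0.15$.
* **Model recovery** — each of the eight variants generates replicate
  sessions from fixed well-separated parameters ($\alpha = 0.12$,
  $\beta = 0.2$, $\rho = 2$, $\phi$ as above); all eight are refit and
  the best-BIC variant recorded. $\alpha = 0.12$ is chosen *below*
  the Kalman learner's gain range — the chosen bandit's steady-state
  gain under the default walk is $\approx 0.45$ and unchosen bandits
  have higher gains still, so no Kalman learner can mimic a slow delta
  learner; a mid-range $\alpha$ (e.g. 0.7) sits inside that gain range
  and is genuinely mimicked, which is worth knowing when interpreting
  learning-rule comparisons on real data. Likewise a large $\rho$
  suppresses the switches that carry the discriminating information.
  The generating variant wins a strict majority of replicates for
  every variant (9 replicates each in the tests, 11 in the acceptance
  script; diagonal rate $\approx 0.92$-$0.95$).
* **End-to-end direction** — across five default cohorts, the apathy
  group's classified P(exploit) and P(stay) are lower and P(random)
  higher than the no-apathy group's, and generated LARS correlates
  negatively with per-subject P(exploit).
* **Determinism** — every pipeline stage rewrites byte-identical
  primary outputs under a fixed seed and config.

These sizes (40 recovery agents, 9-11 model-recovery replicates, five
cohort seeds) are the package's chosen validation scale; all scale up
linearly via the corresponding arguments.

# Numerical choices and edge cases

* Tie-breaks: argmax ties in classification favour `exploit`;
  directed-target ties break to the lowest bandit index; optimizer
  ties to the lowest start index.
* $\sigma_d = 0$ and $\sigma_o = 0$ are allowed (degenerate noise-free
  walks are useful fixtures); $\lambda = 1$ is not, because the
  stationary prior variance is undefined there and the task's walk
  decays by construction.
* The multi-start box on the transformed scale spans
  $\beta \in [10^{-3}, 0.5]$, $\phi \in [0.02, 5]$,
  $\rho \in [-8, 8]$, $\mathrm{logit}(\alpha) \in [-2.5, 2.5]$; these
  are start locations, not constraints — BFGS moves freely outside
  the box, with a Nelder-Mead fallback if BFGS fails.
* $\beta \to 0$ fits (uniform responders) sit at the edge of the log
  transform; the reported estimate is then numerically 0 and the
  Laplace interval is wide, which is the honest answer.
* All randomness flows through named integer seeds; sub-seeds are
  derived arithmetically and kept inside 32-bit range, so every
  simulation, fit, bootstrap and sampler run is exactly reproducible.

# Known limitations

Per-subject fitting only (no hierarchical shrinkage); the Laplace
interval is a local approximation and can be optimistic near transform
boundaries; the cohort generator's absolute parameter levels are a
modelling choice, so only directions and contrasts — not absolute
group means of behavioural metrics — should be compared against real
cohorts; and the two built-in schedules are canonical draws from the
right walk, not the original experimental payout sequences.
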