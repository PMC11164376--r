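---
title: "Modelling longitudinal speech category learning with inverse-Gaussian races"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal speech category learning with inverse-Gaussian races}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonerace)
```

# The scientific setting

`tonerace` analyses multi-session non-native speech category learning
experiments of a standard design: adults learn to assign Mandarin tone
stimuli (4 tone categories x 4 speakers x 5 syllables = 80 stimuli,
duration- and level-normalized) to four response keys under trial-by-trial
feedback. Each of three sessions, separated by roughly one and two months,
contains six 40-trial training blocks built from two speakers, plus one
feedback-free generalization block with the two held-out speakers.
Working-memory capacity is measured once with a 15-trial operation-span
(OSPAN) task, scored 0-75 as the summed length of perfectly recalled
letter spans.

The package provides four connected layers:

1. **Design and scoring** (`make_stimulus_grid()`, `trim_rt()`,
   `block_accuracy()`, `classify_learner()`, `ospan_score()`,
   `maintenance_scores()`, `generalization_score()`, `median_split()`).
2. **A generative decision model** — an independent race of four
   inverse-Gaussian accumulators — and its Bayesian hierarchical fit
   (`fit_session()`).
3. **Association models** — random-intercept linear mixed models linking
   OSPAN to accuracy, maintenance, generalization, and fitted decision
   parameters (`accuracy_model()` and friends).
4. **A synthetic-cohort generator** (`sample_cohort()`,
   `simulate_experiment()`, `simulate_ospan()`) that emulates the full
   design so every downstream stage is testable without any private data.

# The decision model

On each trial, evidence for each response option $d \in \{1,\dots,4\}$
accumulates as an independent unit-diffusion Wiener process with drift
$\mu_{d,s} > 0$ (depending on the true stimulus category $s$) toward a
response-specific boundary $b_d > 0$. The first accumulator to reach its
boundary determines the choice, and the response time is the crossing
time plus a non-decision offset $\delta_s$ (stimulus encoding plus motor
time). The first-passage time of a single accumulator is inverse-Gaussian
(Wald),

$$f(t;\mu,b) = \frac{b}{\sqrt{2\pi t^3}}
  \exp\!\left\{-\frac{(b-\mu t)^2}{2t}\right\},
\qquad
S(t;\mu,b) = 1 - \Phi\!\left(\tfrac{\mu t - b}{\sqrt t}\right)
  - e^{2\mu b}\,\Phi\!\left(-\tfrac{\mu t + b}{\sqrt t}\right),$$

with mean $b/\mu$ and variance $b/\mu^3$, so the joint density of
(choice $d$, RT $\tau$) is
$f_d(\tau-\delta_s)\prod_{d'\neq d} S_{d'}(\tau-\delta_s)$.
The drift is an evidence-quality parameter (units: evidence s$^{-1}$),
the boundary a response-caution parameter (evidence units), and the unit
diffusion coefficient is the standard identifiability normalization for
this model class. Drifts and boundaries are modelled on the log scale,
which enforces positivity (a race of non-positive-drift accumulators
need not terminate) and makes participant effects multiplicative.

## Hierarchical longitudinal structure

Learning changes the decision process across the six training blocks, so
per participant $i$, log drifts $\log\mu_{i,d,s}(t)$ (one trajectory per
response x stimulus pair) and log boundaries $\log b_{i,d}(t)$ (response
only — caution does not depend on the true category) are smooth
functions of block $t$, represented in a B-spline basis:

- a population coefficient vector per curve, with a Gaussian prior
  combining a ridge (SD `pop_prior_sd = 2` on the log scale) and a
  first-difference smoothing penalty (SD `smooth_sd = 1`);
- zero-mean Gaussian participant deviations per curve with *local*
  (participant x cell) variances carrying weakly-informative
  inverse-gamma (`dev_a0 = 1`, `dev_b0 = 2`) hyperpriors. The scale
  mixture gives deviations heavy-tailed marginals, and both the
  granularity and the tail weight matter: a disengaged participant
  deviates enormously in the four correct-response cells while matching
  the population elsewhere, and coarser variances (global or
  per-participant) or tighter hyperpriors demonstrably over-shrink
  exactly those cells — in recovery experiments their log drifts landed
  at a third of the true deviation, while learner recovery barely
  changes with the hyperprior;
- non-decision offsets $\delta_{i,s}$ per participant x stimulus
  category, constant over blocks and sessions, with uniform priors on
  $(0,\ 0.995 \times \min \text{RT}_{i,s})$, guaranteeing positive
  decision times.

The default basis is cubic with boundary knots only (four coefficients
over blocks 1-6, i.e. a cubic polynomial trend). We initially used
interior knots at blocks 2-5 but found that with only six support points
the eight-dimensional basis over-parameterizes the trajectories: it slows
mixing and measurably degrades parameter recovery on synthetic cohorts
(correlation between true and posterior-mean log drifts dropped by about
0.1). Both choices are exposed through `basis_spec()`.

Sessions are fitted separately (no between-session smoothness), with all
participants — learners and non-learners — together; group contrasts are
computed post hoc. Generalization-block trials carry no feedback and are
excluded from fitting by default (`include_generalization` flips this).

## Sampling

`fit_session()` runs an adaptive Metropolis-within-Gibbs sampler:
random-walk proposals on each population and participant coefficient
block (jointly over the basis dimensions, plus a scalar move along the
constant direction, which mixes a trajectory's overall level much faster
than coordinate moves alone), random-walk proposals on each
$\delta_{i,s}$, and conjugate Gibbs draws for the deviation variances.
Proposal scales adapt toward an acceptance rate of 0.3 during burn-in
only. Defaults follow the usual schedule for this model family: 6,000
iterations, 2,000 burn-in, thinning 5, hence 800 retained draws; all
overridable via `ddm_model_config()`.

Two numerical details are worth recording. First, the deviation-variance
Gibbs updates are held fixed during the first half of burn-in: every
deviation starts near its moment estimate, and updating the variances
from a cold start collapses them into a funnel the sampler cannot leave.
Second, the chain is initialized from crude moment estimates — choice
fractions set the relative drifts per participant x stimulus (an
accumulator's win probability grows with its drift share), an early/late
block split sets a linear starting trend, and the mean decision time
sets the overall speed scale. With short chains this matters: the fixed
burn-in budget is spent refining trajectories rather than transporting
every participant from the population curve to their own data.

The race likelihood kernel is implemented in C++ (survival terms in log
space, since $e^{2\mu b}$ overflows long before the product term does);
an R implementation (`race_loglik()`) defines the reference semantics
and the two are tested against each other to $10^{-10}$.

## Diagnostics and summaries

Convergence is monitored with Geweke z-scores (first 10% vs last 50%,
spectral-density-at-zero variances via AR fits) on all population curve
chains plus a random 10% of participant-level drift chains, and with
acceptance-rate summaries. `posterior_predictive_check()` simulates
replicate datasets from retained draws and compares per-block accuracy
and RT quantiles (0.1/0.5/0.9) with the observed data. Point estimates
are posterior means with pointwise 95% credible intervals.
`correct_drift_summary()` averages the four correct accumulators
($d = s$) per participant x block — the quantity carried into the
working-memory analyses — and the boundaries over responses.

## What recovery can and cannot achieve

At the study's data size (40 trials per block, 240 per session per
participant) the per-cell drifts of a near-chance responder are only
weakly identified: profiling the likelihood of such a participant over a
two-fold range of correct-accumulator drift changes it by only a few
nats, because offsets, boundaries, and the remaining drifts partially
compensate. The posterior is then genuinely diffuse and posterior means
are pulled toward the population. Recovery correlations of about 0.8 for
correct-accumulator log drifts (participants x blocks) and about 0.95
for log boundaries, as measured by the test suite on 20-participant
synthetic cohorts with shortened chains, are near the information ceiling
of these conditions rather than a sampler limitation. Non-decision
offsets show a small upward finite-sample bias (posterior mass
accumulates below the minimum observed RT), a well-known feature of
race-model fits at moderate trial counts.

# Behavioural scoring rules

- **RT trimming**: the top and bottom 1% of trials, pooled across all
  participants, sessions and blocks, are removed before fitting
  (`trim_rt()`, linear-interpolation quantiles, rows exactly at a
  quantile retained; correct and incorrect trials kept).
- **Learner classification**: a participant whose final-block (session
  3, block 6) accuracy is at or below 35% is a non-learner. The 35%
  constant is the study's chance band (25% chance for 4 options plus a
  10-point cumulative-binomial margin at 40 trials); we store it as a
  named constant rather than recomputing it because the conventional
  exact-binomial 95th percentile of Binomial(40, 0.25) would give 15/40
  = 37.5%, and fidelity to the stated rule wins. The boundary case is
  deliberate: exactly 35% is a non-learner.
- **OSPAN**: sum of span lengths over perfectly recalled spans (order
  sensitive, all-or-nothing); arithmetic accuracy recorded but never
  used to filter.
- **Maintenance**: accuracy deltas between adjacent blocks separated by
  no delay (blocks 5-6 within sessions 1 and 2) vs by the inter-session
  delay (block 6 to next session's block 1), in percentage points.
- **Generalization score**: generalization-block accuracy minus
  final-training-block accuracy, per session.
- **Median split**: scores at or above the sample median are "high WM";
  used only for plotting/grouping — every model uses raw OSPAN.

# Association models

`fit_random_intercept_lmm()` is a compact profiled-REML engine for the
single-random-intercept models this design needs: the variance ratio
$\lambda = \sigma_b^2/\sigma_e^2$ is profiled out (group-wise
Sherman-Morrison algebra, so the solve is exact and fast), optimized on
the log scale with the $\lambda = 0$ boundary checked explicitly, and
fixed effects come from the GLS solve at the optimum. It reproduces OLS
exactly when the intercept variance is pinned to zero and matches
`lme4::lmer` on benchmark datasets (both are tested). P-values use the
normal approximation to the t-statistic — with hundreds of residual
degrees of freedom the difference from a Satterthwaite correction is
negligible — and the method is recorded in every result object.

The model wrappers mirror the study's analyses: accuracy on OSPAN x
block (numeric 1-6, uncentered) x session (treatment contrasts, baseline
session 1); maintenance deltas on OSPAN x transition x delay;
generalization scores on OSPAN x session; posterior-mean drift or
boundary summaries on OSPAN x block x session. The three derived-score
models default to learners only, as in the study; `accuracy_model()`
exposes the choice. When given single-session data the wrappers drop the
session factor, so reduced pipelines still fit.

# The synthetic cohort

`cohort_config()` fixes the generative population; its defaults are the
study conditions and are not tuned per analysis:

- latent WM truncated-normal on the OSPAN scale (mean 45, SD 15 on
  [0, 75]), close to the study's reported median of 46;
- a learner/non-learner mixture with marginal learner rate 0.68 (the
  study's 73/107) and a mild logistic dependence on WM (slope 0.03
  logits per OSPAN point), consistent with the reported learner vs
  non-learner OSPAN gap of about 7 points;
- learners: correct-accumulator log drifts rise within sessions (total
  gains 0.45/0.30/0.25 across blocks for sessions 1-3) and across
  sessions (gains 0, 0.35, 0.55), with the within-session rise increasing
  by 0.006 per OSPAN point above the mean (`wm_block_gain`, the
  WM-learning coupling; set to 0 for null cohorts) — magnitudes chosen
  so simulated learner accuracies track the study's reported trajectory
  (roughly 36% to 52% across session 1, ending near 68% in session 3);
  incorrect drifts flat at log 0.55; boundaries near log 1.6;
- non-learners: flat, WM-independent log drifts (log 0.5) equal across
  all four accumulators — hence exactly chance accuracy — with lower
  boundaries (log 1.0), emulating fast, disengaged responding;
- non-decision offsets log-normal around 350 ms per participant x
  stimulus category, constant over blocks and sessions;
- OSPAN recall: a span is recalled perfectly with probability
  $\mathrm{logit}^{-1}(a(\mathrm{wm} - c))$ where the 15 difficulty
  thresholds $c$ sit at the midpoints of each trial's cumulative score
  contribution, so a steep slope makes the expected score equal latent
  WM and the default slope (0.2) keeps score and latent WM correlated
  above 0.9; arithmetic accuracy 90% for learners, 79% for non-learners,
  near the study's reported means.

Because session gains (0.35 between sessions 1-2) are smaller than the
within-session rise (0.45), simulated accuracy drops at session starts —
the forgetting signature the maintenance scores measure — while block-5
to block-6 changes stay near zero. Generalization stimuli reuse the
final training block's parameters, so the expected generalization score
is zero; a cohort-level scale on held-out-speaker drift can be emulated
by editing the latents.

What the generator deliberately omits: within-block (trial-by-trial)
learning dynamics and any feedback-driven update rule (parameters are
block-resolution, as in the fitted model), acoustic stimulus structure
(the two-dimensional pitch space is not modelled, so stimulus-level
confusion patterns are exchangeable within category), session-to-session
parameter noise, and RT contaminants such as lapses. Passing tests
therefore demonstrate that the pipeline recovers what this generative
family encodes — not that real data satisfy the model.

# Problem sizes used by the test suite

The suite fits 20-participant single-session cohorts with chains of
1,500 iterations (500 burn-in, thinning 2) for recovery checks, a
10-participant flat-trajectory cohort for null checks, and fifteen
10-participant end-to-end runs (600-iteration chains) for the
coupled-vs-null working-memory effect property. These sizes were chosen
so the full suite exercises every stage at meaningful precision while
remaining routine to run; the same checks pass at larger sizes.

# Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state. `run_pipeline()` derives one seed per stage from a
master seed at configuration time, stores them in the config, and writes
a manifest with config echo and output checksums; identical configs give
identical manifests. The pipeline reads nothing outside its declared
inputs.
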