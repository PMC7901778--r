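---
title: "Modelling Pavlovian-instrumental arbitration in the Go/NoGo task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Pavlovian-instrumental arbitration in the Go/NoGo task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavarb)
```

## The task and what the models must explain

The orthogonalized Go/NoGo task crosses outcome valence with the required
action. Each of the four conditions has its own stimulus; the correct action
yields the positive outcome (reward delivered, or punishment avoided) with
probability 0.7 in the EEG-style design (40 trials per condition) and 0.8 in
the fMRI-style design (60 trials per condition), and the incorrect action
with the complementary probability. Outcomes are coded −1 (loss), 0
(neutral), +1 (win); win stimuli never produce −1 and avoid stimuli never
produce +1. `task_config()` encodes the two designs; `simulate_subject()`
presents the conditions in a fully random intermixed order (no run-length
constraints, since the designs impose none).

Human performance in this task shows a Pavlovian bias: accuracy is higher
on go-to-win than nogo-to-win, and higher on nogo-to-avoid than go-to-avoid.
The modelling question is whether the *strength* of that bias is fixed over
a session or tracks a dynamically updated belief about the controllability
of outcomes.

## The three models

All three models share a state: a Pavlovian value per stimulus and an
instrumental value per stimulus-action pair, learned from outcomes.

The **RL model** updates values with a constant learning rate,
`ΔV = α(ρr − V)`, adds a scaled Pavlovian value and a fixed go bias to the
instrumental go value, and responds through a unit-temperature softmax mixed
with a lapse probability ξ (the outcome scaling ρ plays the role of an
inverse temperature). It has five free parameters: α ∈ [0,1], ρ ∈ (0,20],
π ∈ [−10,10], b ∈ [−10,10], ξ ∈ [0,1].

The **Bayesian models** treat both predictors as Beta-Bernoulli learners.
The value recursion is the posterior-mean update with a decaying learning
rate: the effective count is incremented first, then `v ← v + (r − v)/η`.
The prior is encoded by the initial count (η0, the prior confidence) and the
initial value. The decision value is the model-averaged action value,
`V(s,a) = (1−w)·V_I(s,a) + w·V_P(s,a)`, where the Pavlovian action value is
zero for nogo (the Pavlovian system energizes approach only), and the policy
is a softmax with inverse temperature β ∈ (0,20]. The **Fixed** variant
estimates w as a free constant w_fixed ∈ [0,1]; neither Bayesian variant has
a lapse or go-bias parameter.

The **Adaptive** variant replaces the constant with the posterior
probability of the uncontrollable environment, w = 1/(1+exp(−L)). L starts
at 0 — a uniform prior over environments, so w = 0.5 before any data — and
accumulates, on every trial, the log-likelihood ratio of the observed
outcome event (e = |r|) under the stimulus-only predictor versus the
stimulus-action predictor of the action actually taken, both evaluated at
their pre-update estimates:

`ΔL = e·log(m_s/m_sa) + (1−e)·log((1−m_s)/(1−m_sa))`

with m the event-probability magnitudes of the two estimates. The Adaptive
model therefore has four free parameters: β, v0_pav ∈ [−1,1], η0_pav and
η0_inst ∈ [1,100].

## Numerical and structural choices

Several choices were genuinely open; we document them and the reasons.

**Interior priors for the log-odds update.** Because values are signed
(`v = P(+event) − P(−event)` per stimulus, with valence fixing the sign in
this task), the magnitude |v| is the natural event-probability estimate —
but a *prior* magnitude of zero is incompatible with any Beta prior, and
taking its logarithm makes the very first trials contribute unbounded
evidence. Two safeguards keep the update coherent. First, the instrumental
estimates start at 0.5, the prior predictive of a uniform Beta prior; both
actions share this value, so there is no initial action preference. Second,
magnitudes entering the logs are clipped to the rule-of-succession bounds
`[1/(η+1), η/(η+1)]`: a predictor backed by η effective observations cannot
claim a more extreme event probability than η observations can justify.
(An absolute guard of 1e−4 remains for extreme counts.) This also corrects
the systematic underestimate that |v| gives when beliefs straddle zero.
Without these safeguards the weight saturates at w = 1 within a handful of
trials for typical parameters, and the model degenerates to a purely
Pavlovian agent — dynamics incompatible with the graded weight trajectories
the adaptive account is meant to produce.

**Pre-choice convention.** Traces record the quantities in force when the
action was selected: the w used on trial t is computed from L *before* the
trial-t update, and the log-odds update uses pre-update value estimates.
All analyses bin on this pre-choice w.

**Fitting.** Each subject is fit by maximum likelihood: Nelder-Mead on a
transformed parameter space (scaled logit; ρ, β and the η0s are searched on
a log grid inside their boxes since they are positive scale parameters),
with 10 restarts drawn uniformly over the transformed box. Restart draws
are sequential, so enlarging the restart budget extends, rather than
replaces, the start set. Per-trial probabilities are floored at 1e−12
inside the log to keep the objective finite; BIC = k·ln(n) + 2·nll, and
−BIC/2 serves as the per-subject log model evidence.

**Group-level model comparison.** The random-effects model places a uniform
Dirichlet prior over model frequencies; `rfx_bms()` runs the standard
variational updates to a 1e−6 change tolerance (max 500 iterations).
Exceedance probabilities are Monte-Carlo estimates (default 1e6 Dirichlet
draws; the two-model case has a Beta closed form, used as a test oracle
only). The Bayes omnibus risk compares the variational free energy of the
random-effects model with the exact evidence of the equal-frequency null;
protected exceedance probabilities blend the two:
PXP = (1−BOR)·XP + BOR/K.

**Behavioral analyses.** The go bias of a trial set is the accuracy on
go-required trials minus the accuracy on nogo-required trials. Weight
quantiles are assigned within subject by rank, ties broken by trial order
(5 bins by default; the binning is invariant to monotone transforms of w,
and subjects with a constant weight series are excluded with a warning).
The early/late analysis computes go bias over the first and last n trials
of the intermixed sequence, by default on avoid-condition trials. The
confound checks correlate w with value series per subject and summarize by
the group median, a Wilcoxon signed-rank test, and a default-prior (JZS)
one-sample Bayes factor on the Fisher-z-transformed correlations (Cauchy
prior scale √2/2 on the effect size, marginalized by quadrature) — the
Bayes factor quantifies evidence *for* the null of no confound.

## The synthetic-data generator and what passing tests show

The simulator generates agents from any of the three models through the
same engine that computes likelihoods, so a model evaluated on its own
simulated actions reproduces the simulation trace exactly; this shared-engine
property is what makes recovery experiments internally consistent. For
recovery experiments, true adaptive-model parameters are drawn as
β ~ U[1,10], v0_pav ~ U[−0.25, 0.75] (most mass above zero: an optimistic
prior Pavlovian value), η0_pav, η0_inst ~ U[1,10].

The generator emulates the two study designs' condition structure, trial
counts, contingencies and outcome coding. It does not emulate reaction
times, the lateralized target discrimination of the fMRI variant, monetary
payoff bookkeeping, or any neural observable — so passing tests show that
the *pipeline* behaves as the account predicts on data generated by the
models themselves, not that these models describe human subjects.

Two properties of the simulated agents matter for interpreting the
analyses. First, in these (controllable) designs the adaptive agent's w
typically starts at 0.5, may rise briefly while outcomes are still poorly
predicted, and then falls as the instrumental predictor proves superior —
crossing 0.5 around trial 20 on average and approaching 0 by mid-session.
The "early" window for the early/late go-bias signature is therefore taken
as the first 20 trials in our simulation analyses (the function's default
window of 40 matches the classical analysis of slower-learning human data;
both are arguments). Second, because w spends much of the session near 0,
the Pavlovian prior confidence η0_pav constrains only a short early
stretch of behavior; it is the least identifiable parameter in recovery
experiments, and the pooled true-vs-recovered correlation (computed by
z-scoring each parameter and pooling pairs, i.e. the mean of per-parameter
correlations) is dominated by β and v0_pav.

## Problem sizes

The packaged experiments use the study-scale designs: recovery experiments
simulate 30 subjects on the fMRI design (240 trials each) with 10-restart
fits; model recovery fits all three models to the same cohort; qualitative
go-bias signatures are evaluated over 20 replicate cohorts by sign tests.
Unit tests use reduced designs (5-30 trials per condition) where only the
mechanics, not the statistics, are at stake.

## Known limitations

* Model evidence uses the BIC approximation, which penalizes parameters
  independently of their identifiability; a Laplace or sampling-based
  evidence would treat the weakly identified η0 parameters more gracefully.
* Per-subject MLE with box bounds can return boundary estimates (η0 at 100,
  v0_pav at ±1) for subjects whose likelihood is flat in those directions;
  recovery correlations inherit that noise.
* The reward/punishment sensitivity extension of the RL model and
  hierarchical (empirical-Bayes) fitting are out of scope.
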