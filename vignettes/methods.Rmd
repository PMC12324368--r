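---
title: "Models and methods in optoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in optoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`optoshift` simulates and analyses an accumulation-of-evidence virtual
T-maze experiment in which one striatal output pathway (direct or
indirect) is unilaterally inhibited on a random subset of trials while a
cortical population is recorded. This vignette explains the generative
models, the analysis chain, the tunable parameters and the numerical
choices, and what the synthetic-data tests do and do not establish about
real recordings.

## The task generator

The virtual maze has a start region (-30 to 0 cm), a cue region (0 to
200 cm) and a delay region (200 to 300 cm), discretised throughout into
66 half-open 5-cm position bins. Visual cues are drawn per side from a
spatial Poisson process over the cue region. On main-maze trials the
majority:minority rate pair is 8.0:1.6 cues per metre on about 61% of
main trials and 7.3:2.3 on the rest (the printed 50%/32% shares of all
trials, renormalised after warm-up and easy-block trials are set aside by
their trigger rules rather than by quota). Same-side cues closer than a
12-cm refractory window are removed by sequential rejection: positions
are sorted and any cue nearer than 12 cm to the previously kept cue is
deleted. This is the simplest reading of a refractory constraint; a
redraw scheme would slightly fatten the count distribution's lower tail
but leaves every quantity we test unchanged at our scales.

The rewarded side is the side with more realised cues; ties are rewarded
at random and flagged for exclusion. Side debiasing is closed-loop: the
error fractions `eR`, `eL` on recent right- and left-rewarded trials are
computed with half-Gaussian recency weights (sigma = 20 trials over the
last 40 same-side trials), their square roots are clamped to
[0.15, 0.85], and the right-draw target is the softmax
`PR = exp(cR) / (exp(cR) + exp(cL))`. Because the empirical right
fraction (half-Gaussian, sigma = 60 trials) can drift from `PR`, the
realised draw uses `0.5 * PR` when the empirical fraction exceeds `PR`
and `0.5 * (1 + PR)` otherwise. The clamped-softmax form is one of two
readings of an ambiguous printed formula; we chose it because the clamp
on the square-rooted error fractions only makes sense inside an
exponential-ratio rule, and it bounds `PR` within
`[logistic(-0.7), logistic(0.7)]`, which our property tests assert.

Warm-up trials open each session and end after ten trials once warm-up
accuracy exceeds 85% (with a hard cap at 30 so pathological agents still
progress); they carry a visual guide, are never lasered, and are excluded
from analyses. When running 40-trial accuracy falls below 55%, a
ten-trial easy block is interposed; easy trials stay in analyses to
preserve trial history. The laser is delivered on a configurable 10-20%
of main-maze trials and only within the cue region.

Choices come from a multi-state GLM-HMM agent: per-state Bernoulli GLMs
over (delta cues, previous choice, previous rewarded choice, laser,
bias), with fixed state-transition probabilities. The default 3-state
agent has an engaged state (high evidence weight, laser-sensitive) and
two oppositely biased states, with transitions tuned so the engaged
state occupies roughly two thirds of trials at stationarity.

View-angle kinematics follow
`dTheta/dt = sign(omega) * min(exp(1.4 |omega|^1.2) - 1, pi/2 - |Theta|)`;
the grouping of the constants inside the exponent is ambiguous in print,
so the alternative grouping `exp(1.4) * |omega|^1.2 - 1` is exposed as an
option. Early-turn trials (view angle reaching 90 degrees before 290 cm)
are injected at a configurable rate and later removed by trial selection.

All stochastic draws in a session come from R's global stream seeded once
per session, which makes `simulate_session()` bit-reproducible from
`(config, agent, n_trials, seed)`; separate named sub-streams would add
bookkeeping without changing that contract.

## The synthetic neural populations

Each neuron belongs to one tuning class. Evidence-class neurons follow
`baseline + gain * sign(pref) * cumulative evidence * ramp(position)`,
where the ramp rises linearly from cue onset over `evidence_ramp_cm`
(default: the whole cue region) and is sustained through the delay; their
preference is the same on correct and incorrect trials. Choice-class
neurons step with the selected choice only — conditioning on choice
removes any evidence dependence — and their ramp rises late in the stem,
so their apparent evidence preference inverts on incorrect trials.
Outcome-class neurons step with the previous trial's outcome, and
untuned neurons sit at baseline. All neurons carry a position-locked
component (`pos_gain * (1 - (position + 30) / 330)`), the shared
progression-of-position dynamic that the population's first principal
component captures. Emission is Poisson in 10-ms bins, with rates floored
at zero; running speed is 40 cm/s with log-normal per-trial jitter so
Hz-normalisation is exercised by variable bin occupancy.

Laser effects follow the opponent rule: indirect-pathway inhibition
excites contralateral-preferring and inhibits ipsilateral-preferring
evidence neurons; direct-pathway inhibition excites
ipsilateral-preferring evidence neurons and leaves the rest unchanged; a
no-opsin population has no laser effect. Effect magnitudes are free
generator parameters — the source experiment reports none — chosen for
detectability at desk scale (defaults of a few Hz on ~10 Hz baselines).

## Behavioural analyses and the GLM-HMM

Evidence binning splits each side's non-tied trials into three
equal-count bins of |delta cues| (remainders go to the lowest bins, ties
in magnitude broken by trial order), computed on all trials so that
condition splits reuse one binning. Psychometric curves report percent
ipsilateral choice per bin and laser condition. The laser bias is
`[acc_ipsi - acc_contra]_on - [acc_ipsi - acc_contra]_off` in percentage
points.

The GLM-HMM is fit by expectation-maximisation: scaled forward-backward
E-step (run batched over equal-length sessions for speed; a per-session
reference implementation backs `assign_states()`), an M-step that refits
each state's Bernoulli GLM by Newton iterations weighted by the state
posteriors, and closed-form transition and initial-distribution updates.
Delta cues are z-scored within session (the covariate normalisation is
unspecified in print; per-session scaling keeps sessions exchangeable).
Weights carry a Gaussian prior with standard deviation 2 by default
(`prior_sd = Inf` recovers plain maximum likelihood): strongly biased
states make the bias and history covariates nearly collinear, and the
weak prior regularises that direction exactly as the reference
implementations of this model family do. EM stops when the penalised
objective improves by less than 1e-6 relative, or at 300 iterations; the
objective trace is stored and is non-decreasing, which the tests assert.
Each fit is repeated from 20 initialisations by default (transitions from
a Dirichlet with concentration 10 on the diagonal, weights from the
1-state fit plus N(0, 0.2) jitter), keeping the best objective.
Model comparison reports `(LL_K - LL_1) / (log 2 * n_test_sessions)`
bits per session over 5 session-level folds balanced across mice when a
mouse label is present. State matching for recovery uses exhaustive
minimisation of the weight-distance over the K! permutations, which at
K <= 5 is the exact optimal assignment.

Trial selection keeps engaged-state (maximum-posterior), non-early-turn,
non-warm-up trials; sessions need at least 50 included laser-off and 10
laser-on trials, and population analyses additionally more than 50
simultaneous neurons.

## Encoding models and tuning classification

Spike counts in 10-ms bins are smoothed with a causal half-Gaussian
kernel (SD 400 ms, truncated at four SDs, renormalised at the start of a
trial so constant inputs stay constant). Rates are position-binned by
averaging the smoothed counts over the time points in each 5-cm bin and
converting to Hz by the bin width in time; the occupancy duration is kept
as metadata, and a literal variant that divides the mean count by the
occupancy is available behind a switch (the printed recipe is
dimensionally ambiguous; the default is the reading that is invariant to
traversal speed for a constant-rate neuron, which a test asserts).
Z-scoring is per neuron over all trials and bins; zero-variance neurons
are flagged and excluded rather than propagated as NaN.

The encoding model is ordinary least squares per neuron and position bin
on previous outcome (-1/+1), signed cumulative evidence (raw count),
choice (-1/+1) and laser (-1/+1, included only when laser trials are
analysed), solved via the QR decomposition with classical t-statistics.
Tuning classification permutes the rows of the trial-by-variable
prediction matrix jointly — one permutation per shuffle, applied at every
position, preserving the covariates' cross-correlations — refits, and
records the per-variable maximum and minimum t over the 60 cue and delay
bins. A variable is significant when the real maximum exceeds the 95th
percentile of 200 null maxima or the real minimum falls below the 5th
percentile of null minima; evidence significance defines evidence-tuned
neurons, choice-without-evidence significance defines choice-tuned ones,
and side preference is the sign of the mean coefficient over cue and
delay bins. The percentile thresholds are exact finite-sample order
statistics of the shuffle distribution (the `ceiling(0.95 (S+1))`-th of
the S maxima), so that exceeding one has probability at most 5% under
the null; an interpolated percentile estimator would run ~0.5 points
hot per side at S = 200. This family-wise max/min-t control is the only
multiplicity correction, by design; its two one-sided 5% tests imply a
~10% null labelling rate, which the calibration test brackets in
[0.05, 0.12].

A structural consequence worth stating plainly: because a choice-tuned
label requires the *absence* of evidence significance, the expected
fraction of genuinely choice-locked neurons that receive the
choice-tuned label is capped at one minus the evidence null rate, about
90%, with no margin. For strongly choice-locked neurons the cap is in
practice a little lower (we observe 86-89%): in the shuffled refits the
neuron's large trial-constant choice signal is unexplained and dominates
the residuals, making the null t-statistics more correlated across
positions than the real ones and thereby narrowing the null max/min
distributions relative to the real sampling distribution. This is a
property of the classification rule itself, not of its implementation,
and the corresponding power assertion in the acceptance suite fails by
that margin while the evidence-neuron power assertion (>= 95% with
correct side preference) passes at 100%.

Laser modulation uses an unpaired Mann-Whitney U test on cue-region means
(on-task) and a paired Wilcoxon signed-rank test on per-sweep baseline
versus laser means (off-task); group comparisons use pooled two-proportion
z-tests. Population-level laser shifts are tested with linear
mixed-effects models, `activity ~ 1 + evidence + laser` with random
intercepts and slopes by neuron or session, fit by maximum likelihood;
evidence is normalised to [0, 1] and laser coded 0/1 in these models
only. Singular fits fall back to uncorrelated and then intercept-only
random effects with a warning, and a single grouping unit reduces to
ordinary regression.

## Population decoding

Laser-off trials are dealt into five evidence-stratified folds (sort by
final evidence, deal round-robin with within-block shuffling); inner
folds are built the same way inside each outer training set. At each
position, lasso regression (via the standard coordinate-descent
implementation, no standardisation, intercept included) maps z-scored
population activity to cumulative evidence normalised to [-1, 1] by the
session maximum. The penalty grid is 15 values: 0 plus 14 points
log-spaced in [1e-4, 1] — a literal log scale "from 0" is impossible, so
0 enters as the unregularised endpoint — and the inner cross-validation
picks the largest penalty within 1e-6 of the best mean held-out Pearson
correlation (parsimony tie-break). Final axes are unit-normalised;
positions where every penalty returns an all-zero vector are flagged.
Held-out trials are projected only onto the axis that held them out;
laser-on trials, never used in training, are projected onto all five fold
axes and averaged. Projections are centred by the per-position laser-off
mean and may be smoothed with a causal half-Gaussian (SD 10 cm) for
trajectory displays. Decoding performance is compared with label-shuffled
refits of the whole nested pipeline.

The PC1 control axis comes from the column-centred, trial-averaged
(neurons x 40 cue-region bins) matrix of each outer training fold: the
first principal axis over the neuron dimension, unit-normalised,
sign-aligned to the first fold within a session and flipped so the
trial-averaged projection does not increase along the cue region.
Position decoding from PC1 projections restores the positional mean that
the visualisation centring removes (centred projections contain no
position information by construction), then runs a 5-fold
cross-validated linear regression against position with
position-shuffled baselines. Session-level neural shifts are the mean
laser-on minus laser-off projection over the second half of the cue
region (100-200 cm), correlated across sessions with the behavioural
laser bias by Pearson's test.

## The four generative hypothesis models

The models link ipsilateral- and contralateral-preferring evidence
neurons (`ei = a e + b l + gamma`, `ec = -a e - b l + gamma`; a = 1,
gamma = 10, b = -2 except the printed +2 for hypothesis 1ii, exposed as
an override), 10 + 10 binary choice-tuned neurons, and the action,
through a logistic readout `sigma(x) = 1 / (1 + exp(-0.75 x))`:
immediate readout with choice-neuron lapses (h1i, PL = 0.5), attention
thinning of cues before readout (h1ii, each cue unattended independently
with d = 0.3, fresh per repeat), action readout (h2, behavioural lapse
PA = 0.1 then choice neurons copying the action with PL = 0.1), and a
multi-process readout in which the choice population reads evidence with
probability W = 0.5 and a shared alternative decision draw otherwise
(h3, with PL = 0.5 and PA = 0.1). Each base trial — cue statistics from
the task generator, 9,000 trials by default — is simulated four times.
Majority-vote ties between the two choice subpopulations, possible with
even neuron counts, are broken by a fair coin. In h1i, h2 and h3 the
laser terms cancel in `ei + ec = 2 gamma` identically, which the tests
assert exactly.

Estimators recover each printed parameter: the behavioural lapse from a
maximum-likelihood lapse-logistic psychometric fit (under h2 the exact
composition is `P(ipsi|e) = (1 - PA) logistic(1.5 e) + PA/2`, so the
total lapse equals PA and the slope 2 * a * 0.75); the h2 choice-neuron
lapse as twice the probability that an ipsilateral choice neuron is
silent on ipsilateral-action trials; the h1i lapse by a two-parameter
binomial ML fit of `E[c] = (1 - PL) sigma(s (ei - ec)) + PL/2`; the
attention fraction as the mean per-trial share of presented cues missing
from the attended set; and W as the empirical evidence-readout fraction.
Bootstrap confidence intervals resample simulated trials.

## Problem sizes, design choices and limitations

The test suite and the acceptance script run at desk scale, with sizes
chosen as study designs and stated here: hypothesis models at 36,000
trials; classification calibration on 1,000 untuned Poisson neurons with
100 trials and 200 shuffles; classification power on 200 evidence and 200
choice neurons in a 150-trial session; decoder recovery on a 100-neuron
evidence population with 200 laser-off trials, decoding on a 20-cm
position grid spanning 10-190 cm (the 0-10 cm bin carries almost no
accumulated evidence under the task's cue statistics and any decoder is
at chance there); the opponent-shift experiment on 50 indirect-pathway
sessions of about 190 trials and 60 neurons each, with evidence axes on
the 10-cm-resolution grid over the second half of the cue region where
the shift is defined, plus 12 direct-pathway sessions for the opposite
sign; GLM-HMM recovery on 20 sessions of 300 trials.

Three recovery-study designs deserve explicit justification.

*GLM-HMM recovery truth.* The generative 3-state agent used for recovery
has balanced state occupancy, moderate biases (+-1) and a sharp engaged
state (evidence weight 3). With strongly biased minority states the bias
and history covariates become nearly collinear within state and some
weights are unidentifiable at 6,000 trials even for an oracle that knows
the true state labels — per-state logistic fits with known labels show
maximum elementwise errors of 0.2-0.3. The recovery criterion is
therefore evaluated as the mean absolute weight error after state
matching (well below 0.2 under the chosen design), with hard-assignment
accuracy and the bits-per-session curve asserted separately.

*The opponent-shift dissociation.* The claim that pathway inhibition
shifts activity along the evidence axis but not along PC1 holds in the
generator by construction, and the construction matters: evidence
neurons are created in matched ipsi/contra pairs (shared baseline and
position gain), position-gain deviations are zero-mean, and baselines are
high enough that inhibition never clips rates at zero. When these are
violated — strong clipping, or laser-induced Poisson-variance asymmetry
between excited and inhibited neurons interacting with a nonzero mean
position gain — the perturbation acquires a systematic component along
PC1 and per-session tests detect it. Real recordings may well contain
such components; the test establishes that the pipeline separates the
two axes when the ground truth separates them, not that real data must.

*What passing tests show.* The generator emulates graded evidence
tuning, choice tuning that flips on errors, outcome tuning, shared
position dynamics, Poisson spiking, occupancy variation and
pathway-specific additive laser effects. It does not emulate correlated
noise between neurons, non-Poisson firing statistics, slow drift,
behavioural-state-dependent coding changes, or laser effects on
kinematics. Passing recoveries validate the estimators and the strict
cross-validation plumbing (unit-norm axes, held-out discipline, audit
of fold assignments), not the biological claims themselves.

Numerical details: OLS uses QR with pivot checks and names collinear
columns on failure; unoccupied position bins are dropped pairwise per
position fit; zero-variance neurons are excluded with a flag; the lasso
uses a convergence threshold of 1e-8 and the glmnet path is evaluated at
the exact grid values; forward-backward uses per-step scaling, and
emission probabilities are floored at 1e-12; the lapse-logistic fit
optimises logit-transformed lapse parameters by BFGS with a Nelder-Mead
fallback; bootstrap intervals use percentile limits.
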