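---
title: "Models and methods: contextual task-demand learning, reinstatement, and hippocampal coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

ctdlearn implements, end to end, the analysis of a blocked fMRI paradigm in
which spatial contexts probabilistically cue task demands: four rooms, two of
which contain 75% face-categorization trials and two 75% object trials,
visited over 6 runs of 8 blocks with 8 perceptual decisions per block. The
package covers (i) delta-rule learning models of the task-demand
contingency, (ii) model-based trial-level regressions of accuracy and RT,
(iii) event-level GLM estimation and multivariate noise normalization,
(iv) cross-run pattern-similarity analyses of task-demand reinstatement and
hippocampal pattern separation, and (v) block-level hippocampal–cortical
coupling regressions. Because raw neuroimaging data are large and external,
the package ships a synthetic-study generator that plants every effect the
analyses test, so the whole chain is verifiable from code alone.

## Learning models

Tasks are coded 0 (face) and 1 (object). A delta-rule learner maintains a
prediction $P_o(t) \in [0,1]$ of encountering an object task, updated after
each trial by

$$P_o(t+1) = P_o(t) + \alpha\,(T(t) - P_o(t)),$$

with learning rate $\alpha$ and neutral start $P_o(0) = 0.5$. The unsigned
prediction error attached to trial $t$ is $|T(t) - P_o(t)|$, the discrepancy
between the prediction entering the trial and the task actually required.
(A `lagged` flag reproduces the variant that attaches the previous step's
error to the current trial; the two differ only by a one-trial shift.)

Two learners are compared. The *temporal* model is a single learner that
runs over the whole trial sequence and ignores context changes. The
*contextual* model keeps one independent learner per room, all sharing one
learning rate; on each trial only the current room's learner predicts and
updates. With a single context the two are identical, which the test suite
asserts to $10^{-12}$.

The learning rates are free parameters fitted per subject by grid search
over the lattice 0.01–0.99 in steps of 0.01: for every pair
$(\alpha_t, \alpha_c)$, both prediction-error series are computed over the
full trial sequence and log-RT is regressed on {temporal PE, contextual PE,
task, constant} over the retained trials; the pair minimizing the residual
sum of squares wins, with ties broken deterministically toward the smallest
contextual then temporal rate. The implementation evaluates all 9,801
lattice cells through sufficient statistics (cross-products accumulated
once), so a full per-subject search takes well under a second.

**Identifiability.** With realistic trial-level RT noise (residual SD ≈ 0.2
log-units) and effect sizes in the empirically observed range (z-scored-PE
coefficients of about 0.03 for the temporal and 0.01 for the contextual
learner), the SSE surface over the lattice is shallow, and per-subject
learning-rate estimates are highly variable — particularly the contextual
rate, whose RT coefficient is small. Grid-search estimates should be treated
as descriptive; parameter-recovery simulations in the test suite show exact
recovery in the noise-free limit and errors shrinking with noise, but at
default noise the median absolute estimation error across 33 subjects is of
order 0.1–0.2, not 0.01. This is a property of the design's information
content, not of the optimizer: downstream analyses are robust to it because
prediction-error series at neighboring rates are highly correlated.

## Behavioral analyses

RT analyses exclude error trials, trials immediately following an error
(post-error slowing is a separate process), and trials with RT more than 2.5
SDs above the subject's median, with median and SD computed over correct,
non-post-error trials; the outlier rule is one-sided. Accuracy analyses use
all trials. Prediction errors are z-scored within subject (sample SD,
`n - 1` denominator) over the trials entering each fit. Per subject, a
logistic regression predicts accuracy and an OLS regression predicts
natural-log RT from {temporal PE, contextual PE, task, constant}; the
per-subject coefficients are then submitted to two-sided one-sample t-tests
at the group level, with Benjamini–Hochberg FDR across the family of
reported PE coefficients. Quintile summaries (equal-count bins, remainder to
the lowest bins) visualize the effects.

## Patterns, similarity, and contrasts

The event GLM models each event (context onset at the start of a block,
task-cue onset on each trial) as a stick function convolved with a canonical
double-gamma HRF sampled at TR = 2 s, one regressor per event, plus nuisance
columns. Event patterns are noise-normalized by the inverse symmetric square
root of the voxel residual covariance, shrunk toward its diagonal (default
shrinkage 0.1 — the covariance of a few hundred residual frames over ~100
voxels is ill-conditioned without it). In the synthetic pipeline the direct
event-pattern path is the default; the GLM path is exercised by dedicated
round-trip tests, which keeps the stages independently verifiable.

Pattern similarity is Fisher-transformed Pearson correlation, computed
across runs only, with $|r|$ clamped at $1 - 10^{-7}$ so degenerate inputs
stay finite. Run 1 is excluded from all reinstatement analyses (the
contingency is still being learned there); the context-level validation test
uses all 6 runs, since context identity needs no learning.

Context–trial pairs form a 3 × 2 factorial: context relation (same context /
same CTD / different CTD — i.e., same room, different room sharing the
dominant task, or different room with the other dominant task) by trial
congruency (required task matches the trial's own context's dominant task).
Congruency-dependent reinstatement is tested with the interaction contrast
(+1, −1, +1, −1, −2, +2) over the six cells; the double weight on the
Different-CTD cells compensates their doubled frequency and makes the
contrast exactly orthogonal to both main effects (asserted at construction).
Cell means are unweighted within subject; frequency imbalance is carried by
the weights. For Different-CTD pairs the congruency label follows the
trial's own context; the alternative referent (the context event's CTD)
flips that one factor level and coincides everywhere else.

Trial-level reinstatement is the mean Fisher z of a trial's Same-Context and
Same-CTD pairs, signed +1/−1 by the trial's congruency; Different-CTD pairs
are excluded so the score is not confounded by CTD mismatch. Block-level
reinstatement evaluates the same match/mismatch contrast at the block's
*context onset*: the congruency-signed mean over the pairs involving that
block's room-onset pattern. The room onset is where reinstatement is
hypothesized to occur, and only this reading yields a measure that can carry
block-specific signal — a trial's own pairs involve only other blocks'
context events, so averaging them per block would be structurally blind to
the block's own reinstatement strength.

Context–context similarity (all cross-run pairs of room-onset patterns, one
per block) supports two group tests: validation (Same Context > Different
CTD, all runs) and differentiation (Same CTD < Different CTD, runs 2–6),
plus a run-wise profile showing Same-CTD similarity declining after run 1.

## Brain–behavior and coupling analyses

Per subject, OLS of log-RT on trial-level reinstatement with temporal PE,
task and trial-level cortical univariate activity as covariates of no
interest (optionally adding contextual PE). The coupling regression predicts
block-wise cortical reinstatement from four hippocampal predictors —
block-level context–context similarity in the three conditions plus
univariate activity — with cortical univariate activity as covariate; all
block-level predictors are z-scored within subject so group-level
coefficients are comparable (the scale of raw Fisher-z block means is
arbitrary and subject-dependent). A congruency-signed version of the
hippocampal predictors, broadcast to the block's trials, is regressed on
trial-level log-RT. Finally, the across-subject correlation relates each
subject's mean hippocampal Same-CTD similarity to their behavioral
contextual-PE modulation of accuracy.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* the exact blocked design (2 blocks per context per run; the 75/25
  contingency realized exactly as 6/2 per block — realized counts, not
  Bernoulli draws, so structural tests can be exact; block timelines start
  at the 7.75-s room onset, with 0.25-s cues, 1.5-s stimuli and 4.25-s
  inter-trial intervals);
* behavior generated by the delta-rule forward model at true rates
  (α_t = 0.30, α_c = 0.10), with log-RT and logistic-accuracy coefficients
  at the empirically reported magnitudes (temporal 0.03 and contextual 0.01
  on log-RT; −0.19 contextual on the accuracy logit; objects ~60 ms slower;
  residual log-RT SD 0.20) and a congruency-signed reinstatement term;
* multi-voxel patterns built from run-specific context codes whose Gram
  matrix is met *exactly* (orthonormal mean-zero basis mixed through the
  symmetric square root of the target correlation matrix — a construction
  oracle tests sample correlations to $10^{-6}$ at zero noise), task codes
  expressed at trial onsets, and a reinstatement of the dominant-task code
  at context onset whose gain varies by block;
* hippocampal structure: stronger context codes (amplitude 3 vs. 1 in units
  of voxel-noise SD), same-context stability 0.45 across runs, per-run
  same-CTD targets (0.15 in run 1 collapsing to 0.01 afterwards) against a
  0.14 different-CTD baseline — so differentiation emerges over time — plus
  centered block-level fluctuations of the same-CTD code overlap and of
  univariate amplitude;
* the planted couplings: the cortical gain is
  `gain_mean + 1.0 * fluct + 0.6 * amplitude + noise`, the same block
  states drive the RT reinstatement term, and a per-subject offset on the
  hippocampal same-CTD correlation propagates into that subject's
  contextual-PE accuracy coefficient, planting the across-subject
  similarity–behavior correlation.

Cross-run correlation targets between runs r and r′ are the arithmetic mean
of the two runs' within-run values; within-run values are met exactly.
Positive semi-definiteness of the implied 24 × 24 Gram matrix is checked at
construction, and per-subject correlation offsets are clamped to the
PSD-safe range.

Planted effect sizes were fixed once, during generator design, so that
group-level effects land in the empirically observed range at desk-scale
ROI sizes (120 cortical / 80 hippocampal voxels): interaction contrast
d ≈ 1–2, validation d ≈ 2.5, differentiation d ≈ −0.6, coupling d ≈ 1,
trial-level RT modulation d ≈ −0.4, across-subject r ≈ −0.4. Absolute
similarity values are larger than in real data (real ROIs have thousands of
voxels, which shrinks correlations toward zero); it is the *effect-size
structure*, not the raw similarity scale, that the generator reproduces.

What the generator does **not** emulate: navigation periods (no analysis
uses them), scanner artifacts (motion, outlier volumes — only the exclusion
hook exists), autocorrelated voxel noise, spatial smoothness, and
session-level drifts. Passing tests therefore demonstrate that the
estimators recover the planted statistical structure, not that real data
meet these idealizations.

## Numerical choices and conventions

* z-scoring uses the sample SD (`n - 1`); constant inputs raise an error
  naming the predictor.
* Fisher clamp at $|r| = 1 - 10^{-7}$; natural log for RT; face = 0 /
  object = 1 task coding.
* Grid-search ties break toward the smallest contextual, then temporal rate.
* Covariance shrinkage default 0.1 toward the diagonal; a singular shrunk
  covariance raises an error advising more shrinkage.
* Group tests with zero variance across subjects (or n < 2) are flagged,
  never silently computed; flagged logistic fits (non-convergence,
  separation) are dropped from group inference with a warning.
* FDR families: the reported behavioral PE coefficients; the three
  similarity conditions in the coupling regression. Reported p-values are
  uncorrected, with q-values alongside.
* Determinism: every stochastic step takes a seed; per-subject streams are
  derived from the master seed by a fixed integer map, so identical
  configurations are byte-identical and subject-level results are
  independent of execution order.

## Problem sizes in the test suite

Simulation-heavy tests run at reduced ROI sizes (48 voxels per ROI) and use
33 synthetic subjects for power checks; null-calibration loops use 200
replicates with 12-subject groups, since the type-I rate of the group-level
one-sample t does not depend on group size. Structural and oracle tests run
at full design size. These sizes are the package's choices for routine
verification; all generators accept larger values.

## Limitations

Beyond the generator idealizations above: the learning-rate grid search is
weakly identified at realistic noise (see above); the coupling analyses are
correlational — block-level regressions cannot establish that hippocampal
signals precede cortical reinstatement; and the across-subject correlation
is estimated from 33 subjects, so its sampling error (SE ≈ 0.17) is large
relative to its magnitude. The package reports all of these quantities with
their uncertainty rather than point values alone.
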