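---
title: "A fixed-capacity race model of whole and partial report"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fixed-capacity race model of whole and partial report}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental paradigm and the model

In a mixed whole/partial report task an observer briefly views up to six
graphemes — letter targets and digit distractors — at six display locations,
followed by a pattern mask, and types every letter they recognized. Exposure
durations span 10–150 ms; displays contain 6 targets (6T0D), 4 targets with
2 distractors (4T2D) or 3 targets with 3 distractors (3T3D). Accuracy, not
reaction time, is the datum: each trial yields the *set* of targets reported.

`tvarace` models these report sets with the fixed-capacity independent race
formulation of the Theory of Visual Attention (TVA). Each displayed element
x accrues evidence at an exponential rate

\[ v_x = C \cdot \frac{u_x}{\sum_z u_z}, \qquad
   u_x = \begin{cases} w_x & \text{target} \\
                        \alpha\, w_x & \text{distractor} \\
                        0 & \text{empty location,} \end{cases} \]

where \(C\) is the total processing rate (graphemes/s), \(w\) are spatial
attentional weights over the six locations, and \(\alpha\) is the
distractor-to-target weight ratio (perfect filtering at 0, no filtering
at 1). Element finishing times are independent exponentials with rates
\(v_x\); an element is encoded into visual short-term memory (VSTM) iff it
finishes within the effective exposure **and** is among the first \(K\)
finishers, where the capacity \(K\) is drawn per trial from a free
distribution \(p_K\) on \(\{1,\dots,6\}\). The effective exposure is
\(\tau = \max(0, E - t_0)\) for physical exposure \(E\) and a perceptual
threshold \(t_0 \sim N(\mu_{t_0}, \sigma_{t_0})\) drawn per trial. A lapse
probability completes the model: with probability \(p_\text{lapse}\) a trial
yields no encodings at all. That is 15 free parameters:
2 (threshold) + 1 (C) + 1 (α) + 5 (p_K) + 5 (w) + 1 (lapse).

The observer reports exactly the encoded targets; encoded distractors occupy
capacity slots silently. Report scoring is position-free — a typed letter is
matched to the displayed target set by identity — because responses are
typed strings with no location information.

## Exact trial likelihoods

The probability that exactly the set \(S\) is encoded splits into two
capacity-independent pieces. If \(|S| < k\) the store never fills, so

\[ P_k(S) = \prod_{x \in S}\bigl(1 - e^{-v_x\tau}\bigr)
            \prod_{x \notin S} e^{-v_x\tau} . \]

If \(|S| = k\) the store fills: the elements of \(S\) must be the first
\(k\) finishers and the \(k\)-th finish must fall within \(\tau\). Writing
\(Q\) for the summed rate outside \(S\), the event is
\(\{\max_{x\in S} T_x \le \tau\} \cap \{\max_{x \in S} T_x < \min_{y\notin S} T_y\}\),
and inclusion–exclusion over subsets \(B \subseteq S\) gives the closed form

\[ P_k(S) = \sum_{\emptyset \ne B \subseteq S} (-1)^{|B|+1}
   \frac{V_B}{V_B + Q}\Bigl(1 - e^{-(V_B+Q)\tau}\Bigr),
   \qquad V_B = \sum_{x\in B} v_x . \]

This is algebraically identical to summing, over all \(k!\) orderings of
\(S\), the selection probabilities times the hypoexponential CDF of the
stage rates — the formulation `hypoexp_cdf()` implements and the test suite
uses as an independent oracle — but costs \(O(2^k)\) instead of
\(O(k!\,k)\). Zero-rate elements (e.g. distractors at \(\alpha = 0\)) cancel
exactly and are never encoded.

A trial's report probability marginalizes over the lapse, the threshold
draw, the capacity draw and all encodable distractor subsets:

\[ P(\text{report} = A) = p_\text{lapse}\,\mathbf{1}[A = \emptyset]
  + (1 - p_\text{lapse})\,
  \mathbb{E}_{t_0}\Bigl[\sum_k p_K(k) \sum_{D} P_k(A \cup D)\Bigr] . \]

The threshold integral is the likelihood's only numerical approximation: a
Gauss–Legendre rule over \(\mu_{t_0} \pm 4\sigma_{t_0}\) (default 24 nodes;
the truncated tail mass is about \(6\times 10^{-5}\) and the weights are
renormalized), with negative effective exposures collapsed to \(\tau = 0\).
Twelve nodes change a 540-trial log-likelihood by well under 0.1 and are
used in the cohort-scale runs; the difference is far below sampling noise.

## Fitting

`fit_observer()` minimizes the summed negative log per-trial likelihood on
an unconstrained scale: identity for \(\mu_{t_0}\), log for
\(\sigma_{t_0}\), \(C\) and \(\alpha\), softmax for \(w\) and \(p_K\), logit
for the lapse. Per-trial likelihoods are floored at \(10^{-12}\) (floored
trials are counted and reported) so isolated impossible reports cannot
destroy the objective. The search is a seeded multi-start Nelder–Mead
simplex — the likelihood is smooth but a hand-derived 15-parameter gradient
would be error-prone — with a data-driven first start (capacity initialized
from the mean score at the longest exposure) and random perturbations for
the remaining starts; the incumbent is then polished by re-firing the
simplex until the objective stops improving. Fits are deterministic given
the config seed, invariant to trial order, and additional restarts can only
improve the returned objective.

Two identifiability guards: when a condition contains no distractor trials
\(\alpha\) is fixed at 1 and dropped from the free parameters; reported
graphemes absent from the display (intrusions) are excluded from the
likelihood but logged, since the task's accuracy-feedback instructions make
them rare and the model does not generate them. The capacity summary
reported as \(K\) is the mean \(\sum_k k\,p_K(k)\) of the fitted
distribution; the support \(\{1,\dots,6\}\) was chosen to match the
5-free-parameter count with six display elements (a \(\{0,\dots,5\}\)
support would imply trials that can never yield a report even at long
exposures, which the data contradict).

## The synthetic cohort generator

`simulate_group()` emulates the study design: 9 synesthete/control pairs,
1080 trials per observer in 4 blocks of 270, crossing congruence (2) ×
target/distractor ratio (3) × exposure (6) with 30 trials per cell. Since
270 is not divisible by 36 cells, the full crossing is balanced over pairs
of blocks (15 per cell per 540 trials) while every single-factor margin is
exact within each block (135 per congruence, 90 per ratio, 45 per exposure)
via a seeded 7/8-copy assignment; the two-way exposure × congruence margin
(22.5 per block) cannot be balanced by any scheme. Target and distractor
locations are uniform per trial, and grapheme identities are drawn without
replacement from a per-pair set of 12 letters and 6 digits.

Base parameters are sampled uniformly from ranges typical of this paradigm:
\(C \in [60, 120]\)/s, \(\mu_{t_0} \in [5, 20]\) ms,
\(\sigma_{t_0} \in [2, 6]\) ms, \(E[K] \in [3, 4]\) (a two-point capacity
distribution with that mean), \(\alpha \in [0.4, 0.6]\), lapse
\(\in [0.01, 0.05]\), with mild log-normal jitter on the spatial weights.
The congruence effect defaults, \(\Delta C = +20\) graphemes/s and
\(\Delta K = +0.23\) items applied to the synesthetes' congruent condition,
match the size of the group effects the paradigm is designed to detect;
controls default to null effects. Each control "shadows" its synesthete
with a byte-identical schedule and stimulus assignment, so group contrasts
isolate observer-driven from stimulus-driven congruence effects.

What the generator does *not* emulate: response intrusions and typing
errors, the adaptive accuracy-feedback loop, serial-position or crowding
structure in the spatial weights, and any masking dynamics beyond the hard
\(\tau\) cutoff. Passing recovery tests therefore demonstrate that the
estimator inverts the model's own generative process at realistic trial
counts — not that real observers satisfy the model's independence
assumptions.

## Group analysis

The headline analysis is within-observer: one fit per observer × congruence
condition, then per group and parameter the mean (sd) per condition and a
paired t test on the congruence difference (df = 8 with nine pairs), plus a
matched-pairs difference-of-differences test comparing each synesthete's
congruence effect with their shadowed control's. The paired design makes
these contrasts the information-carrying computation; covariate-adjusted
repeated-measures ANOVA adds nothing bespoke and is deliberately out of
scope. Per-target accuracies pool exposures and ratios with equal cell
weighting, which the balanced design makes exact, and congruence deltas are
reported in percentage points. No multiple-testing correction is applied
across the four parameters, matching the analysis this mirrors.

## Screening

Grapheme-color consistency is scored as the sum of pairwise Euclidean
distances between the three color choices in unit-normalized RGB
(channels/255). The originating consistency criterion is cited rather than
printed in the source literature; this interpretation reproduces the
printed magnitudes (full-set averages around 0.5, inclusion threshold 1.0)
and is isolated behind `consistency_score()` so it can be swapped. A
grapheme is excluded as "gray" when its mean color has channel range < 10
and mean channel within ±30 of the 190,190,190 background — a quantitative
reading of "similar to the background", the only free choice here. Test-set
selection takes the 12 most consistent letters and 6 most consistent digits
(ties broken by character order), requires each selected grapheme to score
below 1, and errors otherwise, naming the shortfall. Incongruent stimulus
colors are the channel-wise inverse \(255 - c\); luminance calibration is
summarized by the Weber contrast \((I_s - I_b)/I_b\).

## Numerical choices and degenerate inputs

* Hypoexponential CDF: partial fractions for distinct rates; Erlang
  (`pgamma`) for equal rates; a matrix-exponential evaluation of the
  underlying transient Markov chain when any two stage rates are within
  \(10^{-7}\) relative, where partial fractions cancel catastrophically.
* A display whose occupied locations all carry zero attentional weight is a
  degenerate-display error rather than a silent NaN.
* All-empty-report data push the lapse/threshold to a boundary; the fit is
  returned with a `boundary` status rather than an error.
* Randomness is confined to explicit seeds: schedules, stimulus sets,
  parameter draws and responses all derive from the master seed of
  `group_spec()`, and fits from the seed in `fit_config()`; reruns are
  byte-identical.

## Problem sizes used in the checks

The shipped checks run the generative/likelihood comparison at \(10^6\)
simulated trials per display for twelve displays spanning all three ratios;
parameter recovery on nine 540-trial observer-conditions (median absolute
errors are well inside 10% for \(C\), 3 ms for \(t_0\), 0.25 items for
\(K\) and 0.15 for \(\alpha\)); and the effect-detection pipeline on five
master seeds of the full 18-observer cohort with \(\Delta C = +20\)/s. These
sizes were chosen to match the study design while keeping a full run on a
single core in the tens of minutes.

## Known limitations

Exposure enters only through the hard threshold cutoff — no
masking-strength or decay modeling; guessing is not modeled (the task
instructions discourage it), so datasets with substantial guessing would
bias the lapse and capacity estimates; standard errors and hierarchical
pooling across observers are out of scope; and with 540 trials per
condition the \(C\)–\(\sigma_{t_0}\)–\(p_K\) trade-off leaves \(C\)
estimates with sampling errors of order 10%, which is why group inference
relies on within-observer paired contrasts rather than absolute values.
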