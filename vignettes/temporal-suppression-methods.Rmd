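---
title: "Models and methods for two-target temporal-suppression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for two-target temporal-suppression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsupp)
```

This vignette documents the statistical machinery in `seqsupp`: what each
model assumes, which tunable parameters matter, what the synthetic observer
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The paradigm

Two Gabor targets (T1, T2) are shown in sequence, 250 ms apart, each at
high or low Michelson contrast. A cue after T2 selects which stimulus to
report. In the discrimination experiments the report is a binary tilt
judgment; in the estimation experiment it is a continuous orientation match
(0–179°). The scientific question is how the *non-target's* contrast
degrades the target's representation — the signature of divisive
normalization operating across time.

## Experiment designs and staircases

`design_spec()` encodes the factorial structure. The discrimination
experiments cross tilt (2) × axis (2) per stimulus with per-stimulus
contrast (2 × 2) and cue (2): 128 cells, replicated 3 times per session
(384 trials) over 3 sessions (1152 trials). The estimation experiment
crosses only contrast and cue (8 cells) with orientations drawn uniformly
per trial; the default 40 repetitions × 2 sessions give 640 trials. Cells
are balanced *within* each session and shuffled with a seeded generator;
whether balancing within session or only across the experiment was intended
is not determinable from the trial totals alone, and within-session
balancing is the stricter (and therefore safer) choice. The factor levels
themselves are fixed properties of the paradigm, so the smallest
expressible design is the 8-cell estimation crossing rather than a literal
one-trial plan.

Training uses 1-up/*N*-down staircases: tilt decreases after *N* consecutive
correct responses and increases after any error, so the asymptote solves
`p^N = 0.5` — 87.1% for the 5-down rule, 79.4% for the 3-down rule
(`staircase_convergence_accuracy()`). Step size, stop rule and burn-in are
not dictated by the asymptote and are configuration: defaults are a 0.4°
step from an 8° start, two interleaved staircases alternating
trial-by-trial, stop at 12 reversals each, first 2 reversals discarded.
Equal up/down steps keep the equilibrium at the nominal asymptote; the
reversal-mean estimator carries a small upward bias (about one point of
percent-correct in our simulations) that shrinks with step size. A run
whose reversal mean lands within one step of the 8° ceiling is flagged
non-converged, mirroring the training rule of repeating the staircase.

## The synthetic observer

`simulate_discrimination_responses()` is a standard equal-variance
signal-detection generator: the decision variable is Normal(±d′/2, 1) by
the cued target's true tilt, compared against a criterion. Defaults build
in the suppression pattern at the sizes used for power analysis: +0.9 d′
for target contrast, −0.4 d′ for non-target contrast, +0.8 d′ for T2 vs
T1, around a base of 1.7. Visibility is sampled independently of accuracy
("missed" rate 8.73%, the average exclusion rate of the discrimination
experiment that collected visibility).

`simulate_estimation_responses()` mirrors the mixture model generatively:
per trial the report is uniform (probability `guess_rate`), the non-target
plus von Mises noise (`swap_rate`), or the target plus von Mises noise and
an attractive shift toward the non-target. The shift is
`bias_gain × b(|Δ|)`, with `b` a derivative-of-Gaussian profile peaking at
25° separation — a descriptive choice: the data pattern being emulated
(attraction rising then falling with separation) does not identify a
mechanism, and both profile and gain are configuration, not claims.
Defaults mirror the qualitative condition pattern of the estimation
experiment: SD 8.5–18.1° across cells (lower-contrast targets and
high-contrast non-targets are noisier, T1 noisier than T2), swap rates
1–24% (highest for low-contrast T1 with a high-contrast non-target), 3%
guessing, bias only for T1, and a 14.91% missed rate. These were fixed
once, from the reported condition ordering, before any recovery testing.

What the generator does **not** emulate: reaction times, serial
dependencies between trials, criterion drift, lapses correlated with
visibility (available only via the `missed_guess` stress-test mode), and
any contrast-response function linking the condition parameters — they are
free inputs. Passing recovery tests therefore validates the *analysis
pipeline*, not any claim that real observers are this well-behaved.

## The orientation-report mixture model

Orientations live on a 180°-periodic circle, so all circular operations use
the doubled angle `θ = 2·error·π/180`. The report density is

\[
p(R_n) = \alpha\,\varphi(R_n - T_n) + \beta\,\varphi(R_n - N_n) +
\gamma\,\tfrac{1}{2\pi},\qquad \gamma = 1 - \alpha - \beta,
\]

with one shared circular SD σ for both von Mises components — the target
and swap responses are assumed to be equally precise, which is the
parameterization that keeps swaps interpretable as "the same percept,
wrong stimulus". The concentration κ is obtained from σ by inverting
`σ_rad = sqrt(−2 ln(I₁(κ)/I₀(κ)))` (series start plus Newton refinement,
accurate to ~1e−12; an independent bisection oracle backs this in the
tests). The uniform component is `1/(2π)` per radian of doubled angle,
equivalently `1/180` per orientation degree.

`fit_mixture()` maximizes the log-likelihood over
{α, β ≥ 0, α + β ≤ 1, σ ∈ [0.5°, 45°]} by Nelder-Mead on an unconstrained
scale (softmax logits for the weight simplex, logit-scaled log σ), with 10
random starts by default; the first start is moment-based (weights 0.75 /
0.10, σ from the central spread of target-relative errors). σ estimates at
a bound are reported via the `boundary` flag rather than masked, because a
σ near its upper bound makes the target and guess components nearly
non-identifiable. The fit floor is 20 trials per cell; cells below it are
excluded and logged rather than fitted.

### Stochastic trial tagging

`tag_trials()` repeats the fit (fresh random starts; the data stay fixed)
and, per iteration, normalizes the per-trial component scores
`α·φ(e_T), β·φ(e_N), γ/(2π)` to a categorical distribution and samples one
label with a single uniform draw. Per-trial probabilities are label
frequencies over iterations (1000 by default), and the condition SD is the
fitted σ averaged over iterations. Two open readings were resolved as
follows:

* **Weighting.** Scores are weighted by the mixture weights — i.e. they
  are posterior responsibilities. Normalizing raw densities instead
  ignores how common each response type is; the unweighted variant is kept
  behind `weighted = FALSE` for sensitivity analysis.
* **What varies across iterations.** Only the optimizer's initialization
  and the tagging draws; a bootstrap-refit mode exists (`bootstrap =
  TRUE`) but is off by default, since per-trial label frequencies are only
  interpretable when every iteration tags the same trials.
* **Restarts per iteration.** `tag_trials()` defaults to 2 restarts per
  iteration (one moment-based, one random) rather than the 10 used for a
  single standalone fit: across 1000 iterations the initialization
  randomness is itself a massive multi-start, and doubling compute per
  iteration changes the averaged σ by less than the Monte-Carlo noise of
  the tagging draws.

Calibration at the acceptance sizes (n = 500 trials, true swap rate 0.20)
recovers mean `p_swap` within ±0.04 over 50 replicates at 200 iterations.

## d′ analysis and the repeated-measures ANOVA

Clockwise tilts of the cued target are the signal class; axes are pooled
before tallying (tilt is defined relative to each trial's axis, so the
axis factor is counterbalance, not signal). Extreme rates use the
log-linear correction (+0.5 to each count, +1 to each total) by default;
`clamp` and `none` are available.

With three two-level within-participant factors every ANOVA effect is a
one-sample t-test on the per-participant ±1 contrast score: `F = t²` with
df (1, n−1), partial η² = `t²/(t² + n − 1)`, and main-effect EMMDs are the
mean of per-participant marginal-mean differences with a t-based 95% CI.
This is algebraically identical to the classical sums-of-squares
formulation — the tests verify agreement with `aov`'s
`Error(participant/(A*B*C))` decomposition to 6 significant figures —
and sphericity is moot because every factor has two levels.

## Bias toward the non-target

`signed_error_toward_nontarget()` re-signs the target-relative error so
positive means displacement along the shorter circular path toward the
non-target; trials with |Δ| = 0 have no direction and are excluded, and at
the ambiguous |Δ| = 90° boundary the +90 convention is kept. Curves bin
|Δ| into 15°-wide bins over (0, 90] (6 bins) — a binned analysis is chosen
over smoothing for testability, and the width is configurable; bins with
fewer than 5 trials per participant are masked. The likely-target
restriction is applied per tagging iteration (trials whose sampled label
is "target"), averaging the per-iteration curves; an argmax-of-averaged-p
mode is available. Without the restriction, swap trials (errors centred on
the non-target) masquerade as attraction, inflating the curve — a
directional property the tests verify on every replicate.

`cluster_permutation_test()` forms clusters from contiguous bins whose
one-sample |t| exceeds the two-tailed critical value at `cluster_alpha`
(0.05), scores them by mass Σ|t|, and compares against the maximum-mass
null from participant-wise sign flips (condition differences reduce to
sign flips of paired differences). Corrected p-values use the (count+1) /
(permutations+1) estimator. Sign flips leave squared values unchanged, so
permuted variances follow from permuted means and the fixed sums of
squares — the whole null distribution is three matrix operations.

## Problem sizes and run times

The validation suites use sizes chosen to make each property decisive on
one CPU in minutes: parameter recovery over the α ∈ {0.6, 0.75, 0.9} ×
β ∈ {0.02, 0.1, 0.25} × σ ∈ {8°, 12°, 16°} grid (the α = 0.9, β = 0.25
cell is not a valid mixture and is skipped) at n = 500 with 20 replicates
per cell; tagging calibration with 200 iterations × 50 replicates;
family-wise error of the cluster test over 200 replicate null experiments
(12 participants × 320 trials, 1000 permutations); and suppression power
over 200 replicate cohorts at the full 12 × 1152 discrimination size.

## Known limitations

* The mixture assumes one shared σ; differently-precise swap responses
  would be absorbed into β and γ.
* With σ near its upper bound, α and γ trade off; boundary fits are
  flagged but the ambiguity is inherent to the model.
* The EMMD confidence intervals are the per-participant-difference t
  intervals; ANOVA-modelled intervals could differ under other error
  structures.
* The bias analysis is within-trial only; serial dependence across trials
  is out of scope.
* `run_pipeline()` analyses synthetic cohorts end-to-end; mapping a real
  deposit's column layout onto the trial schema is left to the user via
  `read_trials()`'s documented CSV schema.
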