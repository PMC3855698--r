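---
title: "Models and methods: TD learning over shared confidence in dyadic decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: TD learning over shared confidence in dyadic decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadRL)
```

## The scientific setting

Two observers repeatedly judge which of two stimulus intervals contained a
low-contrast target and rate their confidence on a signed scale (−5…−1,
+1…+5; sign encodes the chosen interval). When their individual choices
conflict, one member — nominated at random — indicates a joint decision,
and trial feedback follows. `dyadRL` asks whether a minimal reinforcement
learner, observing nothing but the pair of confidence ratings, can learn a
policy for arbitrating such disagreements that yields a *collective
benefit*: joint sensitivity exceeding the better member's.

## The observer and psychometric model

Each decision maker is summarized by a cumulative-Gaussian psychometric
function of the contrast difference $\Delta c$ (second- minus
first-interval target contrast):

$$P(\text{choose 2nd}) = \Phi\!\left(\frac{\Delta c - b}{\sigma}\right),$$

fitted by probit regression (IRLS, deviance tolerance $10^{-8}$, ≤ 100
iterations, no lapse parameter). Sensitivity is the maximum slope at the
inflection, $s = 1/(\sigma\sqrt{2\pi})$, and collective benefit is
$\mathrm{CB} = s_\text{test}/s_\text{max}$ with $s_\text{max}$ the steeper
member's slope. Cohort statistics use $\log \mathrm{CB}$ to tame the ratio
distribution. The sign convention for $b$ (we use $\Phi((\Delta c - b)/\sigma)$)
does not affect slopes or CB.

**Degenerate fits.** A fit is flagged `converged = FALSE` when only one
response category is present, the IRLS deviance is numerically zero
(perfect separation), the contrast coefficient is non-positive, or IRLS
fails to converge. Separation makes the implied slope diverge; in model
comparisons it is capped at 10× the steeper member's slope — keeping CB
finite and biasing comparisons *against* spuriously steep model fits — and
the event is recorded in the result's `notes`.

## The learning model

The state is the pair of transformed confidences: magnitudes 4 and 5 are
collapsed to 4, reducing 10 × 10 = 100 raw combinations to 64 — at 256
trials per session the raw space is unlearnable, and empirically the two
highest confidence levels are used rarely. The action is the joint
decision; reward is +1/−1; values update by the single-step
temporal-difference rule

$$Q(s,a) \leftarrow Q(s,a) + \alpha\,(r - Q(s,a)), \qquad 0 \le \alpha \le 1,$$

from $Q \equiv 0$, so $|Q| \le 1$ always and, for a state with stationary
Bernoulli reward $p$, $Q$ tracks $2p - 1$. The policy is greedy with a
confidence tie-break: at equal Q values — including every first occurrence
of a state — the agent follows the member with the larger absolute
transformed confidence; at equal magnitudes with opposite signs it flips a
seeded coin. We apply the confidence tie-break at *every* Q tie, not only
the first occurrence: this is the minimal consistent completion and makes
$\alpha = 0$ reduce exactly to the confidence-following heuristic, a
property the test suite exploits as an oracle.

Two open design points are switches with defaults:

* **Agreement trials** (`update_on_agreement`, default `TRUE`): the agent
  executes the agreed interval and still updates Q, since states are
  defined on every trial and feedback is always delivered; restricting
  updates to disagreements is available for sensitivity analysis.
* **Similarity training signal** (`train_signal`, default `"forced"`): the
  per-member learners update on the executed empirical decision and its
  reward — the values a human would have formed from experienced
  outcomes — with an `"greedy"` alternative switch.

## Fitting procedures

Sessions are split into three contiguous, near-equal bins (86/85/85 at 256
trials; remainder to the earliest bins) and learning restarts from zero at
each bin start, a deliberately simple answer to non-stationary confidence
reporting; `n_bins = 1` treats the session as one run. The learning-rate
grid defaults to 101 points (step 0.01 — dense search is cheap at this
scale); objective ties go to the smallest α, preferring the slower-learning
model. Every (dyad, member, bin, α) cell derives a deterministic tie-break
seed from the master seed, so grid search is reproducible and
parallelisable, and later bins cannot perturb earlier ones.

* **Max Accuracy** treats the dyad as one unit: per bin, keep the α whose
  free-mode decisions maximize the within-bin slope (fitted on all bin
  trials by default; a disagreement-only switch exists), then collapse the
  winning decisions across bins and fit the overall model slope,
  $\mathrm{CB}_\text{model} = s_\text{model}/s_\text{max}$ and concordance
  $s_\text{model}/s_\text{dyad}$.
* **Max Similarity** treats the dyad as two parallel learners, each scored
  only on the disagreement trials where that member was nominated
  (similarity = fraction of greedy predictions matching the empirical
  decision). A member never nominated in a bin inherits the previous bin's
  winner (first bin: smallest grid α), logged. The aggregate decision on a
  disagreement trial is the nominated member's prediction.

## The synthetic world

The generator is the package's stand-in for an undeposited behavioural
dataset; its defaults state the emulated design once:

| Parameter | Default | Why |
|---|---|---|
| Session | 16 blocks × 16 trials = 256 | the emulated experimental design |
| Contrast magnitudes | 0.015, 0.035, 0.07, 0.15 | placeholders spanning ~58–98% correct at σ = 0.07, config-exposed |
| Observer | evidence $x \sim N(\Delta c - b, \sigma^2)$, choose 2nd iff $x > 0$ | its choice curve is *exactly* the probit model, making psychometric recovery an exact oracle |
| Confidence | magnitude = 1 + #(thresholds below $|x|$), thresholds $\sigma \cdot (0.5, 1, 1.5, 2)$ | cuts at fixed multiples of own noise ⇒ roughly calibrated confidence across unequal observers; high magnitudes rare, as observed empirically |
| Cohort σ | per member uniform on (0.05, 0.09) | realistically unequal members (slope ratios mostly < 1.8, where confidence sharing can still help) |
| Escalation | thresholds × $(1-e)^t$; presets e = 0 ("none"), ~0.001 ("V"), ~0.004 ("VV"), ±50% per-member jitter | geometric decay is the simplest mechanism that raises mean \|confidence\| over time while provably leaving choices — hence accuracy — untouched; V/VV mirror visual-only vs visual+verbal communication conditions |
| Disagreement resolution | nominated member keeps their own choice (pluggable) | how humans resolve disagreement is not modelled; the pipeline accepts any empirical decision column |

Per-member escalation jitter matters: when both members escalate at equal
rates the confidence *comparison* stays roughly calibrated, so asymmetric
rates are what degrade the learner's state information and produce the
negative escalation–benefit relationship at cohort level.

What a green test does **not** establish: the generator contains no verbal
communication channel (only its escalation signature), no perceptual
learning, no sequential dependencies, and no miscalibrated-confidence
styles beyond threshold decay; real dyads violate all of these.

## Numerical choices

* Probit solver: `stats::glm.fit`, epsilon $10^{-8}$, maxit 100; separation
  detected as deviance $< 10^{-6}$; anti-predictive fits (non-positive
  contrast coefficient) report slope 0 so they can never win a slope search.
* Objective comparisons use a $10^{-12}$ strict-improvement margin so
  floating-point noise cannot override the smallest-α tie rule.
* Seed chaining uses a Lehmer-multiplier hash with all intermediates below
  $2^{53}$ (exact in doubles), yielding valid 32-bit seeds.
* CSV writers emit doubles with 17 significant digits (whole numbers keep a
  decimal point), so trial tables and manifests round-trip bit-identically.
* Trial indices are 0-based in tables, 1-based in printed bin summaries.

## Known limitations

* **Learning-rate identifiability.** At 256 trials over 64 states, most
  states are visited once or twice, so greedy predictions are dominated by
  the α-independent first-occurrence rule: the similarity objective is
  piecewise constant with wide plateaus at 1.0, and the smallest-α tie
  rule returns plateau left edges. Our recovery experiment (single-bin
  fits, grid step 0.05 — fixed before measurement, since finer grids
  cannot be resolved by ~40 scored trials) recovers a planted α within one
  grid step in well under 60% of replicates at the study's session length,
  but in 10/10 replicates at 2048 trials: the limit is information in the
  design, not the estimator. The corresponding acceptance test is left
  failing rather than weakened.
* Within-bin slope fits use ~85 trials and are noisy; the capping rule
  above bounds the damage but bin-level winning α values should not be
  over-interpreted.
* The package deliberately omits bootstrap CIs on slopes, alternative link
  functions, eligibility traces, softmax/ε-greedy exploration, and formal
  model selection between the two objectives (their parameter counts
  differ).

## Minimal end-to-end run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, preset = "V", n_dyads = 14, out_dir = tempdir())
res <- reproduce_pipeline(cfg)
res$correlation
```
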