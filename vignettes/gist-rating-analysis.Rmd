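---
title: "Signal detection analysis of gist-of-abnormality rating experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection analysis of gist-of-abnormality rating experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistsdt)
```

## The problem and the experimental design

Radiologists can discriminate normal from abnormal mammograms at above-chance
levels after exposures of a few hundred milliseconds, even when the image
carries no localizable lesion — only a global statistical "gist" of
abnormality. `gistsdt` analyses rating-scale experiments that ask whether
naive observers can *learn* this signal from categorical feedback alone, and
provides a synthetic-experiment generator so every analysis stage can be
exercised and validated without human or image data.

The design the package targets is a multi-session study: a 200-trial
pre-test (80 normal mammograms and 30 each of four abnormal categories —
obvious lesions, subtle lesions, mammograms contralateral to a cancer, and
"priors" taken years before a visible cancer — so 60% of the test set is
abnormal), nine training phases of four 184-trial blocks (72 normal, 27
obvious, 27 subtle, 54 global-abnormal mammograms plus 4 attention trials
per block, 736 trials per phase), then a post-test and a delayed retention
test reusing the same 200 test stimuli. Every response is a rating on a
0–100 scale; during training the only feedback is whether the binarized
rating matched the ground truth. Contralateral and prior cases are pooled
into one *global* category throughout the analysis, since both carry only
the global signal.

## Signal detection metrics

Each trial's rating is binarized at a fixed threshold (default 50, matching
the feedback rule): ratings strictly above the threshold are "abnormal"
decisions. Hits are abnormal decisions on abnormal-truth trials, false
alarms abnormal decisions on normal-truth trials, and

$$d' = z(\mathrm{hit}) - z(\mathrm{fa}), \qquad
  c = -\tfrac{1}{2}\left(z(\mathrm{hit}) + z(\mathrm{fa})\right),$$

with $z$ the standard normal quantile. $d' = 0$ is chance; negative $c$ is a
liberal bias toward responding "abnormal".

Because a cell can yield a hit or false-alarm proportion of exactly 0 or 1
(200-trial test phases make this common for weak observers), the rates pass
through an extreme-proportion correction before the $z$ transform. The
default is the log-linear rule $\tilde p = (k + 0.5)/(n + 1)$ applied to
*every* cell, which keeps all estimates finite and comparable; a
`correction = "clamp"` switch replaces only exact 0/1 by $1/(2n)$ and
$1 - 1/(2n)$. One consequence worth knowing: with unequal class sizes the
log-linear rule leaves a small non-zero $d'$ artifact for fully degenerate
responders (all ratings identical), on the order of 0.1–0.4 depending on
the $n$ ratio; the tests document this rather than hide it.

Within a phase there is a single pool of normal trials, so the false-alarm
rate is computed once per phase and shared across the per-category summaries
(`phase_summaries()`). The per-phase, per-category output table is exactly
the per-cell summary a repeated-measures ANOVA would consume; the ANOVAs
themselves are out of scope here.

## Empirical and likelihood-ratio ROC curves

`empirical_roc()` sweeps the decision threshold over 1..99 (decision rule
"rating ≥ t", so the fixed-threshold metric at 50 coincides with the sweep
point t = 51), appends the (0,0) and (1,1) endpoints, and integrates by the
trapezoid rule. For integer ratings this AUC equals the Mann–Whitney rank
statistic $P(A > N) + \tfrac12 P(A = N)$, and the tests verify that
equivalence exactly against a brute-force pair count.

Raw rating experiments can produce *bimodal* rating distributions (an
observer who expresses "confident abnormal" as either 0-avoidance or
100-seeking), and a monotone threshold sweep is blind to such structure.
`llroc()` therefore builds a proper ROC: each class's rating histogram on
the 0–100 lattice is smoothed with a Gaussian kernel of width 10 —
interpreted as the kernel's standard deviation in rating units, with a
`width_type = "fwhm"` alternative — using a column-normalised kernel matrix
(so mass that would fall outside the lattice is renormalised back onto it),
floored at $\varepsilon = 10^{-6}$ and renormalised; the lattice is then
visited in order of decreasing log-likelihood ratio
$\log(p_A/p_N)$, accumulating class masses. Ordering by the likelihood ratio
of the same densities that supply the masses makes the curve concave by
construction, and on bimodal data its AUC dominates the empirical sweep.

`chance_test()` asks whether an observed LR-ROC AUC beats chance: it pools
both classes' ratings, draws 100 bootstrap samples (resampling with
replacement at the original class sizes, labels carrying no information),
recomputes the LR-ROC AUC for each, and flags the observation as above
chance when it strictly exceeds the nearest-rank 95th percentile of the
null. The paper-facing default is this label-shuffling chance model; a
`null = "within_class"` option gives the variability bootstrap instead,
which is *not* a chance null. Under a true null the flag fires at roughly
the complementary rate (≈ 5–6% — slightly above 1 in 20 because the
observed value competes with 100 exchangeable null draws), which the
acceptance suite verifies over 500 seeds.

## Learner classification and its simulation null

For each participant the nine training-phase $d'$ values (abnormal
categories pooled against the phase's normal trials) are correlated with the
phase index 1..9; a strictly positive Pearson coefficient labels a
*learner*, zero or negative a *non-learner*. A zero-variance trajectory has
an undefined coefficient; it is recorded as 0 and classified non-learner,
consistent with the strict "above 0" definition of a learner.

Splitting on the sign of a noisy correlation could in principle manufacture
a spurious "learning" effect, so `null_simulation()` reproduces the
control analysis: 1000 runs of 15 simulated participants whose every rating
is an independent uniform integer on 0–100 complete a 200-trial pre-test,
nine 720-trial training phases, and a 200-trial post-test; each run is split
with the same correlation rule, and the post-minus-pre $d'$ change is
averaged within each subgroup. Because the split uses training-phase noise
that is independent of the test phases, both subgroup means converge to 0
(the package obtains means within ±0.005 with 95% CI half-widths of about
0.006 over runs, computed as mean ± 1.96 SD/√runs). Attention trials and
the staircase are omitted from the null — neither can affect uniform random
ratings; the full-schedule generator is available when one wants to verify
that equivalence directly.

`phase_deltas()` reports the simple per-participant post-minus-pre and
retention-minus-pre differences in $d'$ and criterion per category group
with group means and 95% CIs, and `score_agreement()` computes the
tie-aware Spearman rank correlation (two-sided p) between per-stimulus mean
human ratings and model-produced abnormality scores rescaled to 0–100, for
comparing human observers with a deep-network classifier's malignancy
probabilities.

## The synthetic experiment generator

The generator emulates the full experimental machinery:

* **Pools** (`stimulus_pools()`): 5668 training stimuli
  (1558/1019/899/1868/324 across normal/obvious/subtle/contralateral/prior)
  and a disjoint 200-stimulus test set reused across the three test phases.
* **Blocks** (`sample_training_block()`): 72/27/27/54 category mix drawn
  without replacement within a block (repeats allowed across blocks, never
  within), the 54 global draws taken from the combined contralateral + prior
  pool so the split is proportional to pool sizes, and one attention trial
  placed uniformly at random in each quarter of the 184 slots.
* **Staircase** (`staircase_update()`): the maximum viewing time starts at
  2500 ms; after a block with total $d' > 0.2$ it drops to 90% of that
  block's mean actual viewing time, after $d' < 0.05$ it rises to 105% of
  the current maximum, capped at 2500 ms; between those bounds it is left
  unchanged (the rule is silent there, and "no change" is the minimal
  reading). A 500 ms floor — the minimum exposure of the task — bounds it
  below. The staircase carries across training phases rather than resetting
  each session: a per-session reset would make the observed rapid decay of
  maximum viewing times to a few hundred milliseconds arithmetically
  impossible, since every session's first block would sit at 2500 ms. A
  `reset_staircase_each_phase` switch provides the other reading.
* **Observers**: `random_observer()` draws uniform integer ratings —
  matching the integer response device; a `continuous` switch exists in the
  null — and `sdt_observer()` is an equal-variance signal detection rater.
  On each trial it draws latent evidence $x \sim N(\mu, 1)$ with $\mu = 0$
  for normals and $\mu = d_\mathrm{eff}$ for abnormals, where
  $d_\mathrm{eff} = \max(0, d_0(\mathrm{cat}) + \Delta d(\mathrm{cat})
  \cdot \mathrm{phases})$, and maps it to a rating
  $\mathrm{round}(100\,\Phi((x - k)/\mathrm{spread}))$. The cutoff
  $k = c_0 + \Delta c \cdot \mathrm{phases} + \bar d_\mathrm{eff}/2$ places
  the criterion parameter in conventional SDT $c$ units (0 = unbiased),
  using the mean effective sensitivity across abnormal categories as the
  midpoint reference — exact when sensitivities are equal across categories,
  and approximate otherwise, which is why the parameter-recovery tests use
  equal-sensitivity observers when they assert exact recovery of $c$. At the
  retention test the learned gain is multiplied by
  $1 - \mathrm{retention\_decay}$. The rating map through $\Phi$ is an
  artifact construct (no generative human rater exists to copy); it was
  chosen because it makes the threshold-50 decision coincide with the latent
  cutoff and yields graded confidence. Rating times are lognormal
  (`meanlog = log(1500)`, `sdlog = 0.4` — a plausible 1–3 s self-paced
  response) and actual viewing times uniform between 500 ms and the current
  maximum, emulating an engaged spacebar-pressing observer.

The trial schema deliberately matches a fixed 14-column CSV header. It
carries no feedback-screen duration; the generator can add an optional
`feedback_time_ms` column (`emit_feedback_time = TRUE`) and
`timing_summaries()` uses it when present, returning an empty-flagged
summary otherwise.

### What the generator does and does not emulate

Passing tests on generated data show that the *analysis machinery* is
correct under a known generative model: counts, corrections, ROC
construction, the staircase arithmetic, the exclusion rules, and the
learner split all behave as specified. They cannot show that real human
raters follow an equal-variance Gaussian evidence model, that real rating
times are lognormal, or that real attention lapses are Bernoulli; nor does
the generator model mammographic texture, memory for repeated stimuli, or
the repetition statistics of the original stimulus sampling (the generator
reports its own repetition behaviour — within-block uniqueness — but does
not target published repetition counts, which are not reproducible from the
stated sampling scheme). Conclusions about real data rest on the analysis
path, not on the observer model.

## Numerical and design choices

* **Ties at the threshold**: a rating of exactly 50 is a "normal" decision,
  mirroring the feedback rule ("above 50" is correct for abnormal truth).
* **Attention misses**: an attention trial is missed when the rating falls
  on the wrong side of 50 given the instruction to rate beaches 0 and
  forests 100; each scheduled attention slot counts once toward the 144
  total (the in-session repetition of failed attention trials is a delivery
  detail, not a scored trial).
* **Exclusion rule 3** ("85% or more of trials rated 50") is applied
  inclusively, per session, over mammogram trials only — those are the
  rated experimental trials; attention and practice trials have their own
  response conventions.
* **Timing outliers** are removed in a single pass (mean and SD from all
  values of the participant-session, then one sweep); iterating the filter
  is a stricter reading with no textual support.
* **Bootstrap percentile**: nearest rank, no interpolation.
* **Seeds**: every stochastic entry point takes a `seed` argument and
  restores the caller's RNG state; the command layer expands one top-level
  seed into per-stage seeds recorded in the run manifest, so any two runs
  with the same configuration are byte-identical.
* **Problem sizes in the test suite**: the simulation null runs at its full
  size (1000 × 15); property checks use 10²–10⁵ trials per case and ≤ 20
  replicate seeds, sizes at which the asserted tolerances have comfortable
  statistical power.

## Known limitations

* The learner/non-learner split on *static* simulated observers (zero
  learning increment) is a fair coin by construction — their trajectory
  correlation is sign-symmetric — so a 9-learner/6-static cohort has an
  expected label-recovery ceiling of exactly (9 + 3)/15 = 80%, and any
  single cohort fluctuates around it. The recovery check on such cohorts is
  therefore an at-the-boundary test: learner-type observers are recovered
  essentially always, static ones at the 50% that the definition implies.
* Criterion recovery is exact only for observers with equal sensitivity
  across abnormal categories (see the cutoff construction above).
* The empirical-AUC/rank-statistic identity holds for integer ratings;
  ratings of exactly 0 or 100 sit outside the 1–99 sweep and are absorbed
  by the appended endpoints.
* No unequal-variance SDT fitting, binormal ROC models, partial AUCs, or
  cross-participant inferential statistics are provided.
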