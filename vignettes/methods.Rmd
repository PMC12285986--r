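---
title: "Models and methods behind vividmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vividmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vividmem)
```

## The scientific setting

Vividness of visual mental imagery is commonly measured with the VVIQ, a
16-item questionnaire scored 1–5 per item, giving totals between 16 (an
*aphantasic* profile, no voluntary imagery) and 80 (a *hyperphantasic*
profile, imagery "as vivid as normal vision"). An extreme-groups design
compares the k highest and k lowest scorers of a cohort on (a) an
object-location visual short-term memory (VSTM) task and (b) regional brain
volumes — hippocampus and its subfields, primary visual cortex (V1), the
fusiform gyrus, and motor/amygdala control regions consumed as tables.

`vividmem` implements that analysis end to end, together with a seeded
synthetic-cohort generator so that every stage can be exercised and
calibrated without any participant data.

## The object-location task and its generative model

The task shows 1 or 3 abstract shapes on a 1536 × 2048-pixel touch screen,
and after a 1 s or 4 s delay asks the participant to identify the studied
shape (out of two) and drag it to its original location: 4 conditions ×
30 trials over 3 blocks, 120 trials. The generator draws item layouts
uniformly on the screen subject to a minimum pairwise separation (default
200 px; the separation used by the original task is not public, and the
classifier below is only well-posed when items do not overlap), and then
draws the placement response from a three-component mixture:

* **target**: target location + isotropic Gaussian noise (sd `sigma_px`);
* **misbinding**: a uniformly chosen non-target + the same Gaussian — the
  participant remembered locations but bound them to the wrong shape;
* **guessing**: a uniform point on the screen — no location information.

Gaussian displacements that leave the screen are redrawn rather than
clipped, so no probability mass accumulates on the edges. Identification
correctness is Bernoulli and response times are positive-truncated
Gaussian. Coordinates are continuous, origin top-left.

Default mixture weights were chosen once as study-like values (3-item
conditions: misbinding 0.18–0.22, guessing 0.14–0.16, precision 85–95 px;
1-item conditions: no misbinding, guessing 0.08–0.12, precision 55–65 px),
with the longer delay degrading precision and identification. VVIQ totals
are rounded truncated Gaussians matching the whole-sample mean 62.23
(SD 12.53); one subject is planted at the scale minimum and one at the
maximum. Item-level VVIQ generation is out of scope.

## The resampling classifier

Scoring inverts the mixture with the published resampling rule rather than
a likelihood fit. For each identified-correct trial the distances between
the response and (i) the target, (ii) the closest own non-target (3-item
trials only), and (iii) one non-target drawn from the same subject's other
trials are compared; the smallest determines the class (target /
misbinding / guessing). The draw is repeated 5000 times by default and the
class tallies become per-trial probabilities. Two implementation decisions
are worth making explicit:

* **Pool definition.** The pool is all non-targets from the *same
  subject's* other trials, excluding the current trial. Within-subject
  pooling avoids leaking another participant's geometry into the
  comparison; pooling across subjects would also be defensible, but only
  the within-subject variant is implemented.
* **Exact mode.** `n_resamples = "exact"` enumerates the whole pool once
  instead of sampling. Because each resample draws pool points uniformly
  with replacement, the enumeration *is* the sampling estimator's
  expectation, deterministically. It is both the fast path for pipelines
  and the oracle the sampling mode is tested against.
* **1-item trials** have no non-target, so term (ii) is dropped and
  misbinding is identically zero — consistent with misbinding scores
  existing only for the two 3-item conditions. Distance ties (probability
  zero for continuous coordinates) resolve to target, then own non-target.

### What the classifier can and cannot recover

A point worth understanding before trusting round-trip numbers: for a
*uniform guess* response, the target, the two own non-targets and the drawn
pool point are all (approximately) independent uniform points, so the
nearest of the four is the pool point with probability only ~¼, an own
non-target with probability ~½, and the target with probability ~¼. A pure
guessing trial is therefore *expected* to classify as roughly
(¼ target, ½ misbinding, ¼ guessing). Mean classified probabilities
consequently recover planted mixture weights only when the guessing weight
is small and `sigma_px` is small relative to the item separation; at the
generator's defaults (guessing 0.14–0.16) the classified misbinding rate
sits visibly above the generative weight. The round-trip recovery test
plants a low-guessing, well-separated regime (weights 0.75/0.22/0.03,
sigma 40 px, separation 400 px), which is the regime in which the
recovery claim is meaningful; this property holds for any implementation
of the published rule, not just this one.

## Scoring summaries and the exclusion rule

Identification accuracy is counted over all trials of a condition; the
localisation error (Euclidean distance response→target, px), response time
and classified probabilities are averaged only over identified-correct
trials. A condition with zero identified-correct trials yields missing
summaries and an `all_excluded` flag — never zeros.

## Extreme groups and boundary ties

`select_extreme_groups()` takes the bottom-k and top-k scorers. With the
default `expand` policy every subject tied at a boundary value joins the
group (so three subjects tied at the old-age boundary make an 11-member
group for k = 10); the `strict` policy keeps exactly k with a seeded,
reported draw among ties. The gap between groups (21 VVIQ points, 14 years
in the motivating design) is computed and reported as a design diagnostic.
Assignment depends only on score values, never on row order.

## Split-plot mixed ANOVA with Type III sums of squares

`mixed_anova()` implements the classical univariate split-plot
decomposition. Each subject's within-cell response vector is projected onto
orthonormal contrasts: the constant direction carries the between-subject
stratum; each within-effect stratum S is spanned by Kronecker products of
orthonormal factor contrasts. Within each stratum the effects (S itself and
its interactions with the between factors) are tested by full-versus-
reduced model comparison on sum-to-zero-coded between designs — which is
exactly Type III, so unbalanced between groups (6:4 sex splits, 10:11 tie-
expanded groups) are handled; with balance it coincides with Type I. The
error term of stratum S is the subject × S residual; partial eta squared is
SS_effect / (SS_effect + SS_error-of-its-stratum).

* **Covariate.** A between-subject covariate (the head-size scaling factor)
  is centred and entered in the between stratum only — it is constant
  within subject and cannot explain within-subject variation.
* **Sphericity.** Degrees of freedom are reported uncorrected by default
  (matching how such tables are conventionally printed); a
  Greenhouse–Geisser epsilon per within stratum is available behind
  `sphericity = "greenhouse-geisser"`, which adjusts the p-value while
  leaving the printed df untouched.
* **Degenerate inputs.** Missing within cells, between factors varying
  within subject, missing responses and rank-deficient designs are hard
  errors with the offending subject or term named; nothing is imputed.

The engine is validated three ways: exact agreement with `stats::aov` on
balanced split-plots, exact agreement with `car::Anova` (Type III) on the
between stratum of unbalanced covariate designs, and a hand-computed 2 × 2
split-plot; its group-effect type-I error is calibrated against 2000 null
simulations (a problem size chosen to keep the full suite comfortably
under typical CI budgets while giving a ±0.013 binomial band).

## Single-case Bayesian inference

Comparing one individual (the aphant or hphant) with a control sample uses
the standard noninformative-prior construction for a normal population:
per iteration, variance ψ = (n−1)s²/χ²₍n−1₎, mean μ ~ N(x̄, ψ/n), effect
size z = (x_case − μ)/√ψ, and the tail probability Φ(z). The point
estimate is the median z (robust to tail draws; the mean is also
reported), the 95% credible interval its 2.5/97.5 percentiles, and
`p_below` the mean of Φ(z) — the estimated proportion of controls falling
below the case. The two-sided p is 2·min(p_below, 1 − p_below); sidedness
is a reporting choice and is stated in the output. The no-covariate
variant is implemented. The closed-form counterpart,
t = (x_case − x̄)/(s·√((n+1)/n)) on n−1 df, is provided as
`crawford_howell_t()`; the Bayesian p converges to it as iterations grow,
which the tests assert at ±0.005 with 2 × 10⁵ iterations, and the null
distribution of the Bayesian p is checked for uniformity.

## Composite tests

* **Fisher's method**: χ² = −2Σln p on 2k df. It is monotone in each input;
  p = 0 is rejected rather than silently producing an infinite statistic.
  Note that combining (0.012, 0.003, 0.048) gives χ²₆ = 26.54,
  p ≈ 1.8 × 10⁻⁴; reports quoting a smaller combined value for these
  inputs are not reproducible under the standard method, and this package
  reports the standard value.
* **Ordering test**: a region matches when its five category values
  (hphant, High-group mean, sample mean, Low-group mean, aphant) stand in
  strictly descending order — a 1/5! = 1/120 event under exchangeability.
  Strict inequality is required (ties are non-matches, and are logged).
  The tail probability of k matches among n regions is an upper-tail
  binomial, computed through `pbinom`'s log-space machinery because naive
  summation underflows at these scales (the 30-of-57 tail is ~10⁻⁴⁶).
* **Sign consistency**: the sign-test tail, `binomial_at_least(n, k, ½)`.
* **2 × 2 χ²** with and without the Yates correction (subtract 0.5 from
  each |O − E|, floored at 0; the corrected statistic never exceeds the
  uncorrected one).
* **Percent differences** require an explicit denominator convention
  (reference / other / midpoint) because group-mean percentages are
  ambiguous without one; the convention travels with the value. The
  default is the reference (first) argument.

## The pipeline and the synthetic study

`run_full_analysis()` chains simulate (or load) → classify → summarise →
select groups → ANOVAs → per-region Welch t-tests → single-case tests →
composite tests, with one explicit derived seed per stochastic stage, and
returns a report bundle that `write_report_bundle()` serialises to CSV +
JSON. Design choices mirroring the motivating analysis: Sets A, B and D
get four-way mixed ANOVAs (VVIQ group × sex between; region × side
within), Set C (amygdala, one region) a three-way without the region
factor; Set A's ANOVA uses its three fully left/right/bilateral regions
(the whole-hippocampus columns, which have no bilateral value, enter the
per-region tests only), and Set D uses left/right sides; per-region tests
default to two-tailed Welch t with the tails logged; "significant" for the
active-versus-control 2 × 2 means p < 0.05 uncorrected, and no
multiple-testing correction is applied across region tests — by design,
the point of the 2 × 2 is precisely the *count* of uncorrected
significances in active versus control sets.

The synthetic volume table plants a multiplicative VVIQ-group effect
(default 1.10) in imagery-implicated Sets A and B only, a male > female
nuisance multiplier (1.05) in all sets, and aphant (0.80) / hphant (1.20)
case multipliers in Sets A/B; bilateral volumes are exactly left + right.
Region baselines are realistic volumes (subfield scale: fimbria ~60 mm³,
CA1 ~640 mm³; structure scale: hippocampus ~3.8 cm³, amygdala ~1.3 cm³)
with 10% between-subject coefficients of variation.

## What passing tests do and do not show

The generator produces clean, stationary mixtures: no learning or fatigue
across blocks, no spatial response biases (real guesses are not uniform —
centre bias is typical), no correlation between VSTM performance and VVIQ
unless planted via the subject-dependent parameter hook, independent noise
across regions rather than the strong inter-regional correlations of real
morphometry, and Gaussian volumes rather than heavy-tailed ones. Passing
the suite therefore certifies the *statistical machinery* — calibration,
oracle agreement, determinism — not the biological claims; applying the
pipeline to real tables is exactly the intended use of the loaders.

## Worked example

```{r, eval = FALSE}
bundle <- run_full_analysis(analysis_config(seed = 1))
print(bundle)
write_report_bundle(bundle, "report")
```
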