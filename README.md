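# vividmem

Statistical toolkit for extreme-groups studies relating vividness of
visual mental imagery (VVIQ, totals 16–80) to object-location visual
short-term memory (VSTM) and regional brain volumes. It is written for
researchers who want to re-run, audit or power such an analysis: every
stage — trial scoring, group design, ANOVAs, single-case inference,
composite tests — is an exported, seeded, unit-tested function, and a
synthetic-cohort generator reproduces the statistical structure of the
study so the whole pipeline runs without any participant data.

## What it computes

**Trial classification.** On each identified-correct trial of the
"What was where?" task, the distances between the placement response and
(i) the target, (ii) the closest own non-target, and (iii) a non-target
drawn from another of the subject's trials are compared; the smallest
determines target / misbinding / guessing. Repeating the draw 5000 times
(or enumerating the pool exactly) yields per-trial probabilities
p_target + p_misbind + p_guess = 1.

**Split-plot mixed ANOVA.** For a between factor B and within factor(s) W,
between effects are tested against the subjects-within-groups error and
each within stratum S against its subject × S residual, with Type III sums
of squares from sum-to-zero coding and full-vs-reduced model comparison,
an optional between-subject covariate (head-size scaling factor), and
partial eta squared η²ₚ = SS_effect / (SS_effect + SS_error).

**Single-case inference.** A case x against controls (x̄, s, n):
ψ = (n−1)s²/χ²₍n−1₎, μ ~ N(x̄, ψ/n), z = (x − μ)/√ψ per Monte-Carlo
iteration; median z, 95% credible interval, and p_below = E[Φ(z)], with
the closed-form oracle t = (x − x̄)/(s√((n+1)/n)) on n−1 df.

**Composite tests.** Fisher's χ² = −2Σln p on 2k df; the strict
five-category ordering test (per-region probability 1/5! = 1/120) with
log-space binomial tails; the sign-consistency (sign-test) tail; 2×2 χ²
with/without Yates correction; percent differences under an explicit
denominator convention.

## Worked example

```r
library(vividmem)
bundle <- run_full_analysis(analysis_config(seed = 1))
print(bundle)
#> Full analysis report
#>   subjects: 53 (high 10 / low 11, gap 19 VVIQ points)
#>   VSTM group p (error/guess/misbind): 0.8184 / 0.4302 / 0.2525
#>   Fisher combined p: 0.565
#>   active-vs-control chi2(1) = 10.486 (Yates p = 0.003886)
#>   sign consistency: 46/47 high > low, p = 3.41e-13
#>   ordering: 40/57 regions matched, p = 8.27e-70
```

Reading this: the simulated cohort of 53 contains a planted aphantasic
(VVIQ 16) and hyperphantasic (VVIQ 80); extreme-group selection took the
10 highest and — after boundary-tie expansion — 11 lowest scorers, 19
points apart. The generator plants **no** VSTM–VVIQ link by default, and
the three VSTM group p-values are accordingly null (their Fisher
combination p = 0.57). It **does** plant a 10% volume advantage for the
High-VVIQ group confined to imagery-implicated Sets A and B, and the
volume side of the report recovers exactly that: significant per-region
differences concentrate in the active sets (χ²(1) = 10.5), the High group
is larger in 46 of 47 active regions (sign-test p ≈ 3×10⁻¹³), and the
predicted hphant > High > sample > Low > aphant ordering holds in 40 of 57
regions. Individual tables live in `bundle$region_tests`,
`bundle$volume_anovas`, `bundle$single_case`, and
`write_report_bundle(bundle, "report")` writes them to CSV/JSON.

Component calls work standalone, on your own tables as well as synthetic
ones:

```r
chi2_2x2(matrix(c(24, 23, 0, 10), 2, 2))
#> chi-squared(1) = 8.8201, p = 0.0029793
t_from_summary(summary_stats(41.9, 11.99, 10), summary_stats(75.5, 2.72, 10))
#> t(18) = -8.6422, p = 8.023e-08 (2-tailed, pooled)
#> 95% CI [-41.7682, -25.4318], Cohen's d = -3.8649
single_case_test(25.2, summary_stats(66.7, 24.0, 52), n_iter = 1e5, seed = 1)
#> case-controls effect size -1.7184 [-2.1549, -1.2947]
#> estimated % of controls below case: 4.64%; two-sided p = 0.092815 (100000 iterations)
```

A thin command-line wrapper over the same functions is provided at
`inst/scripts/vividmem-analyze.R`.

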