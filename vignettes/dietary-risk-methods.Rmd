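---
title: "Methods: censored residue surveys and probabilistic dietary risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored residue surveys and probabilistic dietary risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbrisk)
```

## The problem

National pesticide-monitoring programmes analyse large numbers of food
samples for residues such as carbendazim, a systemic benzimidazole
fungicide. The resulting data are *left-censored*: concentrations below the
limit of detection (LOD) are reported only as non-detects (ND), and the
limit of quantification (LOQ, here 0.01 mg kg⁻¹) defines the threshold at
which a result is considered quantifiable. Public reports typically print
per-food summaries — sample size, detection frequency at the LOQ
(DF\(_{\ge 0.01}\)), the conditional median among quantifiable samples
(median\(_{\ge 0.01}\)), the maximum, and the over-limit ratio (OLR)
against the maximum residue limit (MRL) — but not the underlying records.

`carbrisk` provides three connected layers:

1. **Censored survey summaries** — DF, conditional medians, maxima, OLR,
   over arbitrary grouping keys, with the conventional ½·LOD substitution
   for non-detects.
2. **A calibrated synthetic survey generator** — residue records whose
   summaries reproduce a printed 66-food summary table, so pipelines built
   for undeposited survey data stay testable end to end.
3. **Probabilistic dietary exposure and risk** — Monte Carlo chronic and
   acute hazard quotients for five population groups over the four-category
   diet (vegetables, fruits, cereals, potatoes), plus the deterministic
   high-percentile acute bound used in international short-term intake
   estimates.

## Censored summaries

Non-detects are substituted at half the record's LOD
(`substitute_censored()`); substitution is a *summary-time* operation —
records store concentrations exactly as reported, so raw censoring is never
destroyed at parse time. Detection frequency counts detects with
concentration at or above the threshold; a censored record never counts as
a detection regardless of its LOD (records whose LOD exceeds the threshold
are flagged with a warning, since their status is genuinely ambiguous). The
conditional median uses the midpoint rule for even counts; the over-limit
ratio is strict (`> MRL`), an observation exactly at the limit being
compliant. Per-record LODs default to per-category values (0.001 mg kg⁻¹
everywhere except cereals at 0.01 mg kg⁻¹), all at or below the LOQ, so
substitution at ½·LOD can never cross the detection threshold.

The all-sample "median" column of printed tables is ambiguous when most
samples are censored; `summarize_residues()` offers both behaviours —
substituted-value medians (default) and `censored_as_nd`, which reports
`NA` whenever the central order statistic is censored.

## The synthetic generator

For each food the packaged specification (`default_specs()`) records the
printed sample size `n`, detection frequency `df`, conditional median `m`,
maximum `M`, LOD/LOQ, and MRL. Detect concentrations are modelled as a
lognormal truncated to `[LOQ, ∞)` — the standard residue-distribution
assumption in dietary exposure practice, and the two printed statistics
identify exactly its two parameters:

* the truncated median equals `m`;
* the truncated quantile at plug-in rank `(k − ½)/k`, with `k` the detect
  count, equals `M`. Treating the printed maximum as a plug-in quantile
  rather than an exact sample maximum keeps generation deterministic
  instead of rejection-based.

`calibrate_lognormal()` solves this nested monotone system with `uniroot()`
to a relative tolerance of 10⁻⁶, eliminating μ via the median constraint.
Numerically, truncated quantiles are evaluated in upper-tail form
(`q = Q(s·(1−p))` with `s` the survival mass above the LOQ), which stays
stable under deep truncation where lower-tail CDF values round to 1.

**Sampling design.** Each food draws its records from a deterministic child
stream of the root seed (`child_seed()`), so subsetting or reordering specs
never changes another food's draws. The detect count is the exact
expectation `round(n·df)` placed at randomly permuted positions, and detect
concentrations are generated through shuffled stratified (Latin-hypercube)
uniforms. Marginally each record still follows the calibrated distribution,
but a single generated survey reproduces the printed detection frequency
and conditional median essentially exactly — the appropriate design for a
*calibration* generator, whose purpose is to hand downstream stages data
with known truth, not to add avoidable Monte Carlo noise to that truth.

**Degenerate and infeasible targets.** When `M = m` the fit collapses to a
point mass (σ = 0). Printed conditional medians at or below the LOQ (for
example a table printing "0.00" for a food with a nonzero detection
frequency) are floored at 1.01·LOQ and flagged `median_floored`: a
truncated median exactly at the truncation bound has no finite solution. A
handful of foods print a conditional median close to the LOQ together with
a very large maximum (rice: median 0.02, maximum 5.2 at plug-in rank
0.954). Such pairs are *unattainable by any truncated lognormal*: with the
median pinned near the bound, the conditional tail tends to a
log-exponential limit whose high quantiles are capped near
\(LOQ\,(m/LOQ)^{\ln(1/(1-p))/\ln 2}\). `calibrate_lognormal()` raises a
calibration error for these; the generator falls back to keeping the median
exact with the log-scale dispersion capped (σ = 6, scaled down when the
median sits very close to the LOQ so the survival mass stays
representable). The generated maxima for these few foods therefore
undershoot the printed ones; detection frequencies and conditional medians
— the quantities the analysis layer consumes — are unaffected. The printed
maxima remain available in the specification table and are used directly
where a maximum is the scientifically relevant input (acute what-if
analyses below).

## Trend and association layer

`annual_series()` joins per-year survey summaries with national pesticide
usage (the sum over provinces present in the usage table — a documented
difference from official national statistics). `pesticide_dosage()` is
usage·1000/production in kg ton⁻¹. Spearman correlations use exact
permutation p-values for n ≤ 10 (small provincial comparisons need
exactness) and the t-approximation above; two-group comparisons use the
Mann-Whitney U test, three or more the Kruskal-Wallis test, both two-sided
and tie-corrected, dispatched purely on group count.

## The risk model

For population group \(g\) with mean daily intake \(q_f\) of category
\(f\), mean body weight \(w\), and coefficient of variation \(cv\)
(default 10%), each Monte Carlo iteration draws intake and body weight from
zero-truncated normals (rejection resampling; acceptance ≈ 1 at cv = 0.10)
and concentrations by empirical resampling of the survey's
½·LOD-substituted values (assumption-free, reproducing the survey's
quantiles; a fitted truncated-lognormal mixture model is available as
`concentration_model = "lognormal_fitted"`). Intake, body weight and
concentration are sampled independently; each (population, category,
parameter) triple has its own deterministic child seed, so adding a
category never perturbs another's draws.

The chronic hazard quotient per iteration combines the four diet
categories:

\[
CR_i \;=\; \frac{\sum_f c_{f,i}\, q_{f,i}}{w_i \cdot ADI},
\]

and the acute hazard quotient for a single category is
\(AR_i = c_i q_i / (w_i \cdot ARfD)\). Reference doses default to
ADI = ARfD = 0.02 mg kg⁻¹ day⁻¹, the conservative derivation from a
developmental NOAEL of 10 mg kg⁻¹ day⁻¹ with a safety factor of 500
(`reference_dose_from_noael()`). Distributions report percentiles at ranks
50, 97.5, 99.9984 and 100 (linear interpolation between closest ranks —
the convention matters at the 97.5th rank on small concentration sets, so
it is fixed and documented), exceedance fractions at the reference levels
0.1 and 1, and per-category mean contributions
\(\overline{c_f q_f} / \sum_g \overline{c_g q_g}\).

**The deterministic acute upper bound.** Alongside the Monte Carlo
distribution, `acute_upper_bound()` computes the point estimate combining a
high residue concentration with the 97.5th percentile of intake and the
2.5th percentile of body weight (analytic truncated-normal quantiles):

\[
AR_{upper} = \frac{c \cdot q_{intake}(0.975)}{q_{bw}(0.025)\cdot ARfD}.
\]

Under independence this combination sits at the
\(1 - (1-0.975)(1-0.975)(0.025)\) = 99.99844th percentile rank of the joint
distribution (`combined_exceedance_percentile()`). Published accounts of
this rule sometimes quote "99.9998th"; the bracketed product itself
evaluates to 99.99844, and the formula is implemented as the algebra
dictates, with the discrepancy documented rather than reconciled.

## Consumption defaults

The packaged profiles (`default_consumption()`) follow the structure of the
Fifth China Total Diet Study: five population groups (children 2–7,
adolescent and adult males and females) by four diet categories, means with
a 10% coefficient of variation. Only four intake means are widely quoted
from that survey — vegetables 0.19 (children) and 0.44 (adult males)
kg day⁻¹, cereals 0.22 and 0.45 kg day⁻¹ — and these are used verbatim.
The remaining intakes and the body weights are synthetic TDS-style values,
chosen once so that intake per unit body weight declines from children
through adolescents to adults (the ordering such surveys consistently
show), and — for the children's body weight of 18.5 kg — so that the
deterministic acute upper bound for children consuming cereals at the
highest surveyed rice residue (5.2 mg kg⁻¹) reproduces the published
worked value of 4.6. Users with access to the full TDS tables should
supply them via `read_consumption()`; the defaults are documented
placeholders with the right structure, not survey data.

## What passing tests do and do not show

The synthetic survey reproduces printed *summaries* (counts, detection
frequencies, conditional medians, and — where attainable — maxima) under a
lognormal detect model with uniform province/year allocation. Real surveys
have features the generator deliberately omits: correlated province ×
year × food structure, values between LOD and LOQ, temporal trends within
a food (expressible via per-year spec rows but not baked into the packaged
table), and non-lognormal tails. Parameter-recovery tests therefore
validate the *pipeline* — that the summaries, trend statistics and risk
engine compute what they claim on data with known truth — not the
empirical claims of any particular survey. Likewise the packaged
consumption defaults make the risk outputs structurally realistic without
being survey estimates.

## Problem sizes and numerical choices

The test suite and the acceptance script generate the full 117,289-record
survey (sub-second) and run risk simulations at the conventional 10,000
iterations; property checks that need tighter Monte Carlo error use 10⁵
draws, and the joint-percentile simulation uses 10⁷ triples in chunks.
Root finding uses `stats::uniroot` at tolerance 10⁻¹²  with the defining
quantiles verified to 10⁻⁶ relative; the calibrator returns the first
(least-truncated) of the up to two σ roots the max-quantile constraint can
admit. All randomness descends from a single root seed through labelled
child streams; identical inputs and seed give byte-identical survey files
and risk tables.

## Known limitations

* No processing-factor tier beyond applying a scalar to concentrations
  before simulation; no cumulative multi-pesticide assessment; no animal
  products.
* The generator does not reproduce per-province × per-year joint
  distributions (not printed in summary tables), so spatial association
  analyses on synthetic data test sign and mechanics, not published
  provincial p-values.
* Principal-component source apportionment is out of scope: constructing
  its observation matrix from summary data is under-determined.
* OLR emerges from the calibrated tail rather than being a calibration
  target; for foods with unattainable maxima the synthetic OLR
  undershoots.
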