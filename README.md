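# carbrisk

Censored pesticide-residue surveys and probabilistic dietary risk in R.

`carbrisk` is for analysts working with food-safety monitoring data —
large residue surveys in which most samples are non-detects ("ND") below a
limit of detection (LOD) and results are judged against a limit of
quantification (LOQ) and legal maximum residue limits (MRLs). It was built
around decade-scale carbendazim monitoring of plant-based foods
(vegetables, fruits, mushrooms, cereals, tea) in China, but the machinery
is generic.

It provides:

* **Censored survey summaries** — detection frequency at a threshold
  (DF≥0.01), conditional medians among quantifiable samples
  (median≥0.01), maxima and over-limit ratios (OLR), over arbitrary
  grouping keys, with the standard ½·LOD substitution for non-detects.
* **A calibrated synthetic survey generator** — per-food residue records
  whose summaries reproduce a printed 66-food monitoring table (117,289
  samples), via a truncated-lognormal detect model calibrated to each
  food's conditional median and maximum. Raw records from such programmes
  are rarely deposited; the generator keeps every downstream stage
  testable against known truth.
* **Trend and association tools** — annual series joined with pesticide
  usage, provincial usage/dosage aggregates, Spearman rank correlation,
  Mann-Whitney and Kruskal-Wallis tests.
* **Probabilistic dietary risk** — Monte Carlo chronic and acute hazard
  quotients for five population groups over the four-category diet.

## The model in brief

Chronic risk per Monte Carlo iteration combines the four diet categories
(vegetables, fruits, cereals, potatoes):

```
CR_i = Σ_f  c_{f,i} · q_{f,i}  /  (w_i · ADI)
```

with concentrations `c` resampled from the survey (non-detects at ½·LOD),
intakes `q` and body weight `w` from zero-truncated normals (CV 10%), and
ADI the acceptable daily intake. Acute risk uses a single category and the
acute reference dose: `AR_i = c_i q_i / (w_i · ARfD)`. Both reference
doses default to 0.02 mg kg⁻¹ day⁻¹ (NOAEL 10 mg kg⁻¹ day⁻¹ ÷ safety
factor 500). The deterministic acute upper bound combines a high residue
with the 97.5th intake percentile and the 2.5th body-weight percentile —
jointly the 1 − (1−0.975)(1−0.975)(0.025) = 99.99844th percentile rank of
exposure.

## Worked example

```r
library(carbrisk)

specs  <- default_specs()                  # packaged 66-food summary table
survey <- generate_survey(specs, seed = 1) # 117,289 synthetic records

format_percent(detection_frequency(survey))
#> [1] "12.2%"

summarize_residues(survey, by = "food", mrl_table = default_mrl_table()) |>
  dplyr::filter(food %in% c("Spinach", "Peach", "Rice"))
#> # A tibble: 3 × 7
#>   food        n df_ge_threshold median_all median_above max_conc     olr
#>   <chr>   <int>           <dbl>      <dbl>        <dbl>    <dbl>   <dbl>
#> 1 Peach    2666          0.471      0.0005       0.0601   14.9   0.00375
#> 2 Rice      498          0.0221     0.005        0.0195    0.129 0
#> 3 Spinach  1864          0.0719     0.0005       0.111    79.0   0.0182
```

One row per food: sample size, the fraction of samples quantifiable at
0.01 mg kg⁻¹ (47.1% of peaches, 7.2% of spinach), the all-sample median
(dominated by substituted non-detects at ½·LOD = 0.0005 mg kg⁻¹), the
conditional median among quantifiable samples, the maximum, and the
fraction over the food's MRL (1.8% of spinach exceeds its 0.5 mg kg⁻¹
limit).

Risk for children aged 2–7 on the packaged consumption profiles:

```r
child <- default_consumption()$children_2_7
cfg   <- simulation_config(n_iter = 10000, seed = 1)

chronic_risk(child, survey, cfg)
#> <risk_distribution: chronic risk, combined, children_2_7; 10000 iterations>
#>   percentiles: p50=0.003863, p97.5=0.1559, p99.9984=17.49, p100=17.53
#>   frac > 0.1: 0.0430, frac > 1: 0.0021
#>   contributions: vegetables=0.416, fruits=0.391, cereals=0.191, potatoes=0.002

round(acute_upper_bound(5.2, child, "cereals", cfg), 1) # rice maximum residue
#> [1] 4.6
round(acute_upper_bound(2.0, child, "cereals", cfg), 1) # what-if at the rice MRL
#> [1] 1.8
```

The chronic distribution's median hazard quotient is ~0.004 — far below
the reference level of 1 — with 0.2% of iterations above 1 and 4.3% above
0.1. The acute upper bound says a child eating a 97.5th-percentile cereal
portion at the highest surveyed rice residue (5.2 mg kg⁻¹) exceeds the
acute reference dose 4.6-fold; capping that residue at the 2 mg kg⁻¹ MRL
still leaves a 1.8-fold exceedance.

A YAML-driven end-to-end pipeline (simulate → summarize → trend → risk,
with a JSON run manifest) is available as `run_pipeline()` and as a thin
command-line wrapper in `inst/scripts/carbrisk-pipeline.R`.

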