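# epiilca

Person-centered profiling of pandemic-related experiences measured with
the **Epidemic-Pandemic Impacts Inventory (EPII)**, a 92-item checklist of
adverse and positive experiences across five life domains (work, home
life, social activities/isolation, emotional/physical health and
infection, positive change).

The package is aimed at survey researchers who want to move beyond
cumulative adversity counts: instead of summing endorsed items, it
identifies latent *subgroups of respondents* with distinct patterns of
co-occurring experiences and asks how those subgroups differ on
sociodemographics and psychosocial screens.

## The model

The core is an exploratory **latent class analysis (LCA)** of dichotomous
indicators. With classes k = 1..K, mixing proportions π<sub>k</sub> and
conditional endorsement probabilities ρ<sub>jk</sub> = P(y<sub>j</sub> = 1 | class k),
the likelihood of a response vector y is

    P(y) = Σ_k π_k Π_j ρ_jk^{y_j} (1 − ρ_jk)^{1−y_j}

estimated by multi-start EM (compiled core, response-pattern
aggregation, boundary clamping, deterministic per-start seed streams).
Around the measurement model the package implements the full workflow:

* **Scoring** — EPII dichotomization ("Yes, Me"/"Yes, Person in Home" →
  1), per-domain cumulative counts, and total scores with screening
  cutoffs for the PSS, PHQ-9 (≥ 15), GAD-7 (≥ 15), PC-PTSD-5 (≥ 3) and
  the Duke-UNC social support scale, with within-respondent mean
  imputation of rare item opt-outs and Cronbach's alpha.
* **Indicator screening** — exclusion of items with base rate < 5%, then
  retention of items with a significantly positive Spearman correlation
  (midranks) with the perceived-stress total.
* **Class enumeration** — BIC, sample-size-adjusted BIC, CAIC, AWE,
  BIC-based Bayes factors and approximate correct-model probabilities,
  relative and univariate entropy, average-posterior diagnostics, and a
  parametric bootstrap likelihood-ratio test of K vs K−1.
* **Distal outcomes** — classification-error-corrected three-step
  comparison of classes on continuous (class-specific normal means and
  variances) and categorical outcomes, with an overall chi-square test
  and Bonferroni-adjusted pairwise tests (0.05/10 = 0.005 at K = 5).
* **Synthetic surveys** — `simulate_epii_survey()` generates full raw
  survey tables (4-level EPII coding, scale items, sociodemographics)
  from the class profiles, proportions, base rates and class-conditional
  screen probabilities published for the development sample (N = 652),
  so every stage is testable although the original respondent-level data
  are not shared.

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(epiilca)

dat <- simulate_epii_survey(800, seed = 2024)   # synthetic survey, truth retained
res <- run_epii_pipeline(data = dat, seed = 2024, k_max = 6, n_starts = 30)
res
#> EPII profiling pipeline run
#>   respondents: 800, indicators retained: 35
#>   selected model: 5 classes (entropy 0.879)
#>   distal outcomes compared: 20

tidy(res$enumeration)[, c("k", "loglik", "bic", "entropy", "cmp", "selected")]
#>       k  loglik    bic entropy      cmp selected
#> 1     1 -13489. 27212.  NA     0         FALSE
#> 2     2 -12603. 25681.  0.930  2.08e-143 FALSE
#> 3     3 -12216. 25147.  0.876  2.30e- 27 FALSE
#> 4     4 -12052. 25060.  0.856  2.05e-  8 FALSE
#> 5     5 -11914. 25024.  0.879  1.000e+ 0 TRUE
#> 6     6 -11878. 25194.  0.869  1.23e- 37 FALSE

glance(res$distal$phq9_ge15)
#>   statistic    df  p_value alpha_adjusted n_significant_pairs unstable
#> 1      140.     4 2.94e-29          0.005                   7 FALSE
```

The enumeration table shows the class-count search: the 5-class model
minimizes the BIC and takes essentially all of the correct-model
probability, and its entropy (0.879) indicates well-separated classes —
the structure the generator actually planted. The distal comparison
says the five classes differ strongly in their probability of screening
positive for depression (overall χ²(4) = 140, p < 10⁻²⁸), with 7 of the
10 class pairs significant at the Bonferroni-adjusted 0.005 level.

`autoplot(res$fit)` draws the conditional-probability profile of the
selected model; `autoplot(res$enumeration)` the information-criterion
curves. `run_epii_pipeline(..., out_dir = "report")` writes the
screening, fit-index, posterior-diagnostic, class-profile and
class-comparison tables as CSVs plus a JSON run record.

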