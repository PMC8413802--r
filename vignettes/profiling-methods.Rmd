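---
title: "Profiling pandemic-related experiences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling pandemic-related experiences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the statistical machinery behind `epiilca`: the
latent class model and its assumptions, the screening rules that choose
its indicators, the class-enumeration battery, the corrected three-step
comparison of classes on distal outcomes, and the synthetic survey
generator the package uses in place of the unshared respondent-level
data. It also records the numerical and design choices a maintainer
would want to know about.

## The measurement model

Respondent $i$ supplies a vector of dichotomous indicators
$y_{i1},\dots,y_{iJ}$, here endorsements of pandemic-related experiences
from the Epidemic-Pandemic Impacts Inventory (EPII). The latent class
model assumes a finite number of unobserved subgroups $k = 1,\dots,K$
with mixing proportions $\pi_k$ and class-specific endorsement
probabilities $\rho_{jk}$, and *local independence*: within a class,
items are independent Bernoulli draws, so

$$P(y_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J}
  \rho_{jk}^{y_{ij}} (1-\rho_{jk})^{1-y_{ij}}.$$

Local independence is the substantive assumption doing the work: all
co-occurrence among experiences is attributed to class membership. It is
also the assumption most likely to be violated in real surveys (e.g.
logically nested items such as the childcare series), which is one
reason enumeration diagnostics matter.

Maximization is by EM. The E-step computes posteriors
$\tau_{ik} \propto \pi_k \prod_j \rho_{jk}^{y_{ij}}(1-\rho_{jk})^{1-y_{ij}}$
(in log space with log-sum-exp); the M-step sets $\pi_k$ to the mean
posterior and $\rho_{jk}$ to the posterior-weighted item mean. The
likelihood is multimodal, so `lca_fit()` runs many independently seeded
random starts and reports how often the best log-likelihood was
replicated.

### Numerical choices

* **Starts.** Default 50 random starts: mixing weights from a flat
  simplex draw (normalized exponentials), $\rho$ uniform on
  $(0.1, 0.9)$. The published analysis does not disclose its start
  policy, so this is a declared default, not an inference. A solution
  whose best log-likelihood is not replicated (within $10^{-4}$) by at
  least 2 starts is treated as "no unique solution", which is also the
  enumeration stopping rule.
* **Convergence.** Absolute log-likelihood change below $10^{-6}$, at
  most 1000 iterations. Under weak separation EM creeps along a flat
  ridge; the bootstrap likelihood-ratio test therefore exposes `tol` so
  the same (possibly looser) stopping rule is applied consistently to
  observed and bootstrap statistics.
* **Boundary clamping.** $\rho$ is clamped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-5}$ so the
  log-likelihood stays finite when a class claims an item perfectly;
  clamp events are counted on the returned fit.
* **Pattern aggregation.** EM cost scales with the number of *distinct*
  response patterns, not respondents: duplicate rows are collapsed with
  weights before the compiled EM core runs.
* **Ties.** Modal assignment breaks exact posterior ties toward the
  lowest class index and flags them.
* **Label switching.** Mixture labels are arbitrary; `align_labels()`
  finds the permutation minimizing the total absolute difference between
  conditional-probability columns (exhaustive optimal assignment, cheap
  for $K \le 8$) and `permute_classes()` applies it coherently to
  weights, profiles, posteriors and assignments.
* **Seeding.** Every stochastic routine takes one master seed and
  derives per-start / per-replicate streams from it, so runs are
  bit-reproducible.

## Choosing the indicators

Two screens select the LCA indicators from the 92 EPII items:

1. **Base rate.** Items endorsed by fewer than 5% of respondents
   (strict `<`) are excluded — rare experiences cannot support stable
   class-specific probabilities.
2. **Stress linkage.** Surviving items must correlate significantly and
   *positively* (Spearman with midranks) with the Perceived Stress
   Scale total.

The one-sided default deserves a note: the source analysis reports that
retained items were "significantly positively correlated", and its item
table leaves a negative correlation of larger magnitude than some
starred positive ones unstarred — evidence that the criterion was
positive-only. `spearman_screen()` is configurable to two-sided.
P-values use the large-sample t approximation; a random-permutation
reference (`method = "permutation"`) is available and preferable below
roughly N = 30. No multiplicity correction is applied at this stage,
matching the source procedure.

## Class enumeration

`lca_enumerate()` fits $K = 1, \dots, K_{\max}$ (default 7) and
assembles, per model: the parameter count $d = KJ + (K-1)$, the
log-likelihood, and

* $\mathrm{BIC} = -2LL + d\ln N$,
* $\mathrm{SABIC} = -2LL + d\ln\!\big((N+2)/24\big)$,
* $\mathrm{CAIC} = -2LL + d(\ln N + 1)$ (Bozdogan),
* $\mathrm{AWE} = -2LL + 2d(\ln N + 1.5)$ (Banfield–Raftery),

plus BIC-based evidence weights: with $SIC = -\mathrm{BIC}/2$, the
adjacent-model Bayes factor $BF = \exp(SIC_K - SIC_{K+1})$ (also
returned on the log scale, since real BIC gaps overflow the natural
scale) and the approximate correct-model probability
$cmP_K \propto \exp(SIC_K)$ normalized over the candidate set. The
selected model is the BIC minimum, with $BF > 10$ against the next
model and the largest $cmP$ reported as corroboration. Classification
quality is summarized by relative entropy

$$E = 1 - \frac{\sum_{ik} -\tau_{ik}\ln\tau_{ik}}{N \ln K},$$

the assigned-class-by-class average posterior table, and per-item
*univariate entropy*: the same $E$ computed from single-item posteriors
$\tau^{(j)}_k(y) \propto \pi_k \rho_{jk}^{y}(1-\rho_{jk})^{1-y}$,
averaged over the model-implied distribution of the item. The exact
averaging convention behind the original software's univariate entropy
is undocumented; the definition above is this package's declared
choice. It reproduces the published ranking closely (rank correlation
≈ 0.998 on the published 5-class parameters; the tests assert that the
childcare/teaching items land in the top quartile).

Two published columns are deliberately *not* reproduced: the printed
CAIC and AWE values imply per-parameter penalties matching neither the
cited formulas nor sample-size-adjusted variants, and the printed
Bayes-factor/cmP columns imply adjacent BIC differences an order of
magnitude smaller than the same table's BIC column. Both are excluded
from validation; the package reports the standard forms above.

### Testing K against K − 1

The Vuong-Lo-Mendell-Rubin test used by the original software relies on
approximations to a non-standard reference distribution that the source
does not specify. The package instead implements the **parametric
bootstrap likelihood-ratio test**: simulate `b` datasets from the fitted
$(K-1)$-class model, refit both models on each, and compare the observed
$LR = 2(LL_K - LL_{K-1})$ with the add-one convention
$p = (1 + \#\{LR_b \ge LR\})/(b+1)$. The naive LR statistic is still
reported in the enumeration table for transparency. Bootstrap refits
reuse the parent solutions as warm starts plus a small number of random
starts — a runtime compromise that slightly favors the null fits and, if
anything, makes the test conservative. The test suite checks its size
empirically (200 Monte-Carlo repetitions at $B = 99$ under a one-class
truth, n = 150, J = 5).

## Distal outcomes: corrected three-step comparison

Comparing classes on outcomes excluded from the measurement model uses
the three-step logic: (1) fit the LCA, (2) assign modal classes
$W_i$, (3) treat $W$ as a fallible indicator of the true class with the
known misclassification rates
$Q_{ks} = \sum_i \tau_{ik}[W_i = s] / \sum_i \tau_{ik}$, and estimate
class-specific outcome distributions by ML in

$$P(W = s, y) = \sum_k \hat\pi_k \, Q_{ks} \, f(y \mid k),$$

with $\hat\pi$ and $Q$ *fixed* at their step-1 values (so the standard
errors ignore step-1 uncertainty, as in the source procedures).
Continuous outcomes get class-specific normal means and **unequal
variances**; categorical outcomes class-specific category
probabilities. Standard errors come from the observed information
(numerical Hessian at the optimum, delta method for probabilities).
Overall tests are a Wald chi-square of mean equality (continuous) and a
likelihood-ratio chi-square of homogeneity (categorical); pairwise
tests are Wald tests (on log-odds differences for categorical
outcomes), each compared against the Bonferroni-adjusted level
$\alpha / \binom{K}{2}$ — 0.05/10 = 0.005 at $K = 5$, the threshold the
published comparisons print.

These corrections are advisable only when classes are reasonably
separated; following the source's guidance the package *warns* (rather
than stops) when step-1 entropy falls below 0.60 — the published
solution itself sits at 0.868. With one-hot posteriors $Q$ is the
identity and both procedures reduce exactly to naive assigned-class
summaries, an identity the tests assert numerically.

## The synthetic survey generator

Respondent-level data are not shared, so `simulate_epii_survey()`
generates surveys with the statistical structure the analysis assumes,
parameterized entirely by published summary tables:

* class labels from the published mixing proportions (printed values
  0.181/0.144/0.314/0.173/0.187 sum to 0.999 and are renormalized);
* the 38 retained indicators as Bernoulli draws from the published
  conditional probabilities (printed to two decimals — generator
  fidelity beyond that precision is not claimed);
* the remaining 54 items as class-independent Bernoulli draws at their
  published base rates (no class-conditional rates exist for them; an
  argument allows injecting class dependence for robustness exercises);
* raw 4-level coding: endorsements split "Yes, Me" vs "Yes, Person in
  Home" at 0.8/0.2 (unreported in the source; the pipeline collapses
  them anyway), household-level items (42, 43, 65) coded as plain
  yes/no;
* psychosocial screens as class-conditional Bernoulli draws at the
  published three-step probabilities, *realized as item vectors*: a
  scale total is drawn uniformly on the positive or negative side of
  the cutoff and allocated uniformly across items respecting item
  ranges, so scoring the simulated items reproduces the intended screen
  status exactly;
* perceived stress and social support as truncated-normal totals with
  class-specific means (defaults 24/26/22/16/12 and 14/13/15/19/20, SD
  6 and 4) chosen so that high-exposure classes report higher stress and
  lower support, on scales of 0–40 and 0–25 — these are the package's
  own realism choices, as the source prints no class-specific totals;
* binary sociodemographics as class-conditional draws at the published
  probabilities, independently across characteristics;
* a rare opt-out code (default rate 0.002, matching the reported
  "< 0.25%" nondisclosure) on scale items, exercising the imputation
  path.

What the generator does **not** emulate: local-dependence violations
(real item batteries are logically nested), correlated
sociodemographics, any association between non-indicator items and
class, and item-level response styles. Passing recovery tests therefore
demonstrates that the estimation machinery is correct under the model's
own assumptions — not that the model is right for real surveys.

A note on what recovery can achieve: data generated from the published
parameters are *cleaner* than the original sample (exact local
independence, two-decimal parameters), so the fitted relative entropy on
synthetic data (≈ 0.91 at n = 2000) sits slightly above the published
0.868, while class profiles, proportions, average posteriors and
screen-probability profiles recover to within sampling noise. At
n = 2000 the worst-case error over the 190 conditional probabilities has
a sampling-noise floor around 0.07 (the smallest class holds ~290
respondents), which is exactly where the recovery checks sit.

## Problem sizes used by the tests

The test suite exercises the full pipeline at n = 2000 (and a scaled-down
n = 500 replicate) with 50 starts and $K_{\max} = 7$ for recovery, and
calibrates the bootstrap test with 200 repetitions of $B = 99$ at
n = 150, J = 5 — sizes chosen so the whole suite runs in a few minutes on
one core while keeping Monte-Carlo error well inside the asserted
bounds. The acceptance script uses the n = 2000 configuration.

## Known limitations

* Dichotomous indicators only; no covariates in the measurement model,
  no ordinal/continuous indicators, no multilevel structure.
* The three-step standard errors condition on step-1 estimates.
* The BCH weighting alternative to the ML three-step is not
  implemented.
* EPII nondisclosure is coded as not-endorsed (conservative; counted and
  reported in the run record) — with forced response the source reports
  this was rare.
* One printed fit-table inconsistency in the source (the 3- and 7-class
  log-likelihoods do not reconcile with their own printed BIC/SABIC
  beyond rounding) is surfaced by a validation check that reports the
  discrepancy rather than papering over it.
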