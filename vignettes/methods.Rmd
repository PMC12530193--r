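---
title: "Statistical methods behind qpcrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind qpcrquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrquant)
```

## The quantification model

qPCR reports expression through threshold cycles. Every analysis in this
package is built on the per-observation *efficiency-weighted* ΔC~T~,

$$ w\Delta C_T \;=\; \log_2(E_{target})\,CT_{target} \;-\; \log_2(E_{ref})\,CT_{ref}, $$

where $E$ is the amplification factor per cycle (dimensionless, 2 = perfect
doubling). The weighting converts each gene's C~T~ onto a common
log2-quantity scale, so that

* with all $E = 2$ the analysis is exactly the classical
  2^--ΔΔC~T~^ (Livak) method, and
* with gene-wise constant efficiencies the fold change
  $FC = 2^{-(\overline{w\Delta C_T}_{Tr}-\overline{w\Delta C_T}_{Co})}$
  is algebraically identical to the Pfaffl efficiency-corrected ratio.

Both identities are enforced as machine-precision tests on random inputs, not
assumed. With two reference genes the two weighted reference terms are
averaged on the log2 scale, which equals normalizing by the geometric mean of
the reference quantities; the alternative (summing the terms) would change
the scale of $w\Delta C_T$ and was rejected for that reason.

Relative expression and fold change are lognormal, so $w\Delta C_T$ is
normal: means, standard errors and tests all operate on the log2 scale, and
only the final report back-transforms with $y = 2^{-x}$. Standard errors are
reported as the multiplicatively symmetric pair
$2^{\log_2 c \mp se}$, and confidence limits back-transform a *t*-interval.
A *t* rather than normal quantile is used throughout because qPCR designs are
small (often 3 biological replicates); the degrees of freedom come from the
test or model contrast (Satterthwaite approximation for mixed models).

## Estimators

**Two conditions (t-test).** For each target gene, the i-th row within each
condition is taken to be the i-th biological replicate — the two-condition
layout carries no replicate column, so this positional pairing is a hard
assumption and is documented loudly on `qpcr_ttest()`. Treatment and control
$w\Delta C_T$ values are compared with a pooled, Welch (`var_equal = FALSE`)
or paired *t*-test; `stats::t.test` supplies the machinery and the suite
checks it against hand-coded textbook formulas. p-values across genes are
Benjamini–Hochberg adjusted by default, and significance marks
(`**` ≤ 0.01, `*` ≤ 0.05, `.` ≤ 0.1) are derived from the adjusted value
whenever adjustment is on — the convention is ambiguous in the field, so both
raw and adjusted columns are always returned.

**Factorial designs.** `fit_wdct_model()` fits
$w\Delta C_T \sim$ fixed factors with the biological replicate (and block,
if present) as random intercepts via `lmerTest`. ANOVA means a full
factorial; ANCOVA keeps the main factor plus the other factors as additive
covariates only — interaction contrasts are therefore refused on ANCOVA
fits. Random slopes are deliberately not offered: replicate and block are
exchangeable units, not longitudinal gradients. When the random-effect
variance is estimated at (or within 1e-5 of) zero, or the mixed fit fails,
the model silently carries no information about those intercepts, so the
package refits a fixed-effects `lm` and warns; all downstream contrasts then
use residual df. Marginal means (`emmeans`) weight design cells equally.

**Fold changes vs a calibrator.** Each non-calibrator level is the contrast
of marginal means against the calibrator, back-transformed. The calibrator's
own row is pinned at FC 1, p 1 by definition; its `se_log2` is the SE of its
own marginal mean. Its confidence limits are undefined (a level compared
with itself) and are reported as `NA` rather than a literal 0. If any
interaction involving the main factor is significant at α, a warning points
to `qpcr_means()` with slicing, because marginal fold changes then average
over a real effect modification.

**Relative expression.** One row per factor-level combination,
$RE = 2^{-\text{emmean}}$, sorted descending. Two dispersion summaries are
reported because they answer different questions: `se_log2` (model-based,
drives `lower_se`/`upper_se` and the CI) and `sd` (standard deviation of the
back-transformed per-replicate values within the cell, a description of raw
scatter). Pairwise comparisons default to unadjusted p-values (each letter
then reflects the plain pairwise test at α); any `p.adjust` method can be
selected, and the letters are guaranteed consistent with whichever matrix
was used.

**Compact letter display.** Implemented in-package by insert-and-absorb:
start with one letter column holding all groups, split any column containing
a significantly different pair, absorb subset columns. The defining property
— two groups share a letter *iff* their pairwise p ≥ α — is tested by brute
force on random p-matrices of up to five groups. Letters are assigned in row
order of the supplied matrix, so the RE table (sorted by RE) gets "a" on the
largest mean; ties in set structure are broken by first group membership.

**Repeated measures.** Same contrast machinery with fixed time (and
treatment and their interaction when present) and a random intercept per
individual, which absorbs stable individual offsets — simulated id offsets
with zero residual noise leave the estimated fold changes exact, and the
suite asserts this.

**Efficiency.** Ordinary least squares of C~T~ on log10(dilution);
$E = 10^{-1/slope}$, so slope −3.3219 ⇔ $E = 2$ ⇔ 100%. Both $E$ and percent
efficiency are reported since the literature uses either. Slopes are
compared through one joint model `Ct ~ log10(dilution) × gene` (pooled
residual error, ANCOVA-style) rather than per-pair fits; pairwise
interaction contrasts are BH-adjusted when more than one pair exists. The
dilution column may hold dilution fractions or absolute quantities (both are
log10-transformed; the transform is shift-invariant in the slope so the two
conventions agree) or ready-made log10 values (auto-detected when
non-positive values are present; override with `dilution_scale`).

## The synthetic generator

`simulate_qpcr()`, `simulate_ttest()`, `simulate_repeated()` and
`simulate_dilution()` draw from exactly the model the estimators assume:
normal noise and normal random effects on the $w\Delta C_T$ (log2) scale,
reference C~T~ fixed at `baseline_ref_ct` (default 25 cycles, jitter 0 so
the ground truth lives entirely in the target gene), and the target C~T~
solved from the wΔC~T~ definition. Defaults — 3 biological replicates,
`noise_sd = 0.25` log2 units, efficiencies 2 — reflect a typical small
bench experiment: 0.25 log2 units corresponds to a ~19% coefficient of
variation in expression ratio, mid-range for SYBR assays.

What passing tests on these data do **not** show: robustness to
heavy-tailed or heteroscedastic noise, unstable reference genes, pipetting
outliers, plate effects beyond a single block term, or mis-specified
efficiencies — real data violate the generative model in all of these ways,
which is why `residual_diagnostics()` exists and why the Welch option and
the non-parametric advisories are surfaced.

## Numerical and design choices

* Validation bounds: efficiencies must lie in (1, 2.5] (log2(E) ≤ 0 makes
  the weighting meaningless); values outside [1.6, 2.2] warn but pass.
  C~T~ must be finite and positive. Missing values are rejected with the
  offending row rather than imputed.
* Technical replicates are averaged on the C~T~ scale before analysis
  (matching the layout in which technical-replicate data arrive); biological
  replicates are never averaged — they enter the model.
* Column mapping is positional per the standard layout conventions, with an
  explicit `col_map` override; the number of reference genes and optional
  columns are inferred from column counts, names and value ranges, and every
  inference can be forced by argument.
* Singular-fit tolerance 1e-5 (lme4's `isSingular`); residuals with SD
  below 1e-10 are treated as a degenerate (perfect) fit in diagnostics.
* Shapiro–Wilk requires 3 ≤ n ≤ 5000; the Levene-type test (median-centred)
  needs ≥ 2 cells with ≥ 2 observations, otherwise it is skipped with a
  `NULL` slot.
* Simulation-based suite sizes: 50 random instances for the t-test oracle,
  1000 null simulations for the type-I error (band 5% ± 2 points), 800
  simulations for 95% CI coverage (band ± 3 points), 100 random matrices for
  the letter display and 100 vectors for the BH oracle — sizes chosen so
  each Monte-Carlo band is several standard errors wide.

## Known limitations

* C~T~ values are inputs; computing them from raw fluorescence, and
  per-curve sigmoidal efficiency estimation, are out of scope.
* Non-parametric tests are advised but not executed.
* Absolute (copy-number) quantification is not supported.
* The positional replicate pairing in the two-condition layout cannot be
  verified from the data; mis-ordered rows silently change the paired
  analysis.
* ANCOVA treats the covariates as additive factors; continuous covariates
  are not supported.
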