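# qpcrquant

Efficiency-weighted relative quantification of qPCR data in R.

Quantitative real-time PCR (qPCR) measures gene expression through threshold
cycles (C<sub>T</sub>): the cycle at which a reaction's fluorescence crosses
the detection threshold, with lower C<sub>T</sub> meaning more starting
template. Turning C<sub>T</sub> values into biologically interpretable
**relative expression (RE)** and **fold change (FC)** statistics — with honest
standard errors, confidence limits and significance tests — is the job of this
package. It is aimed at molecular biologists analysing single- or
multi-factorial qPCR experiments (up to three factors, optional blocking,
technical replicates, repeated measures) with one target gene normalized
against one or two reference genes.

## The model

All inference happens on the **efficiency-weighted ΔC<sub>T</sub>** scale:

```
wΔCT = log2(E_target) · CT_target − log2(E_ref) · CT_ref
```

where `E` is the per-cycle amplification factor (2 = perfect doubling, i.e.
100% efficiency). RE and FC are lognormally distributed, so wΔCT values are
normal and standard t-tests and (mixed-model) ANOVA apply directly; results
are back-transformed with `y = 2^(−x)` only at the reporting step:

- **Relative expression** (ΔC<sub>T</sub> method): `RE = 2^(−mean wΔCT)` per
  condition.
- **Fold change** (ΔΔC<sub>T</sub> method):
  `FC = 2^(−(mean wΔCT_Tr − mean wΔCT_Co))` against a calibrator condition.
- **Standard errors** computed on the log2 scale are reported as the
  multiplicatively symmetric bounds `Lower.se = 2^(log2 FC − se)`,
  `Upper.se = 2^(log2 FC + se)`; confidence limits back-transform the
  t-interval.

With all efficiencies equal to 2 this reduces exactly to the Livak
2<sup>−ΔΔCT</sup> method; with gene-specific efficiencies it reproduces the
Pfaffl efficiency-corrected ratio (both identities are enforced by tests).
Amplification efficiencies are estimated from dilution-series standard curves
(`E = 10^(−1/slope)` of the C<sub>T</sub> ~ log10(dilution) regression) with
statistical pairwise comparison of slopes between genes.

Statistical machinery: t-tests (paired/unpaired, pooled or Welch) for
two-condition designs with Benjamini–Hochberg adjustment across genes; linear
mixed models (`lmerTest`, biological replicate / block / individual as random
intercepts, Satterthwaite df, with a fixed-effects fallback for degenerate
fits) and `emmeans` marginal-mean contrasts for factorial, ANCOVA and
repeated-measures designs; compact letter displays summarizing all pairwise
RE comparisons; Shapiro–Wilk and Levene-type residual diagnostics.

## Worked example

```r
library(qpcrquant)

# A single-factor experiment with known ground truth: true RE of 1, 4 and
# 0.5 for control, drought and salt (so true FCs vs control are 4 and 0.5)
d <- simulate_qpcr(list(treatment = c("control", "drought", "salt")),
                   n_rep = 3, true_re = c(1, 4, 0.5),
                   noise_sd = 0.2, seed = 11)

qpcr_anova_fc(d, calibrator = "control")
#> # A tibble: 3 x 11
#>   contrast              fc  p_value sig      lcl    ucl se_log2 lower_se upper_se
#>   <chr>              <dbl>    <dbl> <chr>  <dbl>  <dbl>   <dbl>    <dbl>    <dbl>
#> 1 control            1     1        ""    NA     NA       0.114    0.924    1.08
#> 2 drought vs control 3.83  1.35e-4  "**"   2.95   4.95    0.134    3.49     4.20
#> 3 salt vs control    0.416 7.07e-4  "**"   0.321  0.539   0.134    0.379    0.457
```

The calibrator's own row is pinned at FC 1 / p 1 by definition. The drought
estimate 3.83 [2.95, 4.95] recovers the simulated 4-fold induction; salt
(0.416, i.e. ~2.4-fold repression) recovers the simulated 0.5. `**` marks
p ≤ 0.01. `autoplot()` on this result draws the publication-style bar plot
with whiskers at the SE bounds (or confidence limits) and the significance
marks above the bars.

Standard-curve efficiency analysis:

```r
dil <- simulate_dilution(c(GAPDH = 2.0, MYB = 1.88),
                         dilutions = c(1, 0.1, 0.01, 0.001),
                         noise_sd = 0.08, seed = 2)
qpcr_efficiency(dil)
#>   gene  slope intercept r_squared efficiency percent_efficiency
#> 1 GAPDH -3.33      20.0     0.999       2.00               99.8
#> 2 MYB   -3.65      20.0     1.000       1.88               88.0
compare_slopes(dil)
#>   gene_pair    slope_difference     se    df p_value
#> 1 GAPDH vs MYB            0.321 0.0572     4 0.00497
```

The slopes differ significantly (p ≈ 0.005): MYB amplifies at 88%
efficiency, so the efficiency-weighted analysis matters for this primer pair.

Other entry points: `qpcr_ttest()` (two-condition, any number of genes),
`qpcr_anova_re()` (per-condition RE with grouping letters),
`qpcr_repeated()` (time courses with an individual-level random intercept),
`qpcr_means()` (pairwise contrasts for any effect, with slicing),
`residual_diagnostics()`, `mean_technical_reps()`, `read_qpcr()` /
`write_qpcr_results()`. A command-line wrapper lives in
`inst/cli/qpcrquant.R`:

```sh
Rscript inst/cli/qpcrquant.R ttest --input x.csv --out r   # r_results.csv + r_plot.png
```

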