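---
title: "Quality control for targeted RNA panels with control probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for targeted RNA panels with control probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelqc)
```

## The problem

Targeted RNA panels (HTG EdgeSeq-style, typically run on FFPE material)
return a probe × sample matrix of read counts with two built-in control
sets: positive controls — synthetic spike-ins added at known input — and
negative controls targeting non-human sequences. A well-behaved sample
spends only a few percent of its reads on the spike-ins and nearly nothing
on the negative probes; a failed hybridisation inflates the spike-in share,
and contamination or background inflates the negative-control share.
`panelqc` formalises those two observations into a per-sample
PASS/ALERT/FAIL verdict and keeps the verdict attached to the downstream
normalization and ordination steps.

## The two filters

Let the library size of sample $i$ be the sum of its counts over **all**
probes, controls included — the control percentages below are shares "of the
total library", so the denominator must include the controls themselves.

**Positive filter.** With $p_i$ the percentage of reads on the spike-ins:
FAIL if $p_i > 40$, ALERT if $p_i > 10$, else PASS. The 40/10 pair reflects
the empirical 0–5% range of good samples: 10% is suspicious, beyond 40% the
sample is mostly control signal.

**Negative filter.** Counts are CPM-normalised per sample. With $M$
negative probes, the per-sample background level is
$\mathrm{CPM}_i = \sum_{j=1}^{M} \mathrm{cpm}(X_{ij})/M$ and its deviance
from the run average is
$\Delta_i = \mathrm{CPM}_i - \tfrac{1}{N}\sum_{j=1}^{N}\mathrm{CPM}_j$.
The $\Delta_i$ sum to zero by construction; a sample outside
$\pm 2\,\mathrm{SD}(\Delta)$ has sample-specific background and is flagged
ALERT. The band is *relative*, so a run in which every sample is
contaminated alike shifts together and no deviance leaves the band — which
is exactly why a second, absolute sub-filter exists: FAIL whenever the
negative-control share exceeds 10% of the library. The
`complete_run_failure` scenario in the generator reproduces this situation,
and the test suite asserts that the band flags nobody while the fraction
rule flags everyone.

**Combination.** FAIL dominates ALERT dominates PASS across the two
filters.

## Tunable parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `pos_fail` | % of library | 40 | positive share above which a sample FAILs |
| `pos_alert` | % of library | 10 | positive share above which a sample is ALERT |
| `neg_fail` | % of library | 10 | negative share above which a sample FAILs |
| `sd_mult` | SD units | 2 | half-width of the deviance band |

All four are carried by `qc_thresholds()` and validated
(`0 < pos_alert < pos_fail ≤ 100`, etc.).

## Numerical and semantic choices

* **Strict inequalities everywhere.** The thresholds are worded as
  "exceeds": a sample at exactly 40.0% is ALERT, not FAIL. This also makes
  the degenerate band harmless: when all deviances are equal,
  $\mathrm{SD}(\Delta) = 0$ and $|\Delta_i| > 0$ is false for every sample.
* **Deviance-outlier severity is ALERT, not FAIL.** The flag-combination
  rule requires both filters to be able to emit ALERT, and explicit
  "fails" wording is reserved for the fraction rules; treating band
  outliers as warnings keeps the two severities meaningfully distinct. The
  fraction sub-filter is the only FAIL path on the negative side.
* **Two-sided band by default, one-sided on request.** The band is printed
  as $\pm 2$ SD, so `|Δ|` is compared by default; since only *elevated*
  negative-control signal indicates contamination, `band = "upper"`
  restricts the test to the high side.
* **SD with the N−1 denominator.** The run is a sample of the process, and
  with small N the distinction matters. With fewer than 3 samples the band
  is statistically meaningless, so the sub-filter is skipped with a warning
  and `deviance_filter_applied = FALSE` is recorded.
* **Integer counts.** Instrument exports are read counts; parsed numerics
  within 1e-9 of an integer are rounded, anything else is rejected naming
  the offending cell. NaN/negative values never survive parsing, so the QC
  path needs no missing-value handling.
* **Deterministic ordination.** PCA uses an SVD with the sign of each
  component fixed so its largest-magnitude gene loading is positive;
  `hclust` ties break by input order. Re-running any export is
  bit-identical.

## Normalization

`cpm` is the default; `log2cpm` is `log2(cpm + 1)`. The `vst` option is a
closed-form stabilizer for negative-binomial counts with variance
$\mu + \alpha\mu^2$:
$g(x) = \tfrac{2}{\sqrt{\alpha}}\operatorname{asinh}\sqrt{\alpha x}$, with
the Poisson limit $g(x) = 2\sqrt{x}$ at $\alpha = 0$. The common dispersion
$\alpha$ is a method-of-moments estimate: counts are rescaled to the median
library size, each gene with positive mean $m$ and variance $s^2$
contributes $\alpha_g = \max(0, (s^2 - m)/m^2)$, and $\alpha$ is the median
over informative genes (constant genes are excluded). The median resists
the long right tail of per-gene moment estimates; the rescaling removes
library-size variance that would otherwise inflate $s^2$. This is
deliberately a self-contained "vst (NB closed form)" — it makes no claim of
numerical agreement with any other package's variance-stabilizing
transform, only of the stabilization property itself, which the tests
verify: on simulated NB genes spanning means 10–10,000 the per-decile
variance of transformed values varies by less than a factor of 3, against
several orders of magnitude on raw counts.

For visualisation the control probes are removed before normalization by
default — in a failed run they would dominate the PCA — while the QC
filters always see the full matrix.

## Downstream exports

`pca_samples()` restricts to the 500 most variable genes (a conventional
cut for expression matrices; the probe universe of these panels is often
smaller, in which case all genes are used), centers genes without unit
scaling, and can exclude FAIL or FAIL+ALERT samples when a QC result is
supplied. `hclust_orders()` z-scores rows (constant rows are flagged and
zeroed), supports euclidean or correlation distances with average, complete
or Ward linkage, and returns leaf orders and merge trees rather than a
rendered image — the numeric exports are the tested surface; plots are
convenience artifacts via `autoplot()`.

## The synthetic-run generator

`simulate_run()` emulates the statistical structure the QC method relies
on: lognormal library sizes (mean 1e6 reads, 0.2 log-SD jitter), exact
read budgets for the control sets (rounded multinomial within the 4 POS and
4 ANT probes), and the remaining reads multinomially distributed over genes
with negative-binomial weights (common dispersion 0.3) around a fixed
lognormal abundance profile. Budgeting the controls exactly — rather than
drawing them independently — separates the flag ground truth (deterministic
up to rounding) from expression realism (stochastic), so every preset can
guarantee its advertised flags: `clean_run` keeps positive fractions in
0.5–4% (inside the 0–5% good-quality range) and negative fractions below
1%; `single_pos_failure` puts one sample at 50%; `alert_only` at 15%;
`single_neg_contamination` puts 15% of one sample's reads in the negative
probes; `complete_run_failure` contaminates all samples alike at 18–22%.
Defaults are 16 samples × 100 genes.

What the generator does **not** emulate: probe-level hybridisation
chemistry, FFPE degradation gradients, batch structure across runs, or real
panel gene content. Passing tests therefore demonstrate the correctness of
the QC arithmetic and the flag logic under controlled contamination — not
the field performance of the thresholds on real instrument output.

## Problem sizes

The test suite and the acceptance script run in seconds by design: QC
oracle comparisons use 10-probe × 6-sample matrices, deviance conservation
uses 1,000 random runs, the boundary scan walks percentages in 1-point
steps, and the stabilization diagnostics use 400 genes × 50 samples (with
dispersion recovery at 200 × 50, where the estimate for a true
$\alpha = 0.5$ lands within [0.3, 0.7]).

## Known limitations

* The instrument's proprietary workbook layout is undocumented; the
  "instrument" dialect (metadata rows before a `"Sample Name"` header row)
  is a documented stand-in, and plain CSV/TSV is the primary format.
* The thresholds are panel-calibrated constants, not estimates; runs from
  other chemistries may need different values via `qc_thresholds()`.
* No probe-level QC, background subtraction or batch correction — the
  verdict is per sample, and differential expression is out of scope.
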