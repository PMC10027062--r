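# panelqc

Sample-level quality control for targeted RNA expression panels that carry
built-in control probes — the probe × sample count matrices produced by
HTG EdgeSeq-style instruments, whose panels include four positive controls
(synthetic spike-ins) and four negative controls (probes against non-human
sequences). `panelqc` turns those control reads into a reproducible
PASS/ALERT/FAIL verdict per sample, plus QC-aware normalization and
exploratory exports (PCA, clustered heatmap data) for the cleaned matrix.

## The method

For each sample *i* (of *N* in the run), with library size equal to the
total reads over **all** probes:

**Positive-control filter.** The percentage of reads allocated to the
spike-ins is compared to two strict thresholds: the sample **FAIL**s when it
exceeds 40%, and is flagged **ALERT** when it exceeds 10% (good-quality
samples sit in the 0–5% range).

**Negative-control filter.** Counts are normalised to counts per million
(CPM) and the mean CPM of the *M* negative probes is computed per sample,

    CPM_i = Σ_j cpm(X_ij) / M        (j over the M negative probes)

then centred on the run average to give a deviance

    Δ_i = CPM_i − Σ_j CPM_j / N .

Samples whose deviance falls outside ±2·SD(Δ) show sample-specific
background and are flagged **ALERT**. Because a run in which *every* sample
is contaminated shifts together — leaving all deviances inside the band — a
second sub-filter **FAIL**s any sample whose negative-control reads exceed
10% of its library size, regardless of the band.

**Combination.** A sample is FAIL when either filter is FAIL, else ALERT
when either is ALERT, else PASS. All four constants (40, 10, 10, 2) are
tunable via `qc_thresholds()`.

## Worked example

```r
library(panelqc)

run <- simulate_run(scenario_config("single_pos_failure", seed = 7))
qc  <- run_qc(run$counts)
qc
#> <panel_qc> 16 samples: 15 PASS, 0 ALERT, 1 FAIL
#>   deviance band: [-1020, 1020] CPM (SD 510.1, two-sided)
#> <qc_thresholds> pos FAIL > 40%, pos ALERT > 10%, neg FAIL > 10%, band = 2 SD

qc_flagged_table(qc)
#> # A tibble: 1 × 9
#>   sample_id library_size pos_pct neg_pct neg_mean_cpm delta pos_flag neg_flag
#> 1 S1             1087424      50   0.198         495. -696. FAIL     PASS
```

Sample `S1` was generated with 50% of its reads in the spike-ins: half the
library is control signal, so the sample fails the positive filter. Its
negative-control percentage (0.2%) and deviance (−696 CPM, inside the
±1020 CPM band) are unremarkable — the failure is a sample-preparation
problem, not contamination.

Downstream, on the control-free matrix:

```r
norm <- normalize_counts(run$counts, method = "vst",
                         controls = detect_controls(run$counts))
pca  <- pca_samples(norm, qc = qc, exclude = "fail")   # 15 samples kept
autoplot(qc, "deviance"); autoplot(pca)
tidy(qc); glance(qc)     # broom-style accessors
```

The same pipeline is scriptable from a shell via the installed CLI
(`exec/panelqc`): subcommands `qc`, `normalize`, `analyze`, `simulate` and
`config-show`; `qc` exits 0 when every sample is usable, 3 when any sample
FAILs, 1 on error, so it can gate a pipeline.

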