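# fcnet

Graph-theoretic analysis of resting-state functional-connectivity networks,
packaged as a reproducible pipeline with a validated synthetic cohort
generator.

Studies of brain disorders such as post-stroke aphasia increasingly compare
the *topology* of whole-brain functional networks between a patient group and
controls, rather than individual connections. The standard recipe — and what
this package implements end to end — is:

1. **Connectivity.** For each subject, regional fMRI time series
   (T × N) are reduced to an N × N Fisher-z correlation matrix,
   `z = atanh(r)`, zero diagonal.
2. **Thresholding.** The matrix is binarized across a band of network
   sparsities `s = 0.05, 0.10, …, 0.40`: at each `s` the
   `round(s·N(N−1)/2)` strongest positive correlations become edges, so
   all subjects have identical network density.
3. **Topology.** At each threshold: clustering coefficient `Cp`,
   characteristic path length `Lp`, global and local efficiency
   `Eglob`/`Eloc`, and nodal degree (DC), betweenness (BC, Brandes),
   nodal efficiency (NEg) and nodal local efficiency (NEloc). `Cp` and
   `Lp` are normalized against degree-preserving Maslov–Sneppen null
   ensembles to give `gamma = Cp/Cp_rand`, `lambda = Lp/Lp_rand`, and
   small-worldness `sigma = gamma/lambda`.
4. **AUC.** Each metric's trajectory across the band is summarized by its
   trapezoidal area under the curve — a threshold-independent scalar.
5. **Statistics.** Group comparisons of the AUCs (Welch/Student t,
   Mann–Whitney U, 5000-shuffle permutation tests), Bonferroni-corrected
   nodal tests at the strict (`0.05/N`) and liberal (`1/N`) levels, and
   brain-behavior Pearson/partial correlations within the patient group.

Because raw clinical fMRI data are rarely available, the package includes a
synthetic cohort generator (`generate_cohort()`) that emulates the data
structure of a two-group aphasia study — modular inter-node covariance, a
patient-specific connectivity reduction in designated modules, and clinical
scores coupled to lesion severity — so the whole pipeline is testable
against a known ground truth, including its type-I error and power.

## Worked example

```r
library(fcnet)

# simulate a cohort: 24 patients (graded lesion in 2 of 6 modules),
# 19 controls, 60 nodes, 150 timepoints
cohort <- generate_cohort(coupled_cohort_config(seed = 20210))

# profile every subject across the sparsity band (no null ensembles here)
profiles <- profile_cohort(cohort$series,
                           global_metrics = c("Cp", "Lp", "Eglob", "Eloc"),
                           nodal_metrics = c("DC", "NEg"))

# group statistics on the AUCs
cmp <- compare_groups(profiles, cohort$clinical, n_perm = 5000, seed = 11)
cmp$global[, c("metric", "t", "p_t", "p_perm", "significant")]
#>   metric         t          p_t     p_perm significant
#> 1     Cp -4.810170 2.074818e-05 0.00019996        TRUE
#> 2     Lp  4.914024 2.290776e-05 0.00019996        TRUE
#> 3  Eglob  4.505908 7.113235e-05 0.00019996        TRUE
#> 4   Eloc -7.030378 2.265739e-08 0.00019996        TRUE
```

Patients show strongly reduced clustering and local efficiency (negative t:
patient mean below control mean) — the lesion planted by the generator —
with longer path lengths, and parametric and permutation p-values agreeing.
Brain-behavior correlations within the patient group then recover the
planted coupling between local efficiency and the composite language score:

```r
subset(cmp$behavior, score == "language_ability" & metric == "Eloc")
#>    metric            score         r          p_r partial_r    p_partial
#> 26   Eloc language_ability 0.6743855 0.0003015794 0.7538339 0.0001237854
```

Published clinical summary tables can be re-tested directly from their
printed mean ± sd triples:

```r
two_sample_t(c(mean = 14.42, sd = 6.86, n = 24),   # patients, MMSE
             c(mean = 29.21, sd = 0.98, n = 19))   # controls
#> welch_t: statistic = -10.43, df = 24.18, p = 1.981e-10
```

The `analysis/` directory contains the full workflow as numbered scripts
(simulate → connectivity → metrics → statistics → calibration), each writing
its tables under `results/`.

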