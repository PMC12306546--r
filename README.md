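# scvrelate

Identify the relationship structure among multiple datasets — which
datasets group together and how the groups relate — from the latent
dependence structure that joint blind source separation reveals.

## Who this is for

Analysts holding `K` related data matrices (multi-task or multi-subject
neuroimaging contrasts, multi-cohort omics, any collection of datasets
suspected to share latent sources) who want a *data-driven* grouping of the
datasets plus a dendrogram of how the groups relate, without choosing
similarity thresholds by hand.

## The method

Datasets follow the joint mixing model `x[k] = A[k] s[k]`, `k = 1..K`.  The
r-th **source component vector (SCV)** stacks the r-th latent source across
datasets; its `K x K` covariance `C_r` (sources zero-mean, unit-variance)
says which datasets carry correlated copies of that source.  A
block-diagonal `C_r` with `d_r >= 2` blocks has exactly `d_r` eigenvalues
greater than 1, and each such eigenvalue's eigenvector is supported on one
block.  The pipeline:

1. **IVA-L-SOS** — independent vector analysis under a multivariate
   Laplacian source model with non-identity SCV covariance, run from
   several random initialisations with consistency-based selection, jointly
   estimates demixing matrices `W[k]` and SCVs.
2. **Bootstrap eigenvalue counting** — for each SCV, every eigenvalue of
   `abs(S S'/V)` is tested against `H0: lambda <= 1` using `B` column
   resamples and threshold rank `floor((B+1)(1-Pfa))`; the rejection count
   `d_hat` classifies the SCV as common (`d_hat = 1`) or structured
   (`d_hat > 1`).
3. **Ward clustering** — the `d_hat` leading eigenvectors of all structured
   SCVs are concatenated into a `K x sum(d_hat)` feature matrix whose rows
   are clustered (Euclidean distance, Ward linkage); the dendrogram is the
   relationship structure and cutting it yields grouping labels, scored
   against known labels by adjusted mutual information (AMI) when
   available.

A simulation harness generates block-correlated multivariate-Laplacian
SCVs with planted ground truth (block counts `d`, grouping labels, mixing
matrices), so every claim above is testable end to end.

## Worked example

```r
library(scvrelate)

design <- scv_design(rho = 0.2)   # 6 SCVs, K = 10 datasets, V = 1000,
                                  # true d = (1,2,2,2,3,4),
                                  # labels (1,1,1,1,2,2,2,3,3,3)
report <- run_pipeline(
  design = design,
  config = pipeline_config(n_runs = 5, B = 1000, Pfa = 0.05,
                           n_clusters = 3, seed = 5)
)
print(report)
```

```
3-step relationship-structure pipeline
  d_hat: (3, 2, 4, 1, 2, 2)
  common SCVs: {4}; structured SCVs: {1, 2, 3, 5, 6}
  labels: (1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  AMI vs truth: 1
  joint-ISI vs true mixing: 0.01494
  timings (s): simulate 0.02, iva 5.20, eigen_count 0.26, relate 0.01
```

Reading the output: the six estimated SCVs carry block counts
`(3, 2, 4, 1, 2, 2)` — the planted multiset `{1, 2, 2, 2, 3, 4}` up to the
arbitrary SCV order of blind separation.  SCV 4 is common (one eigenvalue
above 1: all datasets correlated) and is excluded from clustering.  The
eigenvector features of the five structured SCVs cluster the ten datasets
exactly into the planted groups — AMI 1 against the ground truth — and the
demixing matrices agree with the true mixing up to a shared permutation and
scaling (joint-ISI 0.015; 0 is perfect).  `report$structure` holds the
dendrogram (`export_newick()` writes it as a tree), and `write_report()`
serialises everything to JSON/CSV.

A command-line wrapper covers the same flow from a shell:

```sh
Rscript inst/cli/scv-relate.R simulate --rho 0.2 --V 1000 --seed 1 --out sim/
Rscript inst/cli/scv-relate.R run --input sim/ --n-runs 5 --bootstrap 1000 \
    --pfa 0.05 --n-clusters 3 --seed 1 --out results/
```

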