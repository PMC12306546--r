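---
title: "Identifying the relationship structure among multiple datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying the relationship structure among multiple datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scvrelate)
```

## The problem

Given $K$ datasets $\mathbf{X}^{[k]} \in \mathbb{R}^{R \times V}$ that share
latent structure, we want to know *how the datasets are related*: which
datasets form groups, and how close those groups are to each other.  In
multi-task neuroimaging, for instance, each dataset is one task contrast
across subjects and the groups correspond to families of cognitive tasks; in
subgroup analysis each dataset is one subject.  The answer `scvrelate`
produces is a dendrogram over the $K$ datasets, plus flat grouping labels.

The generative model is joint blind source separation:
$\mathbf{x}^{[k]} = \mathbf{A}^{[k]} \mathbf{s}^{[k]}$, with an unknown
square mixing matrix per dataset.  The $r$-th *source component vector*
(SCV) collects the $r$-th latent source across all $K$ datasets; its
$K \times K$ covariance matrix $\mathbf{C}_r$ (sources are zero-mean,
unit-variance, so covariance = correlation) encodes which datasets carry
dependent copies of that source.  Two covariance shapes matter:

* **common SCV** — all off-diagonal correlations non-zero: every dataset
  participates.  Such a matrix has exactly one eigenvalue greater than 1.
* **structured SCV** — block-diagonal (up to a symmetric permutation) with
  $d_r \ge 2$ blocks of correlated datasets.  It has exactly $d_r$
  eigenvalues greater than 1, and the eigenvector of each such eigenvalue is
  supported on one block (non-zero entries exactly on the block members).

Those two facts are what the whole method rests on: the number of
eigenvalues above 1 counts the blocks, and the corresponding eigenvectors
say which datasets form each block.

## The three steps

1. **Estimate the SCVs** with independent vector analysis (IVA) under a
   multivariate-Laplacian source model with non-identity SCV covariance
   (IVA-L-SOS): heavy-tailed marginals capture higher-order dependence while
   the profiled SCV covariance captures second-order structure.  Multiple
   random restarts are run and the most self-consistent run is selected.
2. **Classify each estimated SCV** as common ($\hat d_r = 1$) or structured
   ($\hat d_r > 1$) by estimating $\hat d_r$, the number of covariance
   eigenvalues greater than 1, with a bootstrap hypothesis test.  Direct
   counting overestimates $d_r$ on finite samples because spurious sample
   correlations push trailing eigenvalues above 1; the bootstrap test
   calibrates each eigenvalue's decision at a user-chosen false-alarm
   probability.
3. **Cluster the datasets**: concatenate the $\hat d_r$ leading eigenvectors
   of every structured SCV into a feature matrix
   $\mathbf{F} \in \mathbb{R}^{K \times \sum \hat d_r}$ and run
   agglomerative (Ward) clustering on its rows.  The merge tree is the
   estimated relationship structure; cutting it yields flat labels.

Common SCVs are deliberately excluded from step 3 — a component shared by
everything says nothing about how the datasets differ.

## Step 1 in detail: the IVA objective and its optimiser

IVA minimises the mutual information among estimated SCVs, equivalently
(up to constants)

$$J(\mathbf{W}) = \sum_{r=1}^{R}\Big[\tfrac1V \sum_{v=1}^{V}
 \sqrt{\hat{\mathbf{s}}_{rv}^\top \boldsymbol\Sigma_r^{-1}\hat{\mathbf{s}}_{rv}}
 + \tfrac12 \log\det \boldsymbol\Sigma_r\Big]
 - \sum_{k=1}^{K}\log|\det \mathbf{W}^{[k]}|,$$

where $\boldsymbol\Sigma_r$ is profiled as the sample covariance of the
current $r$-th SCV (plus a $10^{-8}$ ridge before inversion).  The square
root term is the negentropy of the multivariate-Laplacian model
$p(\mathbf{s}) \propto \exp(-\sqrt{\mathbf{s}^\top\boldsymbol\Sigma^{-1}\mathbf{s}})$.

The optimiser combines three ingredients, each of which earned its place:

* **Relative-gradient descent with gauge fixing.**  Each dataset is
  pre-whitened, and updates follow the relative gradient with an adaptive
  step that only accepts objective decreases, so the recorded objective
  trajectory is non-increasing by construction.  $J$ is exactly invariant
  to rescaling any demixing row (the profiled $\boldsymbol\Sigma_r$ absorbs
  it), so the diagonal of the relative gradient is pure scale drift; it is
  projected out and the demixing rows are pinned to unit norm instead.
* **Block-swap moves.**  Solutions exist in which a whole correlated block
  of datasets is coherently assigned to the wrong SCV among SCVs with
  similar covariance structure.  Such configurations are themselves
  block-coherent, so they are local minima for any purely continuous
  update *and* for single-dataset row swaps — the block has to move as one
  unit.  When gradient descent stalls, the optimiser therefore tries, for
  every SCV pair, exchanging the demixing rows over candidate dataset
  subsets (the connected components of the two estimated block graphs,
  their complements, and singletons), keeping any exchange that lowers
  $J$.  In our planted-model experiments this step is what takes the
  joint-ISI of random-initialisation runs from roughly $0.1$ down to the
  $0.01$–$0.02$ attained when starting at the true demixing.
* **Restarts with consistency selection.**  `iva_ensemble()` runs several
  random orthogonal initialisations, measures cross-run discrepancy after
  greedy permutation-and-sign matching of SCVs (mean of
  $1 - |\text{row correlation}|$), and selects the run with the smallest
  mean discrepancy to the others.

At convergence source rows are rescaled to unit sample variance (so the SCV
covariance in step 2 is a correlation matrix), and sources remain defined
only up to per-row sign and SCV order — every downstream step is invariant
to both.

## Step 2 in detail: the bootstrap block-count test

For one SCV matrix $\hat{\mathbf S}_r \in \mathbb{R}^{K\times V}$ the test
computes $\hat{\mathbf C}_r = |\tfrac1V\hat{\mathbf S}_r\hat{\mathbf S}_r^\top|$
(the elementwise absolute value absorbs the sign ambiguity) and its sorted
eigenvalues $\hat\lambda_r^{[1]} \ge \dots \ge \hat\lambda_r^{[K]}$.  For
each $k$ it tests $H_0: \lambda_r^{[k]} \le 1$ with statistic
$\hat T = \hat\lambda_r^{[k]} - 1$, whose null distribution is approximated
by $B$ bootstrap replicates: columns are resampled with replacement (one
shared index draw per replicate, preserving cross-row dependence),
eigenvalues recomputed, and $\hat T^*_b = \hat\lambda^{[k]}_{r,b} -
\hat\lambda^{[k]}_r$ collected.  With
$\eta = \lfloor (B+1)(1-P_{fa}) \rfloor$ and the $\hat T^*$ sorted
ascending, $H_0$ is rejected when $\hat T \ge \hat T^*_{(\eta)}$ (ties
reject).  $\hat d_r$ is the number of rejections.

Defaults are $B = 1000$ and $P_{fa} = 0.05$, typical values at which the
estimate is stable; raising $B$ further sharpens the threshold estimate at
linear cost, while $P_{fa}$ directly trades the risk of overestimating
$d_r$ against test power.  Bootstrap replicates are not re-centred: the
resample-and-recompute loop mirrors the covariance computation exactly.
Eigenvector alignment across replicates is unnecessary since only
eigenvalues enter the statistic.  SCVs with $\hat d_r = 0$ (identity
covariance, i.e. completely uncorrelated datasets) fall outside the
common/structured dichotomy and are excluded with a warning.

One calibration property deserves honesty: on *fully independent* data,
where every population eigenvalue sits exactly at the $H_0$ boundary, the
test of the largest eigenvalue is anti-conservative (we measure a rejection
rate near $0.33$ at $P_{fa} = 0.05$, $K = 5$, $V = 1000$).  The elementwise
absolute value inflates the observed statistic by roughly
$(K-1)\,\mathbb{E}|r|$ ($r$ a null sample correlation), while the bootstrap
increments shift by only about $(\sqrt2 - 1)$ of that, at any $V$.  This
regime — an SCV with identity covariance — is exactly the one the method
excludes from consideration, and the trailing eigenvalues' tests are, if
anything, conservative there; but users should not read $\hat d_r \ge 1$ on
utterly uncorrelated data as evidence of a common component.

## Step 3 in detail: features, linkage, labels

Each feature column (a leading eigenvector) is sign-fixed by its
largest-magnitude entry; since $\hat{\mathbf C}_r$ is elementwise
non-negative, block eigenvectors are non-negative up to a global sign, and
the convention restores the "block members positive" interpretation.
Clustering uses Euclidean distance between the rows of $\mathbf F$ and
Ward's minimum-variance criterion (`hclust` method `"ward.D2"`, operating
on unsquared distances); ties are resolved by `hclust`'s deterministic
agglomeration order, so results are reproducible given $\mathbf F$.  The
merge table is also exported in a children/height/size layout and as a
Newick tree.

Flat labels come from cutting the tree, either at a user-supplied number of
clusters or — an extension beyond reading the dendrogram by eye — at the
largest gap between consecutive merge heights.  The gap heuristic prefers
the *finest* partition consistent with a large gap; on designs whose
structured SCVs genuinely distinguish sub-blocks it will return those
sub-blocks rather than a coarser grouping, which is why evaluation against
known labels fixes the cut level explicitly.

Agreement with ground-truth labels is scored by adjusted mutual
information: $\text{AMI} = (\text{MI} - \mathbb{E}[\text{MI}]) /
(\max(H_U, H_V) - \mathbb{E}[\text{MI}])$, with the expected mutual
information computed under the hypergeometric permutation model.  The
"max" normalisation is the reference default; the arithmetic, geometric
and min variants are available through an argument.  AMI is 1 for equal
clusterings (up to relabelling) and near 0 for independent ones.

## The synthetic-data generator

`scv_design()` encodes the reference simulation: $R = 6$ SCVs over
$K = 10$ datasets, $V = 1000$ samples, block counts $d = (1,2,2,2,3,4)$,
ground-truth labels $(1,1,1,1,2,2,2,3,3,3)$.  Each SCV covariance has unit
diagonal, zeros off-block, and $\rho + n(k,l)$ within blocks with symmetric
$n(k,l) \sim \mathcal N(0, 0.05^2)$ — the perturbation keeps block
covariances non-proportional, which the identifiability of IVA requires.
The third design matrix leaves one dataset uncorrelated and the fourth
leaves four.  Published facts pin the block *counts* and the group
structure but not every membership; the defaults (C1: 1–10; C2: 1–4, 5–10;
C3: 1–4, 5–9; C4: 1–3, 5–7; C5: 1–4, 5–7, 8–10; C6: 1–2, 3–4, 5–7, 8–10)
are a reconstruction consistent with all of them and are configurable.

Sampling uses the Gaussian scale-mixture construction of the multivariate
Laplacian: $\mathbf s = \sqrt{w}\,\mathbf z$ with
$\mathbf z \sim \mathcal N(0, \mathbf C_r)$ and $w \sim \text{Exp}(1)$,
giving covariance exactly $\mathbf C_r$ and marginal excess kurtosis 3.
The shared mixing variable also induces the cross-block higher-order
dependence that lets IVA hold an SCV together.  Rows are centred exactly;
variances are left stochastic (unit at the population level).  Mixing
matrices have i.i.d. standard-normal entries, redrawn above condition
number $10^6$.  If a perturbation draw breaks positive definiteness the
noise is redrawn (up to 100 times) rather than eigenvalue-clipped, which
would distort the covariance model.

What the generator does *not* emulate: additive observation noise (the
intended use assumes noise is removed by PCA in an overdetermined
pre-processing step), spatial or temporal structure of real imaging data,
non-square or shared mixing, and asymmetric or skewed sources.  Passing
the simulation suite therefore demonstrates correctness of the estimation
machinery under the stated model, not robustness to everything real data
can do.

## Seeding and reproducibility

Every random stage draws from a named substream derived from one master
seed (`substream_seed()`), e.g. `simgen`, `iva.run i`, `bootstrap r`.
Results are therefore bit-reproducible for a given seed and independent of
stage order or parallel scheduling, and any stage can be re-run alone with
identical results.  The bootstrap resampling loop is implemented in C++
(RcppArmadillo) but draws its indices through R's RNG, so it obeys the same
seeds.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_runs` | 20 | IVA restarts; 5 already suffice on the reference design |
| `B` | 1000 | bootstrap resamples per SCV (cost is linear in `B`) |
| `Pfa` | 0.05 | per-eigenvalue false-alarm probability; controls overestimation of $d_r$ |
| `tol` | 1e-6 | IVA convergence tolerance on relative demixing change |
| `max_iter` | 1024 | IVA iteration cap |
| `R` | — | PCA target dimension for raw data; on real data a plateau of stable results over a range of `R` values is the practical selection criterion |
| `n_clusters` | `NULL` | dendrogram cut; `NULL` uses the height-gap heuristic |

## Scale of the validation experiments

The shipped tests exercise the reference design at its native size
($K = 10$, $V = 1000$, $B = 1000$): 50 Monte-Carlo replicates for
block-count recovery at $\rho \in \{0.2, 0.5, 0.8\}$, ten end-to-end
pipeline runs (five restarts each) at $\rho \in \{0.2, 0.8\}$, 200
replicates for false-alarm calibration, and ten-seed medians for
demixing quality at $V \in \{500, 1000, 2000\}$ — sizes chosen to give
stable Monte-Carlo estimates while keeping the whole suite comfortably
runnable on a laptop.  At these sizes the pipeline attains AMI 1 in every
run, median joint-ISI $\approx 0.014$, and per-SCV recovery probabilities
at or near 1 — with two honest exceptions: the identity-boundary
calibration of the largest eigenvalue documented above, and recovery at
the weakest correlation $\rho = 0.2$, where individual SCVs dip to
$P(\hat d = d)$ between $0.7$ and $0.9$ (most severely the SCV with two
2-dataset blocks, whose block eigenvalue $1 + \rho = 1.2$ sits within
reach of the bootstrap threshold under Laplacian-inflated sampling
noise).

## Known limitations

* The IVA cost is non-convex; the block-swap moves remove the dominant
  failure mode on block-structured SCVs, but adversarial covariance
  designs can still trap the optimiser, and restarts remain advisable.
* The bootstrap test is calibrated for the structured/common regimes the
  method targets, not at the exact identity-covariance boundary (see
  above).
* The gap-based automatic cut is a heuristic; when a known number of
  groups exists, pass `n_clusters`.
* Datasets must be reduced to a common dimension $R$ beforehand
  (`pca_reduce()`); the package offers no automatic order selection.
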