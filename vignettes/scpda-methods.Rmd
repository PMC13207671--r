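---
title: "scpda: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scpda: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpda)
```

This vignette documents the statistical models behind each pipeline stage,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## The analysis problem

Single-cell proteomics matrices are small-n, high-missingness objects: a
cell yields on the order of 1,000–2,500 quantified protein groups, and
whether a protein is observed depends strongly on its abundance
(missing-not-at-random, left-censored). A two-group comparison (e.g. a
dozen wild-type cells against a dozen cells with induced lysosomal
storage) acquired in two instrument batches therefore needs, in order:
background subtraction against cell-free procedural blanks, depth and
replication filters, a censoring-aware imputation, batch correction that
does not erase the biology, and only then differential testing and
downstream enrichment/network analysis. `scpda` fixes this stage order;
the orchestrator will not permute blank subtraction after the detection
filter because the filters' outcomes depend on it.

## Stage models and parameters

### Blank subtraction

For protein $i$, background is the mean *linear* intensity over blanks
(missing treated as 0), subtracted from every cell; non-positive results
become missing. The mean (not the max) is used so a single noisy blank
cannot erase a protein, and flooring to *missing* (not zero) keeps the
value's semantics consistent with left-censoring: "below background" and
"below detection" are the same epistemic state downstream.

### Depth and detection filters

* `min_proteins = 900` — a sample is kept iff it identifies **at least**
  900 proteins ("fewer than 900" excludes 899, keeps 900 exactly).
* `min_reps = 4` — a protein is kept iff observed in ≥ 4 replicates in at
  least one group; a 4/0 split passes, a 3/3 split fails. "Detected"
  means non-missing after blank subtraction, before imputation.

Both filters are idempotent.

### Normalization and left-censored imputation

Values are log2-transformed and each sample's median is shifted to the
global median of per-sample medians (not to zero, so log2 intensities
remain interpretable). Imputation parameters are estimated **after**
centering and **before** imputation from the pooled observed values
across the whole matrix:

$$\mu_{imp} = \mu_{obs} - 1.8\,\sigma_{obs}, \qquad
  \sigma_{imp} = 0.3\,\sigma_{obs}$$

with $\sigma_{obs}$ using the $n-1$ denominator (immaterial at 10^4–10^5
observations, but fixed for reproducibility). Every missing cell receives
an independent draw from $N(\mu_{imp}, \sigma_{imp}^2)$. Draws are
generated in protein-major traversal from a single seeded stream, so the
result is a pure function of (matrix, parameters, seed). `shift` and
`width` are exposed; 1.8/0.3 are the field-standard downshift defaults. A
global pooled distribution (not per-sample) is the default reading of
"global data distribution"; per-sample imputation is deliberately not a
default because with ~1,500 observations per cell its parameters are
noisy.

### Batch correction

`combat_adjust()` implements the parametric location–scale empirical
Bayes model: sample $j$ in batch $b$ has
$y_{ij} = \alpha_i + X_j \beta_i + \gamma_{bi} + \delta_{bi}
\varepsilon_{ij}$, where $X$ carries the biological condition. The
condition enters the standardization design and is restored unadjusted,
which is what "preserving biological variation via a covariate" means
operationally. Priors: $\gamma_{bi} \sim N(\bar\gamma_b, \tau_b^2)$,
$\delta_{bi}^2 \sim$ inverse-gamma with method-of-moments
hyperparameters; posteriors iterate to absolute tolerance `1e-8` (max
500 iterations, both configurable). The non-parametric variant,
reference-batch mode, and missing-data handling are out of scope (the
matrix is complete by this stage; blanks were consumed earlier).

Numerical edge cases, which the canonical implementation would answer
with `NaN`:

* pooled residual variance is floored at `1e-12`;
* a within-batch standardized variance below `1e-8` — possible only in
  (near-)noiseless inputs — is treated as "no scale effect"
  ($\delta^* = 1$) rather than divided by;
* collapsed priors ($\tau^2 \approx 0$, or all $\hat\delta$ equal) use
  their point-mass posterior limits.

These choices make the exactly-identifiable zero-noise additive case
correct to ~1e-12 instead of failing on rounding noise.

### Differential abundance

Pooled-variance two-tailed Student's $t$ per protein (Welch available by
flag, off by default to keep one canonical path), Benjamini–Hochberg
step-up across the full tested list. Classes: `up` iff $q < 0.05$
(strict) and linear FC $\ge 1.5$ (inclusive); `down` symmetric; zero
pooled variance yields an `unclassifiable` protein rather than a
fabricated p-value. Fold change is computed on the matrix the test sees
(imputed, batch-adjusted log2 values). BH was chosen because the source
convention names only "FDR"; it is the field default and is property-
tested against a literal step-up oracle.

Top-$k$ ($k = 60$) selection orders by $q$, then larger $|log2FC|$, then
protein id — fully deterministic — and rows are clustered by
average-linkage on correlation distance. Group separation is quantified
as the mean silhouette of group labels in the top-2 PCA plane: unlike a
UMAP embedding it is deterministic and testable, and the embedding proper
is a pluggable visualization concern.

### Enrichment

ORA uses the upper-tail hypergeometric $P(X \ge k)$ with $K$ and $k$
counted after intersecting each set with the background population, which
is the post-filter quantified proteome (not the whole-organism
annotation universe — enrichment against proteins that could never have
been observed is anti-conservative). The significance flag mirrors the
conventional raw $p < 0.05$; BH $q$ is reported alongside but not used
for the flag. GO-hierarchy up-propagation is out of scope: sets are taken
as the GMT provides them.

GSEA uses the weighted KS running sum (weight 1 on $|score|$), gene-set
permutation by default — with 12 + 12 cells the phenotype-permutation
space is limited, and gene-set nulls are cheap and smooth — and the
ranking metric is the Student $t$ statistic. NES divides ES by the mean
|null ES| of matching sign; the FDR is the sign-stratified pooled-null
comparison; `p_perm` carries the add-one correction so it can never be
zero. Significance is flagged at FDR < 0.25, the conventional GSEA
screening threshold.

### Network hubs

Maximal cliques are enumerated with pivoting Bron–Kerbosch and reported
in a canonical order (sorted members, lexicographic list), so outputs are
stable across platforms. $MCC(v) = \sum_{C \ni v} (|C|-1)!$ over maximal
cliques $C$ containing $v$; an isolated node owns its singleton maximal
clique and scores $0! = 1$, a convention the plugin literature leaves
implicit and we fix explicitly. For triangle-free graphs MCC reduces to
the degree, which the tests exploit as a closed-form check. Edge scores
are used only for thresholding (`min_score`), not for weighted
centrality. Hub ties break by degree, then node id.

## The synthetic-data generator

`generate_dataset()` draws per-protein baseline abundances
$\mu_i \sim N(\mu_0, \sigma_0^2)$, plants `up`/`down` effects on fixed
fractions of proteins with $|log2FC| \sim U(fc_{lo}, fc_{hi})$, applies
per-(batch, protein) additive shifts $\gamma \sim N(0, sd_\gamma)$ and
residual scales $\delta \sim U$, adds cell noise, and then observes each
value through a Bernoulli detection with logistic probability in the true
log2 intensity — the smooth, tunable operationalization of
left-censoring. Contaminant proteins (a fixed fraction) receive linear
background in blanks *and* cells, so blank subtraction has real signal to
remove. Batches interleave within each group (the real batch layout of
the emulated experiment is unreported; interleaving guarantees
non-confounding). Randomness splits into three fixed streams (protein
parameters, cells, blanks) derived from one seed, so adding blanks never
perturbs cell draws.

Defaults state the emulated world once: 12 cells per group, 3 blanks,
2,500 proteins, 30% up / 5% down (the strongly up-shifted asymmetry the
pipeline targets), $\mu_0 = 19$, $\sigma_0 = 2.2$, $\sigma_{cell} = 0.5$,
detection midpoint 18.5 with scale 1.2 (≈1,500 detected proteins per
cell, matching the ~1,400 typical of the emulated design), batch
$\gamma$ SD 0.4, $\delta \in [0.8, 1.25]$, 8% contaminants at log2 level
15.

What a green test on this generator does **not** establish: peptide- or
ion-level effects (ratio compression, shared peptides), retention-time or
mobility artifacts, correlated protein co-regulation (proteins are
independent given the design), non-normal heavy-tailed cell noise, or
more than two groups. Tests that target stages downstream of censoring
set the detection midpoint to −100 (detection probability 1 to double
precision) so they measure the stage, not the censoring model.

## Known limitations

* The imputation model is single-component global; censoring-aware
  likelihood estimation (e.g. truncated-normal MLE) would be less biased
  when missingness is extreme, and is deliberately out of scope.
* Moderated tests (limma-style shrinkage) would gain power at n = 12 per
  group; the package keeps the plain Student test as the canonical,
  specification-matching path.
* The sign-stratified GSEA FDR is conservative with few terms; with
  strongly signal-laden rankings, uniformly drawn "decoy" sets genuinely
  contain signal and may be flagged — that is correct behaviour, not
  miscalibration (p-value calibration under a null ranking is tested
  separately).
* Clique enumeration is exponential in the worst case; intended inputs
  are DEP subnetworks of at most a few hundred nodes, well within desk
  scale.
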