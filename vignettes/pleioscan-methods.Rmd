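---
title: "Methods: pleiotropy mapping with weighted LOCO mixed models, multi-trait meta-analysis and gene-based Monte Carlo tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pleiotropy mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pleioscan)
```

## The problem

Large-scale genetic evaluations in livestock produce estimated breeding
values (EBVs) rather than raw phenotypes. Deregressed EBVs (dEBVs) behave as
pseudo-phenotypes suitable for genome-wide association, but they come with
heterogeneous reliabilities: a bull with thousands of progeny records carries
far more information than a bull with few. `pleioscan` implements a complete
pipeline for mapping *pleiotropic* loci and genes — variants and genes
affecting several traits at once — from per-trait dEBV tables and dense SNP
genotypes, the situation typical of a beef-cattle (e.g. Nellore) reference
population scored for weight and carcass visual-score traits.

## The single-trait model

For each trait the null model is a weighted polygenic (GBLUP-type) mixed
model

$$y = 1\mu + g + e,\qquad g \sim N(0,\,K\sigma^2_g),\qquad
  e \sim N(0,\,W\sigma^2_e),$$

where $y$ is the vector of dEBVs, $K$ the genomic relationship matrix and
$W = \mathrm{diag}(w)$ accounts for heteroscedastic residuals. The weights
follow the deregression theory:

$$w_i = \lambda^{-1}(d_i + c),\qquad \lambda = \frac{1-h^2}{h^2},\qquad
  d_i = \frac{1-r^2_i}{r^2_i},$$

with $r^2_i$ the record's reliability (squared accuracy), $h^2$ the trait
heritability before deregression, and $c$ a blending constant. The defaults
are $c = 0.5$ and a minimum accuracy of $0.50$ for a record to be retained.

Two interpretation points are deliberate and configurable:

* **Accuracy filter.** The 0.50 threshold is applied to the accuracy
  $r = \sqrt{r^2}$ (i.e. records with $r^2 \ge 0.25$ are kept). The
  alternative reading — thresholding the reliability itself — is available
  via `accuracyFilter(..., on = "reliability")`.
* **Direction of the weight in $h^2$.** Since $\lambda$ decreases with
  $h^2$, $w$ *increases* with $h^2$ at fixed $r^2$ and $c$: records of a
  highly heritable trait get relatively larger residual weight. This follows
  directly from the formula and is asserted by the tests.

### REML and the LOCO scan

Variance components are estimated by restricted maximum likelihood using the
standard one-dimensional trick: transform by $W^{-1/2}$, eigendecompose the
transformed $K$ once, and profile the restricted likelihood over the ratio
$\delta = \sigma^2_g/\sigma^2_e$ only, with $\mu$ and $\sigma^2_e$ in closed
form given $\delta$. The optimiser is `optimize()` on $\log\delta$ over
$[-12, 12]$ with tolerance $10^{-8}$; the no-genetic-variance boundary is
checked explicitly and returned as $\sigma^2_g = 0$ when it dominates.

Single-marker tests are mmscore-type score tests against the fitted
covariance $V = K\sigma^2_g + W\sigma^2_e$:

$$b = (x'V^{-1}x)^{-1}x'V^{-1}y^*,\qquad
  \mathrm{SE}(b) = (x'V^{-1}x)^{-1/2},\qquad t = b/\mathrm{SE}(b),$$

with $y^* = y - 1\hat\mu$ and $x$ the mean-centered, mean-imputed dosage.
Two-sided p-values use the normal distribution (the score test's large-sample
reference). To avoid proximal contamination — the tested marker being partly
absorbed by the random polygenic term — the scan is organised
leave-one-chromosome-out (LOCO): markers on chromosome $j$ are tested
against a null model whose $K$ excludes all chromosome-$j$ markers.

Numerical and design choices:

* **GRM estimator.** VanRaden method 1,
  $K = ZZ'/(2\sum_k p_k(1-p_k))$ with $Z$ mean-imputed and centered by
  $2p_k$; a standardized-marker variant is available
  (`computeGrm(..., method = "standardized")`).
* **Per-fold REML.** Variance components are re-estimated for every LOCO
  fold by default; `gwaLoco(..., perLocoReml = FALSE)` estimates them once
  genome-wide and rebuilds only $\mu$ and $V$ per fold, which is
  substantially cheaper and nearly identical in practice.
* **LOCO matrices in one pass.** `computeLocoGrms()` accumulates
  per-chromosome cross-products and assembles each fold by subtraction; it
  agrees with direct exclusion builds to $10^{-10}$ (not bitwise, because of
  floating-point cancellation).
* **Conditional scans.** `conditionalScan()` projects both $y$ and each
  tested $x$ onto the $V$-orthogonal complement of the intercept and the
  fixed dosages, which is GLS-correct covariate adjustment; fixed markers
  are reported flagged with $p = 1$ and collinear covariates are dropped
  with a warning.

## Multi-trait meta-analysis

For each marker, the signed $t$-values across the $q$ traits are combined as
$t'C^{-1}t$, referred to $\chi^2_q$. $C$ is the correlation matrix of
$t$-values across all genome-wide markers — a cheap, data-driven proxy for
the correlation of marker effects under overlapping polygenic architectures.
Assuming unit diagonal overstates significance when some traits are, on
average, more correlated than others, so each diagonal element is inflated
to $1 + \bar r_i$, where $\bar r_i$ is the signed mean of trait $i$'s
off-diagonal row (`diagMode = "absolute"` switches to absolute values). The
correction makes the statistic conservative under the null — the package
asserts empirically that its mean falls below $q$ under
$t \sim N(0, C_{\mathrm{raw}})$.

The significance threshold is chosen by the empirical FDR rule: sort the
p-values, let $s$ be the largest rank $i$ with $p_{(i)} \le f i/m$
($f = 0.05$), and declare significant all $p < \alpha = fs/m$ (strict
inequality; ties exactly at $\alpha$ are excluded). This is the familiar
step-up construction; the test suite checks its rejection set against
`p.adjust(..., "BH")` away from the boundary.

$C$ is computed on all markers passing QC (no LD pruning), with markers
flagged in any trait dropped complete-case.

## Gene-based (VEGAS-style) tests and the pleiotropy call

Per trait and gene: the gene interval is expanded by $\pm$100 kb (floored at
position 1, both ends inclusive), member markers are collected, and the gene
statistic is the sum of squared $t$-values over a *pruned* member subset in
which all pairwise squared dosage correlations are $\le 0.5$ — pruning both
de-duplicates the signal and guarantees a well-conditioned correlation
matrix $D$ for the null. Significance comes from adaptive Monte Carlo:
draw $z \sim \mathrm{MVN}(0, D)$, compare $\sum z^2$ with the observed
statistic, starting at $k = 10^3$ draws and escalating tenfold (reusing all
draws) whenever the current $p$ estimate falls below $1/k$, capped at
$10^6$; a statistic never reached is reported as $p = 10^{-6}$ with an
explicit `censored` flag rather than a fabricated smaller value. Genes with
no markers get $p = 1$.

* **Pruning.** Selecting a maximum subset under pairwise constraints is a
  maximum-clique-type problem. For $\le$15 candidates an exhaustive search
  returns the true maximum (ties resolved towards lower marker indices);
  larger sets use a deterministic greedy rule (ascending violation count,
  ties by index) whose output always satisfies the constraint and, on random
  instances, falls at most one marker short of the brute-force optimum.
* **Reproducible parallel structure.** Each (gene, trait) pair derives its
  own 32-bit sub-seed from the global seed, so scans are reproducible
  regardless of evaluation order.
* **Repair.** If $D$ is not positive definite despite pruning, eigenvalues
  are clipped at $10^{-8}$ and the matrix rescaled to unit diagonal; failure
  after repair is an error naming the gene.

A gene is *listed* for a trait when its gene p-value is below 0.01 (strict);
genes listed for at least 4 of the 9 traits are pleiotropy candidates.
Exclusion rules (specific gene ids, or whole chromosomes with named
exceptions, as one does for a dominant LD block around a lead gene) are
user-supplied inputs, never hard-coded gene lists.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes, at
desk scale, so everything runs end to end with no external data:

* **Genotypes.** LD-blocked biallelic dosages from a haplotype-copy model:
  within a block each marker copies the previous marker's allele on the same
  haplotype with probability `withinBlockR`, else redraws at the block's
  allele frequency (uniform over `mafRange`). Copying preserves margins, so
  the expected adjacent-marker dosage correlation *equals* `withinBlockR` —
  no threshold-attenuation calibration is needed, which is why this scheme
  was preferred over a latent Gaussian autoregression. Blocks are
  independent; positions step by 1–10 kb; entries are masked at
  `missingRate`.
* **Traits.** True breeding values are a scaled sum of a shared-QTL part
  (dosages of `nQtl` markers times a $q \times n_{qtl}$ effect matrix,
  jointly scaled to `qtlVarFrac` of the genetic variance) and polygenic
  backgrounds correlated across traits at `bgCorr` through a shared marker
  effect component. dEBVs add per-record noise with variance
  $\mathrm{var}(TBV)(1-r^2_i)/r^2_i$ for a reliability drawn uniformly from
  `reliabilityRange`, so $\mathrm{cor}(\mathrm{dEBV}, TBV)^2 \to r^2$.
* **Defaults as study conditions.** $n = 1000$ individuals, $20{,}000$
  markers on 29 autosomes, nine traits with heritabilities
  $(0.37, 0.26, 0.25, 0.25, 0.26, 0.33, 0.31, 0.31, 0.30)$, three QTLs each
  affecting $\ge 5$ traits with mixed signs, reliabilities in
  $(0.15, 0.95)$ so the 0.50 accuracy filter is genuinely exercised, and
  `bgCorr = 0.75`, which yields mean cross-trait TBV correlations near 0.55
  and mean post-filter dEBV correlations near 0.33 — the "moderate"
  magnitude regime the method targets. Exact matching of any particular
  published correlation matrix is not attempted.
* **What is not emulated.** Maternal effects, contemporary groups, selection,
  real LD decay beyond block boundaries, and the deregression procedure
  itself (dEBVs are generated directly from their definition). Passing tests
  therefore demonstrate correctness of the *statistical machinery* under a
  clean generative model, not robustness to every artefact of field data.

## Problem sizes used by the test suite

Simulation-based checks are sized to finish in minutes while leaving clear
statistical margins:

* Null calibration of the LOCO scan: $n = 300$, $20{,}000$ independent
  markers on 10 chromosomes, pure-noise dEBVs (a polygenic-only trait is
  *not* marker-wise null under LOCO, because the tested chromosome's
  polygenic effects are excluded from $K$); Kolmogorov–Smirnov test against
  the standard normal and a type-I error band at $\alpha = 0.05$.
* REML recovery: one $1000 \times 1500$ genotype panel, 50 phenotype
  replicates at true ratio 0.4, tolerance $\pm 0.05$ on the mean.
* Pleiotropy recovery: 20 replicates of $n = 400$, $3000$ markers on six
  chromosomes, with one common (MAF $\ge 0.2$) QTL placed inside an
  annotated gene and affecting five of nine traits at `qtlVarFrac = 0.25`;
  success requires the QTL to top the meta-analysis scan *and* its host gene
  to be listed ($p < 0.01$) for $\ge 4$ traits.
* Gene-test calibration: 200 genes scanned on a null trait; Monte Carlo
  p-values for closed-form cases ($\chi^2_1$ tail at stat 4, $\chi^2_2$ at
  5.99) within three binomial standard errors.

## Known limitations

* The score test's normal reference and the $\chi^2_q$ reference for the
  meta statistic are large-sample approximations; at very small $n$ they are
  anticonservative.
* The $t$-value correlation matrix is a proxy for effect correlation; with
  very few markers it is noisy, and the diagonal correction is empirical —
  its exact null distribution is not derived, only its conservativeness is
  verified by simulation.
* The greedy pruning rule is near-optimal but not guaranteed maximal beyond
  the exhaustive-search size.
* The Monte Carlo p-value floor of $10^{-6}$ bounds the resolution of
  gene-level significance; the `censored` flag marks affected genes.
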