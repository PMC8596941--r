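---
title: "Methods: from allele dosages to brain/behavior associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from allele dosages to brain/behavior associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsvbm)
```

## What the package computes

`prsvbm` implements a common imaging-genetics inferential chain as
reusable, tested components:

1. **Polygenic risk score (PRS).** For subject $s$ with effect-allele
   dosages $P_{si} \in [0,2]$ at $m$ risk loci and source-GWAS odds
   ratios $\mathrm{OR}_i$,
   $$\mathrm{PRS}_s = \sum_{i=1}^{m} w_i \, P_{si}, \qquad
     w_i = \ln \mathrm{OR}_i .$$
   The "effect allele" is the allele the odds ratio refers to, not the
   genome-assembly REF base; when a VCF stores the ALT dosage for the
   opposite allele the dosage is reoriented as $2 - \mathrm{DS}$, and
   genotype probabilities are collapsed to a dosage as
   $0\,P(\text{hom-other}) + 1\,P(\text{het}) + 2\,P(\text{hom-effect})$.

2. **Population-stratification PCs.** Variant columns are centered and
   scaled (sample SD, denominator $n-1$); the genetic relationship
   matrix is $G = XX^\top/m$ and the top $K$ (default 6) unit-norm
   eigenvectors enter all downstream regressions as covariates.

3. **Behavioral association inference.** Each outcome is regressed on
   intercept, sex, age, PC1..PCK and the score. The score coefficient's
   two-sided p-value comes from Freedman–Lane permutation (default
   $B = 5000$): residuals of the covariates-only fit are permuted,
   reduced-model fitted values are added back, and the full model is
   refit. $p = \max(\#\{|t^*_b| \ge |t_{obs}|\}/B,\ 1/B)$; the floor
   $1/B$ is what a permutation scheme can resolve (0.0002 at
   $B = 5000$). Across outcomes, p-values are adjusted by the
   two-stage sharpened FDR procedure (below).

4. **Voxelwise mapping.** The same regression runs at every voxel of a
   subject-aligned volume stack inside an intensity mask (voxel kept iff
   every subject exceeds 0.05). Family-wise error is controlled by
   max-T permutation: the same Freedman–Lane permutation schedule is
   applied at all voxels, the map-wide maximum t (per direction) is
   recorded per permutation, and
   $p_{FWE}(v) = \max(\#\{ \max_b t^* \ge t_{obs}(v)\}/B,\ 1/B)$.
   Cluster extent is reported at an uncorrected one-sided threshold
   (default $p < .001$ at the model's residual df) with connected-
   component labeling (6/18/26-connectivity, default 18).

## Two-stage sharpened FDR

The Benjamini–Krieger–Yekutieli two-stage procedure at level $q$:

* Stage 1: Benjamini–Hochberg step-up at $q' = q/(1+q)$; let $r_1$ be
  the rejection count and $\hat m_0 = \max(m - r_1, 1)$ the estimated
  number of true nulls (floored so that a stage 1 that rejects
  everything cannot zero out stage 2).
* Stage 2 in adjusted-p form:
  $p^{adj}_i = \min\!\bigl(1,\ \mathrm{BH}(p_i)\,
  \tfrac{\hat m_0}{m}\,(1+q)\bigr)$, where $\mathrm{BH}$ is the usual
  step-up adjusted p-value.

The sharpening factor $\hat m_0 (1+q) / m$ is a constant across the
set, so the adjusted values stay order-isomorphic to BH wherever the
cap at 1 does not bind (a tested invariant; the BH inner step is
cross-checked against `stats::p.adjust` in the suite). For display the
package rounds **half away from zero** to 3 decimals, the convention
needed to print, e.g., 0.0385 as 0.039.

## Permutation details and numerical choices

* **Scheme.** Freedman–Lane is the default because the tested
  coefficient sits in a model with covariates and permuting reduced-
  model residuals preserves the covariate structure under the null;
  permuting the raw outcome (`scheme = "raw_y"`) is available for
  comparison.
* **Shared schedule.** `make_permutations(n, B, seed)` is the single
  source of permutations for both the behavioral test and max-T, so a
  one-voxel mask reproduces the one-sided behavioral permutation p
  exactly (tested).
* **p floor.** Empirical p-values are `count/B` floored at `1/B`, not
  `(count+1)/(B+1)`: the floor convention matches reporting permutation
  resolution as once-in-B.
* **Tie tolerance.** The identity permutation reproduces the observed
  statistic only up to floating-point reassociation; counting uses a
  relative slack of `1e-8` so empirical and enumerated p-values agree
  exactly (tested against an `lm`-refit enumeration oracle at
  $n \le 6$).
* **Degenerate fits.** A voxel/outcome fully explained by covariates
  alone (or constant) carries no score information and gets $t = 0$; an
  outcome explained exactly by the score would have $t = \infty$ and is
  reported as a large finite sentinel (1e15).
* **PCA route.** With $m < n$ the eigendecomposition of $G$ is computed
  through the dual $m \times m$ matrix $X^\top X/m$ and lifted,
  $u_j = X v_j / \sqrt{m\lambda_j}$ — algebraically identical (tested
  against the direct $n \times n$ eigendecomposition and against the
  SVD) and $O(nm^2)$ instead of $O(n^3)$. Component signs follow the
  convention that each column's largest-magnitude entry is positive.
* **Boundary rule.** Significance uses strict $p_{FWE} < .05$ by
  default but the rule is exposed (`strict`), since published tables
  sometimes print a boundary value like .050 as significant after
  rounding.

## The synthetic world

The generator states one default world and the tests measure it; its
parameters were chosen once, from the emulated study design, and are
not tuned to outcomes:

* **Sample.** 1,558 subjects (899 coded male), age uniform on [18, 27].
* **Genotypes.** 24 risk loci; odds ratios uniform on [1.05, 1.25], the
  magnitude range typical of genome-wide-significant loci for a highly
  polygenic psychiatric phenotype; hard calls binomial$(2, f)$ blurred
  by truncated Gaussian noise (sd 0.05) to emulate imputation dosages.
* **Structure.** Two equal subpopulations whose per-variant frequencies
  are drawn independently from [0.1, 0.9]. Draws being independent
  across populations gives strong, PCA-detectable differentiation while
  keeping the *direction* of each variant's difference random — with
  systematically directional differences (e.g. disjoint ranges for all
  loci) the all-positive-weight score degenerates into a population
  indicator and the PCs rightly absorb nearly all of its variance,
  which is a confound demonstration, not a usable test world. Disjoint
  ranges are still used in targeted PCA-recovery tests.
* **Phenotypes.** 14 outcomes named after a cognitive/mood battery;
  each is `beta_prs * z(score) + 0.2*sex + 0.05*z(age) + N(0, 1)` with
  optional MCAR missingness (reproducing per-outcome n variation under
  casewise deletion). `beta_prs` defaults to 0 (null world).
* **Volumes.** Baseline 1 plus Gaussian noise smoothed at 8 mm FWHM
  (20×20×20 voxels at 3 mm; $\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$,
  separable convolution, edge-renormalized kernel). A *point* effect
  `beta_voxel * z(score)` is added at the planted voxels after
  smoothing. Planted-effect worlds use a larger baseline (e.g. 2–3) so
  that negative score tails cannot push the planted voxel below the
  mask threshold — the generator's contract is that in-brain
  intensities stay above it.

What a green test does *not* establish: the generator has no linkage
disequilibrium, no admixture gradients, no genotype-calling error
model, no anatomy, and point (unsmoothed) voxel effects — so passing
recovery tests shows the inferential chain is correct, not that it is
robust to the messiness of real imaging-genetics data.

## Scaled-down calibration scales

The calibration suites run at reduced scale to stay within desk-time
budgets, stated here so the numbers are interpretable: type-I error
uses 500 replicate null datasets at $B = 200$ (band [.03, .07] around
the nominal .05); FWER uses 200 replicate 15×15×15 null stacks of 100
subjects at $B = 500$ (band [.02, .08]); recovery uses 50 seeds. The
production defaults remain $B = 5000$.

## Known limitations

* The permutation p floor makes p-values at `1/B` ties; at small $B$
  the null distribution is visibly discrete.
* Max-T controls FWE at voxel level only; cluster-level corrected
  p-values and TFCE are out of scope.
* The NIfTI-1 codec covers the subset this package writes and reads
  (single-file `.nii`, float32/float64/int16/uint8, sform affine);
  it is not a general NIfTI implementation.
* Missing dosages are scored over observed variants without rescaling
  (with a per-subject missing count emitted); no imputation of missing
  genotype or phenotype data is attempted.
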