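---
title: "Methods: two-cohort kidney cis-eQTL mapping, colocalisation and MR"
author: "nephroQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cohort kidney cis-eQTL mapping, colocalisation and MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroQTL)
```

# The statistical model

The package estimates, for every gene *g* and every SNP *v* within 1 Mb of
the nearest gene boundary, the linear model

$$ y_{g} = \alpha + \beta_{gv}\, d_v + \mathbf{C}\gamma + \varepsilon $$

where $y_g$ is the normalised (rank-based inverse-normal transformed)
expression of the gene, $d_v$ the genotype dosage in $[0,2]$, and
$\mathbf{C}$ the covariates: age, sex, the top three genotype principal
components, hidden expression factors and any cohort indicators. Each of
two cohorts is analysed separately; per-pair estimates are pooled with
fixed-effect inverse-variance weights
($w_k = 1/\mathrm{se}_k^2$, $\hat\beta = \sum w_k \hat\beta_k / \sum w_k$,
$\mathrm{se} = 1/\sqrt{\sum w_k}$), and genes measured in only one cohort
carry that cohort's estimate through unchanged. Per-study p-values use the
t reference at residual degrees of freedom; the meta p-value uses the
normal reference of the pooled z. An alternative reading of the
meta-analysis — combining z-scores rather than betas — exists; we pool
betas because the inverse-variance weights are defined on the effect
scale, and document the choice here.

Gene-level significance is calibrated by permutation. At each of
$B = 2000$ iterations one random permutation of sample labels is applied
*jointly* to the expression matrix and the non-genetic covariates, while
genotypes and genotype PCs keep their original order (the PCs are a
function of the genotypes and must stay with them). The full two-cohort
regression and meta chain is re-run and the smallest meta-P per gene
recorded, giving each gene's empirical null cdf $F_i$. The observed
smallest meta-P is converted to an adjusted p with the pseudocount
convention $(1+\#\{\text{null} \le \text{obs}\})/(B+1)$, which keeps
adjusted p strictly positive and makes its null distribution uniform on
the grid $\{1/(B{+}1), \dots, 1\}$. Storey q-values (smoother-estimated
$\pi_0$, df-3 spline over $\lambda \in \{0.05,\dots,0.95\}$) define
eGenes at $q<0.05$; with fewer than 100 genes the smoother is unreliable
and $\pi_0$ falls back to 1, in which case q-values equal
Benjamini–Hochberg adjusted p. The genome-wide threshold $P_t$ is the
adjusted p of the gene whose q is closest to 5% (ties resolved toward the
smaller adjusted p), and per-gene nominal thresholds are the
left-continuous empirical-quantile inversion
$P_{t,i} = F_i^{-1}(P_t)$ — the smallest null value $x$ with
$F_i(x)\ge P_t$. A nearly-equivalent chain in the literature approximates
$F_i$ with a fitted Beta distribution; we keep the raw empirical
inversion because it is the form actually defined by the printed
formula and is exactly testable against order statistics.

## Batched regression

Scanning all cis pairs per permutation would be infeasible pair-by-pair.
We use the Frisch–Waugh–Lovell decomposition: the covariate design (with
intercept) is orthonormalised once per permutation, expression and dosage
matrices are residualised against it, and per-pair beta, se, t and p are
recovered from residual cross-products with the correct residual degrees
of freedom ($n - q_{\text{cov}} - 2$). This is *identical* to per-pair
OLS — the test suite verifies agreement to $10^{-10}$ — not an
approximation.

# Normalisation chain

Four steps, in a fixed order enforced by the `ExpressionMatrix` stage
tag (`tpm → log → qnorm → rbint`):

1. $\log_2(\mathrm{TPM}+1)$;
2. quantile normalisation across samples whose target distribution is
   the per-rank **median** (not mean) of the sample-sorted values — the
   "robust" variant; ties receive average ranks and interpolated
   targets;
3. per-gene outlier imputation: a Huber robust regression (tuning 1.345)
   of the gene on the known covariates (intercept-only when none are
   supplied; the regressor set is configurable because the original
   description does not pin it down), residuals beyond
   $Q_1 - 3\,\mathrm{IQR}$ or $Q_3 + 3\,\mathrm{IQR}$ flagged, the model
   refitted without them and flagged values replaced by fitted values;
4. per-gene rank-based inverse normal transform with Blom offsets,
   $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, average ranks for ties
   (so tied inputs stay tied) and an all-zero output with a warning for
   zero-variance genes. The offset is configurable; Blom is the common
   default where the source method names only "rank-based inverse normal
   transformation".

A subtlety worth recording: sample exchangeability (identical sorted
value vectors in every sample) holds exactly **after step 2**. The
per-gene transform of step 4 re-ranks values within genes, so sample
sorted vectors afterwards agree only up to the tie structure — the test
suite asserts the property at the stage where it is a theorem.

Hidden expression factors are the top principal components of the
expression matrix after projecting out known covariates — a deliberate
PCA surrogate playing the adjustment role of PEER-style latent factors,
whose variational model is out of scope. For transcriptome-wide matrices
the conventional sample-size tiering applies (15 factors under 150
samples, 30 up to 250, 45 above; `defaultHiddenFactorK()`). On the small
synthetic panels the pipeline caps the factor count at a quarter of the
gene count: factor counts approaching the gene count absorb the cis
signal itself, which is a dimensioning artefact of small simulations,
not a property of real data.

# QC filters

Variant filters (first failing rule wins, itemised in the `QcReport`):
duplicated (chrom, pos); non-SNP alleles; sex/MT chromosomes; call rate
< 95%; imputation $R^2 < 0.4$ (imputed panels); MAF < 5%; Hardy–Weinberg
exact p below the caller's threshold — 0.001 for genotyped panels,
$10^{-6}$ for imputed ones. The HWE test is the exact conditional test
(sum of probabilities of heterozygote counts no more probable than the
observed one, given the allele counts); whether the genotyped-panel
filter was originally exact or chi-square is not recoverable, so the
statistic is configurable (`hwe_test = "chisq"`), with exact as the
default matching the standard toolchain convention. Sample filters:
missingness > 5%, heterozygosity rate beyond ±3 SD, plus a caller-supplied
exclusion list for relatedness/ancestry/sex checks, which this package
does not compute. The gene filter keeps a gene only if TPM > 0.1
(strictly) in at least 50% of the samples of **every** batch.

# The synthetic two-cohort generator

`simulateCohorts()` draws a variant panel shared by both cohorts (the
panel is fixed by the config seed; per-cohort seeds only move the
samples): LD blocks of SNPs whose haplotypes come from a latent
multivariate Gaussian with compound-symmetric correlation $r$ thresholded
at each variant's allele frequency (a Gaussian copula). Two independent
haplotypes per sample guarantee Hardy–Weinberg proportions by
construction. The realised dosage correlation is the thresholded-Gaussian
attenuation of the latent $r$ (at MAF 0.5 it is exactly
$\tfrac{2}{\pi}\arcsin r$, which the tests use as a closed-form oracle);
`within_block_r` is therefore the *latent* correlation dial, not the
realised $r^2$. Genes sit one per block, 3 Mb apart, so the 1 Mb cis
window of a gene covers exactly its own block's SNPs — ground truth for
recovery scoring is unambiguous.

Expression is built on a latent log2 scale — planted beta · dosage for
eGenes, age and sex effects, sparse loadings on i.i.d. standard-normal
hidden factors, Gaussian noise — and reported as TPM $= 2^{\text{latent}}$,
so `log2(TPM)` recovers the planted coefficients exactly while the full
TPM normalisation chain still has real work to do. Defaults mirror the
two-cohort design the package targets: cohorts of 180 and 100, MAF
uniform on [0.05, 0.5] (the post-QC range), residual SD 1, effect-size
SD 0.5 (typical planted effects of half an expression SD per allele),
three hidden factors, and an optional between-study jitter of the
planted betas to exercise heterogeneity.

Trait scenarios: *shared* drives a quantitative trait through the
expression of the strongest planted eGene (trait and expression share
one causal SNP); *distinct* drives it through a second SNP of the same
block with $r^2 < 0.2$ to the eQTL SNP (an error if the LD structure
cannot supply one); *null* is pure noise. GWAS summary statistics are
per-SNP trait-on-dosage regressions. MR summary sets draw true exposure
effects uniform on [0.1, 0.5], add directional pleiotropy
$\alpha_j \sim N(\mu, \sigma^2)$ on a configurable invalid fraction, and
retain $\theta$ in the attached metadata.

What the generator does **not** emulate: realistic recombination maps
(LD is block-constant), population structure and admixture, read-level
noise or mapping artefacts, non-Gaussian expression error, and
case–control ascertainment. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under its stated
assumptions — not that those assumptions hold in any particular real
cohort.

# Colocalisation (RTC)

Within a user-supplied interval (recombination coldspots in production
use; the synthetic blocks in tests), the expression of the eGene is
regressed on the GWAS SNP and the residual "pseudo-phenotype" is
re-tested against each of the $N$ interval SNPs. SNPs are ranked by
descending p (highest p → rank 0) and the score is $(N-\text{rank})/N$
at the eQTL SNP; ≥ 0.9 calls colocalisation (inclusive). Two published
formulations of RTC exist — residualise on the GWAS SNP and rank all
interval SNPs (used here), or residualise on each interval SNP in turn —
and we implement the former as the package's default because it is the
form the score definition above describes. Covariates enter both
regressions by default (`covariates = NULL` reduces to the GWAS-SNP-only
form). Ties in p receive average ranks; ties are measure-zero on real
data but common on toy examples.

# Mendelian randomisation

Instruments are selected greedily: order by ascending eQTL p, keep while
$p < 0.08$ and $r^2 < 0.2$ against every kept SNP. The unusual-looking
0.08 is deliberate and configurable. Harmonisation aligns the outcome
beta to the exposure effect allele (sign flip on swaps, complement on
strand flips) and drops palindromic A/T and C/G SNPs by default.

The three estimators:

* **robust IVW** — zero-intercept regression of $\beta_Y$ on $\beta_X$
  with weights $1/\mathrm{se}_Y^2$, fitted by MM-estimation with Tukey's
  bisquare (tuning 4.685). "Robust" is operationalised as MM/bisquare —
  the convention of the established MR software family. A closed-form
  plain IVW is kept as the reference implementation and oracle.
* **penalised weighted median** — ratio estimates
  $\theta_j = \beta_{Yj}/\beta_{Xj}$ with weights
  $w_j = \beta_{Xj}^2/\mathrm{se}_{Yj}^2$ multiplied by
  $\min(1,\, 20\,\Pr(\chi^2_1 > Q_j))$, $Q_j$ the instrument's
  contribution to Cochran's Q at the plain-IVW estimate (the published
  penalisation constant 20, configurable); the estimate interpolates the
  cumulative-weight percentile function at 0.5; the standard error comes
  from a seeded parametric bootstrap (2000 resamples by default —
  analysis-scale simulations pass a smaller count explicitly when only
  point estimates are needed).
* **robust MR-Egger** — as robust IVW but with an intercept and inputs
  orientated so $\beta_X \ge 0$; the intercept estimates directional
  pleiotropy, and at least three instruments are required.

First-order weights are used throughout (se of the exposure ignored in
the weights), the standard two-sample practice. Degenerate exact-fit
instrument sets (zero residual scale, where MM estimation is undefined)
fall back to weighted least squares, and zero standard errors are
reported as p = 0. Sensitivity: Cochran's
$Q = \sum w_j(\theta_j - \hat\theta)^2$ with $\chi^2_{J-1}$ reference
and the Egger intercept test. A gene is called causal when at least two
of the three estimators are significant at the Bonferroni family level
$\alpha/m$ (m = 7 for the eGene family, 11 for the isoform family in the
motivating use case).

# Expression–phenotype meta-analysis

Case–control studies contribute signed z-scores (from the study p-value
and the direction of the log2 fold difference) combined by Stouffer's
weighted Z with $w_k = \sqrt{n_k}$; the original description of the
weighting ("sample size and the binomial distribution of P values") is
ambiguous, so the standard signed-z construction is the documented
default. Correlation studies are de-biased with the Olkin–Pratt
correction $G_k = r_k\big(1 + (1-r_k^2)/(2(n_k-3))\big)$ and pooled with
fixed-effect weights $n_k - 1$ (configurable to $n_k-3$; the source
prints no weights). Significance requires both $p < \alpha/m$ and no
detected heterogeneity (Cochran's Q p ≥ 0.05, on the Fisher-z scale for
correlations).

# Numerical choices and degenerate inputs

* Exact relations (se = 0) report p = 0 rather than NaN.
* Constant dosages and collinear covariate sets are skipped with a
  logged reason, never silently dropped.
* An empty post-QC panel is a warning-bearing empty result, not a crash.
* Matched-SNP tolerances are relative
  ($|x-x_0|/x_0 \le$ tol, 10% for MAF, 50% for LD buddies, gene density,
  distance); candidates with no eligible match are skipped and counted.
  The enrichment p pools the matched sets into one 2×2 Fisher table
  (fold = observed / mean null count); an empirical rank p over the null
  counts is available, since the original test's exact construction over
  100 sets is not recoverable.
* BED intervals are 0-based half-open, variant and gene coordinates
  1-based inclusive; every conversion lives in the I/O layer
  (`readBedTrack()`), and a SNP at 1-based position $p$ hits $[s,e)$ iff
  $s \le p-1 < e$.
* All RNG flows from explicit seeds; reruns of the pipeline with one
  config are byte-identical (the manifest records md5 hashes of every
  artefact).

# Problem sizes used by the test suite

The suite exercises the machinery at sizes chosen to make Monte-Carlo
assertions sharp yet quick: null calibration of eGene calling at 200
genes × 5 cis SNPs, two cohorts of 180 + 100, B = 2000 permutations;
effect recovery at n = 280, MAF 0.3, 200 replicates per planted beta
(nominal 95% CI coverage is asserted at ≥ 93%, three binomial standard
deviations below nominal for 200 replicates); RTC discrimination at 100
replicates per scenario (12-SNP intervals, 250 samples); MR recovery at
30 instruments × 500 replicates. The Fisher engine is compared to a
hypergeometric enumeration oracle over every 2×2 table with total
n ≤ 30.

# Known limitations

* The permutation engine assumes the two cohorts share the variant
  panel and cis-pair list; partially overlapping panels are handled by
  intersection, not imputation.
* Storey's smoother needs a few hundred genes to estimate $\pi_0$
  stably; below 100 genes q-values are BH, which is conservative.
* The copula LD model cannot target an exact realised $r^2$; tests that
  need a specific LD value construct haplotype tables directly.
* RTC inherits the single-causal-variant logic of its score; intervals
  with several independent signals dilute the ranking.
* The expression–phenotype meta-analysis consumes per-study summary
  rows; it does not fetch or re-process any external database.
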