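---
title: "Gene-based mapping and pathway enrichment: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based mapping and pathway enrichment: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Complex metabolic traits — blood metabolites such as non-esterified fatty
acids (NEFA), beta-hydroxybutyrate (BHBA) and glucose in dairy cows around
calving — are typically shaped by many variants of small effect acting
jointly within genes and pathways.  Per-SNP association scans (single-marker
analysis, SMA) pay a heavy multiple-testing price across hundreds of
thousands of markers and ignore the joint action of SNPs in linkage
disequilibrium (LD).  `gwaspath` implements the alternative two-level
strategy: a **gene-based score test** that aggregates all SNPs mapped to a
gene into one statistic, followed by **permutation-calibrated gene-set
enrichment** of the resulting gene ranking against pathway annotations.

# The statistical model

For a phenotype vector $y$ of $n$ animals and the $n \times m$ dosage matrix
$X \in \{0,1,2\}^{n\times m}$ of a gene's SNPs, the working model is the
linear regression

$$ y = Z\theta + X\beta + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2 I_n), $$

with $Z$ an $n\times(k+1)$ covariate matrix (intercept, group indicators,
stratification components).  The gene-level null hypothesis is
$H_0\colon \beta = 0$; $\theta$ is a nuisance removed by projection and never
reported.

## The SSU score test

With $P_Z = Z(Z^tZ)^{-1}Z^t$ and the maximum-likelihood null scale
$\hat\sigma^2 = \tfrac1n (y - P_Z y)^t (y - P_Z y)$, the covariate-adjusted
score vector and its covariance are

$$ U = \frac{1}{\hat\sigma} X^t (y - P_Z y), \qquad
   C = (X - P_Z X)^t (X - P_Z X). $$

The test statistic is the **sum of squared standardized scores**

$$ \mathrm{SSU} = U^t\, \mathrm{Diag}(C)^{-1}\, U, $$

which weights each SNP by the inverse of its own projected variance rather
than by the full inverse covariance $C^{-1}$ of the classic score statistic.
This keeps the statistic stable for large, strongly collinear SNP blocks and
has repeatedly been found more powerful on genetic data, particularly in the
presence of SNP interactions.  Projections are applied through a QR
decomposition; the explicit inverse $(Z^tZ)^{-1}$ is never formed.

## The null distribution: cumulant-matched chi-square

Under $H_0$, $U \mathrel{\dot\sim} N(0, C)$, so SSU is a quadratic form
$\sum_i \lambda_i z_i^2$ with $\lambda_i$ the eigenvalues of
$\mathrm{Diag}(C)^{-1/2}\, C\, \mathrm{Diag}(C)^{-1/2}$ and $z_i$ i.i.d.
standard normal.  `chi2_quadform_pvalue()` matches the first three cumulants
$c_k = \sum_i \lambda_i^k$ to a scaled, shifted chi-square: with
$a = c_3/c_2$, $b = c_1 - c_2^2/c_3$ and $d = c_2^3/c_3^2$, the p-value is
the upper $\chi^2_d$ tail at $(q-b)/a$.  When the spectrum is numerically
degenerate ($c_3 \le 10^{-12}$) the two-moment Satterthwaite match (scale
$c_2/c_1$, df $c_1^2/c_2$) is used.  Negative round-off eigenvalues are
clipped at zero; SNP columns constant after projection
($C_{ii} \le 10^{-10}$) are dropped and counted per gene.

The plug-in approximation treats $\hat\sigma$ as known.  Its adequacy at the
cohort sizes targeted here ($n \approx 244$) is verified empirically: the
test suite measures the type-I error over 1000 simulated null genes (sizes
1–25 SNPs, LD $\rho \in \{0, 0.5, 0.9\}$) and requires it to sit within
$0.05 \pm 0.02$ at $\alpha = 0.05$.  A phenotype-permutation p-value
(`ssu_permutation_pvalue()`, add-one corrected) is exposed as the exact
alternative and is required to agree with the asymptotic p within $\pm 0.02$
on the calibration range $p \in [0.01, 0.5]$.  Permutation of raw phenotypes
is the default; residual permutation is available by flag for designs where
covariates are strongly confounded with genotype.

## Population stratification

Genotype PCA standardizes each SNP column by its binomial standard deviation
$\sqrt{\hat p(1-\hat p)}$ and eigendecomposes the sample-by-sample covariance.
The number of components carrying real structure is decided by the
**Tracy-Widom test** in the Patterson formulation: sequentially from the top,
the leading remaining eigenvalue is centered and scaled with constants built
from an effective marker number estimated from the remaining spectrum's
moments, compared to tabulated TW1 critical values (default
$\alpha = 0.01$), stopping at the first non-significant component.
Null calibration (no structure) and power (two groups at $F_{st} = 0.1$)
are both exercised in the tests.

The covariate matrix mirrors the stratified design of the motivating study:
the PCA is run **within the larger breed group only**, and component columns
carry those scores with exact zeros for the other group:
$Z = (1_n, I_{G1}, PC_2, \dots, PC_{17})$ in the original 17-component
design — note the deliberate exclusion of component 1, and the extended
variant $Z^* = (1_n, I_E, I_{G1}, PC_1, \dots, PC_{17})$ with a study-origin
indicator.  Both layouts are reproduced verbatim by
`build_covariate_matrix()`; the zero-padded subgroup components are unusual
but are part of the published design, so they are kept rather than
"corrected".  Why component 1 appears in $Z^*$ but not $Z$ is not explained
in the source design; both variants are provided and the default follows
$Z$.

## Multiple testing

`bonferroni_threshold()` returns $\alpha/m$ and $-\log_{10}(\alpha/m)$;
`bh_select()` implements the Benjamini-Hochberg step-up on raw p-values
(largest $k$ with $p_{(k)} \le kq/m$; ties selected together), which
guarantees the printed inequality $\alpha' m / R(\alpha') \le q$.  Adjusted
p-values from `stats::p.adjust` are emitted alongside for convenience and
cross-checked in the tests.

## Pathway enrichment

Genes are ranked by $r(g) = -\log_{10} p_g$ from the gene-based test
(joint mode: $r(g) = -\log_{10}(p_1 p_2 p_3)$ across the three metabolites,
which is exactly the sum of the single-trait metrics).  Ties are broken by
genomic position, stably, so rankings are reproducible.  Two set statistics
are computed per pathway $S$ against the ranked list $L$ of $N$ tested
genes:

* **Weighted Kolmogorov-Smirnov enrichment score (WKST).**  A running sum
  starts at 0, increases by $r_i / \sum_{g \in S} r_g$ at members and
  decreases by $1/(N - N_S)$ at non-members; ES is the running-sum value of
  maximal absolute deviation (sign preserved).  Increments and decrements
  each total 1, so the walk provably ends at 0 — asserted to $10^{-12}$ on
  every call path.  If all member metrics are zero (every member at
  $p = 1$), the increments fall back to equal weights $1/N_S$; in that
  degenerate case the location of the maximal deviation can tie to the last
  ulp and the ES sign is arbitrary.
* **Wilcoxon rank-sum statistic (WRST).**  The sum of member positions in
  $L$; small values mean concentration at the top.

Significance comes from **phenotype permutation**: each permutation reruns
the full gene-based test on the shuffled phenotype, re-ranks all genes and
recomputes both statistics for every pathway.  One shared permutation
stream serves all pathways — each permuted ranking is scored against every
pathway — which is statistically equivalent to per-pathway permutation and
roughly two orders of magnitude cheaper.  Enrichment is one-sided toward
over-representation at the top (ES exceedances $\ge$, RS exceedances
$\le$); both the raw estimator $\#/N$ and the add-one-corrected
$(1+\#)/(1+N)$ are reported, the corrected one as the headline.  Pathways
are *ranked* by these p-values rather than declared significant, following
the two-step logic in which gene-level uncertainty is deliberately not
propagated; the package reports top-$k$ lists per method and their
intersection ("ranked at least $k$-th by both").

# The synthetic cohort generator

Because the motivating study's animal data are not deposited, every stage
is exercised on synthetic cohorts with the statistical structure the
analysis assumes:

* **Stratification** by the Balding-Nichols model: group frequencies drawn
  from $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ around ancestral
  frequencies, a single divergence parameter $F_{st}$ (default 0.1, enough
  for the leading PC to separate groups, as high-density cattle panels
  do).  Group sizes default to a 73:27 split, mirroring a cohort dominated
  by one breed group.
* **LD** within gene blocks from a latent AR(1) Gaussian
  ($\mathrm{cor} = \rho^{|i-j|}$, default $\rho = 0.5$) thresholded at the
  frequency quantile; two independent haplotypes summed per individual.
  This gives tunable, analytically checkable LD decay, not a realistic
  cattle LD map.
* **Phenotypes** from the generative counterpart of the working model:
  $y = Z\theta + X\beta + \varepsilon$ per trait and time point T1/T2/T3,
  with one shared genetic term scaled per time (default multipliers 0.5,
  1, 0.5 concentrating signal at the high-load time T2) so ratio
  phenotypes between times stay genetically informative.  Per-time
  baselines (defaults 4.3/5.6/4.6 on a unit noise scale) sit well above
  zero so raw-scale ratios are well behaved.  Causal SNP effects are given
  in units of the residual SD; dosages are oriented to the realized minor
  allele at generation time, so the written files and the readers'
  canonical coding agree exactly.
* **Annotations**: gene intervals covering their blocks, 20 kbp
  inter-block gaps so the 5 kbp mapping flanks never bridge genes,
  intergenic SNPs placed mid-gap so they map nowhere; pathway memberships
  dealt from a shuffled gene list (a partition when sizes allow, minimum 5
  members), with causal genes swapped into the designated causal pathway
  size-neutrally.

What the generator does **not** emulate: realistic allele-frequency
spectra, pedigree/kinship structure, LD between genes, multi-allelic
variants, genotyping error, or real between-time phenotype correlation
(the shared-term-with-multipliers scheme is a stand-in, not an inference
about the data).  Passing tests therefore demonstrate correctness of the
statistical machinery under the assumed model, not performance on real
cattle data.

# Problem sizes and numerical choices

The shipped simulations are desk-scale by design: cohorts of 120–300
animals, 1000–2500 SNPs, 10–250 genes, 500–10000 permutations — large
enough for the asymptotics being tested, small enough that the full suite
and the acceptance script each run in minutes on one CPU.  Tolerances worth
knowing: degenerate-column cutoff $C_{ii} \le 10^{-10}$; eigenvalue clipping
at 0; residual-variance guard $10^{-12}$ relative for phenotype-in-span
detection; QC thresholds compared with a $10^{-12}$ guard so SNPs at
exactly the 0.95/0.05 boundaries are kept (inclusive reading of the
published rules); PCA component signs fixed by forcing the
largest-magnitude loading positive.

Design points that were genuinely open and the choices made:

* Missing genotypes are mode-imputed per SNP after QC (the original study
  used haplotype phasing within subgroups; at the $\le 5\%$ missingness QC
  guarantees, mode imputation is adequate and dependency-free).
* QC uses the pooled sample (whether the original QC preceded the group
  split is unstated).
* A SNP inside two overlapping flanked genes counts for both genes.
* Phenotype exclusion for missing values is per trait/time rather than
  global, preserving more data; ratio phenotypes with non-positive
  denominators drop the sample with a warning.  For traits recorded as log
  concentrations, single-time analyses use the log values while ratios are
  formed on the raw scale ($e^{x_2-x_1}$), with a log-difference switch.
* The SMA uses the same covariate matrix $Z$ as the gene-based test.

# Known limitations

* The plug-in chi-square approximation is slightly anti-conservative at
  very small $n$ relative to the covariate rank; the permutation p-value is
  the arbiter there.
* With a single causal gene inside a pathway, the rank-sum statistic has
  little power by construction (one top rank shifts RS by well under one
  null SD); the weighted KS score, which upweights the top of the ranking,
  is the sensitive statistic in that regime.  Pathway recovery claims in
  the tests reflect this asymmetry.
* The Tracy-Widom machinery assumes approximately independent markers; the
  within-gene LD of the generator mildly inflates the effective marker
  estimate, which the null-calibration test bounds in practice.
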