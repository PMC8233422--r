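---
title: "Single-step threshold models and genomic window scans for binary traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step threshold models and genomic window scans for binary traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabscan)
```

## The problem

Binary fitness outcomes in livestock — here, pregnancy loss after a confirmed
early pregnancy in dairy cattle — are routinely analysed on the liability
scale: a latent continuous variable $z$ determines the outcome through a
threshold, $Y = 1$ iff $z > 0$. The liability follows a linear mixed model

$$z = X\beta + Z_1 a + Z_2 s + \varepsilon,\qquad \varepsilon \sim N(0, 1),$$

with fixed effects $\beta$ (year-season of breeding, type of breeding, and —
for lactating parities — days-in-milk class and uterine-disease status), an
additive genetic animal effect $a \sim N(0,\, H\sigma^2_a)$, and an iid
service-sire effect $s \sim N(0,\, I\sigma^2_{ss})$ for the bull used in the
insemination. The residual variance is fixed at 1 and the threshold at 0 —
the standard probit identification; an overall mean is absorbed in the first
fixed factor, and every later factor carries a corner constraint (first level
fixed at zero) because the joint incidence matrix is otherwise rank
deficient.

$H$ merges pedigree and genomic information (single-step GBLUP):

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}\end{bmatrix},$$

where $A$ is the numerator relationship matrix, $A_{22}$ its block for the
genotyped animals (computed by the tabular method on the ancestor closure, so
paths through ungenotyped ancestors are kept), and $G$ the VanRaden
genomic relationship matrix built from dosages centred at twice the observed
allele frequency. $G$ is singular by construction (centred rows sum against
the ones vector), so it is blended, $G^* = w G + (1-w) A_{22}$ with
$w = 0.95$ by default, before inversion. With no genotyped animals, or with
$G = A_{22}$ and $w = 1$, $H^{-1} = A^{-1}$ exactly; both identities are
asserted in the test suite.

Downstream of the fit, marker effects are back-solved from the genomic
breeding values of the genotyped animals,
$\hat s = D M' (M D M')^{-1} \hat a_g$ with equal SNP weights $D = I$ by
default, and the genome is scanned in 2.0 Mb windows: the share of additive
variance attributed to window $i$ is
$\mathrm{var}(u_i)/\sigma^2_a \times 100$, where $u_i$ is the per-animal sum
of centred marker contributions inside the window and the variance is
empirical across genotyped animals. Genes tagged by at least one SNP in the
top 5% of the $|\hat s|$ distribution are flagged, and user-supplied gene
sets (GMT files) are tested for overrepresentation of flagged genes with the
upper-tail cumulative hypergeometric (Fisher's exact) test.

## Fitting: Gibbs sampling with data augmentation

`fit_threshold()` iterates three exact steps:

1. **Liabilities.** $z_r$ is drawn from $N(\eta_r, 1)$ truncated to
   $(0,\infty)$ or $(-\infty,0]$ according to $y_r$. Tail draws
   ($|\eta| \gtrsim 0.45$ past the bound) use a shifted-exponential rejection
   sampler, stable far beyond $|\eta| = 6$; records with missing outcomes are
   drawn untruncated.
2. **Location effects.** Single-site updates from each coefficient's full
   conditional normal, with two additions that proved necessary for mixing:
   - for an animal carrying a single record — the typical case, since each
     cow contributes one record per parity — $(z_r, a_i)$ are drawn jointly:
     $z_r$ from its conditional with $a_i$ integrated out, then
     $a_i \mid z_r$. A plain single-site scheme leaves $z_r$ and $a_i$ locked
     in a random walk whose relaxation time we measured in the hundreds of
     thousands of sweeps; the collapsed draw removes that coupling at $O(1)$
     cost.
   - an interweaved non-centred rescale move: writing $a = s\,\tilde a$ with
     $\tilde a \sim N(0, H)$, the full conditional of $s$ given $\tilde a$ is
     Gaussian, and a Metropolis accept/reject on the prior-plus-Jacobian
     ratio yields large global moves of $(a, \sigma^2_a)$ together.
   Both are exact MCMC moves targeting the same posterior; with them,
   overdispersed starts agree and effective sample sizes for $\sigma^2_a$
   rise by an order of magnitude at the chain lengths used below.
3. **Variances.** Scaled inverse chi-square draws with
   $q_a = a'H^{-1}a$ and $q_{ss} = s's$; the residual variance is never
   sampled.

Defaults follow field practice for binary fertility traits: 600,000
iterations with a 100,000-iteration burn-in and thinning interval 100.
Posterior summaries are means, SDs and 95% equal-tail intervals of the
retained samples. Heritability is reported per retained sample as

$$h^2 = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_{ss} + 1},$$

i.e. the service-sire variance is included in the phenotypic denominator;
`include_ss_in_h2 = FALSE` switches to $\sigma^2_a/(\sigma^2_a+1)$, and the
choice used is recorded in the fit object (`h2_denominator`).

### Variance priors

The default prior for each variance is a scaled inverse chi-square with 4
degrees of freedom and scale 0.03 (mode 0.02). This is a deliberate,
weakly-informative compromise with two properties that matter for threshold
models: it keeps real mass near zero, so a truly null variance component can
shrink to the boundary; and its polynomial tail damps the long right tail
that the marginal likelihood of $\sigma^2_a$ carries when every animal has a
single binary record (the likelihood is nearly flat in $\sigma^2_a$ beyond
what family resemblance constrains). A prior centred on the start value
(`prior_scale_* = NULL`) or a flat scale-reference prior (`prior_df_* = 0`)
are available; note that a mode-at-0.1 prior of this family places
essentially no mass below 0.03 and therefore cannot express a null variance,
while the flat prior noticeably inflates posterior means under sparse
information.

### Convergence

`convergence_diagnostics()` reports, per stored trace, the Geyer
initial-positive-sequence effective sample size and a Geweke z-score (first
10% vs last 50%, variances scaled by ESS), alongside optional trace plots;
reports from fewer than 50 retained samples are flagged unreliable.

## The synthetic-data generator

The study data this pipeline targets are proprietary herd records, so the
package ships a generator (`simulate_study()`) whose defaults emulate their
published structure: a binary outcome with ~8–14% incidence (default target
13.5%), liability variances $\sigma^2_a = 0.2$ and $\sigma^2_{ss} = 0.05$,
fixed factors with the published level counts (39 year-seasons, 2 breeding
types, 3 DIM classes and binary uterine disease for lactating parities), a
multi-generation pedigree with a genotyped subset, and a SNP panel carrying
a few large-effect QTL windows.

Concrete choices, and why:

- **Pedigree.** Discrete generations; within each generation a small
  fraction of animals (`sire_fraction`, default 0.01) serves as sires and
  every other animal is a dam, so large paternal half-sib families arise as
  they do under artificial insemination. Family structure is what identifies
  $\sigma^2_a$ from binary data: with full-sib pairs instead, the per-family
  binomial noise on the liability scale (~0.14 at 13.5% incidence and family
  size two) is several times the family variance (0.05), and no estimator
  can recover the input heritability at the tested precision.
- **Genotypes.** Independent gene-drop: founder alleles from per-SNP
  frequencies drawn in `founder_maf_range`, one allele transmitted per
  parent per locus, no within-chromosome linkage. The window scan needs
  co-located QTL and SNPs, not LD, and linkage-free loci make the variance
  bookkeeping exact; designated QTL therefore sit exactly on panel SNPs.
- **Breeding values.** QTL contributions carry `qtl_var_fraction` of
  $\sigma^2_a$ (split equally across QTL, effects scaled by
  $\sqrt{2p(1-p)}$); the polygenic remainder descends the pedigree as
  midparent average plus a Mendelian-sampling deviation with variance
  $\tfrac12(1 - (F_s+F_d)/2)\sigma^2_{poly}$, using exact pedigree
  inbreeding.
- **Intercept calibration.** The liability intercept is solved numerically
  so that the *marginal* incidence — integrating the animal, service-sire
  and residual terms and averaging over the realised fixed effects — equals
  `incidence_target`. Setting the intercept to $\Phi^{-1}(p)$ alone would
  ignore the variance of the random terms and miss the target by several
  points at a 13.5% incidence.
- **Fixed effects.** Level values are drawn once per level from
  $N(0, 0.2^2)$ and centred within factor; the source study reports level
  counts but not magnitudes.
- **Genotyped subset.** A random `prop_genotyped` share of phenotyped
  animals plus all of their sires, echoing panels built from genotyped cows
  with records and AI sires; the exact sampling design of the real genotyped
  subset is not recoverable from published counts.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: linkage disequilibrium and haplotype
structure, genotyping error, selection and non-random mating, overlapping
generations, culling-driven missingness, and any environment-by-genetics
correlation. Parameter-recovery results here show the estimator is correct
under its own assumptions, not that those assumptions hold in a herd.

## Scan and enrichment conventions

- Windows slide one index SNP at a time; a window is the half-open interval
  $[\mathrm{pos},\ \mathrm{pos} + 2\,\mathrm{Mb})$ on one chromosome,
  truncated at chromosome ends. A non-overlapping tiled mode exists for
  variance bookkeeping: with unlinked loci the tiled window variances sum to
  the variance of $M\hat s$ up to cross-window sampling covariance, which
  shrinks as $1/\sqrt{n}$ — the packaged check uses 150,000 animals so its
  sampling noise (roughly 0.3% SD) sits well inside the 1% bound.
- $M$ is centred with the same allele frequencies as $G$, so $\hat s$ lives
  on the scale of $\hat a_g$. Because observed-frequency centring makes
  $MM'$ exactly singular, the kernel is regularised by the same blending as
  $G^*$ (towards $A_{22}$ when available, else a scaled identity); with
  external centring frequencies and full-rank kernels, $M\hat s$ reproduces
  $\hat a_g$ to machine precision.
- SNP-to-gene assignment uses the gene body plus a 15 kb flank on either
  side, boundary inclusive ("within 15 kb" read as $\le$), strand ignored; a
  SNP near several genes counts for all of them. The gene universe is the
  set of genes with at least one mapped SNP.
- "Top 5%" ranks $|\hat s|$ by default, since allele coding makes the sign
  arbitrary; a signed mode exists. Ties at the threshold are all included.
- The enrichment P-value is the standard upper-tail cumulative
  hypergeometric, computed with log-gamma binomial coefficients; terms keep
  only genes in the universe and need at least 10 of them after
  intersection. Raw P-values are primary (matching the field's reporting
  practice); a Benjamini–Hochberg column is emitted for convenience and
  never used for filtering. The calibration check's design — 2,000 genes,
  200 flagged, term sizes 100–300 — was fixed from the exact null rejection
  rates of the discrete test (mean 0.0395 at $\alpha = 0.05$); smaller terms
  make the test conservative through discreteness alone.

## Numerical and interface choices

- Pedigrees must be topologically ordered with consecutive ids and 0 for
  unknown parents; inbreeding comes from memoised kinship recursion, and
  $A^{-1}$ is assembled directly by Henderson's rules with
  inbreeding-adjusted Mendelian-sampling variances. The suite checks sparse
  assembly against dense inversion of the tabular $A$ on random pedigrees
  (tolerance $10^{-10}$).
- Blended $G^*$ is refused if its reciprocal condition number falls below
  $10^{-12}$; degenerate variance draws are floored at $10^{-8}$; a chain
  whose variance exceeds $10^6$ aborts as divergent.
- Per-parity models are fitted independently on their record subsets; the
  parity-by-parity output table carries heritabilities on the diagonal and
  Pearson correlations of back-solved SNP-effect vectors off the diagonal.
  All parities share the QC'd panel and one $H^{-1}$.
- File formats: pedigree/phenotype CSV, PLINK RAW + MAP dosage text, GFF3
  and BED gene models (normalised to the internal 1-based closed convention
  via rtracklayer), GMT gene sets, and a 1-based lower-triangle coordinate
  text format for sparse symmetric matrices. Malformed lines raise
  line-numbered errors; `run_pipeline()` writes a manifest with a
  configuration hash and per-file checksums, and re-runs under the same seed
  are bit-identical.

## Problem sizes used in the packaged checks

Chain lengths and population sizes in the test suite are scaled-down
versions of the defaults, chosen to keep each check sharp at desk scale:
parameter recovery uses ~5,100 records over five generations (1,200
founders) with 20,000 iterations, 4,000 burn-in and thinning 10, across five
seeds; the null-recovery run uses the same design with $\sigma^2_a = 0$;
scan power uses 20 replicates of 150 genotyped animals × 200 SNPs with one
QTL at 15% of $\sigma^2_a$ and all additive variance borne by the panel; the
permutation calibration uses 1,000 permutations. The demo pipeline runs a
few hundred records end to end in well under a minute per invocation.

## Known limitations

- The sampler is single-chain; between-chain diagnostics (e.g. split-R̂)
  are not built in, though seeds make independent runs trivial.
- No REML or EM alternative, no multi-trait or recursive models, and no
  genotype-by-parity interaction model: parities are compared through
  separate fits, as in the motivating analysis.
- The scan offers no single-SNP P-values and no iterative SNP reweighting
  (equal weights only).
- Enrichment consumes user-supplied annotation files; no identifier
  translation or live database retrieval is attempted.
- `a22()` uses the dense tabular method on the pruned ancestor set — exact,
  but quadratic in the subset size; populations beyond desk scale would want
  an indirect (Colleau-type) algorithm.
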