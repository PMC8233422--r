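# liabscan

Liability threshold models and genomic window scans for binary traits in
pedigreed, partly genotyped livestock populations.

Binary fitness outcomes — the motivating case is pregnancy loss after a
confirmed early pregnancy in dairy cattle — are analysed on the liability
scale: `Y = 1` iff a latent liability `z` exceeds 0, with

```
z = X beta + Z1 a + Z2 ss + e,    e ~ N(0, 1)
a ~ N(0, H sigma2_a),             ss ~ N(0, I sigma2_ss)
```

where `a` is the additive genetic effect with the single-step (ssGBLUP)
relationship matrix `H` merging pedigree and SNP information,

```
H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1],
```

and `ss` is an iid service-sire effect. The model is fitted by Gibbs
sampling with truncated-normal data augmentation (residual variance fixed
at 1). From the fit, SNP effects are back-solved as
`s_hat = D M'(M D M')^-1 a_hat_g`, 2.0 Mb windows are ranked by the share
of additive variance they explain (`var(u_i)/sigma2_a * 100`), genes tagged
by top-5% SNP effects are flagged, and gene sets are tested for
overrepresentation with the cumulative hypergeometric test. A synthetic-data
generator (pedigree gene-drop with liability phenotypes and toy annotations)
makes every stage testable without proprietary herd records.

The package is aimed at quantitative geneticists who want a transparent,
fully scriptable ssGBLUP threshold-model workflow with known-truth
validation, rather than a wrapper around external BLUP binaries.

## Worked example

Simulate a small study, fit the threshold model on the nulliparous records
with a pedigree-only relationship matrix, and scan the genome:

```r
library(liabscan)

cfg <- sim_config(n_founders = 800, n_generations = 3,
                  offspring_per_mating = 1, parities = "nulliparous",
                  n_chromosomes = 3, snps_per_chromosome = 80,
                  chrom_length_bp = 2e7, n_qtl = 3, prop_genotyped = 0.15,
                  sigma2_a = 0.2, sigma2_ss = 0.05,
                  incidence_target = 0.135, seed = 7)
study <- simulate_study(cfg)
study
#> Simulated liability study
#>   3152 animals in pedigree (800 founders), 2352 records
#>   375 genotyped animals x 240 SNPs, 3 QTL
#>   observed incidence 0.118

qc   <- qc_filter(study$genotypes, study$snp_map)
geno <- impute_missing(qc$genotypes)
ai   <- a_inverse(study$pedigree)
A22m <- a22(study$pedigree, rownames(geno))
H    <- h_inverse(ai$A_inv, A22m, g_matrix(geno), blend = 0.95)

fit <- fit_threshold(y ~ year_season + breed_type, study$phenotypes, H,
                     config = gibbs_config(n_iter = 10000, burn_in = 2000,
                                           thin = 5, seed = 1))
fit
#> Liability threshold animal model (Gibbs)
#>   2352 records, 3152 animals, 50 service sires
#>   1600 stored samples (n_iter 10000, burn-in 2000, thin 5)
#>             mean     sd   2.5%  97.5%
#> sigma2_a  0.1172 0.1083 0.0187 0.4095
#> sigma2_ss 0.0487 0.0218 0.0177 0.0999
#> h2        0.0939 0.0692 0.0176 0.2822
#>   h2 denominator: sigma2_a + sigma2_ss + 1
```

The posterior-summary block reads as in any Bayesian variance-component
analysis. The generating values were `sigma2_a = 0.2` (h2 = 0.16) and
`sigma2_ss = 0.05`: with ~2,400 binary records the service-sire variance is
recovered well while the additive variance carries wide uncertainty — its
95% interval [0.019, 0.41] covers the truth. (Binary records at 12–14%
incidence are weakly informative about `sigma2_a`; the packaged
parameter-recovery checks use ~5,100 records, where posterior-mean h2 lands
within ±0.07 of 0.16.) `summary(fit)` adds the fixed-effect levels,
`plot(fit)` draws traces, and `convergence_diagnostics(fit)` reports
effective sample sizes and Geweke z-scores.

Scanning continues from the fit:

```r
s  <- backsolve_snp_effects(fit$gebv[rownames(geno)], geno,
                            blend = 0.95, A22 = A22m)
wt <- window_variance_percent(window_partition(qc$snp_map), geno, s,
                              sigma2_a = mean(fit$samples[, "sigma2_a"]))
head(wt[order(-wt$pct_var), c("chrom", "start_bp", "index_snp", "n_snps",
                              "pct_var")], 3)
#>     chrom start_bp index_snp n_snps  pct_var
#> 229     3 16853370  SNP_3_69      8 1.351894
#> 230     3 17074126  SNP_3_70      7 1.284657
#> 233     3 17797474  SNP_3_73      8 1.223198
```

Each row is a sliding 2.0 Mb window with the share of additive variance its
back-solved marker effects explain; at this demo size (375 genotyped
animals) the ranking is noisy — the simulated QTL (`study$true_qtl`) sit
elsewhere — which is exactly the regime the power checks quantify at larger
scale. `manhattan_plot(wt)` draws the genome-wide picture;
`map_snps_to_genes()`, `flag_significant_genes()` and `enrich_terms()` take
the effects through to gene-set P-values, and `run_pipeline()` executes the
whole sequence (simulation through enrichment, three parities) with a
manifest of checksummed outputs.

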