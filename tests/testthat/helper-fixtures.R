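# Shared fixtures, built in code at test time.

# random topologically ordered pedigree: each animal is a founder with
# probability p_founder, otherwise gets two distinct earlier parents
random_pedigree <- function(n, seed, p_founder = 0.3) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= 2L || runif(1) < p_founder) next
    pr <- sample.int(i - 1L, 2L)
    sire[i] <- pr[1L]; dam[i] <- pr[2L]
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam)
}

# small genotype panel of unrelated animals at given allele frequencies
random_dosages <- function(n_animals, freqs, seed) {
  set.seed(seed)
  m <- length(freqs)
  g <- matrix(rbinom(n_animals * m, 2L, rep(freqs, each = n_animals)),
              n_animals, m)
  dimnames(g) <- list(as.character(seq_len(n_animals)),
                      sprintf("SNP%03d", seq_len(m)))
  g
}

# evenly spaced SNP map over a set of chromosomes
even_snp_map <- function(n_chrom, snps_per_chrom, spacing_bp = 5e5) {
  do.call(rbind, lapply(seq_len(n_chrom), function(ch)
    data.frame(snp_id = sprintf("SNP_%d_%d", ch, seq_len(snps_per_chrom)),
               chrom = as.character(ch),
               pos_bp = spacing_bp * seq_len(snps_per_chrom))))
}

# study configuration used by the parameter-recovery checks
recovery_config <- function(seed, sigma2_a = 0.2, sigma2_ss = 0.05) {
  sim_config(n_founders = 1200, n_generations = 5, offspring_per_mating = 1,
             n_chromosomes = 1, snps_per_chromosome = 10,
             n_qtl = if (sigma2_a > 0) 2L else 0L,
             qtl_var_fraction = if (sigma2_a > 0) 0.1 else 0,
             sigma2_a = sigma2_a, sigma2_ss = sigma2_ss,
             incidence_target = 0.135, parities = "nulliparous",
             prop_genotyped = 0, seed = seed)
}
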