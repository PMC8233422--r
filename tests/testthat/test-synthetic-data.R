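# Synthetic-data generator: pedigree topology, gene-drop Mendelian
# consistency, liability phenotype calibration, annotation fixtures,
# reproducibility.

test_that("configuration validation rejects degenerate settings", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_founders = 1, n_generations = 0),
               class = "liabscan_config_error")
  expect_error(sim_config(incidence_target = 0), class = "liabscan_config_error")
  expect_error(sim_config(founder_maf_range = c(0, 0.5)),
               class = "liabscan_config_error")
  expect_error(sim_config(qtl_var_fraction = 1.2),
               class = "liabscan_config_error")
})

test_that("pedigree simulation is topologically ordered with founder coding", {
  ped0 <- simulate_pedigree(sim_config(n_founders = 2, n_generations = 0))
  expect_equal(nrow(ped0), 2L)
  expect_true(all(ped0$sire == 0L & ped0$dam == 0L))

  ped <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 3,
                                      offspring_per_mating = 2, seed = 4))
  nf <- ped$animal[ped$generation > 0]
  expect_true(all(ped$sire[nf] < nf & ped$dam[nf] < nf))
  expect_true(all(ped$sire[nf] > 0L & ped$dam[nf] > 0L))
  # parents always come from the previous generation
  gen <- ped$generation
  expect_true(all(gen[ped$sire[nf]] == gen[nf] - 1L))
})

test_that("a closed small population accumulates pedigree inbreeding", {
  ped <- simulate_pedigree(sim_config(n_founders = 20, n_generations = 5,
                                      offspring_per_mating = 2, seed = 9))
  Fped <- inbreeding(ped)
  expect_gt(mean(Fped[ped$generation == 5]), 0)
})

test_that("gene drop is Mendelian-consistent and matches founder frequencies", {
  cfg <- sim_config(n_founders = 200, n_generations = 2,
                    offspring_per_mating = 1, n_chromosomes = 2,
                    snps_per_chromosome = 40,
                    founder_maf_range = c(0.3, 0.5), seed = 21)
  ped <- simulate_pedigree(cfg)
  map <- simulate_snp_map(cfg)
  g <- gene_drop_genotypes(ped, map, c(0.3, 0.5), cfg)
  expect_true(all(g %in% 0:2))

  # transmissibility bounds: a parent with dosage 2 always transmits the
  # allele, a parent with dosage 0 never does
  nf <- which(ped$sire > 0 & ped$dam > 0)
  lo <- (g[ped$sire[nf], ] == 2L) + (g[ped$dam[nf], ] == 2L)
  hi <- 2L - (g[ped$sire[nf], ] == 0L) - (g[ped$dam[nf], ] == 0L)
  expect_true(all(g[nf, ] >= lo & g[nf, ] <= hi))

  p_drawn <- attr(g, "founder_freq")
  p_real <- colMeans(g[ped$generation == 0, ]) / 2
  expect_true(all(abs(p_real - p_drawn) < 0.1))
})

test_that("liability phenotypes hit the target incidence", {
  # pure Bernoulli(0.5): no genetic, service-sire or fixed-effect variance
  cfg0 <- sim_config(n_founders = 3000, n_generations = 1,
                     offspring_per_mating = 2, n_chromosomes = 1,
                     snps_per_chromosome = 5, n_qtl = 0, qtl_var_fraction = 0,
                     sigma2_a = 0, sigma2_ss = 0, fixed_effect_sd = 0,
                     incidence_target = 0.5, parities = "nulliparous",
                     seed = 31)
  st0 <- simulate_study(cfg0, keep_true_genotypes = FALSE)
  n0 <- nrow(st0$phenotypes)
  expect_lt(abs(mean(st0$phenotypes$y) - 0.5), 2 * sqrt(0.25 / n0))

  # study-scale incidence with all variance components active
  cfg <- sim_config(n_founders = 5100, n_generations = 1,
                    offspring_per_mating = 4, n_chromosomes = 1,
                    snps_per_chromosome = 5, n_qtl = 2, qtl_var_fraction = 0.2,
                    incidence_target = 0.135, parities = "nulliparous",
                    seed = 32)
  st <- simulate_study(cfg, keep_true_genotypes = FALSE)
  expect_gt(nrow(st$phenotypes), 15000)
  expect_lt(abs(mean(st$phenotypes$y) - 0.135), 0.01)
})

test_that("true breeding values realise the configured additive variance", {
  cfg <- sim_config(n_founders = 2000, n_generations = 1,
                    offspring_per_mating = 1, n_chromosomes = 2,
                    snps_per_chromosome = 50, n_qtl = 4,
                    qtl_var_fraction = 0.3, sigma2_a = 0.2, sigma2_ss = 0.05,
                    seed = 33)
  st <- simulate_study(cfg, keep_true_genotypes = FALSE)
  founders <- as.character(st$pedigree$animal[st$pedigree$generation == 0])
  v <- var(st$true_breeding_values[founders])
  expect_lt(abs(v - 0.2), 0.1 * 0.2 + 3 * 0.2 * sqrt(2 / 2000))
  expect_true(all(st$true_qtl$snp_index %in% seq_len(nrow(st$snp_map))))
})

test_that("annotation fixture honours term-size bounds and QTL seeding", {
  map <- even_snp_map(2, 50)
  ann <- simulate_annotation(map, n_genes = 120, n_terms = 15,
                             genes_per_term = c(10, 30), seed = 5)
  expect_equal(nrow(ann$genes), 120L)
  expect_true(all(ann$genes$start < ann$genes$end))
  expect_true(all(lengths(ann$sets) >= 10))
  expect_length(simulate_annotation(map, 50, 0, seed = 5)$sets, 0L)
  expect_error(simulate_annotation(map, 0, 5, seed = 5),
               class = "liabscan_config_error")

  qtl <- map[25, , drop = FALSE]
  ann2 <- simulate_annotation(map, 120, 5, seed = 6, qtl_snps = qtl)
  expect_true("TERM_QTL" %in% names(ann2$sets))
  expect_gte(length(ann2$sets$TERM_QTL), 10L)
})

test_that("identical configurations reproduce identical studies", {
  cfg <- sim_config(n_founders = 60, n_generations = 2, n_chromosomes = 2,
                    snps_per_chromosome = 20, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$true_breeding_values, s2$true_breeding_values)
})
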