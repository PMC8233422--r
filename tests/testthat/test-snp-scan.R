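# SNP back-solving, window partitioning, window variance shares,
# cross-parity correlations.

test_that("back-solved effects reconstruct the GEBVs on full-rank kernels", {
  set.seed(41)
  p <- runif(50, 0.2, 0.5)
  g <- random_dosages(20, p, seed = 41)
  a_g <- rnorm(20)
  # centring with external (generating) frequencies keeps M D M' full rank;
  # centring by the fixture's own observed frequencies would make it
  # exactly singular (the centred rows sum against the ones vector)
  s <- backsolve_snp_effects(a_g, g, blend = 1, allele_freq = p)
  M <- sweep(g, 2, 2 * p)
  expect_lt(max(abs(M %*% s - a_g)), 1e-8)
  # zero GEBVs give zero effects
  s0 <- backsolve_snp_effects(rep(0, 20), g, blend = 1, allele_freq = p)
  expect_equal(max(abs(s0)), 0)
  # scalar weights cancel between D M' and (M D M')^{-1}
  s2 <- backsolve_snp_effects(a_g, g, weights = rep(2, 50), blend = 1,
                              allele_freq = p)
  expect_lt(max(abs(s - s2)), 1e-10)
  expect_error(backsolve_snp_effects(rnorm(5), g),
               class = "liabscan_data_error")
})

test_that("GEBV names are aligned to the genotype rows before back-solving", {
  set.seed(42)
  p <- runif(30, 0.2, 0.5)
  g <- random_dosages(10, p, seed = 42)
  a_g <- setNames(rnorm(10), rownames(g))
  shuffled <- a_g[sample(names(a_g))]
  s1 <- backsolve_snp_effects(a_g, g, blend = 1, allele_freq = p)
  s2 <- backsolve_snp_effects(shuffled, g, blend = 1, allele_freq = p)
  expect_equal(s1, s2)
})

test_that("sliding windows follow the half-open 2.0 Mb convention", {
  map <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                    chrom = "1", pos_bp = c(0.1e6, 1.0e6, 1.9e6, 2.5e6))
  w <- window_partition(map, span_bp = 2e6)
  expect_equal(nrow(w), 4L)
  expect_equal(w$snps[[1]], c(1L, 2L, 3L))  # 2.5 Mb not in [0.1, 2.1)
  expect_equal(w$n_snps, c(3L, 3L, 2L, 1L))

  single <- data.frame(snp_id = "only", chrom = "9", pos_bp = 5e5)
  w1 <- window_partition(single)
  expect_equal(w1$n_snps, 1L)

  two <- rbind(map, data.frame(snp_id = "t1", chrom = "2", pos_bp = 0.2e6))
  w2 <- window_partition(two)
  expect_true(all(vapply(seq_len(nrow(w2)), function(i)
    length(unique(two$chrom[w2$snps[[i]]])) == 1L, logical(1))))

  expect_error(window_partition(map[c(2, 1, 3, 4), ]),
               class = "liabscan_data_error")
})

test_that("tiled windows partition each chromosome without overlap", {
  map <- even_snp_map(2, 30, spacing_bp = 2.5e5)
  w <- window_partition(map, span_bp = 2e6, mode = "tiled")
  expect_equal(sort(unlist(w$snps)), seq_len(nrow(map)))
  expect_equal(sum(w$n_snps), nrow(map))
})

test_that("window variance shares isolate a single causal SNP", {
  set.seed(43)
  p <- runif(60, 0.2, 0.5)
  g <- random_dosages(400, p, seed = 43)
  map <- even_snp_map(3, 20, spacing_bp = 3e5)  # 6 Mb chromosomes
  s <- rep(0, 60); names(s) <- colnames(g)
  qtl <- 25  # middle of chromosome 2
  s[qtl] <- 0.4
  w <- window_partition(map, span_bp = 2e6, mode = "tiled")
  sigma2_a <- var(sweep(g, 2, 2 * p)[, qtl] * 0.4)
  wt <- window_variance_percent(w, g, s, sigma2_a)
  in_qtl <- vapply(wt$snps, function(ix) qtl %in% ix, logical(1))
  expect_equal(wt$pct_var[in_qtl], 100, tolerance = 1e-10)
  expect_true(all(wt$pct_var[!in_qtl] == 0))
  expect_error(window_variance_percent(w, g, s, 0),
               class = "liabscan_data_error")

  # all effects zero: all windows zero
  wt0 <- window_variance_percent(w, g, rep(0, 60), 0.2)
  expect_true(all(wt0$pct_var == 0))
})

test_that("cross-parity correlation contracts hold", {
  s1 <- rnorm(200)
  expect_equal(cross_parity_correlation(s1, s1), 1)
  s_orth <- rnorm(200)
  s_orth <- s_orth - mean(s_orth)
  v <- s1 - mean(s1)
  s_orth <- s_orth - v * sum(s_orth * v) / sum(v * v)
  expect_lt(abs(cross_parity_correlation(s1, s_orth)), 1e-12)
  expect_warning(r <- cross_parity_correlation(s1, rep(1, 200)),
                 "zero-variance")
  expect_true(is.na(r))
  expect_error(cross_parity_correlation(s1, rnorm(10)),
               class = "liabscan_data_error")
})

test_that("shared genetic architectures yield high effect correlations", {
  # two parities share the same QTL effects; each adds its own small
  # polygenic per-SNP deviations (about a tenth of the QTL effect variance)
  set.seed(44)
  p <- runif(240, 0.2, 0.5)
  g <- random_dosages(150, p, seed = 44)
  M <- sweep(g, 2, 2 * p)
  beta <- rep(0, 240)
  beta[c(20, 80, 150, 210)] <- 0.3
  dev_sd <- sqrt(0.1 * var(beta))
  b1 <- beta + rnorm(240, 0, dev_sd)
  b2 <- beta + rnorm(240, 0, dev_sd)
  s1 <- backsolve_snp_effects(as.numeric(M %*% b1), g, blend = 1,
                              allele_freq = p)
  s2 <- backsolve_snp_effects(as.numeric(M %*% b2), g, blend = 1,
                              allele_freq = p)
  expect_gt(cross_parity_correlation(s1, s2), 0.8)

  # disjoint architectures decorrelate
  beta_b <- rep(0, 240)
  beta_b[c(40, 110, 180, 230)] <- 0.3
  s3 <- backsolve_snp_effects(as.numeric(M %*% (beta_b + rnorm(240, 0, dev_sd))),
                              g, blend = 1, allele_freq = p)
  expect_lt(abs(cross_parity_correlation(s1, s3)), 0.2)
})
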