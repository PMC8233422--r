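# Threshold-model Gibbs sampler: truncated augmentation, conjugate full
# conditionals, variance draws, heritability, determinism, diagnostics,
# prior recovery.

test_that("liability draws respect truncation and half-normal moments", {
  set.seed(1)
  z1 <- sample_liabilities(rep(0, 1e5), rep(1L, 1e5))
  expect_true(all(z1 > 0))
  expect_lt(abs(mean(z1) - sqrt(2 / pi)), 0.01)
  z0 <- sample_liabilities(rep(0, 1e5), rep(0L, 1e5))
  expect_true(all(z0 <= 0))
  # far-tail robustness
  zt <- sample_liabilities(rep(-8, 1000), rep(1L, 1000))
  expect_true(all(is.finite(zt) & zt > 0))
  zt2 <- sample_liabilities(c(-30, 30), c(1L, 0L))
  expect_true(all(is.finite(zt2)))
  # NA outcome: unconstrained normal draw
  zna <- sample_liabilities(rep(2, 1e5), rep(NA_integer_, 1e5))
  expect_lt(abs(mean(zna) - 2), 0.02)
})

test_that("single animal-record full conditional is N(z/2, 1/2)", {
  z0 <- 1.7
  dat <- data.frame(animal_id = 1, service_sire = "s", y = 1L)
  hin <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1),
                              dimnames = list("1", "1"))
  # no fixed effects; service-sire variance ~0 pins ss at zero, so with
  # sigma2_a = 1 the conditional of a is exactly N(z/2, 1/2)
  fit <- fit_threshold(y ~ 1, dat, hin,
                       config = gibbs_config(n_iter = 60000, burn_in = 5000,
                                             thin = 1, seed = 2,
                                             start_sigma2_a = 1,
                                             start_sigma2_ss = 1e-8),
                       update_z = FALSE, update_var = FALSE,
                       store_effects = TRUE, z_init = z0)
  a_draws <- fit$samples[, "a:1"]
  expect_lt(abs(mean(a_draws) - z0 / 2), 0.02)
  expect_lt(abs(var(a_draws) - 0.5), 0.05)
})

test_that("fixed-liability chain means solve the mixed-model equations", {
  set.seed(33)
  n_anim <- 12; n_sire <- 3; reps <- 30
  ped <- data.frame(animal = 1:n_anim,
                    sire = c(0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
                    dam = c(0L, 0L, 0L, 0L, 2L, 3L, 4L, 1L, 2L, 4L, 1L, 3L))
  ai <- a_inverse(ped)
  dat <- data.frame(
    animal_id = rep(1:n_anim, each = reps),
    batch = rep(c("b1", "b2", "b3"), length.out = n_anim * reps),
    service_sire = sprintf("s%d", sample.int(n_sire, n_anim * reps,
                                             replace = TRUE)),
    y = 1L)
  z <- rnorm(nrow(dat), 0, 1)
  # small prior variances pin the animal and sire means, keeping the
  # near-confounded mean directions well conditioned for the MC comparison
  s2a <- 0.1; s2s <- 0.05
  fit <- fit_threshold(y ~ batch, dat, ai$A_inv,
                       config = gibbs_config(n_iter = 4e6, burn_in = 2e5,
                                             thin = 100, seed = 5,
                                             start_sigma2_a = s2a,
                                             start_sigma2_ss = s2s),
                       update_z = FALSE, update_var = FALSE, z_init = z)
  mm <- mme_oracle(fit$design, as.matrix(ai$A_inv), s2a, s2s, z)
  expect_lt(max(abs(fit$gebv - mm$a)), 1e-3)
  expect_lt(max(abs(fit$ss_effects - mm$ss)), 1e-3)
  expect_lt(max(abs(coef(fit)[names(mm$beta)] - mm$beta)), 1e-3)
})

test_that("variance draws follow the scaled inverse chi-square", {
  set.seed(6)
  # q = 10 over 10 effects, flat prior: draws are 10 / chisq_10 with mean 10/8
  d <- sample_variance(q = 10, n_effects = 10, n = 1e5)
  expect_lt(abs(mean(d) - 1.25) / 1.25, 0.02)
  # prior domination: enormous df concentrates at the prior scale
  d2 <- sample_variance(q = 0, n_effects = 0, prior_df = 1e6,
                        prior_scale = 0.42, n = 1e4)
  expect_lt(abs(mean(d2) - 0.42), 0.01)
  # degenerate quadratic form is floored, not zero or negative
  d3 <- sample_variance(q = 0, n_effects = 5, n = 100)
  expect_true(all(d3 >= 1e-8))
})

test_that("heritability follows the documented formula", {
  expect_equal(heritability(0, 3), 0)
  expect_equal(heritability(0.2, 0.05), 0.16)
  expect_equal(heritability(1, 0), 0.5)
  expect_equal(heritability(0.2, 0.05, include_ss = FALSE), 0.2 / 1.2)
  expect_equal(heritability(c(0.2, 1), c(0.05, 0)), c(0.16, 0.5))
})

test_that("fits are deterministic given the seed and respect truncation", {
  cfg <- sim_config(n_founders = 150, n_generations = 2, n_chromosomes = 1,
                    snps_per_chromosome = 10, parities = "nulliparous",
                    seed = 12)
  st <- simulate_study(cfg, keep_true_genotypes = FALSE)
  ai <- a_inverse(st$pedigree)
  gc <- gibbs_config(n_iter = 2000, burn_in = 500, thin = 5, seed = 77)
  f1 <- fit_threshold(y ~ year_season + breed_type, st$phenotypes, ai$A_inv,
                      config = gc)
  f2 <- fit_threshold(y ~ year_season + breed_type, st$phenotypes, ai$A_inv,
                      config = gc)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$gebv, f2$gebv)
  expect_equal(f1$violations, 0)
  # stored liabilities agree in sign with the outcomes
  expect_true(all(sign(f1$final_z)[st$phenotypes$y == 1] > 0))
  expect_true(all(f1$final_z[st$phenotypes$y == 0] <= 0))
})

test_that("with outcomes withheld the variance posterior reproduces its prior", {
  dat <- data.frame(animal_id = 1:3, mu = "m",
                    service_sire = c("s1", "s2", "s1"), y = NA_integer_)
  ped <- data.frame(animal = 1:3, sire = 0L, dam = 0L)
  ai <- a_inverse(ped)
  cfg <- gibbs_config(n_iter = 4e5, burn_in = 5e4, thin = 20, seed = 3,
                      prior_df_a = 4, prior_scale_a = 0.15,
                      start_sigma2_a = 0.1)
  fit <- fit_threshold(y ~ mu, dat, ai$A_inv, config = cfg)
  post_med <- median(fit$samples[, "sigma2_a"])
  prior_med <- 4 * 0.15 / qchisq(0.5, 4)
  expect_lt(abs(post_med - prior_med) / prior_med, 0.1)
})

test_that("effective sample size matches known autocorrelation structure", {
  set.seed(9)
  n <- 5000
  expect_lt(abs(effective_size(rnorm(n)) - n) / n, 0.2)
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  ratio <- effective_size(ar) / (n * (1 - rho) / (1 + rho))
  expect_gt(ratio, 0.5); expect_lt(ratio, 1.7)
  expect_true(is.na(effective_size(rep(1, 100))))
})

test_that("convergence diagnostics report ESS, Geweke and reliability", {
  set.seed(10)
  tr <- cbind(sigma2_a = rnorm(500, 1), sigma2_ss = rnorm(500, 2))
  d <- convergence_diagnostics(tr)
  expect_equal(d$parameter, c("sigma2_a", "sigma2_ss"))
  expect_true(all(d$reliable))
  expect_true(all(abs(d$geweke_z) < 4))
  d2 <- convergence_diagnostics(tr[1:20, ])
  expect_false(any(d2$reliable))
  pf <- tempfile(fileext = ".png")
  convergence_diagnostics(tr, plot_file = pf)
  expect_true(file.exists(pf))
  unlink(pf)
})
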