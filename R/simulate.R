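# Synthetic-data generator: pedigree, gene-dropped genotypes, liability
# phenotypes, and toy annotations. Defaults emulate the data structure of a
# large Holstein pregnancy-loss study: binary outcomes with ~8-14% incidence,
# additive animal and service-sire random effects on the liability scale,
# fixed effects for year-season of breeding (39 levels), type of breeding (2),
# DIM class (3, lactating parities only) and uterine disease (binary,
# lactating only), a multi-generation pedigree with a genotyped subset, and a
# SNP panel carrying a few large-effect QTL windows.

#' Configuration for the synthetic study generator
#'
#' Collects and validates every knob of the generator. The residual variance
#' of the liability is fixed at 1 (probit identification) and is not a field.
#'
#' @param n_founders Number of founder animals (unknown parents).
#' @param n_generations Number of discrete generations bred from the founders.
#' @param offspring_per_mating Offspring produced by each dam.
#' @param sire_fraction Fraction of each generation used as sires of the
#'   next; the small default mirrors dairy populations, where few sires
#'   serve many dams and large paternal half-sib families result.
#' @param n_chromosomes,snps_per_chromosome,chrom_length_bp SNP panel layout.
#' @param n_qtl Number of designated QTL; each QTL sits exactly on a panel SNP.
#' @param qtl_var_fraction Fraction of the additive variance `sigma2_a`
#'   attributed to the designated QTL (the remainder is polygenic).
#' @param sigma2_a Liability-scale additive genetic variance.
#' @param sigma2_ss Liability-scale service-sire variance.
#' @param incidence_target Marginal incidence of the binary outcome; controls
#'   the liability intercept.
#' @param fixed_effect_levels Named integer vector of levels per fixed factor.
#'   `dim_class` and `uterine_disease` apply to lactating parities only.
#' @param fixed_effect_sd SD of the per-level fixed-effect values (drawn once
#'   per level, then centred within factor).
#' @param parities Parity labels; each phenotyped animal is assigned one
#'   record in one parity.
#' @param n_service_sires Size of the separate service-sire pool.
#' @param prop_genotyped Fraction of phenotyped animals that are genotyped
#'   (their sires are genotyped as well).
#' @param missing_rate Fraction of genotype calls set missing in the observed
#'   matrix.
#' @param founder_maf_range Range of founder minor-allele frequencies,
#'   within (0, 0.5].
#' @param seed Integer seed; identical configurations reproduce byte-identical
#'   fixtures.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders = 200L, n_generations = 3L,
                       offspring_per_mating = 2L, sire_fraction = 0.01,
                       n_chromosomes = 3L, snps_per_chromosome = 100L,
                       chrom_length_bp = 1e8, n_qtl = 5L,
                       qtl_var_fraction = 0.25,
                       sigma2_a = 0.2, sigma2_ss = 0.05,
                       incidence_target = 0.135,
                       fixed_effect_levels = c(year_season = 39L,
                                               breed_type = 2L,
                                               dim_class = 3L,
                                               uterine_disease = 2L),
                       fixed_effect_sd = 0.2,
                       parities = c("nulliparous", "primiparous", "multiparous"),
                       n_service_sires = 50L,
                       prop_genotyped = 0.35, missing_rate = 0.01,
                       founder_maf_range = c(0.05, 0.5),
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              sire_fraction = sire_fraction,
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_qtl = as.integer(n_qtl),
              qtl_var_fraction = qtl_var_fraction,
              sigma2_a = sigma2_a, sigma2_ss = sigma2_ss,
              incidence_target = incidence_target,
              fixed_effect_levels = fixed_effect_levels,
              fixed_effect_sd = fixed_effect_sd,
              parities = parities,
              n_service_sires = as.integer(n_service_sires),
              prop_genotyped = prop_genotyped,
              missing_rate = missing_rate,
              founder_maf_range = founder_maf_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_founders < 2L)
    config_error("n_founders must be >= 2 (got %d)", cfg$n_founders)
  counts <- c("offspring_per_mating", "n_chromosomes", "snps_per_chromosome",
              "n_service_sires")
  for (nm in counts)
    if (cfg[[nm]] < 1L) config_error("%s must be >= 1", nm)
  if (cfg$n_generations < 0L) config_error("n_generations must be >= 0")
  if (cfg$n_qtl < 0L) config_error("n_qtl must be >= 0")
  if (cfg$sigma2_a < 0 || cfg$sigma2_ss < 0)
    config_error("variances must be >= 0")
  if (cfg$sire_fraction <= 0 || cfg$sire_fraction >= 1)
    config_error("sire_fraction must lie in (0, 1)")
  fracs <- c("qtl_var_fraction", "prop_genotyped", "missing_rate")
  for (nm in fracs)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) config_error("%s must lie in [0, 1]", nm)
  if (cfg$incidence_target <= 0 || cfg$incidence_target >= 1)
    config_error("incidence_target must lie in (0, 1)")
  r <- cfg$founder_maf_range
  if (length(r) != 2L || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    config_error("founder_maf_range must lie within (0, 0.5]")
  if (is.null(names(cfg$fixed_effect_levels)) ||
      any(cfg$fixed_effect_levels < 1L))
    config_error("fixed_effect_levels must be a named vector of counts >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  pedigree: %d founders, %d generations x %d offspring/mating\n",
              x$n_founders, x$n_generations, x$offspring_per_mating))
  cat(sprintf("  panel: %d chromosomes x %d SNPs, %d QTL (%.0f%% of sigma2_a)\n",
              x$n_chromosomes, x$snps_per_chromosome, x$n_qtl,
              100 * x$qtl_var_fraction))
  cat(sprintf("  liability: sigma2_a = %.3g, sigma2_ss = %.3g, incidence = %.3g\n",
              x$sigma2_a, x$sigma2_ss, x$incidence_target))
  invisible(x)
}

#' Simulate a multi-generation pedigree
#'
#' Founders have both parents coded 0. In each later generation a small
#' share (`sire_fraction`) of the previous generation serves as sires; every
#' remaining animal of that generation is a dam and produces
#' `offspring_per_mating` offspring, each by a sire drawn at random. This
#' yields the large paternal half-sib families typical of dairy cattle. The
#' returned pedigree is topologically ordered (parents precede offspring)
#' with consecutive integer ids.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `animal`, `sire`, `dam`, `generation`.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n0 <- config$n_founders
  ped <- data.frame(animal = seq_len(n0), sire = 0L, dam = 0L, generation = 0L)
  prev <- ped$animal
  nid <- n0
  for (g in seq_len(config$n_generations)) {
    if (length(prev) < 2L)
      config_error("generation %d has fewer than 2 candidate parents", g - 1L)
    n_sires <- max(1L, round(config$sire_fraction * length(prev)))
    perm <- sample(prev)
    sires <- perm[seq_len(n_sires)]
    dams <- perm[-seq_len(n_sires)]
    k <- config$offspring_per_mating
    off <- data.frame(animal = nid + seq_len(length(dams) * k),
                      sire = sires[sample.int(length(sires), length(dams) * k,
                                              replace = TRUE)],
                      dam = rep(dams, each = k),
                      generation = g)
    ped <- rbind(ped, off)
    prev <- off$animal
    nid <- nid + length(dams) * k
  }
  ped
}

#' Simulate a SNP map
#'
#' Positions are drawn uniformly along each chromosome and sorted; chromosome
#' labels are autosome numbers as character strings.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos_bp`.
#' @export
simulate_snp_map <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, config$snps_per_chromosome))
    data.frame(snp_id = sprintf("SNP_%d_%d", ch, seq_along(pos)),
               chrom = as.character(ch), pos_bp = pos)
  })
  do.call(rbind, maps)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder alleles are drawn from per-SNP frequencies sampled uniformly from
#' `founder_maf_range`; every descendant receives one allele from each parent.
#' Loci are unlinked (independent gene-drop): transmission at a heterozygous
#' parent is a fair coin per locus. The complete true dosage matrix for all
#' pedigree animals is returned; use [observe_genotypes()] to restrict to a
#' genotyped subset and introduce missingness.
#'
#' @param pedigree Topologically ordered pedigree `data.frame`.
#' @param snp_map SNP map as from [simulate_snp_map()].
#' @param founder_maf_range Range of founder allele frequencies in (0, 0.5].
#' @param config A [sim_config()] object (supplies the seed).
#' @return Integer matrix animals x SNPs of dosages 0/1/2, with the SNP map
#'   and founder allele frequencies attached as attributes `snp_map` and
#'   `founder_freq`.
#' @export
gene_drop_genotypes <- function(pedigree, snp_map,
                                founder_maf_range = config$founder_maf_range,
                                config) {
  validate_sim_config(config)
  if (nrow(snp_map) < 1L || nrow(pedigree) < 1L)
    data_error("pedigree and SNP map must be non-empty")
  r <- founder_maf_range
  if (r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    config_error("founder_maf_range must lie within (0, 0.5]")
  set.seed(config$seed + 3L)
  n <- nrow(pedigree)
  m <- nrow(snp_map)
  p <- runif(m, r[1], r[2])
  geno <- matrix(0L, n, m,
                 dimnames = list(as.character(pedigree$animal), snp_map$snp_id))
  transmit <- function(dose) {
    # one allele from a parent given its dosage; fair coin at heterozygotes
    het <- dose == 1L
    out <- as.integer(dose == 2L)
    if (any(het)) out[het] <- rbinom(sum(het), 1L, 0.5)
    out
  }
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) {
      geno[i, ] <- rbinom(m, 2L, p)
    } else {
      al_s <- if (s > 0L) transmit(geno[s, ]) else rbinom(m, 1L, p)
      al_d <- if (d > 0L) transmit(geno[d, ]) else rbinom(m, 1L, p)
      geno[i, ] <- al_s + al_d
    }
  }
  attr(geno, "snp_map") <- snp_map
  attr(geno, "founder_freq") <- p
  geno
}

#' Restrict genotypes to a genotyped subset with missing calls
#'
#' @param genotypes Complete dosage matrix from [gene_drop_genotypes()].
#' @param genotyped_ids Animal ids (matching rownames) to retain.
#' @param missing_rate Fraction of retained calls set to `NA`.
#' @param seed Integer seed.
#' @return Integer dosage matrix with `NA` for missing calls.
#' @export
observe_genotypes <- function(genotypes, genotyped_ids, missing_rate = 0,
                              seed = 1L) {
  idx <- match(as.character(genotyped_ids), rownames(genotypes))
  if (anyNA(idx)) data_error("genotyped ids absent from genotype matrix")
  set.seed(seed)
  obs <- genotypes[idx, , drop = FALSE]
  if (missing_rate > 0) {
    miss <- runif(length(obs)) < missing_rate
    obs[miss] <- NA_integer_
  }
  attr(obs, "snp_map") <- attr(genotypes, "snp_map")
  attr(obs, "founder_freq") <- attr(genotypes, "founder_freq")
  obs
}

# choose QTL SNPs spaced >= 2 * span apart so their 2.0 Mb windows are distinct
pick_qtl_snps <- function(snp_map, n_qtl, min_gap_bp = 4e6) {
  if (n_qtl == 0L) return(integer(0))
  ord <- sample.int(nrow(snp_map))
  chosen <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in chosen) {
      if (snp_map$chrom[i] == snp_map$chrom[j] &&
          abs(snp_map$pos_bp[i] - snp_map$pos_bp[j]) < min_gap_bp) {
        ok <- FALSE; break
      }
    }
    if (ok) chosen <- c(chosen, i)
    if (length(chosen) == n_qtl) break
  }
  if (length(chosen) < n_qtl)
    config_error("cannot place %d QTL at least %g bp apart on this map",
                 n_qtl, min_gap_bp)
  sort(chosen)
}

#' Simulate binary liability phenotypes
#'
#' True breeding values are the sum of QTL contributions (a `qtl_var_fraction`
#' share of `sigma2_a`, split equally over the designated QTL) and a polygenic
#' remainder sampled down the pedigree as midparent average plus a
#' Mendelian-sampling deviation with variance
#' `0.5 * (1 - (F_s + F_d) / 2) * sigma2_poly`. Each non-founder animal
#' receives one record in one parity. The record liability is
#' `z = intercept + fixed effects + a + ss + e` with `e ~ N(0, 1)` and
#' `Y = 1` iff `z > 0`. The intercept is calibrated so that the marginal
#' incidence (integrating over the animal, service-sire and residual terms)
#' matches `incidence_target`.
#'
#' @param pedigree Pedigree `data.frame`.
#' @param genotypes Complete true dosage matrix from [gene_drop_genotypes()]
#'   (all pedigree animals), with its `snp_map`/`founder_freq` attributes.
#' @param config A [sim_config()] object.
#' @return A phenotype `data.frame` (columns `animal_id`, `parity`,
#'   `year_season`, `breed_type`, `dim_class`, `uterine_disease`,
#'   `service_sire`, `y`) with attributes `true_breeding_values`, `true_qtl`,
#'   `true_params`.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  validate_sim_config(config)
  if (nrow(genotypes) != nrow(pedigree))
    data_error("genotype matrix rows (%d) != pedigree animals (%d)",
               nrow(genotypes), nrow(pedigree))
  snp_map <- attr(genotypes, "snp_map")
  p <- attr(genotypes, "founder_freq")
  set.seed(config$seed + 4L)

  n <- nrow(pedigree)
  # QTL component of the true breeding values
  qtl_idx <- integer(0)
  qtl_eff <- numeric(0)
  qtl_part <- numeric(n)
  sigma2_qtl <- config$qtl_var_fraction * config$sigma2_a
  if (config$n_qtl > 0L && sigma2_qtl > 0) {
    qtl_idx <- pick_qtl_snps(snp_map, config$n_qtl)
    share <- sigma2_qtl / config$n_qtl
    pq <- p[qtl_idx]
    qtl_eff <- sample(c(-1, 1), config$n_qtl, replace = TRUE) *
      sqrt(share / (2 * pq * (1 - pq)))
    W <- sweep(genotypes[, qtl_idx, drop = FALSE], 2L, 2 * pq)
    qtl_part <- as.numeric(W %*% qtl_eff)
  }

  # polygenic remainder down the pedigree (uses pedigree inbreeding)
  sigma2_poly <- config$sigma2_a - sigma2_qtl
  Fped <- .cpp_inbreeding(as.integer(pedigree$sire), as.integer(pedigree$dam))
  poly <- numeric(n)
  sd0 <- sqrt(sigma2_poly)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) {
      poly[i] <- rnorm(1L, 0, sd0)
    } else {
      mid <- (if (s > 0L) poly[s] else 0) / 2 + (if (d > 0L) poly[d] else 0) / 2
      Fs <- if (s > 0L) Fped[s] else 0
      Fd <- if (d > 0L) Fped[d] else 0
      ms_var <- 0.5 * (1 - (Fs + Fd) / 2) * sigma2_poly
      poly[i] <- mid + rnorm(1L, 0, sqrt(ms_var))
    }
  }
  tbv <- qtl_part + poly
  names(tbv) <- as.character(pedigree$animal)

  pheno_animals <- pedigree$animal[pedigree$generation > 0L]
  if (length(pheno_animals) == 0L)
    config_error("no non-founder animals to phenotype (n_generations = 0)")
  nr <- length(pheno_animals)

  # fixed-effect values: drawn once per level, centred within factor
  lev <- config$fixed_effect_levels
  fe_values <- lapply(lev, function(k) {
    v <- rnorm(k, 0, config$fixed_effect_sd)
    v - mean(v)
  })

  parity <- sample(config$parities, nr, replace = TRUE)
  lact <- parity != "nulliparous"
  ys <- sample.int(lev[["year_season"]], nr, replace = TRUE)
  bt <- sample.int(lev[["breed_type"]], nr, replace = TRUE)
  dc <- ifelse(lact, sample.int(lev[["dim_class"]], nr, replace = TRUE),
               NA_integer_)
  ud <- ifelse(lact, sample.int(lev[["uterine_disease"]], nr, replace = TRUE),
               NA_integer_)
  sires <- sample.int(config$n_service_sires, nr, replace = TRUE)
  ss_eff <- rnorm(config$n_service_sires, 0, sqrt(config$sigma2_ss))

  fe <- fe_values[["year_season"]][ys] + fe_values[["breed_type"]][bt] +
    ifelse(lact, fe_values[["dim_class"]][dc], 0) +
    ifelse(lact, fe_values[["uterine_disease"]][ud], 0)

  # intercept: marginal incidence over a, ss and e matches the target
  sd_marg <- sqrt(1 + config$sigma2_a + config$sigma2_ss)
  target <- config$incidence_target
  f <- function(c0) mean(pnorm((c0 + fe) / sd_marg)) - target
  intercept <- uniroot(f, lower = qnorm(target) * sd_marg - 10,
                       upper = qnorm(target) * sd_marg + 10)$root

  a_rec <- tbv[match(pheno_animals, pedigree$animal)]
  z <- intercept + fe + a_rec + ss_eff[sires] + rnorm(nr)
  pheno <- data.frame(
    animal_id = pheno_animals,
    parity = parity,
    year_season = sprintf("YS%02d", ys),
    breed_type = sprintf("BT%d", bt),
    dim_class = ifelse(lact, sprintf("DIM%d", dc), NA_character_),
    uterine_disease = ifelse(lact, sprintf("UD%d", ud), NA_character_),
    service_sire = sprintf("SS%03d", sires),
    y = as.integer(z > 0))
  attr(pheno, "true_breeding_values") <- tbv
  attr(pheno, "true_qtl") <- data.frame(
    snp_id = snp_map$snp_id[qtl_idx], snp_index = qtl_idx, effect = qtl_eff)
  attr(pheno, "true_params") <- list(
    sigma2_a = config$sigma2_a, sigma2_ss = config$sigma2_ss,
    intercept = intercept, fixed_effects = fe_values,
    service_sire_effects = ss_eff)
  pheno
}

#' Simulate gene models and gene-set collections
#'
#' Gene intervals are placed uniformly on the simulated chromosomes (overlap
#' permitted); terms sample gene ids without replacement. If `qtl_snps` is
#' supplied (rows of the SNP map), one extra term is seeded with all genes
#' lying within `qtl_flank_bp` of those SNPs, padded with random genes up to
#' the minimum term size, giving downstream enrichment a true positive.
#'
#' @param snp_map SNP map `data.frame`.
#' @param n_genes Number of genes to place (>= 1).
#' @param n_terms Number of random terms (0 gives an empty collection).
#' @param genes_per_term Length-2 range of term sizes.
#' @param seed Integer seed.
#' @param qtl_snps Optional subset of `snp_map` rows marking true QTL.
#' @param qtl_flank_bp Flank used to seed the QTL term.
#' @return A list with `genes` (gene model `data.frame`: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`) and `sets` (named list of gene-id vectors).
#' @export
simulate_annotation <- function(snp_map, n_genes, n_terms,
                                genes_per_term = c(10L, 30L), seed = 1L,
                                qtl_snps = NULL, qtl_flank_bp = 1e6) {
  if (n_genes < 1L) config_error("n_genes must be >= 1")
  if (n_terms < 0L) config_error("n_terms must be >= 0")
  set.seed(seed)
  chroms <- unique(snp_map$chrom)
  chrom_len <- vapply(chroms, function(ch)
    max(snp_map$pos_bp[snp_map$chrom == ch]) + 1e6, numeric(1))
  ch <- sample(chroms, n_genes, replace = TRUE)
  len <- sample(5e3:8e4, n_genes, replace = TRUE)
  start <- vapply(seq_len(n_genes), function(i)
    sample.int(max(1, chrom_len[[ch[i]]] - len[i]), 1L), numeric(1))
  genes <- data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
                      chrom = ch, start = start, end = start + len,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE))
  sets <- list()
  if (n_terms > 0L) {
    lo <- genes_per_term[1]; hi <- genes_per_term[2]
    if (lo > n_genes) config_error("genes_per_term lower bound exceeds n_genes")
    sizes <- sample(lo:min(hi, n_genes), n_terms, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes$gene_id, k))
    names(sets) <- sprintf("TERM%04d", seq_len(n_terms))
  }
  if (!is.null(qtl_snps) && nrow(qtl_snps) > 0L) {
    near <- unique(unlist(lapply(seq_len(nrow(qtl_snps)), function(i) {
      sel <- genes$chrom == qtl_snps$chrom[i] &
        genes$end >= qtl_snps$pos_bp[i] - qtl_flank_bp &
        genes$start <= qtl_snps$pos_bp[i] + qtl_flank_bp
      genes$gene_id[sel]
    })))
    lo <- genes_per_term[1]
    if (length(near) < lo)
      near <- unique(c(near, sample(setdiff(genes$gene_id, near),
                                    lo - length(near))))
    sets[["TERM_QTL"]] <- near
  }
  list(genes = genes, sets = sets)
}

#' Simulate a complete study
#'
#' Orchestrates [simulate_pedigree()], [simulate_snp_map()],
#' [gene_drop_genotypes()], the genotyped-subset selection and
#' [simulate_phenotypes()] into one reproducible object. The genotyped subset
#' is a random `prop_genotyped` share of the phenotyped animals plus all of
#' their sires, echoing panels where cows with records and sires in the
#' pedigree are genotyped.
#'
#' @param config A [sim_config()] object.
#' @param keep_true_genotypes Keep the complete true dosage matrix (needed to
#'   re-derive true QTL contributions; memory grows with pedigree size).
#' @return An object of class `simulated_study`: a list with `pedigree`,
#'   `snp_map`, `genotypes` (observed, genotyped subset, with missingness),
#'   `phenotypes`, `genotyped_ids`, `true_breeding_values`, `true_qtl`,
#'   `true_params`, and optionally `genotypes_true`.
#' @export
simulate_study <- function(config = sim_config(), keep_true_genotypes = TRUE) {
  validate_sim_config(config)
  ped <- simulate_pedigree(config)
  snp_map <- simulate_snp_map(config)
  geno_true <- gene_drop_genotypes(ped, snp_map, config$founder_maf_range,
                                   config)
  pheno <- simulate_phenotypes(ped, geno_true, config)

  set.seed(config$seed + 5L)
  pheno_animals <- unique(pheno$animal_id)
  n_g <- max(1L, round(config$prop_genotyped * length(pheno_animals)))
  core <- sort(sample(pheno_animals, n_g))
  sires <- setdiff(unique(ped$sire[match(core, ped$animal)]), 0L)
  genotyped_ids <- sort(unique(c(core, sires)))
  geno_obs <- observe_genotypes(geno_true, genotyped_ids, config$missing_rate,
                                seed = config$seed + 6L)
  out <- list(pedigree = ped, snp_map = snp_map, genotypes = geno_obs,
              phenotypes = pheno, genotyped_ids = genotyped_ids,
              true_breeding_values = attr(pheno, "true_breeding_values"),
              true_qtl = attr(pheno, "true_qtl"),
              true_params = attr(pheno, "true_params"),
              config = config)
  if (keep_true_genotypes) out$genotypes_true <- geno_true
  structure(out, class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated liability study\n")
  cat(sprintf("  %d animals in pedigree (%d founders), %d records\n",
              nrow(x$pedigree), sum(x$pedigree$generation == 0L),
              nrow(x$phenotypes)))
  cat(sprintf("  %d genotyped animals x %d SNPs, %d QTL\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$true_qtl)))
  cat(sprintf("  observed incidence %.3f\n", mean(x$phenotypes$y)))
  invisible(x)
}
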