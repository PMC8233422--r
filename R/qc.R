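# Genotype quality control: animal call rate, sex-chromosome removal, SNP call
# rate, minor allele frequency, Hardy-Weinberg equilibrium; then mean
# imputation of the surviving panel. Filters are applied in a fixed order so
# the per-filter accounting is reproducible; MAF and HWE are computed on
# non-missing calls after animal removal.

#' Quality-control thresholds
#'
#' @param animal_call_rate Minimum fraction of non-missing calls per animal.
#' @param snp_call_rate Minimum fraction of non-missing calls per SNP.
#' @param maf Minimum minor allele frequency.
#' @param hwe_p Minimum Hardy-Weinberg exact-fit chi-square P-value. The
#'   conventional array-QC default of 1e-6 is used; set to 0 to disable.
#' @param sex_chromosomes Chromosome labels treated as sex chromosomes.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(animal_call_rate = 0.95, snp_call_rate = 0.95,
                          maf = 0.01, hwe_p = 1e-6,
                          sex_chromosomes = c("X", "Y")) {
  structure(list(animal_call_rate = animal_call_rate,
                 snp_call_rate = snp_call_rate, maf = maf, hwe_p = hwe_p,
                 sex_chromosomes = sex_chromosomes),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against expectations under the allele frequency estimated from the same
#' counts. A monomorphic SNP has no definable departure and returns P = 1.
#'
#' @param counts Integer vector `c(n_AA, n_Aa, n_aa)`.
#' @return The chi-square P-value.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    data_error("counts must be three non-negative genotype counts")
  n <- sum(counts)
  if (n == 0L) data_error("total genotype count is zero")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  unname(pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Filter a genotype panel
#'
#' Applies, in order: animal call rate, sex-chromosome SNP removal, SNP call
#' rate, minor allele frequency, and Hardy-Weinberg equilibrium. Returns the
#' filtered matrix and map together with a full removal accounting.
#'
#' @param genotypes Dosage matrix (animals x SNPs, `NA` = missing) with
#'   dosage coded as the count of the A allele.
#' @param snp_map SNP map `data.frame` (`snp_id`, `chrom`, `pos_bp`), one row
#'   per genotype column.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `genotypes`, `snp_map` and `report` (class
#'   `qc_report`): in/out counts, per-filter removals, and the removed ids.
#' @export
qc_filter <- function(genotypes, snp_map, thresholds = qc_thresholds()) {
  if (ncol(genotypes) != nrow(snp_map))
    data_error("genotype columns (%d) != SNP map rows (%d)",
               ncol(genotypes), nrow(snp_map))
  if (!identical(colnames(genotypes), snp_map$snp_id))
    data_error("genotype column names do not match SNP map snp_id order")
  th <- thresholds
  n_animals_in <- nrow(genotypes)
  n_snps_in <- ncol(genotypes)

  # 1. animal call rate (over the full input panel)
  acr <- rowMeans(!is.na(genotypes))
  bad_animals <- rownames(genotypes)[acr < th$animal_call_rate]
  g <- genotypes[acr >= th$animal_call_rate, , drop = FALSE]
  if (nrow(g) == 0L) data_error("all animals removed by call-rate filter")

  removed <- list()
  keep <- rep(TRUE, ncol(g))

  # 2. sex-chromosome SNPs
  sex <- snp_map$chrom %in% th$sex_chromosomes
  removed$sex_chromosome <- snp_map$snp_id[keep & sex]
  keep <- keep & !sex

  # 3. SNP call rate
  scr <- colMeans(!is.na(g))
  low_cr <- scr < th$snp_call_rate
  removed$snp_call_rate <- snp_map$snp_id[keep & low_cr]
  keep <- keep & !low_cr

  # 4. minor allele frequency (non-missing calls, post animal filter)
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  low_maf <- maf < th$maf
  removed$maf <- snp_map$snp_id[keep & low_maf]
  keep <- keep & !low_maf

  # 5. Hardy-Weinberg equilibrium
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    if (!keep[j]) return(1)
    x <- g[, j]
    hwe_test(c(sum(x == 2L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
               sum(x == 0L, na.rm = TRUE)))
  }, numeric(1))
  fail_hwe <- hwe_p < th$hwe_p
  removed$hwe <- snp_map$snp_id[keep & fail_hwe]
  keep <- keep & !fail_hwe

  if (!any(keep)) data_error("all SNPs removed by quality control")

  report <- structure(list(
    n_animals_in = n_animals_in, n_animals_out = nrow(g),
    n_snps_in = n_snps_in, n_snps_out = sum(keep),
    removed_animals = bad_animals,
    removals = vapply(removed, length, integer(1)),
    removed_snps = removed,
    thresholds = th), class = "qc_report")
  list(genotypes = g[, keep, drop = FALSE],
       snp_map = snp_map[keep, , drop = FALSE],
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  animals: %d in, %d out (%d removed, call rate < %g)\n",
              x$n_animals_in, x$n_animals_out, length(x$removed_animals),
              x$thresholds$animal_call_rate))
  cat(sprintf("  SNPs: %d in, %d out\n", x$n_snps_in, x$n_snps_out))
  for (nm in names(x$removals))
    cat(sprintf("    removed by %s: %d\n", nm, x$removals[[nm]]))
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Each missing call is replaced by the SNP's mean dosage among non-missing
#' calls (equal to twice the observed allele frequency), leaving allele
#' frequency estimates unchanged; non-missing entries are untouched.
#'
#' @param genotypes Post-QC dosage matrix with `NA` for missing calls.
#' @return A numeric matrix with no missing entries.
#' @export
impute_missing <- function(genotypes) {
  g <- genotypes
  storage.mode(g) <- "double"
  nmiss <- colSums(is.na(g))
  if (any(nmiss == nrow(g)))
    data_error("SNP(s) with 100%% missing calls cannot be imputed: %s",
               paste(colnames(g)[nmiss == nrow(g)], collapse = ", "))
  if (any(nmiss > 0L)) {
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2L]]
  }
  for (at in c("snp_map", "founder_freq"))
    attr(g, at) <- attr(genotypes, at)
  g
}
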