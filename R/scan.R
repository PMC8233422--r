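# Genome scan from a single-step evaluation: back-solve SNP marker effects
# from the GEBVs of the genotyped animals,
#   s_hat = D M' [M D M']^{-1} a_hat_g,
# with M the centred dosage matrix used for G and D diagonal SNP weights
# (equal weights by default), then express each 2.0 Mb window's share of the
# additive variance as var(u_i) / sigma2_a * 100 with u_i the window sum of
# marker contributions over the genotyped animals.

# centre dosages by twice the observed allele frequency (the G centring)
center_dosages <- function(genotypes, allele_freq = NULL) {
  if (anyNA(genotypes))
    data_error("genotypes contain missing calls; impute before the scan")
  p <- if (is.null(allele_freq)) colMeans(genotypes) / 2 else allele_freq
  list(M = sweep(genotypes, 2L, 2 * p), p = p)
}

#' Back-solve SNP effects from genomic breeding values
#'
#' Computes `s_hat = D M' (M D M')^{-1} a_hat_g` on the centred dosages. With
#' `blend < 1` the kernel `M D M'` is regularised towards `A22` (if supplied)
#' or towards a scaled identity, mirroring the blending used to invert G;
#' with `blend = 1` and a full-rank kernel, `M s_hat` reconstructs `a_hat_g`
#' exactly.
#'
#' @param a_g Named GEBV vector of the genotyped animals (names matching the
#'   genotype rownames) or an unnamed vector in row order.
#' @param genotypes Complete (imputed) dosage matrix of the genotyped
#'   animals.
#' @param weights Per-SNP diagonal weights `D` (default: equal weights 1).
#' @param blend Weight on `M D M'` in the regularised kernel, in (0, 1].
#' @param A22 Optional pedigree relationships of the genotyped animals used
#'   as the regularisation target (scaled to the kernel).
#' @param allele_freq Optional allele frequencies for centring (defaults to
#'   the observed frequencies of `genotypes`).
#' @return Named numeric vector of SNP effects (class `snp_effects`, with the
#'   weights and centring frequencies as attributes).
#' @export
backsolve_snp_effects <- function(a_g, genotypes, weights = NULL, blend = 1,
                                  A22 = NULL, allele_freq = NULL) {
  n <- nrow(genotypes)
  if (length(a_g) != n)
    data_error("GEBV length (%d) != genotyped animals (%d)", length(a_g), n)
  if (!is.null(names(a_g)) && !is.null(rownames(genotypes))) {
    idx <- match(rownames(genotypes), names(a_g))
    if (anyNA(idx)) data_error("GEBV names do not cover the genotyped animals")
    a_g <- a_g[idx]
  }
  if (blend <= 0 || blend > 1) config_error("blend must lie in (0, 1]")
  cd <- center_dosages(genotypes, allele_freq)
  M <- cd$M
  if (is.null(weights)) weights <- rep(1, ncol(M))
  if (length(weights) != ncol(M))
    data_error("weights length != SNP count")
  MD <- sweep(M, 2L, weights, `*`)
  K <- tcrossprod(MD, M)               # M D M'
  if (blend < 1) {
    target <- if (!is.null(A22)) mean(diag(K)) / mean(diag(A22)) * A22
              else diag(mean(diag(K)), n)
    K <- blend * K + (1 - blend) * target
  }
  s <- as.numeric(crossprod(MD, solve(K, as.numeric(a_g))))
  names(s) <- colnames(genotypes)
  structure(s, class = c("snp_effects", "numeric"),
            weights = weights, allele_freq = cd$p)
}

#' Partition a SNP map into genomic windows
#'
#' Sliding mode (the default) builds one window per index SNP containing all
#' SNPs of the same chromosome with position in
#' `[pos_index, pos_index + span_bp)` (half-open, truncated at chromosome
#' ends). Tiled mode cuts each chromosome into non-overlapping `span_bp`
#' bins, used for variance-bookkeeping checks.
#'
#' @param snp_map SNP map `data.frame` sorted by (chrom, pos_bp).
#' @param span_bp Window span in base pairs (2.0 Mb default).
#' @param mode `"sliding"` or `"tiled"`.
#' @return A `data.frame` with one row per window: `chrom`, `start_bp`,
#'   `end_bp`, `index_snp`, `n_snps`, and a list column `snps` of SNP-map row
#'   indices.
#' @export
window_partition <- function(snp_map, span_bp = 2e6,
                             mode = c("sliding", "tiled")) {
  mode <- match.arg(mode)
  chrom_f <- factor(snp_map$chrom, levels = unique(snp_map$chrom))
  if (any(duplicated(rle(as.integer(chrom_f))$values)))
    data_error("SNP map must be sorted by (chromosome, position)")
  if (any(tapply(snp_map$pos_bp, chrom_f, is.unsorted)))
    data_error("SNP map must be sorted by (chromosome, position)")
  rows <- split(seq_len(nrow(snp_map)), chrom_f)
  win <- list()
  for (ch in names(rows)) {
    idx <- rows[[ch]]
    pos <- snp_map$pos_bp[idx]
    if (mode == "sliding") {
      for (k in seq_along(idx)) {
        inw <- idx[pos >= pos[k] & pos < pos[k] + span_bp]
        win[[length(win) + 1L]] <- list(
          chrom = ch, start_bp = pos[k], end_bp = pos[k] + span_bp,
          index_snp = snp_map$snp_id[idx[k]], n_snps = length(inw),
          snps = inw)
      }
    } else {
      bins <- unique(pos %/% span_bp)
      for (b in bins) {
        inw <- idx[pos %/% span_bp == b]
        win[[length(win) + 1L]] <- list(
          chrom = ch, start_bp = b * span_bp, end_bp = (b + 1) * span_bp,
          index_snp = snp_map$snp_id[inw[1L]], n_snps = length(inw),
          snps = inw)
      }
    }
  }
  out <- data.frame(
    chrom = vapply(win, `[[`, character(1), "chrom"),
    start_bp = vapply(win, `[[`, numeric(1), "start_bp"),
    end_bp = vapply(win, `[[`, numeric(1), "end_bp"),
    index_snp = vapply(win, `[[`, character(1), "index_snp"),
    n_snps = vapply(win, `[[`, integer(1), "n_snps"))
  out$snps <- lapply(win, `[[`, "snps")
  out
}

#' Percentage of additive variance explained by genomic windows
#'
#' For each window, `u_i` is the per-animal sum of centred marker
#' contributions `M_j s_j` over the window's SNPs; the reported percentage is
#' the empirical variance of `u_i` across the genotyped animals divided by
#' the additive variance, times 100.
#'
#' @param windows Window table from [window_partition()].
#' @param genotypes Complete dosage matrix of the genotyped animals.
#' @param s SNP effects aligned with the genotype columns (e.g. from
#'   [backsolve_snp_effects()]).
#' @param sigma2_a Additive genetic variance (posterior mean from the
#'   matching [fit_threshold()] run).
#' @param allele_freq Optional centring frequencies (defaults to observed).
#' @return The window table with `var_u` and `pct_var` columns appended
#'   (class `window_table`; `sigma2_a` kept as an attribute).
#' @export
window_variance_percent <- function(windows, genotypes, s, sigma2_a,
                                    allele_freq = NULL) {
  if (sigma2_a <= 0) data_error("sigma2_a must be positive")
  if (length(s) != ncol(genotypes))
    data_error("SNP effect length != genotype columns")
  M <- center_dosages(genotypes, allele_freq)$M
  Ms <- sweep(M, 2L, as.numeric(s), `*`)
  var_u <- vapply(windows$snps, function(idx)
    var(rowSums(Ms[, idx, drop = FALSE])), numeric(1))
  out <- windows
  out$var_u <- var_u
  out$pct_var <- 100 * var_u / sigma2_a
  attr(out, "sigma2_a") <- sigma2_a
  class(out) <- c("window_table", class(out))
  out
}

#' Correlation between two SNP-effect vectors
#'
#' Pearson correlation of effects estimated on the same SNP panel, the
#' between-run genetic correlation used when contrasting separate fits (e.g.
#' parities). A zero-variance vector has no defined correlation and returns
#' `NA` with a warning.
#'
#' @param s1,s2 SNP-effect vectors on identical panels (names checked when
#'   present).
#' @return Pearson correlation (or `NA`).
#' @export
cross_parity_correlation <- function(s1, s2) {
  if (length(s1) != length(s2))
    data_error("effect vectors differ in length")
  if (!is.null(names(s1)) && !is.null(names(s2)) &&
      !identical(names(s1), names(s2)))
    data_error("effect vectors cover different SNP panels")
  if (sd(s1) == 0 || sd(s2) == 0) {
    warning("zero-variance SNP-effect vector: correlation undefined")
    return(NA_real_)
  }
  cor(as.numeric(s1), as.numeric(s2))
}

#' Manhattan-style window plot
#'
#' Plots each window's percentage of additive variance against its genomic
#' start position, chromosomes concatenated and alternately shaded.
#'
#' @param window_table A [window_variance_percent()] result.
#' @param file Optional PNG path; when given, the plot is written there.
#' @param main Plot title.
#' @return Invisibly, the plotted table.
#' @export
manhattan_plot <- function(window_table, file = NULL,
                           main = "Window share of additive variance") {
  wt <- window_table
  chroms <- unique(wt$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(wt$end_bp[wt$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  xpos <- wt$start_bp + offs[wt$chrom]
  draw <- function() {
    cols <- c("grey30", "steelblue")[(match(wt$chrom, chroms) %% 2L) + 1L]
    plot(xpos / 1e6, wt$pct_var, pch = 16, cex = 0.6, col = cols,
         xlab = "genome position (Mb, chromosomes concatenated)",
         ylab = "% of additive variance", main = main)
  }
  if (!is.null(file)) {
    png(file, width = 1000, height = 400)
    draw()
    dev.off()
  } else draw()
  invisible(wt)
}
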