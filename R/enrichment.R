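# SNP-based gene-set enrichment: assign SNPs to genes (gene body plus a 15 kb
# flank on either side, boundary inclusive; a SNP near several genes counts
# for all of them), flag genes carrying at least one SNP in the top 5% of the
# |effect| distribution, and test each functional term for overrepresentation
# of flagged genes with the upper-tail (cumulative) hypergeometric test.

#' Map SNPs to genes
#'
#' A SNP is assigned to a gene iff its position lies within
#' `[start - flank_bp, end + flank_bp]` (closed interval, strand ignored) on
#' the same chromosome. SNPs near several genes are assigned to all of them;
#' unmapped SNPs are recorded.
#'
#' @param snp_map SNP map `data.frame` (`snp_id`, `chrom`, `pos_bp`).
#' @param genes Gene models `data.frame` (`gene_id`, `chrom`, `start`, `end`,
#'   1-based closed coordinates) as from [read_gene_models()] or
#'   [simulate_annotation()].
#' @param flank_bp Flank capturing proximal regulatory sequence (15 kb
#'   default).
#' @return A list of class `snp_gene_map`: `pairs` (`data.frame` of
#'   `snp_id`, `gene_id`), `gene_snps` (named list gene -> SNP ids),
#'   `snp_genes` (named list SNP -> gene ids), `unmapped` (SNP ids).
#' @export
map_snps_to_genes <- function(snp_map, genes, flank_bp = 15000) {
  if (nrow(genes) == 0L) data_error("empty gene model table")
  snp_gr <- GenomicRanges::GRanges(
    snp_map$chrom, IRanges::IRanges(snp_map$pos_bp, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - flank_bp), genes$end + flank_bp))
  # chromosomes present on only one side are legitimate (unmapped SNPs);
  # silence the seqlevel-mismatch note findOverlaps emits for them
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, gene_gr))
  pairs <- data.frame(
    snp_id = snp_map$snp_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])
  pairs <- pairs[order(match(pairs$snp_id, snp_map$snp_id),
                       match(pairs$gene_id, genes$gene_id)), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    gene_snps = split(pairs$snp_id, pairs$gene_id),
    snp_genes = split(pairs$gene_id, pairs$snp_id),
    unmapped = setdiff(snp_map$snp_id, pairs$snp_id),
    flank_bp = flank_bp), class = "snp_gene_map")
}

#' Flag genes tagged by top SNP effects
#'
#' Relevant SNPs are those whose |effect| (or signed effect, with
#' `mode = "signed"`) reaches the `1 - top_fraction` quantile of the mapped
#' effect distribution; ties at the threshold are all included. A gene is
#' flagged iff at least one of its SNPs is relevant. The gene universe is the
#' set of genes with at least one mapped SNP.
#'
#' @param s Named SNP-effect vector (names = SNP ids).
#' @param snp_gene_map A [map_snps_to_genes()] result.
#' @param top_fraction Tail fraction defining relevant SNPs (0.05 default).
#' @param mode `"absolute"` ranks |effect| (allele coding makes the sign
#'   arbitrary); `"signed"` ranks the raw effect.
#' @return A list of class `flagged_genes`: `N` (universe size), `S` (flagged
#'   genes), `flagged` (gene ids), `universe` (gene ids), `relevant_snps`,
#'   `threshold`.
#' @export
flag_significant_genes <- function(s, snp_gene_map, top_fraction = 0.05,
                                   mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (is.null(names(s))) data_error("SNP effects must be named by SNP id")
  if (any(!is.finite(s))) data_error("SNP effects must be finite")
  universe <- names(snp_gene_map$gene_snps)
  if (length(universe) == 0L) data_error("empty gene universe: no mapped SNPs")
  stat <- if (mode == "absolute") abs(s) else as.numeric(s)
  names(stat) <- names(s)
  thr <- quantile(stat, 1 - top_fraction, names = FALSE)
  relevant <- names(stat)[stat >= thr]
  flagged <- universe[vapply(snp_gene_map$gene_snps, function(sn)
    any(sn %in% relevant), logical(1))]
  structure(list(N = length(universe), S = length(flagged),
                 flagged = flagged, universe = universe,
                 relevant_snps = relevant, threshold = thr,
                 top_fraction = top_fraction, mode = mode),
            class = "flagged_genes")
}

#' Upper-tail cumulative hypergeometric P-value
#'
#' `P(X >= g)` for `X ~ Hypergeometric(N, S, K)`: the probability of seeing
#' at least `g` flagged genes in a term of `K` genes drawn from a universe of
#' `N` genes of which `S` are flagged, computed as
#' `1 - sum_{i=0}^{g-1} C(S,i) C(N-S,K-i) / C(N,K)` with log-gamma
#' binomials. `g = 0` returns exactly 1.
#'
#' @param N Universe size. @param S Flagged genes in the universe.
#' @param K Term size (vectorised with `g`). @param g Flagged genes in the
#'   term.
#' @return P-value(s) in `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(N, S, K, g) {
  n <- max(length(K), length(g))
  K <- rep_len(K, n); g <- rep_len(g, n)
  if (S > N || any(K > N) || S < 0 || any(g < 0) || any(g > pmin(S, K)))
    data_error("invalid hypergeometric configuration (need 0 <= g <= min(S, K) <= N)")
  vapply(seq_len(n), function(r) {
    if (g[r] == 0L) return(1)
    i <- 0:(g[r] - 1L)
    ok <- (K[r] - i) <= (N - S) & i <= S
    lp <- lchoose(S, i[ok]) + lchoose(N - S, K[r] - i[ok]) - lchoose(N, K[r])
    min(1, max(0, 1 - sum(exp(lp))))
  }, numeric(1))
}

#' Test gene sets for overrepresentation of flagged genes
#'
#' Each term is intersected with the gene universe before the size filter;
#' terms retaining fewer than `min_term_size` genes are dropped. Results are
#' sorted by P-value. Raw P-values are the primary output; a
#' Benjamini-Hochberg FDR column is appended for convenience but never used
#' for filtering.
#'
#' @param flags A [flag_significant_genes()] result.
#' @param collection Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_term_size Minimum post-intersection term size (10 by default).
#' @param database Optional label recorded in the result.
#' @return A `data.frame`: `term_id`, `N`, `S`, `K`, `g`, `p_value`, `fdr`,
#'   `database`.
#' @export
enrich_terms <- function(flags, collection, min_term_size = 10L,
                         database = NA_character_) {
  if (length(collection) == 0L) {
    warning("empty gene-set collection")
    return(data.frame(term_id = character(0), N = integer(0), S = integer(0),
                      K = integer(0), g = integer(0), p_value = numeric(0),
                      fdr = numeric(0), database = character(0)))
  }
  uni <- flags$universe
  inter <- lapply(collection, function(gs) intersect(unique(gs), uni))
  K <- vapply(inter, length, integer(1))
  keep <- K >= min_term_size
  inter <- inter[keep]; K <- K[keep]
  g <- vapply(inter, function(gs) length(intersect(gs, flags$flagged)),
              integer(1))
  p <- if (length(K)) hypergeometric_pvalue(flags$N, flags$S, K, g) else numeric(0)
  out <- data.frame(term_id = names(inter), N = flags$N, S = flags$S,
                    K = K, g = g, p_value = p,
                    fdr = p.adjust(p, "BH"), database = database,
                    row.names = NULL)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Enrichment dot plot
#'
#' Displays each term's percentage of flagged genes against its significance
#' (point size scales with -log10 P).
#'
#' @param results An [enrich_terms()] table (typically its top rows).
#' @param file Optional PNG path.
#' @param max_terms Number of top terms to show.
#' @return Invisibly, the plotted subset.
#' @export
enrichment_dotplot <- function(results, file = NULL, max_terms = 20L) {
  res <- head(results[order(results$p_value), , drop = FALSE], max_terms)
  draw <- function() {
    old <- par(mar = c(4, 12, 2, 2))
    on.exit(par(old))
    pct <- 100 * res$g / res$K
    y <- rev(seq_len(nrow(res)))
    sz <- 0.5 + 2 * (-log10(pmax(res$p_value, 1e-12)) /
                       max(1, -log10(pmax(min(res$p_value), 1e-12))))
    plot(pct, y, pch = 16, cex = sz, yaxt = "n", ylab = "",
         xlab = "% significant genes in term", main = "Gene-set enrichment")
    axis(2, at = y, labels = res$term_id, las = 2, cex.axis = 0.7)
  }
  if (!is.null(file)) {
    png(file, width = 800, height = 150 + 25 * nrow(res))
    draw()
    dev.off()
  } else draw()
  invisible(res)
}
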