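# SNP-to-gene mapping, top-effect gene flagging, cumulative hypergeometric
# test, term enrichment.

toy_genes <- data.frame(
  gene_id = c("GA", "GB", "GC"),
  chrom = c("1", "1", "2"),
  start = c(50000, 80000, 10000),
  end = c(60000, 95000, 20000),
  strand = "+")

test_that("SNPs map to genes within the inclusive 15 kb flank", {
  map <- data.frame(snp_id = c("in_body", "at_75k", "at_75k1", "between"),
                    chrom = "1",
                    pos_bp = c(55000, 75000, 75001, 70000))
  sgm <- map_snps_to_genes(map, toy_genes, flank_bp = 15000)
  genes_of <- function(s) sgm$snp_genes[[s]]
  expect_equal(genes_of("in_body"), c("GA"))
  # boundary: 60,000 + 15,000 = 75,000 is included, 75,001 is not
  expect_true("GA" %in% genes_of("at_75k"))
  expect_false("GA" %in% sgm$pairs$gene_id[sgm$pairs$snp_id == "at_75k1"])
  # a SNP within 15 kb of two genes belongs to both
  expect_setequal(genes_of("between"), c("GA", "GB"))
  # chromosome mismatch leaves SNPs unmapped
  map2 <- data.frame(snp_id = "far", chrom = "9", pos_bp = 55000)
  expect_equal(map_snps_to_genes(map2, toy_genes)$unmapped, "far")
})

test_that("top-fraction flagging counts distinct and tied effects correctly", {
  sgm <- list(gene_snps = split(sprintf("snp%03d", 1:100),
                                rep(sprintf("g%02d", 1:50), each = 2)),
              pairs = data.frame(snp_id = sprintf("snp%03d", 1:100),
                                 gene_id = rep(sprintf("g%02d", 1:50), each = 2)))
  class(sgm) <- "snp_gene_map"
  s <- setNames(seq(0.01, 1, length.out = 100), sprintf("snp%03d", 1:100))
  fl <- flag_significant_genes(s, sgm, top_fraction = 0.05)
  expect_length(fl$relevant_snps, 5L)
  expect_equal(fl$N, 50L)
  # the gene whose best SNP sits just below the cut is not flagged; the
  # top-ranked genes are (ranks 96-100 are relevant, 93-94 are not)
  expect_false("g47" %in% fl$flagged)
  expect_true(all(c("g48", "g49", "g50") %in% fl$flagged))

  # ties at the threshold are all included
  s_tie <- setNames(c(seq(0.01, 0.90, length.out = 90), rep(1, 10)),
                    sprintf("snp%03d", 1:100))
  fl_tie <- flag_significant_genes(s_tie, sgm, top_fraction = 0.05)
  expect_length(fl_tie$relevant_snps, 10L)

  # absolute mode ranks |effect|
  s_neg <- s; s_neg[100] <- -5
  fl_abs <- flag_significant_genes(s_neg, sgm)
  expect_true("snp100" %in% fl_abs$relevant_snps)
})

test_that("cumulative hypergeometric matches enumeration and closed forms", {
  expect_equal(hypergeometric_pvalue(10, 4, 5, 0), 1)
  expect_equal(hypergeometric_pvalue(10, 4, 5, 3), 11 / 42)
  # exhaustive enumeration over draws, moderate universes
  set.seed(51)
  for (N in c(6, 9, 11)) {
    for (rep in 1:8) {
      S <- sample(0:N, 1); K <- sample(1:N, 1)
      g <- sample(0:min(S, K), 1)
      expect_lt(abs(hypergeometric_pvalue(N, S, K, g) -
                      enumerate_hyper_tail(N, S, K, g)), 1e-12)
    }
  }
  # independent distribution-function route (absolute agreement: the
  # complement form carries ~1e-16 absolute error in extreme tails)
  for (rep in 1:20) {
    N <- sample(20:200, 1); S <- sample(1:N, 1); K <- sample(1:N, 1)
    g <- sample(0:min(S, K), 1)
    expect_lt(abs(hypergeometric_pvalue(N, S, K, g) -
                    phyper(g - 1, S, N - S, K, lower.tail = FALSE)), 1e-10)
  }
  # tail probabilities are monotone in g and the pmf sums to one
  N <- 40; S <- 12; K <- 15
  gs <- 0:min(S, K)
  pv <- hypergeometric_pvalue(N, S, K, gs)
  expect_true(all(diff(pv) <= 1e-12))
  pmf <- pv - c(pv[-1], 0)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_error(hypergeometric_pvalue(10, 12, 5, 1),
               class = "liabscan_data_error")
})

test_that("term enrichment filters by post-intersection size and sorts by P", {
  universe <- sprintf("g%03d", 1:60)
  flags <- structure(list(N = 60L, S = 12L,
                          flagged = sprintf("g%03d", 1:12),
                          universe = universe), class = "flagged_genes")
  coll <- list(
    small = sprintf("g%03d", 1:9),                 # below min size
    small_after = c(sprintf("g%03d", 55:60), sprintf("x%d", 1:10)),
    enriched = sprintf("g%03d", 1:20),
    whole = universe)
  res <- enrich_terms(flags, coll, min_term_size = 10)
  expect_setequal(res$term_id, c("enriched", "whole"))
  expect_equal(res$p_value[res$term_id == "whole"], 1)
  expect_equal(res$g[res$term_id == "whole"], 12L)
  expect_lt(res$p_value[res$term_id == "enriched"], 0.001)
  expect_equal(res$term_id[1], "enriched")
  expect_warning(empty <- enrich_terms(flags, list()), "empty")
  expect_equal(nrow(empty), 0L)
})
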