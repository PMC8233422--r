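# Relationship matrices for single-step evaluation: tabular pedigree A,
# inbreeding and sparse A-inverse by Henderson's rules, the genotyped-subset
# block A22, the VanRaden genomic matrix G, and the combined H-inverse
#   H^{-1} = A^{-1} + [0 0; 0 G*^{-1} - A22^{-1}]
# on the genotyped coordinates, with G blended towards A22 for invertibility.

validate_pedigree <- function(pedigree) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(pedigree)))
    data_error("pedigree needs columns animal, sire, dam")
  n <- nrow(pedigree)
  if (!identical(as.integer(pedigree$animal), seq_len(n)))
    data_error("pedigree animals must be numbered 1..n in topological order")
  s <- as.integer(pedigree$sire); d <- as.integer(pedigree$dam)
  if (any(s < 0L) || any(d < 0L) || any(s > n) || any(d > n))
    data_error("parent ids must be 0 (unknown) or valid animal ids")
  if (any(s >= pedigree$animal & s > 0L) || any(d >= pedigree$animal & d > 0L))
    data_error("pedigree not topologically ordered (or animal is its own ancestor)")
  invisible(pedigree)
}

#' Tabular pedigree relationship matrix
#'
#' Dense numerator relationship matrix by the tabular method. Intended for
#' small pedigrees and for the genotyped-subset block; complexity is O(n^2).
#'
#' @param pedigree Topologically ordered pedigree `data.frame` with columns
#'   `animal` (1..n), `sire`, `dam` (0 = unknown).
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
pedigree_a <- function(pedigree) {
  validate_pedigree(pedigree)
  n <- nrow(pedigree)
  A <- matrix(0, n, n)
  s <- as.integer(pedigree$sire); d <- as.integer(pedigree$dam)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      ai <- 0.5 * ((if (s[i] > 0L) A[s[i], prev] else 0) +
                   (if (d[i] > 0L) A[d[i], prev] else 0))
      A[i, prev] <- ai
      A[prev, i] <- ai
    }
    A[i, i] <- 1 + 0.5 * (if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0)
  }
  dimnames(A) <- list(as.character(pedigree$animal),
                      as.character(pedigree$animal))
  A
}

#' Inbreeding coefficients and sparse A-inverse
#'
#' Inbreeding is computed exactly by memoised kinship recursion; the inverse
#' numerator relationship matrix is assembled directly by Henderson's rules
#' with inbreeding, using the Mendelian-sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (with the usual adjustments for unknown
#' parents). On any pedigree the assembled sparse matrix equals the dense
#' inverse of the tabular A.
#'
#' @inheritParams pedigree_a
#' @return A list with `F` (per-animal inbreeding coefficients) and `A_inv`
#'   (sparse symmetric matrix, animal ids as dimnames).
#' @export
a_inverse <- function(pedigree) {
  validate_pedigree(pedigree)
  s <- as.integer(pedigree$sire); d <- as.integer(pedigree$dam)
  Fped <- .cpp_inbreeding(s, d)
  tr <- .cpp_ainv_triplets(s, d, Fped)
  ids <- as.character(pedigree$animal)
  A_inv <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                dims = c(length(s), length(s)),
                                dimnames = list(ids, ids))
  list(F = setNames(Fped, ids), A_inv = A_inv)
}

#' Pedigree inbreeding coefficients
#'
#' @inheritParams pedigree_a
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(pedigree) a_inverse(pedigree)$F

# ancestor closure of a set of animals (indices), including the set itself
ancestor_closure <- function(pedigree, idx) {
  s <- as.integer(pedigree$sire); d <- as.integer(pedigree$dam)
  keep <- logical(nrow(pedigree))
  keep[idx] <- TRUE
  for (i in rev(seq_len(nrow(pedigree)))) {
    if (keep[i]) {
      if (s[i] > 0L) keep[s[i]] <- TRUE
      if (d[i] > 0L) keep[d[i]] <- TRUE
    }
  }
  which(keep)
}

#' Pedigree relationships among the genotyped animals (A22)
#'
#' Tabular-method relationships restricted to the genotyped subset. The
#' pedigree is first pruned to the ancestor closure of the genotyped animals,
#' so all ancestral paths through non-genotyped animals are retained.
#'
#' @inheritParams pedigree_a
#' @param genotyped_ids Animal ids of the genotyped subset.
#' @return Dense symmetric matrix over `genotyped_ids` (in that order).
#' @export
a22 <- function(pedigree, genotyped_ids) {
  validate_pedigree(pedigree)
  idx <- match(as.character(genotyped_ids), as.character(pedigree$animal))
  if (anyNA(idx))
    data_error("genotyped id(s) absent from pedigree: %s",
               paste(genotyped_ids[is.na(idx)], collapse = ", "))
  keep <- ancestor_closure(pedigree, idx)
  remap <- integer(nrow(pedigree))
  remap[keep] <- seq_along(keep)
  sub <- data.frame(
    animal = seq_along(keep),
    sire = ifelse(pedigree$sire[keep] > 0L, remap[pmax(pedigree$sire[keep], 1L)], 0L),
    dam = ifelse(pedigree$dam[keep] > 0L, remap[pmax(pedigree$dam[keep], 1L)], 0L))
  A <- pedigree_a(sub)
  out <- A[remap[idx], remap[idx], drop = FALSE]
  dimnames(out) <- list(as.character(genotyped_ids),
                        as.character(genotyped_ids))
  out
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = W W' / (2 * sum p_j (1 - p_j))` where `W` is the dosage matrix
#' centred by twice the observed allele frequency of each SNP.
#'
#' @param genotypes Complete (imputed) dosage matrix, animals x SNPs.
#' @return Dense symmetric matrix with animal ids as dimnames, with the
#'   observed allele frequencies attached as attribute `allele_freq`.
#' @export
g_matrix <- function(genotypes) {
  if (anyNA(genotypes))
    data_error("genotypes contain missing calls; impute before building G")
  if (nrow(genotypes) < 2L) data_error("G needs at least 2 animals")
  p <- colMeans(genotypes) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    data_error("all SNPs monomorphic: zero denominator for G")
  W <- sweep(genotypes, 2L, 2 * p)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  attr(G, "allele_freq") <- p
  G
}

#' Single-step H-inverse
#'
#' Combines the sparse pedigree A-inverse with the genomic information of the
#' genotyped subset: `G* = blend * G + (1 - blend) * A22` is inverted and
#' `G*^{-1} - A22^{-1}` is added on the genotyped coordinates. With no
#' genotyped animals, or with `G = A22` and `blend = 1`, the result is
#' exactly `A^{-1}`.
#'
#' @param A_inv Sparse A-inverse with animal ids as dimnames (from
#'   [a_inverse()]).
#' @param A22 Dense pedigree relationships of the genotyped subset.
#' @param G Dense genomic relationship matrix (same animals and order as
#'   `A22`).
#' @param blend Weight on `G` in the blend, in (0, 1]; the 0.95/0.05 default
#'   is the standard remedy for a singular `G`.
#' @return Sparse symmetric H-inverse with the dimnames of `A_inv`.
#' @export
h_inverse <- function(A_inv, A22, G, blend = 0.95) {
  if (blend <= 0 || blend > 1) config_error("blend must lie in (0, 1]")
  gen_ids <- rownames(A22)
  if (is.null(gen_ids) || length(gen_ids) == 0L)
    return(forceSymmetric(A_inv))
  if (!identical(dim(A22), dim(G)) ||
      !identical(rownames(A22), rownames(G)))
    data_error("A22 and G must cover the same animals in the same order")
  idx <- match(gen_ids, rownames(A_inv))
  if (anyNA(idx)) data_error("genotyped animal(s) absent from A-inverse")
  G_star <- blend * G + (1 - blend) * A22
  rc <- rcond(G_star)
  if (!is.finite(rc) || rc < 1e-12)
    data_error("blended G is numerically singular (reciprocal condition number %.2e)", rc)
  corr <- solve(G_star) - solve(A22)
  H_inv <- as(A_inv, "CsparseMatrix")
  H_inv[idx, idx] <- H_inv[idx, idx] + corr
  forceSymmetric(H_inv)
}
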