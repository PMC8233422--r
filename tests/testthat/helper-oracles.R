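# Independent oracles used to check the implementation by a second route.

# exhaustive enumeration of the hypergeometric upper tail: draw every
# K-subset of a universe whose first S members are flagged and tally overlap
enumerate_hyper_tail <- function(N, S, K, g) {
  subsets <- utils::combn(N, K)
  overlap <- colSums(subsets <= S)
  mean(overlap >= g)
}

# dense mixed-model-equations solution for fixed liabilities and variances;
# parameterisation matches model_design (first factor free, later factors
# corner-constrained with level 1 dropped)
mme_oracle <- function(design, hinv, sigma2_a, sigma2_ss, z) {
  n <- length(z)
  Xs <- list()
  keep_names <- character(0)
  for (k in seq_along(design$factors)) {
    lv <- design$level_names[[k]]
    drop1 <- design$constrained[k]
    for (l in seq_along(lv)) {
      if (drop1 && l == 1L) next
      Xs[[length(Xs) + 1L]] <- as.numeric(design$factor_idx[, k] == l)
      keep_names <- c(keep_names,
                      paste(design$factors[k], lv[l], sep = ":"))
    }
  }
  X <- if (length(Xs)) do.call(cbind, Xs) else matrix(0, n, 0)
  n_anim <- length(design$animal_ids)
  n_sire <- length(design$sire_ids)
  Z1 <- matrix(0, n, n_anim); Z1[cbind(seq_len(n), design$animal_idx)] <- 1
  Z2 <- matrix(0, n, n_sire); Z2[cbind(seq_len(n), design$sire_idx)] <- 1
  W <- cbind(X, Z1, Z2)
  p <- ncol(X)
  P <- matrix(0, ncol(W), ncol(W))
  P[p + seq_len(n_anim), p + seq_len(n_anim)] <- as.matrix(hinv) / sigma2_a
  P[p + n_anim + seq_len(n_sire), p + n_anim + seq_len(n_sire)] <-
    diag(n_sire) / sigma2_ss
  sol <- solve(crossprod(W) + P, crossprod(W, z))
  list(beta = if (p) setNames(sol[seq_len(p)], keep_names) else numeric(0),
       a = sol[p + seq_len(n_anim)],
       ss = sol[p + n_anim + seq_len(n_sire)])
}
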