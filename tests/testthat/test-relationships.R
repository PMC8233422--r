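# Pedigree algebra (tabular A, inbreeding, Henderson A-inverse), genotyped
# block A22, VanRaden G, and the single-step H-inverse.

test_that("worked pedigree examples match the tabular algebra", {
  # single founder
  one <- data.frame(animal = 1L, sire = 0L, dam = 0L)
  expect_equal(unname(pedigree_a(one)), matrix(1))
  expect_equal(unname(as.matrix(a_inverse(one)$A_inv)), matrix(1))

  # two unrelated founders and their offspring
  trio <- data.frame(animal = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  A <- pedigree_a(trio)
  expect_equal(unname(A), matrix(c(1, 0, .5, 0, 1, .5, .5, .5, 1), 3))
  expect_equal(unname(as.matrix(a_inverse(trio)$A_inv)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3))

  # full-sib mating: offspring of two full sibs has F = 0.25
  ped <- data.frame(animal = 1:5, sire = c(0L, 0L, 1L, 1L, 3L),
                    dam = c(0L, 0L, 2L, 2L, 4L))
  expect_equal(unname(inbreeding(ped)[5]), 0.25)
  expect_equal(unname(diag(pedigree_a(ped))), 1 + unname(inbreeding(ped)))
})

test_that("sparse Henderson A-inverse equals the dense tabular inverse", {
  for (seed in 1:10) {
    ped <- random_pedigree(sample(20:120, 1), seed = seed)
    res <- a_inverse(ped)
    A <- pedigree_a(ped)
    expect_lt(max(abs(as.matrix(res$A_inv) - solve(A))), 1e-10)
    expect_equal(unname(diag(A)), 1 + unname(res$F))
  }
})

test_that("pedigree validation rejects malformed pedigrees", {
  bad <- data.frame(animal = 1:3, sire = c(0L, 3L, 1L), dam = c(0L, 0L, 2L))
  expect_error(a_inverse(bad), class = "liabscan_data_error")
  expect_error(a_inverse(data.frame(animal = c(1L, 3L), sire = 0L, dam = 0L)),
               class = "liabscan_data_error")
})

test_that("A22 equals the matching block of the full tabular A", {
  ped <- random_pedigree(100, seed = 42)
  A <- pedigree_a(ped)
  ids <- sort(sample(ped$animal, 30))
  expect_equal(a22(ped, ids), A[as.character(ids), as.character(ids)])
  # all animals genotyped: A22 is the full matrix
  expect_equal(a22(ped, ped$animal), A)
  expect_error(a22(ped, c(1, 999)), class = "liabscan_data_error")
})

test_that("A22 keeps relationships routed through ungenotyped ancestors", {
  # grandparent and grandchild genotyped, intermediate generation not
  ped <- data.frame(animal = 1:5, sire = c(0L, 0L, 1L, 0L, 3L),
                    dam = c(0L, 0L, 2L, 0L, 4L))
  A22g <- a22(ped, c(1L, 5L))
  expect_equal(unname(A22g[1, 2]), 0.25)
})

test_that("VanRaden G matches its defining formula", {
  g <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2, dimnames = list(1:3, c("S1", "S2")))
  G <- g_matrix(g)
  expect_equal(unname(G), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3),
               ignore_attr = TRUE)
  # identical genotypes: off-diagonal equals the diagonals
  g2 <- rbind(g, g[1, , drop = FALSE])
  rownames(g2) <- 1:4
  G2 <- g_matrix(g2)
  expect_equal(G2[1, 4], G2[1, 1])
  # base population: mean diagonal near 1
  big <- random_dosages(300, runif(4000, 0.1, 0.5), seed = 13)
  expect_lt(abs(mean(diag(g_matrix(big))) - 1), 0.05)
  mono <- matrix(2L, 3, 2, dimnames = list(1:3, c("a", "b")))
  expect_error(g_matrix(mono), class = "liabscan_data_error")
})

test_that("H-inverse reduces to A-inverse in its exact special cases", {
  ped <- random_pedigree(60, seed = 7)
  ai <- a_inverse(ped)
  # no genotyped animals
  empty <- matrix(numeric(0), 0, 0)
  expect_equal(as.matrix(h_inverse(ai$A_inv, empty, empty)),
               as.matrix(ai$A_inv))
  # G identical to A22 with blend 1: the correction cancels exactly
  ids <- as.character(sort(sample(ped$animal, 20)))
  A22m <- a22(ped, ids)
  H <- h_inverse(ai$A_inv, A22m, A22m, blend = 1)
  expect_lt(max(abs(as.matrix(H) - as.matrix(ai$A_inv))), 1e-10)
})

test_that("H from inverting H-inverse matches the composite closed form", {
  ped <- random_pedigree(50, seed = 3)
  ai <- a_inverse(ped)
  ids <- as.character(sort(sample(ped$animal, 20)))
  A22m <- a22(ped, ids)
  G <- g_matrix(random_dosages(20, runif(500, 0.15, 0.5), seed = 31))
  dimnames(G) <- list(ids, ids)
  blend <- 0.95
  Hinv <- h_inverse(ai$A_inv, A22m, G, blend = blend)
  H <- solve(as.matrix(Hinv))

  A <- pedigree_a(ped)
  gi <- match(ids, rownames(A))
  ni <- setdiff(seq_len(nrow(A)), gi)
  Gs <- blend * G + (1 - blend) * A22m
  A22i <- solve(A[gi, gi])
  H22 <- Gs
  H12 <- A[ni, gi] %*% A22i %*% Gs
  H11 <- A[ni, ni] + A[ni, gi] %*% A22i %*% (Gs - A[gi, gi]) %*% A22i %*% A[gi, ni]
  expect_lt(max(abs(H[gi, gi] - H22)), 1e-8)
  expect_lt(max(abs(H[ni, gi] - H12)), 1e-8)
  expect_lt(max(abs(H[ni, ni] - H11)), 1e-8)
  expect_true(all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0))
})
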