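test_that("identity permutation is (+1, ..., +n) and at distance zero from itself", {
  expect_identical(geneOrder(identityPermutation(3)), c(1L, 2L, 3L))
  expect_identical(geneOrder(identityPermutation(1)), 1L)
  id5 <- identityPermutation(5)
  expect_equal(dcjDistance(id5, id5), 0L)
  expect_equal(reversalDistance(id5, id5), 0L)
  expect_error(identityPermutation(0), "positive")
  expect_error(SignedPermutation(c(1L, 2L, 2L)), "1\\.\\.3")
})

test_that("reversals flip segment order and signs, and are involutions", {
  expect_identical(
    geneOrder(applyReversal(SignedPermutation(1:3), ReversalOp(1, 3))),
    c(-3L, -2L, -1L))
  expect_identical(
    geneOrder(applyReversal(SignedPermutation(1:4),
                            ReversalOp(2, 4, mode = "elements"))),
    c(1L, -4L, -3L, -2L))
  expect_error(applyReversal(SignedPermutation(1:3), ReversalOp(2, 4)),
               "invalid reversal")
  expect_error(applyReversal(SignedPermutation(1:3),
                             ReversalOp(2, 5, mode = "elements")),
               "unknown gene")
  set.seed(101)
  for (i in 1:500) {
    n <- sample(2:10, 1)
    p <- SignedPermutation(rand_perm(n))
    ab <- sort(sample.int(n, 2))
    op <- ReversalOp(ab[1], ab[2])
    expect_identical(geneOrder(applyReversal(applyReversal(p, op), op)),
                     geneOrder(p))
  }
})

test_that("relabel composes with the inverse and preserves BFS distance (left invariance)", {
  set.seed(102)
  for (i in 1:50) {
    p <- randomPermutation(6)
    expect_identical(geneOrder(relabel(p, p)), 1:6)
    expect_identical(geneOrder(relabel(p, identityPermutation(6))),
                     geneOrder(p))
  }
  # exhaustive on all pairs of the 8-element group at n = 2
  M <- enumerateSignedPermutations(2)
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(nrow(M))) {
      p <- SignedPermutation(M[i, ]); q <- SignedPermutation(M[j, ])
      expect_equal(bfsOracleDistance(p, q),
                   bfsOracleDistance(relabel(p, q), identityPermutation(2)))
    }
  }
  # sampled at n = 4
  set.seed(103)
  id4 <- identityPermutation(4)
  for (i in 1:100) {
    p <- SignedPermutation(rand_perm(4))
    q <- SignedPermutation(rand_perm(4))
    expect_equal(bfsOracleDistance(p, q),
                 bfsOracleDistance(relabel(p, q), id4))
  }
})

test_that("uniform sampling covers the signed group with the right frequencies", {
  set.seed(104)
  s1 <- replicate(1000, geneOrder(randomPermutation(1)))
  expect_true(abs(mean(s1 == 1L) - 0.5) <= 0.05)
  draws <- replicate(8000, paste(geneOrder(randomPermutation(2)),
                                 collapse = " "))
  tab <- table(draws)
  expect_length(tab, 8L)
  expect_true(all(abs(tab / 8000 - 0.125) <= 0.03))
  # chi-square uniformity over the 8 cells
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.001)
  # seeded determinism
  a <- geneOrder(randomPermutation(50, seed = 7))
  b <- geneOrder(randomPermutation(50, seed = 7))
  expect_identical(a, b)
})
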