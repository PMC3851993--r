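test_that("distance breakdown handles the trivial and one-step cases", {
  id <- identityPermutation(4)
  b <- distanceBreakdown(id, id)
  expect_equal(b@dcj, 0L)
  expect_equal(b@reversal, 0L)
  expect_equal(reversalDistance(SignedPermutation(-1L)), 1L)
  expect_equal(dcjDistance(SignedPermutation(-1L)), 1L)
  expect_error(distanceBreakdown(identityPermutation(3),
                                 identityPermutation(4)),
               "same number of genes")
})

test_that("the assembled reversal distance matches BFS exhaustively at n = 2 and 3", {
  for (n in 2:3) {
    tab <- bfsDistanceTable(n)
    M <- enumerateSignedPermutations(n)
    expect_equal(nrow(M), 2^n * factorial(n))
    hp <- vapply(seq_len(nrow(M)), function(i)
      reversalDistance(SignedPermutation(M[i, ])), integer(1L))
    bfs <- unname(tab[apply(M, 1L, paste, collapse = " ")])
    expect_identical(hp, bfs)
  }
})

test_that("both distances satisfy the metric axioms and dcj <= reversal", {
  set.seed(130)
  for (i in 1:200) {
    p <- SignedPermutation(rand_perm(8))
    q <- SignedPermutation(rand_perm(8))
    r <- SignedPermutation(rand_perm(8))
    for (metric in c("dcj", "reversal")) {
      d <- function(a, b) {
        bd <- distanceBreakdown(a, b)
        if (metric == "dcj") bd@dcj else bd@reversal
      }
      dpq <- d(p, q); dqr <- d(q, r); dpr <- d(p, r)
      expect_equal(d(p, p), 0L)
      expect_equal(dpq, d(q, p))
      expect_lte(dpr, dpq + dqr)
    }
    bd <- distanceBreakdown(p, q)
    expect_lte(bd@dcj, bd@reversal)
    expect_equal(bd@reversal, bd@dcj + bd@hurdles + bd@fortress)
  }
})

test_that("the BFS oracle is symmetric, refuses large n, and is zero on equal genomes", {
  expect_equal(bfsOracleDistance(identityPermutation(3),
                                 identityPermutation(3)), 0L)
  expect_equal(bfsOracleDistance(identityPermutation(3),
                                 SignedPermutation(c(-3L, -2L, -1L))), 1L)
  expect_error(bfsOracleDistance(identityPermutation(8),
                                 identityPermutation(8)), "n <= 7")
  set.seed(131)
  for (i in 1:30) {
    p <- SignedPermutation(rand_perm(4))
    q <- SignedPermutation(rand_perm(4))
    expect_equal(bfsOracleDistance(p, q), bfsOracleDistance(q, p))
  }
  for (i in 1:5) {
    p <- SignedPermutation(rand_perm(5))
    q <- SignedPermutation(rand_perm(5))
    expect_equal(bfsOracleDistance(p, q), bfsOracleDistance(q, p))
  }
})

test_that("one walk step moves each distance by at most one (Lipschitz along trajectories)", {
  set.seed(132)
  for (rep in 1:10) {
    traj <- runWalk(30, steps = 15, seed = 1000 + rep)
    for (metric in c("dcj", "reversal")) {
      prof <- distanceProfile(traj, metric, at = 0:15)
      expect_true(all(abs(diff(prof$distance)) <= 1L))
      expect_true(all(prof$distance <= prof$step))
      expect_equal(prof$distance[1], 0L)
    }
  }
})
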