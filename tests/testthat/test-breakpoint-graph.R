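test_that("the identity graph has n+1 trivial cycles with all-positive orientation", {
  for (n in c(1, 3, 7)) {
    bp <- buildBreakpointGraph(identityPermutation(n))
    expect_equal(countCycles(bp), n + 1L)
    cl <- classifyCycles(bp)
    expect_true(all(cl$length == 1L))
    expect_true(all(!cl$oriented))
    expect_true(all(edgeOrientations(bp)$black == 1L))
    ch <- componentsHurdles(bp)
    expect_equal(ch$h, 0L)
    expect_equal(ch$fortress, 0L)
  }
})

test_that("edge counts and degree invariants hold; non-identity genomes lose cycles", {
  bp <- buildBreakpointGraph(SignedPermutation(c(-3L, -2L, -1L)))
  expect_equal(nrow(bp@blackEdges), 4L)
  expect_equal(nrow(bp@greyEdges), 4L)
  expect_true(validObject(bp))
  set.seed(120)
  for (i in 1:30) {
    g <- rand_perm(8)
    if (identical(g, 1:8)) next
    expect_lt(countCycles(buildBreakpointGraph(SignedPermutation(g))), 9L)
  }
  # one non-redundant reversal of the identity leaves exactly n cycles
  p <- applyReversal(identityPermutation(10), ReversalOp(3, 6))
  expect_equal(countCycles(buildBreakpointGraph(p)), 10L)
})

test_that("cycle counts agree with an independent union-find recount", {
  set.seed(121)
  for (i in 1:200) {
    g <- rand_perm(8)
    expect_equal(countCycles(buildBreakpointGraph(SignedPermutation(g))),
                 uf_cycle_count(g))
  }
})

test_that("orientation labels are deterministic and govern cycle splitting", {
  set.seed(122)
  # determinism: rebuilding gives identical labels
  g <- rand_perm(9)
  bp1 <- buildBreakpointGraph(SignedPermutation(g))
  bp2 <- buildBreakpointGraph(SignedPermutation(g))
  expect_identical(edgeOrientations(bp1), edgeOrientations(bp2))

  # a reversal on black edges a and b+1 (positions [a, b]) merges two
  # cycles, splits one cycle iff the two edges are crossing (opposite
  # orientation), and otherwise leaves the count unchanged
  for (i in 1:500) {
    n <- 7L
    g <- rand_perm(n)
    bp <- medianwalk:::.bp_build(g)
    if (runif(1) < 0.15) {
      a <- sample.int(n, 1); b <- a
    } else {
      ab <- sort(sample.int(n, 2)); a <- ab[1]; b <- ab[2]
    }
    e1 <- a; e2 <- b + 1L
    g2 <- g; g2[a:b] <- -rev(g2[a:b])
    dC <- medianwalk:::.bp_build(g2)$ncyc - bp$ncyc
    if (bp$blackCycle[e1] != bp$blackCycle[e2]) {
      expect_equal(dC, -1L)
    } else if (bp$blackXi[e1] != bp$blackXi[e2]) {
      expect_equal(dC, 1L)
    } else {
      expect_equal(dC, 0L)
    }
  }
})

test_that("every oriented cycle admits a cycle-splitting reversal; parallel two-edge cycles are unoriented", {
  set.seed(123)
  for (i in 1:50) {
    n <- 7L
    g <- rand_perm(n)
    bp <- medianwalk:::.bp_build(g)
    cl <- classifyCycles(buildBreakpointGraph(SignedPermutation(g)))
    for (ci in cl$cycle[cl$oriented]) {
      edges <- which(bp$blackCycle == ci)
      found <- FALSE
      for (a in edges) {
        for (b in edges) {
          if (a >= b) next
          g2 <- g; g2[a:(b - 1L)] <- -rev(g2[a:(b - 1L)])
          if (medianwalk:::.bp_build(g2)$ncyc == bp$ncyc + 1L) found <- TRUE
        }
      }
      expect_true(found)
    }
    # unoriented length-2 cycles have parallel black edges
    for (ci in cl$cycle[!cl$oriented & cl$length == 2L]) {
      xi <- bp$blackXi[bp$blackCycle == ci]
      expect_equal(xi[1], xi[2])
    }
  }
})

test_that("hurdles make the HP distance exceed DCJ ((3,2,1) and (2,1) are classic hurdles)", {
  b <- distanceBreakdown(SignedPermutation(c(3L, 2L, 1L)))
  expect_equal(b@cycles, 2L)
  expect_equal(b@hurdles, 1L)
  expect_equal(b@dcj, 2L)
  expect_equal(b@reversal, 3L)
  b2 <- distanceBreakdown(SignedPermutation(c(2L, 1L)))
  expect_equal(b2@hurdles, 1L)
  expect_equal(b2@reversal, 3L)
})

test_that("a constructed fortress is recognised and its distance certified by an actual scenario", {
  g <- fortress_permutation()
  p <- SignedPermutation(g)
  ch <- componentsHurdles(buildBreakpointGraph(p))
  expect_equal(ch$h, 3L)
  expect_true(all(ch$components$superHurdle[ch$components$hurdle]))
  expect_equal(ch$fortress, 1L)
  b <- distanceBreakdown(p)
  expect_equal(b@reversal, b@dcj + 3L + 1L)
  # greedy sorting following the formula reaches the identity in exactly
  # the formula's number of reversals: an explicit scenario of that length
  expect_equal(greedy_sort_len(g), b@reversal)
  # a single nested-pair block alone is two hurdles, no fortress
  blk <- g[1:8]
  chb <- componentsHurdles(buildBreakpointGraph(SignedPermutation(blk)))
  expect_equal(chb$h, 2L)
  expect_equal(chb$fortress, 0L)
})

test_that("greedy HP-guided sorting always sorts in exactly the claimed distance", {
  set.seed(124)
  for (i in 1:10) {
    g <- rand_perm(10)
    expect_equal(greedy_sort_len(g),
                 reversalDistance(SignedPermutation(g)))
  }
})

test_that("the debug dump lists every edge with cycle and orientation", {
  lines <- dumpBreakpointGraph(buildBreakpointGraph(identityPermutation(3)),
                               file = tempfile())
  expect_length(lines, 8L)
  expect_true(all(grepl("cycle=", lines)))
})
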