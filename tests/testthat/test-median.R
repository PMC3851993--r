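test_that("total distance sums the per-genome metric", {
  id <- identityPermutation(6)
  expect_equal(totalDistance(id, list(id, id, id)), 0)
  set.seed(150)
  for (i in 1:20) {
    A <- lapply(1:3, function(j) SignedPermutation(rand_perm(6)))
    x <- SignedPermutation(rand_perm(6))
    for (metric in c("dcj", "reversal")) {
      direct <- sum(vapply(A, function(y) {
        bd <- distanceBreakdown(x, y)
        if (metric == "dcj") bd@dcj else bd@reversal
      }, integer(1L)))
      expect_equal(totalDistance(x, A, metric), direct)
    }
    # two identical members reduce total distance at p to one distance
    p <- A[[1L]]
    expect_equal(totalDistance(p, list(id, p, p), "reversal"),
                 reversalDistance(p))
  }
})

test_that("perimeter bound and input upper bound sandwich the exhaustive median", {
  id <- identityPermutation(5)
  expect_equal(perimeterLowerBound(list(id, id, id)), 0L)
  set.seed(151)
  for (i in 1:25) {
    A <- lapply(1:3, function(j) SignedPermutation(rand_perm(5)))
    for (metric in c("dcj", "reversal")) {
      lb <- perimeterLowerBound(A, metric)
      ub <- inputUpperBound(A, metric)
      expect_lte(lb, ub$value)
      m <- medianValue(medianExact(A, metric, mode = "exhaustive"))
      expect_lte(lb, m)
      expect_lte(m, ub$value)
    }
  }
  # triangle-tight family {id, p, p}: median is p with value d(id, p)
  for (i in 1:15) {
    p <- SignedPermutation(rand_perm(5))
    A <- list(id, p, p)
    d <- reversalDistance(p)
    expect_equal(perimeterLowerBound(A, "reversal"), d)
    ub <- inputUpperBound(A, "reversal")
    expect_equal(ub$value, d)
    res <- medianExact(A, "reversal")
    expect_equal(medianValue(res), d)
    expect_equal(totalDistance(medianWitness(res), A, "reversal"),
                 medianValue(res))
  }
})

test_that("branch-and-bound agrees with exhaustive enumeration and closes", {
  set.seed(152)
  for (i in 1:15) {
    A <- lapply(1:3, function(j) SignedPermutation(rand_perm(4)))
    for (metric in c("dcj", "reversal")) {
      ex <- medianExact(A, metric, mode = "exhaustive")
      bb <- medianExact(A, metric, mode = "bnb", budget = 1e5)
      expect_true(isClosed(ex))
      expect_true(isClosed(bb))
      expect_equal(medianValue(bb), medianValue(ex))
      expect_equal(totalDistance(medianWitness(bb), A, metric),
                   medianValue(bb))
    }
  }
  for (i in 1:3) {
    A <- lapply(1:3, function(j) SignedPermutation(rand_perm(5)))
    ex <- medianExact(A, "reversal", mode = "exhaustive")
    bb <- medianExact(A, "reversal", mode = "bnb", budget = 2e5)
    expect_equal(medianValue(bb), medianValue(ex))
  }
})

test_that("an exhausted search budget yields a flagged open interval, never a silent value", {
  set.seed(153)
  repeat {   # find an instance the certificate alone cannot close
    A <- lapply(1:3, function(j) SignedPermutation(rand_perm(5)))
    if (inputUpperBound(A, "reversal")$value >
        perimeterLowerBound(A, "reversal")) break
  }
  res <- medianExact(A, "reversal", mode = "bnb", budget = 0)
  expect_false(isClosed(res))
  expect_true(is.na(medianValue(res)))
  b <- medianBounds(res)
  expect_lte(b["lower"], b["upper"])
})

test_that("epsilon is zero for unmoved ensembles and certified below the phase", {
  ev0 <- epsilonValue(runEnsemble(3, n = 60, steps = 0, seed = 4), "dcj")
  expect_equal(ev0$epsilon, 0)
  expect_equal(medianValue(ev0$median), 0)
  # below the phase (u/n = 0.1 < 1/4) the certificate usually proves
  # m = k u, hence epsilon = 0
  hits <- 0L
  for (r in 1:5) {
    gs <- runEnsemble(3, n = 100, steps = 10, seed = 200 + r)
    ev <- epsilonValue(gs, "reversal")
    if (isClosed(ev$median) && identical(ev$epsilon, 0)) hits <- hits + 1L
    if (isClosed(ev$median)) expect_gte(ev$epsilon, 0)
  }
  expect_gte(hits, 3L)
  # epsilon >= 0 on exhaustively solved random instances too
  set.seed(154)
  for (i in 1:10) {
    A <- lapply(1:3, function(j) SignedPermutation(rand_perm(5)))
    ev <- epsilonValue(A, "dcj", mode = "exhaustive")
    expect_gte(ev$epsilon, 0)
  }
})
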