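test_that("at n = 2 the only element pair forces the full reversal", {
  set.seed(140)
  for (i in 1:10) {
    st <- stepWalk(identityPermutation(2))
    expect_identical(geneOrder(st$state), c(-2L, -1L))
  }
  expect_error(stepWalk(identityPermutation(1)), "n >= 2")
})

test_that("element pairs are drawn uniformly", {
  set.seed(141)
  id4 <- identityPermutation(4)
  keys <- replicate(3000, {
    st <- stepWalk(id4)
    paste(st$op@a, st$op@b)
  })
  tab <- table(keys)
  expect_length(tab, 6L)           # the choose(4,2) pairs
  expect_true(all(abs(tab / 3000 - 1 / 6) <= 0.03))
})

test_that("walks are deterministic given the seed and replay to their endpoint", {
  t1 <- runWalk(40, steps = 25, seed = 9)
  t2 <- runWalk(40, steps = 25, seed = 9)
  expect_identical(t1@ops, t2@ops)
  expect_identical(geneOrder(walkEndpoint(t1)), geneOrder(walkEndpoint(t2)))
  expect_identical(geneOrder(replayTrajectory(t1)),
                   geneOrder(walkEndpoint(t1)))
  expect_identical(geneOrder(runWalk(10, steps = 0, seed = 1)@endpoint),
                   1:10)
  # the alternative black-edge-gap sampling also replays exactly
  t3 <- runWalk(30, steps = 20, sampling = "positions_with_singletons",
                seed = 5)
  expect_identical(geneOrder(replayTrajectory(t3)),
                   geneOrder(walkEndpoint(t3)))
  # after one step the distance is exactly one
  t4 <- runWalk(10, steps = 1, seed = 2)
  expect_equal(reversalDistance(walkEndpoint(t4)), 1L)
})

test_that("the Poisson schedule draws its step count from a rate-1 clock", {
  t0 <- runWalk(10, time = 0, seed = 3)
  expect_equal(walkSteps(t0), 0L)
  expect_identical(geneOrder(walkEndpoint(t0)), 1:10)
  set.seed(142)
  steps <- replicate(300, walkSteps(runWalk(5, time = 3)))
  expect_gt(mean(steps), 2.5)
  expect_lt(mean(steps), 3.5)
  ta <- runWalk(10, time = 4, seed = 11)
  tb <- runWalk(10, time = 4, seed = 11)
  expect_identical(ta@ops, tb@ops)
})

test_that("ensembles use independent child streams and obey the step bound", {
  gs <- runEnsemble(3, n = 200, steps = 0, seed = 1)
  for (e in endpoints(gs)) expect_identical(geneOrder(e), 1:200)
  gs1 <- runEnsemble(3, n = 200, steps = 10, seed = 1)
  g_id <- totalDistance(identityPermutation(200), gs1, "reversal")
  expect_lte(g_id, 30L)
  expect_equal(g_id, 0L + sum(vapply(endpoints(gs1), reversalDistance,
                                     integer(1L))))
  gs2 <- runEnsemble(3, n = 50, steps = 5, seed = 1)
  gs3 <- runEnsemble(3, n = 50, steps = 5, seed = 2)
  same <- mapply(function(a, b) identical(geneOrder(a), geneOrder(b)),
                 endpoints(gs2), endpoints(gs3))
  expect_false(all(same))
})

test_that("mean distance grows with the step count and tracks (1 - f(c)) n", {
  set.seed(143)
  n <- 1000L
  checkpoints <- c(0L, 125L, 250L, 500L)
  means <- sapply(seq_along(checkpoints), function(j) {
    mean(sapply(1:5, function(r) {
      traj <- runWalk(n, steps = checkpoints[j], seed = 5000 + 10 * j + r,
                      record = FALSE)
      dcjDistance(walkEndpoint(traj))
    }))
  })
  expect_true(all(diff(means) >= -0.005 * n))
  # c = 0.5 sits in the linear regime: distance/n close to 0.25
  frac <- means[3] / n
  expect_gt(frac, 0.22)
  expect_lt(frac, 0.28)
  # the same law holds under black-edge-gap sampling
  tg <- runWalk(n, steps = 250L, sampling = "positions_with_singletons",
                seed = 77, record = FALSE)
  expect_lt(abs(dcjDistance(walkEndpoint(tg)) / n - 0.25), 0.04)
})

test_that("distance profiles respect their checkpoint contract", {
  traj <- runWalk(50, steps = 20, seed = 21)
  expect_error(distanceProfile(traj, "dcj", at = c(0, 25)), "\\[0, 20\\]")
  prof <- distanceProfile(traj, "dcj", at = c(0, 5, 20))
  expect_equal(prof$step, c(0L, 5L, 20L))
  expect_equal(prof$distance[1], 0L)
})
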