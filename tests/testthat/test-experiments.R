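test_that("experiment tables are deterministic given the master seed", {
  a <- scalingExperiment(n = 200, cGrid = 0.5, replicates = 3, seed = 7)
  b <- scalingExperiment(n = 200, cGrid = 0.5, replicates = 3, seed = 7)
  expect_identical(a, b)
  d <- scalingExperiment(n = 200, cGrid = 0.5, replicates = 3, seed = 8)
  expect_false(identical(a$dcj, d$dcj))
  expect_true(all(!is.na(a$seed)))
})

test_that("scaling rows satisfy the breakdown identity and the c = 0 degenerate case", {
  df <- scalingExperiment(n = 300, cGrid = c(0, 0.5), replicates = 4,
                          seed = 3)
  expect_equal(df$reversal - df$dcj, df$hurdles + df$fortress)
  z <- df[df$c == 0, ]
  expect_true(all(z$dcj == 0L))
  expect_true(all(z$resid_dcj == 0))
  sm <- attr(df, "summary")
  expect_equal(nrow(sm), 2L)
  # the c = 0.5 mean tracks the linear-regime prediction loosely at n = 300
  expect_lt(abs(sm$mean_dcj_n[sm$c == 0.5] - 0.25), 0.05)
})

test_that("hurdle tables expose the reversal-minus-dcj decomposition", {
  df <- hurdleExperiment(n = 300, c = 1, replicates = 5, seed = 2)
  expect_equal(mean(df$reversal - df$dcj),
               mean(df$hurdles + df$fortress))
  expect_true(all(df$u == 150L))
  df0 <- hurdleExperiment(n = 100, c = 0, replicates = 2, seed = 2)
  expect_true(all(df0$hurdles == 0L))
})

test_that("certificate success decays across the phase", {
  df <- phaseExperiment(n = 100, k = 3, u = c(0, 10, 50), replicates = 8,
                        seed = 5)
  sm <- attr(df, "summary")
  r <- sm$certificate_rate[match(c(0, 10, 50), sm$u)]
  expect_equal(r[1], 1)                # u = 0 is always certified, m = 0
  expect_gt(r[2], r[3])                # n/10 beats n/2
  expect_true(all(df$m[df$u == 0] == 0))
  expect_true(all(df$eps_lower <= df$eps_upper))
  # recovery statistic: certified below-phase medians sit at m = k u
  below <- df[df$u == 10 & df$certificate, ]
  expect_true(all(below$recovery == 1))
})

test_that("above-phase tables certify an order-n error", {
  df <- abovePhaseExperiment(n = 200, k = 3, u = 600, replicates = 4,
                             seed = 6)
  expect_true(all(df$eps_lb >= 0))
  expect_gt(mean(df$eps_lb_n), 0.2)
  expect_false(any(is.na(df$alpha)))   # u/n = 3 > 1/2
  expect_equal(df$kcn_minus_m_lb, 3 * 600 - df$upper)
})

test_that("ball-volume estimates respect the reversal-in-dcj nesting", {
  bv <- ballVolumeExperiment(n = 100, c = 0.5, draws = 200, seed = 9)
  expect_lte(bv$gamma_reversal, bv$gamma_dcj)
  expect_equal(bv$gamma_dcj, 0)
  expect_lt(bv$mean_cycles_n, 0.2)
})

test_that("the critical-constant report prints the root with its bound checks", {
  out <- capture.output(rep <- cStarReport())
  expect_true(any(grepl("c\\* = 2\\.7", out)))
  expect_true(rep$above2)
  expect_true(rep$atMost3)
})

test_that("result tables round-trip through CSV with a summary block", {
  df <- hurdleExperiment(n = 100, c = 0.5, replicates = 3, seed = 4)
  path <- tempfile(fileext = ".csv")
  writeResultTable(df, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "#summary,")))
  back <- utils::read.csv(text = lines[!startsWith(lines, "#summary,")])
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$hurdles, df$hurdles)
})
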