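test_that("extractROI aggregates valid pixels", {
  # constant map
  agg <- extractROI(constantMap(1.5), roiSpec(1, 1, 40, 40))
  expect_equal(agg$meanMuSp, 1.5)
  expect_equal(agg$sdMuSp, 0)
  expect_identical(agg$nValid, 1600L)
  # checkerboard of a and b
  cb <- matrix(1.2, 40, 40)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 1.8
  mp <- constantMap(0)
  mp@muSp[, , 1] <- cb
  agg <- extractROI(mp, roiSpec(1, 1, 40, 40))
  expect_equal(agg$meanMuSp, 1.5)
  # 10% masked pixels: mean over the remaining 90%, count 1440
  v <- matrix(TRUE, 40, 40)
  v[seq_len(160)] <- FALSE
  mp <- constantMap(2.0, valid = v)
  mp@muSp[, , 1][!v] <- 99 # masked values must not leak into the mean
  agg <- extractROI(mp, roiSpec(1, 1, 40, 40))
  expect_identical(agg$nValid, 1440L)
  expect_equal(agg$meanMuSp, 2.0)
})

test_that("extractROI rejects bad regions", {
  mp <- constantMap(1.5)
  expect_error(extractROI(mp, roiSpec(10, 10, 40, 40)), "outside the map")
  v <- matrix(FALSE, 40, 40)
  v[seq_len(400)] <- TRUE # only 25% valid
  expect_error(extractROI(constantMap(1.5, valid = v),
                          roiSpec(1, 1, 40, 40)), "valid")
})

test_that("cohortSummary computes intersubject mean and sample SD", {
  tb <- data.frame(
    subject = rep(c("S1", "S2", "S3"), 2),
    location = rep(c("forehead", "palm"), each = 3),
    wavelength = 851,
    muSp = c(1.5, 1.6, 1.7, 1.4, 1.4, 1.4))
  sm <- cohortSummary(tb, 851)
  fh <- sm[sm$location == "forehead", ]
  expect_equal(fh$mean, 1.6)
  expect_equal(fh$sd, sd(c(1.5, 1.6, 1.7))) # n - 1 denominator
  expect_identical(fh$n, 3L)
  expect_false(fh$flagged)
  # all subjects identical -> SD 0
  expect_equal(sm$sd[sm$location == "palm"], 0)
  # single-subject group flagged, SD undefined
  tb1 <- rbind(tb, data.frame(subject = "S1", location = "neck",
                              wavelength = 851, muSp = 1.2))
  sm1 <- cohortSummary(tb1, 851)
  expect_true(sm1$flagged[sm1$location == "neck"])
  expect_true(is.na(sm1$sd[sm1$location == "neck"]))
  expect_error(cohortSummary(tb, 471), "no rows")
})

test_that("coefficientOfVariation matches the definition and examples", {
  expect_equal(coefficientOfVariation(1.46, 0.115), 0.0788, tolerance = 1e-3)
  expect_equal(coefficientOfVariation(2, 1), 0.5)
  expect_equal(coefficientOfVariation(3, 0), 0)
  expect_error(coefficientOfVariation(0, 1), "> 0")
  expect_error(coefficientOfVariation(-1, 1), "> 0")
})

test_that("oneWayAnova matches the hand-computed example", {
  an <- oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  tb <- anovaTable(an)
  expect_equal(tb$ss[1], 1.5)
  expect_equal(tb$ss[2], 4.0)
  expect_equal(tb$df[1:2], c(1, 4), tolerance = 1e-12)
  expect_equal(tb$F[1], 1.5)
  # SS and df additivity
  expect_equal(tb$ss[3], tb$ss[1] + tb$ss[2])
  expect_equal(tb$df[3], tb$df[1] + tb$df[2])
  # identical groups: F = 0
  an0 <- oneWayAnova(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(anovaTable(an0)$ss[1], 0)
  expect_error(oneWayAnova(list(a = 1:3)), "at least 2 groups")
  expect_error(oneWayAnova(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("anovaFromSummary is equivalent to oneWayAnova on raw data", {
  set.seed(31)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    n <- sample(3:12, 1)
    groups <- lapply(seq_len(k), function(i)
      rnorm(n, mean = runif(1, 0, 3), sd = runif(1, 0.2, 1)))
    names(groups) <- paste0("g", seq_len(k))
    raw <- anovaTable(oneWayAnova(groups))
    sm <- anovaTable(anovaFromSummary(
      vapply(groups, mean, numeric(1)),
      vapply(groups, sd, numeric(1)),
      rep(n, k)))
    expect_equal(sm$ss, raw$ss, tolerance = 1e-10)
    expect_equal(sm$df, raw$df, tolerance = 1e-12)
    expect_equal(sm$F[1], raw$F[1], tolerance = 1e-10)
    expect_equal(sm$p[1], raw$p[1], tolerance = 1e-10)
  }
  expect_error(anovaFromSummary(c(1, 2), c(0.1), c(5, 5)), "equal length")
  expect_error(anovaFromSummary(c(1, 2), c(0.1, 0.2), c(5, 1)), "n >= 2")
  # two equal means: no between-group variation
  expect_equal(anovaTable(anovaFromSummary(c(1, 1), c(0.2, 0.3),
                                           c(5, 5)))$ss[1], 0)
})

test_that("tukeyHsd follows the studentized range distribution", {
  # two equal means -> p = 1
  tk <- tukeyHsd(c(a = 1, b = 1), mse = 0.1, dfError = 10, n = 5)
  expect_equal(tk@p["a", "b"], 1)
  expect_false(tk@significant["a", "b"])
  # monotonicity: larger |difference| at fixed MSE gives smaller p
  deltas <- seq(0.1, 1.2, by = 0.1)
  ps <- vapply(deltas, function(d)
    tukeyHsd(c(a = 0, b = d, c = 5), mse = 0.5, dfError = 20,
             n = 8)@p["a", "b"], numeric(1))
  expect_true(all(diff(ps) < 0))
  # symmetry and flag consistency
  tk <- tukeyHsd(c(a = 0, b = 1, c = 3), mse = 0.5, dfError = 20, n = 8)
  expect_identical(tk@p, t(tk@p))
  off <- row(tk@p) != col(tk@p)
  expect_identical(tk@significant[off], (tk@p < tk@alpha)[off])
  expect_error(tukeyHsd(c(a = 1), mse = 0.1, dfError = 5, n = 3),
               "at least 2 groups")
  expect_error(tukeyHsd(c(a = 1, b = 2), mse = 0, dfError = 5, n = 3),
               "mse")
})

test_that("bundled reference tables load and reconcile", {
  ref <- referenceCohortSummary()
  expect_identical(nrow(ref), 10L)
  expect_identical(names(ref), c("location", "mean", "sd"))
  expect_equal(ref$mean[ref$location == "forehead"], 1.65)
  an <- referenceAnova()
  expect_identical(an$df, c(9L, 140L, 149L))
  tk <- referenceTukey()
  expect_identical(nrow(tk), 45L)
  expect_true(all(tk$p[tk$censored] == 0.001))
  rt <- reproduceTables()
  expect_s4_class(rt$anova, "AnovaResult")
  expect_s4_class(rt$tukey, "TukeyMatrix")
  expect_identical(dim(rt$tukey@p), c(10L, 10L))
})
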