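test_that("the cleavage index follows the V1-over-T2 ratio formula", {
  bt <- makeBandTable(v1c = c(10, 10, 10), v1l = c(10, 20, 10),
                      t2c = c(10, 10, 10), t2l = c(10, 10, 20))
  rec <- computeIndex(bt)
  expect_equal(rec$index, c(1, 2, 0.5))
  expect_equal(rec$log_index, log10(c(1, 2, 0.5)))
})

test_that("index values equal a row-by-row re-evaluation on a printed table", {
  v1c <- c(12, 30, 7.5, 44, 2, 90, 18, 5)
  v1l <- c(24, 30, 15, 11, 2, 45, 54, 5)
  t2c <- c(6, 10, 30, 8, 4, 9, 6, 25)
  t2l <- c(6, 20, 30, 16, 1, 9, 2, 25)
  rec <- computeIndex(makeBandTable(v1c, v1l, t2c, t2l))
  oracle <- oracleIndexFlags(v1l, v1c, t2l, t2c)
  expect_equal(rec$index, oracle$index, tolerance = 1e-15)
  expect_equal(rec$log_index, oracle$log_index, tolerance = 1e-15)
})

test_that("zero intensities are excluded (not Inf) unless a pseudocount is used", {
  bt <- makeBandTable(v1c = c(10, 0, 10), v1l = c(10, 10, 10),
                      t2c = c(10, 10, 10), t2l = c(10, 10, 0))
  expect_warning(rec <- computeIndex(bt), "excluded")
  expect_equal(rec$position, 1L)
  expect_equal(S4Vectors::metadata(rec)$n_excluded, 2L)
  expect_true(all(is.finite(rec$index)))
  rec2 <- computeIndex(bt, pseudocount = 1)
  expect_equal(nrow(rec2), 3L)
})

test_that("the empirical null is the plain mean and sample SD of log(index)", {
  rec <- S4Vectors::DataFrame(position = 1:3,
                              index = 10^c(-0.2, 0, 0.2),
                              log_index = c(-0.2, 0, 0.2))
  null <- fitNull(rec)
  expect_equal(null@mean, 0)
  expect_equal(null@sd, 0.2)
  expect_equal(null@n, 3L)

  # degenerate: identical logs
  recD <- S4Vectors::DataFrame(position = 1:3, index = rep(1, 3),
                               log_index = rep(0, 3))
  nullD <- fitNull(recD)
  expect_equal(nullD@sd, 0)
  expect_error(callSignificant(recD, nullD), "degenerate")
  expect_error(fitNull(recD[1, ]), "at least 2")
})

test_that("large-sample null moments match a streaming oracle to 1e-12", {
  tx <- makeTranscript(defaultTranscriptPlan(), seed = 31)
  sim <- simulateFootprint(tx, noiseCV = 0.1, seed = 13)
  rec <- computeIndex(sim$bandTable)
  null <- fitNull(rec)
  stream <- oracleStreamingMoments(rec$log_index)
  expect_equal(null@mean, stream$mean, tolerance = 1e-12)
  expect_equal(null@sd, stream$sd, tolerance = 1e-12)
})

test_that("significance calls use strict two-SD exceedance with the fitted null", {
  # null parameters as estimated in the original footprinting analysis
  null <- new("NullModel", mean = -0.0011, sd = 0.20, n = 500L, k = 2,
              logBase = 10, robust = FALSE)
  rec <- S4Vectors::DataFrame(
    position = 1:4,
    index = 10^c(0.45, -0.0011 + 0.4, -0.0011 - 0.4, -0.5),
    log_index = c(0.45, -0.0011 + 0.4, -0.0011 - 0.4, -0.5))
  out <- callSignificant(rec, null)
  expect_equal(as.character(out$flag),
               c("positive", "none", "none", "negative"))
  expect_equal(out$z, (rec$log_index + 0.0011) / 0.2)
})

test_that("end-to-end flags equal the brute-force oracle on random tables", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(50:400, 1)
    v1c <- rlnorm(n); v1l <- rlnorm(n)
    t2c <- rlnorm(n); t2l <- rlnorm(n)
    rec <- computeIndex(makeBandTable(v1c, v1l, t2c, t2l))
    rec <- callSignificant(rec, fitNull(rec))
    oracle <- oracleIndexFlags(v1l, v1c, t2l, t2c)
    expect_identical(as.character(rec$flag), oracle$flag)
    expect_equal(rec$z, oracle$z, tolerance = 1e-12)
  }
})

test_that("rescaling any single lane leaves every z and flag unchanged", {
  set.seed(5)
  n <- 200
  mats <- list(v1c = rlnorm(n), v1l = rlnorm(n),
               t2c = rlnorm(n), t2l = rlnorm(n))
  base <- computeIndex(do.call(makeBandTable, mats))
  baseCalled <- callSignificant(base, fitNull(base))
  for (lane in names(mats)) {
    scaled <- mats
    scaled[[lane]] <- scaled[[lane]] * 3.7
    rec <- computeIndex(do.call(makeBandTable, scaled))
    rec <- callSignificant(rec, fitNull(rec))
    # log indices shift by a common constant; sd, z and flags are invariant
    shift <- rec$log_index - baseCalled$log_index
    expect_equal(diff(range(shift)), 0, tolerance = 1e-10)
    expect_equal(rec$z, baseCalled$z, tolerance = 1e-9)
    expect_identical(as.character(rec$flag),
                     as.character(baseCalled$flag))
  }
})

test_that("swapping ligand and control lanes inverts the index and exchanges signs", {
  set.seed(6)
  n <- 300
  v1c <- rlnorm(n); v1l <- rlnorm(n); t2c <- rlnorm(n); t2l <- rlnorm(n)
  fwd <- computeIndex(makeBandTable(v1c, v1l, t2c, t2l))
  fwd <- callSignificant(fwd, fitNull(fwd))
  rev <- computeIndex(makeBandTable(v1l, v1c, t2l, t2c))
  rev <- callSignificant(rev, fitNull(rev))
  expect_equal(rev$index, 1 / fwd$index, tolerance = 1e-12)
  expect_equal(rev$z, -fwd$z, tolerance = 1e-9)
  swap <- c(none = "none", positive = "negative", negative = "positive")
  expect_identical(as.character(rev$flag),
                   unname(swap[as.character(fwd$flag)]))
})

test_that("region summaries tally flags per region with an unannotated catch-all", {
  rec <- S4Vectors::DataFrame(position = 1:12, index = rep(1, 12),
                              log_index = rep(0, 12))
  rec$z <- c(3, -3, 0, 0, 2.5, 0, 0, 0, -2.5, 0, 3, 0)
  rec$flag <- factor(
    ifelse(rec$z > 2, "positive", ifelse(rec$z < -2, "negative", "none")),
    levels = c("none", "positive", "negative"))
  regionsDf <- data.frame(name = c("A", "B", "C"),
                          start = c(1, 5, 9), end = c(4, 8, 10))
  rs <- regionSummary(rec, regionsDf)
  expect_equal(rs$n_positions, c(4, 4, 2, 2))
  expect_equal(rs$n_positive, c(1, 1, 0, 1))
  expect_equal(rs$n_negative, c(1, 0, 1, 0))
  expect_equal(rs$density, c(2/4, 1/4, 1/2, 1/2))
  # no flags anywhere -> all densities zero
  rec0 <- rec; rec0$flag <- factor("none",
    levels = c("none", "positive", "negative"))
  rs0 <- regionSummary(rec0, regionsDf)
  expect_true(all(rs0$density == 0))
  # overlapping regions count positions once per region, and are noted
  ovl <- data.frame(name = c("A", "A2"), start = c(1, 3), end = c(4, 6))
  rsO <- regionSummary(rec, ovl)
  expect_equal(attr(rsO, "overlapping"), 2)
})

test_that("the robust null uses median and scaled MAD", {
  rec <- S4Vectors::DataFrame(position = 1:5, index = rep(1, 5),
                              log_index = c(-0.1, 0, 0.1, 0.2, 5))
  null <- fitNull(rec, robust = TRUE)
  expect_equal(null@mean, 0.1)
  expect_equal(null@sd, stats::mad(rec$log_index))
  expect_true(null@robust)
})
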