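test_that("well-separated Gaussian bands are detected with unit areas", {
  grid <- seq(0, 200, 0.2)
  prof <- gaussTrace(grid, centers = c(60, 120), widths = c(3, 3),
                     areas = c(1, 1))
  ps <- detectBands(prof, minProminence = 0.05)
  pk <- peaks(ps)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$center, c(60, 120), tolerance = 1e-3)
  expect_equal(pk$area, c(1, 1), tolerance = 1e-3)
})

test_that("a constant baseline is removed before area estimation", {
  grid <- seq(0, 100, 0.1)
  prof <- gaussTrace(grid, centers = 50, widths = 2, areas = 7.5,
                     baseline = 0.3)
  ps <- detectBands(prof, minProminence = 0.05, baselineWindow = 401L)
  pk <- peaks(ps)
  expect_equal(nrow(pk), 1L)
  # oracle: trapezoid integral of the baseline-free component
  oracle <- oracleTrapezoidArea(grid, 7.5 * dnorm(grid, 50, 2))
  expect_equal(pk$area, oracle, tolerance = 0.02)
})

test_that("flat and all-zero traces yield an empty PeakSet", {
  grid <- seq(0, 10, 0.1)
  zero <- gaussTrace(grid, numeric(), numeric(), numeric())
  expect_equal(nrow(peaks(detectBands(zero))), 0L)
  flat <- gaussTrace(grid, numeric(), numeric(), numeric(), baseline = 2)
  expect_equal(nrow(peaks(detectBands(flat))), 0L)
})

test_that("areas scale linearly with the trace (scaling equivariance)", {
  grid <- seq(0, 150, 0.2)
  prof <- gaussTrace(grid, centers = c(40, 75, 110), widths = c(2, 2.4, 3),
                     areas = c(2, 5, 3))
  a1 <- peaks(detectBands(prof))$area
  prof2 <- prof
  prof2@trace$density <- prof2@trace$density * 7.3
  a2 <- peaks(detectBands(prof2))$area
  expect_equal(a2, 7.3 * a1, tolerance = 1e-6)
  # area conservation: fitted areas stay within the total trace integral
  total <- oracleTrapezoidArea(grid, prof@trace$density)
  expect_lte(sum(a1), total * 1.02)
  expect_equal(sum(a1), total, tolerance = 0.02)
})

test_that("peaks at anchor centers are assigned the anchor nucleotides", {
  anchors <- data.frame(position = c(10L, 20L, 30L),
                        center = c(100, 200, 320))
  ps <- PeakSet(center = c(100, 200, 320), width = rep(1, 3),
                area = rep(1, 3))
  out <- peaks(assignPositions(ps, anchors))
  expect_identical(out$position, c(10L, 20L, 30L))
  expect_error(assignPositions(ps, data.frame(position = c(10L, 5L),
                                              center = c(100, 200))),
               "co-monotone")
})

test_that("position assignment matches the exhaustive nearest-interpolant oracle", {
  set.seed(42)
  anchors <- data.frame(position = seq(10L, 90L, by = 10L),
                        center = cumsum(runif(9, 20, 30)))
  centers <- sort(runif(40, min(anchors$center) - 10,
                        max(anchors$center) + 10))
  ps <- PeakSet(center = centers, width = rep(1, 40),
                area = runif(40, 1, 2))
  got <- peaks(assignPositions(ps, anchors))$position
  # oracle: predicted center for every candidate nucleotide, argmin distance
  cand <- 0:120
  predicted <- quadfoot:::linInterp(anchors$position, anchors$center, cand)
  want <- vapply(centers, function(cc) cand[which.min(abs(predicted - cc))],
                 integer(1))
  # collisions: larger area keeps the nucleotide
  expect_true(all(is.na(got) | got == want))
  expect_true(all(want[!is.na(got)] == got[!is.na(got)]))
})

test_that("simulated lanes round-trip: areas within 5% and positions 100% correct at noise 0", {
  tx <- makeTranscript(defaultTranscriptPlan(), seed = 2)
  sim <- simulateFootprint(tx, noiseCV = 0, positions = 301:340, seed = 9)
  traces <- simulateLaneTraces(sim$bandTable)
  sets <- lapply(traces, function(tr) {
    ps <- detectBands(tr, minProminence = 0.02)
    assignPositions(ps, traceAnchors(tr, every = 10L))
  })
  truthAreas <- bandIntensities(sim$bandTable)
  for (lane in names(sets)) {
    pk <- peaks(sets[[lane]])
    pk <- pk[!is.na(pk$position), ]
    expect_equal(pk$position, positions(sim$bandTable))
    expect_equal(pk$area, unname(truthAreas[, lane]), tolerance = 0.05)
  }
  bt <- buildBandTable(sets)
  expect_equal(positions(bt), positions(sim$bandTable))
})

test_that("band tables restrict to positions present in all four lanes and count the rest", {
  mk <- function(pos) PeakSet(center = as.numeric(pos) * 10,
                              width = rep(1, length(pos)),
                              area = rep(2, length(pos)),
                              position = as.integer(pos))
  sets <- list(V1_control = mk(10:50), V1_ligand = mk(10:50),
               T2_control = mk(10:50), T2_ligand = mk(10:50))
  bt <- buildBandTable(sets)
  expect_equal(nrow(bt), 41L)
  sets$T2_ligand <- mk(setdiff(10:50, 20L))
  bt2 <- buildBandTable(sets)
  expect_equal(nrow(bt2), 40L)
  expect_equal(S4Vectors::metadata(bt2)$missing$n, 1L)
  expect_equal(S4Vectors::metadata(bt2)$missing$positions, 20L)
  sets$T2_ligand <- mk(integer())
  expect_warning(bt3 <- buildBandTable(sets), "no position")
  expect_equal(nrow(bt3), 0L)
  expect_error(buildBandTable(sets[c(1, 1, 2, 3)]), "named exactly")
})
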