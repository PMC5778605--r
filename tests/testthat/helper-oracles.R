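# Independent oracles used to freeze expected values. Each deliberately
# re-derives its quantity by a different route than the package code.

# Brute-force re-implementation of index -> null -> flags in one function,
# written against the formula directly (no pseudocount, zero rows dropped).
oracleIndexFlags <- function(v1l, v1c, t2l, t2c, k = 2) {
  ok <- v1l > 0 & v1c > 0 & t2l > 0 & t2c > 0
  idx <- (v1l[ok] / v1c[ok]) / (t2l[ok] / t2c[ok])
  li <- log10(idx)
  m <- sum(li) / length(li)
  s <- sqrt(sum((li - m)^2) / (length(li) - 1))
  z <- (li - m) / s
  flag <- rep("none", length(z))
  flag[z > k] <- "positive"
  flag[z < -k] <- "negative"
  list(index = idx, log_index = li, mean = m, sd = s, z = z, flag = flag,
       used = which(ok))
}

# Streaming (Welford) mean/sd, as an independent check of fitNull.
oracleStreamingMoments <- function(x) {
  m <- 0; m2 <- 0; n <- 0
  for (xi in x) {
    n <- n + 1
    d <- xi - m
    m <- m + d / n
    m2 <- m2 + d * (xi - m)
  }
  list(mean = m, sd = sqrt(m2 / (n - 1)))
}

# Bisection on the one-site mass-action equation, solving for the complex
# concentration x in [0, min(R, L)] such that x*Kd = (R-x)(L-x) ... i.e.
# root of g(x) = (R-x)(L-x) - Kd*x.
oracleBoundFraction <- function(kd, R, L, tol = 1e-12) {
  if (R == 0 || L == 0) return(0)
  g <- function(x) (R - x) * (L - x) - kd * x
  lo <- 0; hi <- min(R, L)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  ((lo + hi) / 2) / L
}

# Monte-Carlo oracle of the null log10-index SD: the index is a ratio of
# two pairs of mean-1 lognormals with coefficient of variation cv.
oracleIndexSdMC <- function(cv, nDraws = 1e6, seed = 424242) {
  set.seed(seed)
  s <- sqrt(log(1 + cv^2))
  draw <- function() rlnorm(nDraws, meanlog = -s^2 / 2, sdlog = s)
  idx <- (draw() / draw()) / (draw() / draw())
  sd(log10(idx))
}

# Trapezoid integration of a trace segment (area oracle for band fitting).
oracleTrapezoidArea <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Exhaustive substring-enumeration G4 oracle. Candidate windows are checked
# character-by-character: a window must start/end at maximal G-run
# boundaries, contain exactly `nTracts` maximal runs >= minTract, have every
# inter-run gap within [loopMin, loopMax], and span <= maxSpan. Overlapping
# windows are merged; tract decomposition is re-derived per merged region.
oracleScanG4 <- function(seq, minTract = 3, loopMin = 1, loopMax = 7,
                         nTracts = 4, maxSpan = 45) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  isG <- chars == "G"
  runStart <- which(isG & !c(FALSE, isG[-n]))
  runEnd <- which(isG & !c(isG[-1], FALSE))
  long <- (runEnd - runStart + 1) >= minTract
  ls <- runStart[long]; le <- runEnd[long]
  wins <- NULL
  for (a in seq_along(ls)) for (b in seq_along(le)) {
    if (b < a) next
    s0 <- ls[a]; e0 <- le[b]
    if (e0 - s0 + 1 > maxSpan) next
    inside <- which(ls >= s0 & le <= e0)
    if (length(inside) != nTracts) next
    if (inside[1] != a || inside[length(inside)] != b) next
    gaps <- ls[inside][-1] - le[inside][-length(inside)] - 1
    if (all(gaps >= loopMin & gaps <= loopMax))
      wins <- rbind(wins, c(s0, e0))
  }
  if (is.null(wins)) return(data.frame(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(wins[, 1], wins[, 2]))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

# Random RNA string, optionally G-enriched to exercise the G4 pattern space.
randomRna <- function(len, pG = 0.25) {
  pOther <- (1 - pG) / 3
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE,
               prob = c(pOther, pOther, pG, pOther)), collapse = "")
}

# Gaussian trace builder for band-detection tests.
gaussTrace <- function(grid, centers, widths, areas, baseline = 0) {
  dens <- rep(baseline, length(grid))
  for (i in seq_along(centers))
    dens <- dens + areas[i] * dnorm(grid, centers[i], widths[i])
  new("LaneProfile", laneId = "test", enzyme = "none",
      condition = "control",
      trace = data.frame(migration = grid, density = dens),
      bandModel = data.frame())
}

# Minimal four-lane BandTable from explicit intensity vectors.
makeBandTable <- function(v1c, v1l, t2c, t2l,
                          positions = seq_along(v1c)) {
  mat <- cbind(V1_control = v1c, V1_ligand = v1l,
               T2_control = t2c, T2_ligand = t2l)
  rownames(mat) <- positions
  lanes <- colnames(mat)
  BandTable(mat, data.frame(laneId = lanes,
                            enzyme = sub("_.*", "", lanes),
                            condition = sub(".*_", "", lanes),
                            row.names = lanes))
}
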