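#' Construct a BandTable from an intensity matrix
#'
#' @param intensity numeric matrix, rows = nucleotide positions (rownames or
#'   `positions` give the coordinates), columns = lanes.
#' @param laneInfo data.frame (one row per lane) with columns `enzyme` and
#'   `condition`; rownames (or a `laneId` column) name the lanes.
#' @param positions integer vector of nucleotide positions (defaults to
#'   rownames of `intensity`).
#' @param missing optional record of positions dropped upstream, stored in
#'   `metadata(x)$missing`.
#' @return a [BandTable-class].
#' @export
BandTable <- function(intensity, laneInfo, positions = NULL,
                      missing = NULL) {
  if (is.null(positions)) positions <- as.integer(rownames(intensity))
  if (is.null(positions) || anyNA(positions))
    stop("nucleotide positions must be given (rownames or 'positions')",
         call. = FALSE)
  if ("laneId" %in% names(laneInfo) && is.null(rownames(laneInfo)))
    rownames(laneInfo) <- laneInfo$laneId
  colnames(intensity) <- rownames(laneInfo)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(position = as.integer(positions)),
    colData = S4Vectors::DataFrame(laneInfo)
  )
  bt <- new("BandTable", se)
  if (!is.null(missing)) S4Vectors::metadata(bt)$missing <- missing
  bt
}

# The four lane roles the cleavage index needs, in canonical order.
indexLaneRoles <- function() c("V1_control", "V1_ligand",
                               "T2_control", "T2_ligand")

#' Simulate a four-lane enzymatic footprinting experiment
#'
#' Generates the duplex-specific (RNase V1) and single-strand-specific
#' (RNase T2) lanes, each with and without ligand, for one transcript. Each
#' position carries a latent true reactivity per enzyme; the ligand condition
#' multiplies it by the planted per-region fold change; the observed band
#' intensity is `lane_scale x true_reactivity x lognormal(1, noise_cv)`.
#' Positions outside planted regions have a ligand/control true ratio of
#' exactly 1 for both enzymes, so the downstream cleavage index is exactly
#' centred there.
#'
#' @param transcript an [AnnotatedTranscript-class].
#' @param effects effect plan: `NULL` (no planted changes) or a data.frame
#'   with columns `enzyme` (`"V1"`/`"T2"`), `fold` (> 0) and either `region`
#'   (a region name of `transcript`) or explicit `start`,`end` coordinates.
#' @param laneScales named positive numerics for the four lanes
#'   (`V1_control`, `V1_ligand`, `T2_control`, `T2_ligand`); lane-loading
#'   differences that the T2 denominator of the index is designed to cancel.
#' @param noiseCV coefficient of variation of the multiplicative measurement
#'   noise (>= 0).
#' @param positions analyzed nucleotide positions (primer coverage); default
#'   the whole transcript.
#' @param baselineSdLog sd (natural log) of the latent per-position
#'   reactivity across positions.
#' @param seed integer seed.
#' @return list with `bandTable` (a [BandTable-class]) and `truth`
#'   (a [FootprintTruth-class]).
#' @examples
#' tx <- makeTranscript(defaultTranscriptPlan(), seed = 1)
#' sim <- simulateFootprint(tx,
#'   effects = data.frame(region = "Q2", enzyme = "V1", fold = 2.5),
#'   noiseCV = 0.1, seed = 7)
#' sim$bandTable
#' @export
simulateFootprint <- function(transcript, effects = NULL,
                              laneScales = c(V1_control = 1, V1_ligand = 1,
                                             T2_control = 1, T2_ligand = 1),
                              noiseCV = 0.1, positions = NULL,
                              baselineSdLog = 0.5, seed) {
  if (noiseCV < 0) stop("noiseCV must be >= 0", call. = FALSE)
  roles <- indexLaneRoles()
  if (!all(roles %in% names(laneScales)))
    stop("laneScales must name the four lanes: ",
         paste(roles, collapse = ", "), call. = FALSE)
  laneScales <- laneScales[roles]
  if (any(laneScales <= 0)) stop("lane scales must be > 0", call. = FALSE)
  if (is.null(positions)) positions <- seq_len(length(transcript@seq))
  positions <- sort(unique(as.integer(positions)))
  if (any(positions < 1L) || any(positions > length(transcript@seq)))
    stop("analyzed positions outside the transcript", call. = FALSE)
  n <- length(positions)

  # per-position fold maps, one per enzyme
  fold <- matrix(1, nrow = n, ncol = 2L,
                 dimnames = list(NULL, c("V1", "T2")))
  if (!is.null(effects) && nrow(effects)) {
    if (any(effects$fold <= 0))
      stop("effect fold-changes must be > 0", call. = FALSE)
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      if (!e$enzyme %in% c("V1", "T2"))
        stop("effect enzyme must be V1 or T2", call. = FALSE)
      if (!is.null(e$region) && !is.na(e$region)) {
        rg <- transcript@regions
        j <- match(e$region, names(rg))
        if (is.na(j)) stop("unknown region '", e$region, "'", call. = FALSE)
        rng <- IRanges::start(rg)[j]:IRanges::end(rg)[j]
      } else {
        rng <- as.integer(e$start):as.integer(e$end)
      }
      hit <- positions %in% rng
      fold[hit, e$enzyme] <- fold[hit, e$enzyme] * e$fold
    }
  }

  withSeed(seed, {
    true <- array(NA_real_, dim = c(n, 2L, 2L),
                  dimnames = list(position = positions,
                                  enzyme = c("V1", "T2"),
                                  condition = c("control", "ligand")))
    for (enz in c("V1", "T2")) {
      base <- stats::rlnorm(n, meanlog = 0, sdlog = baselineSdLog)
      true[, enz, "control"] <- base
      true[, enz, "ligand"] <- base * fold[, enz]
    }
    obs <- matrix(NA_real_, nrow = n, ncol = 4L,
                  dimnames = list(positions, roles))
    for (role in roles) {
      enz <- sub("_.*", "", role)
      cond <- sub(".*_", "", role)
      obs[, role] <- laneScales[[role]] * true[, enz, cond] *
        lognormNoise(n, noiseCV)
    }
    ratio <- fold[, "V1"] / fold[, "T2"]   # T2-corrected true ratio
    changed <- which(ratio != 1)
    truth <- new("FootprintTruth",
      trueReactivity = true,
      changedPositions = data.frame(
        position = positions[changed],
        sign = ifelse(ratio[changed] > 1, "+", "-"),
        stringsAsFactors = FALSE),
      laneScales = laneScales, noiseCV = noiseCV,
      positions = positions)
    laneDf <- data.frame(
      laneId = roles,
      enzyme = sub("_.*", "", roles),
      condition = sub(".*_", "", roles),
      row.names = roles, stringsAsFactors = FALSE)
    list(bandTable = BandTable(obs, laneDf, positions = positions),
         truth = truth)
  })
}

#' Render band tables as 1-D gel-lane densitometry traces
#'
#' Converts each lane of a [BandTable-class] into a synthetic densitometry
#' trace: one Gaussian band per nucleotide, with band spacing shrinking
#' geometrically with band index (compression toward the top of the gel) and
#' band width growing linearly with migration distance (diffusive
#' broadening). Band area equals the lane intensity at that position.
#'
#' @param bandTable a [BandTable-class].
#' @param spacing0 migration-gap between the first two bands (a.u.).
#' @param shrink geometric spacing factor per band (0 < shrink <= 1).
#' @param width0 Gaussian sd of the first band (a.u.).
#' @param widthSlope linear growth of band sd per band index.
#' @param origin migration coordinate of the first band.
#' @param resolution trace sampling step (a.u.).
#' @return named list of [LaneProfile-class], one per lane.
#' @export
simulateLaneTraces <- function(bandTable, spacing0 = 10, shrink = 0.998,
                               width0 = 1, widthSlope = 0.01, origin = 50,
                               resolution = 0.25) {
  stopifnot(shrink > 0, shrink <= 1, width0 > 0, spacing0 > 0)
  pos <- positions(bandTable)
  n <- length(pos)
  centers <- origin + c(0, cumsum(spacing0 * shrink^(seq_len(n - 1L) - 1L)))
  widths <- width0 + widthSlope * (seq_len(n) - 1L)
  grid <- seq(centers[1L] - 6 * widths[1L],
              centers[n] + 6 * widths[n], by = resolution)
  mat <- bandIntensities(bandTable)
  info <- laneInfo(bandTable)
  out <- lapply(seq_len(ncol(mat)), function(j) {
    dens <- rep(0, length(grid))
    for (i in seq_len(n))
      dens <- dens + mat[i, j] * stats::dnorm(grid, centers[i], widths[i])
    new("LaneProfile",
        laneId = rownames(info)[j],
        enzyme = as.character(info$enzyme[j]),
        condition = as.character(info$condition[j]),
        trace = data.frame(migration = grid, density = dens),
        bandModel = data.frame(position = pos, center = centers,
                               width = widths, area = mat[, j]))
  })
  names(out) <- rownames(info)
  out
}

#' Calibration anchors from a simulated lane
#'
#' Takes every `every`-th modelled band of a simulated [LaneProfile-class] as
#' a (nucleotide, migration-center) anchor pair, emulating the sequencing
#' ladder used to register gel bands to nucleotides.
#'
#' @param profile a [LaneProfile-class] with a band model.
#' @param every anchor stride in bands.
#' @return data.frame with `position` and `center`.
#' @export
traceAnchors <- function(profile, every = 10L) {
  bm <- profile@bandModel
  if (!nrow(bm)) stop("profile has no band model", call. = FALSE)
  idx <- unique(c(seq(1L, nrow(bm), by = every), nrow(bm)))
  data.frame(position = bm$position[idx], center = bm$center[idx])
}
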