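#' Construct a PeakSet
#'
#' @param center,width,area numeric vectors (centers strictly increasing).
#' @param position integer vector of assigned nucleotides (`NA` =
#'   unassigned).
#' @return a [PeakSet-class].
#' @export
PeakSet <- function(center = numeric(), width = numeric(),
                    area = numeric(), position = NA_integer_) {
  n <- length(center)
  pk <- data.frame(center = as.numeric(center), width = as.numeric(width),
                   area = as.numeric(area),
                   position = rep_len(as.integer(position), n))
  new("PeakSet", peaks = pk)
}

#' Detect and quantify gel bands in a 1-D lane trace
#'
#' Plays the role gel-quantification software (SAFA, OptiQuant) played for
#' the original phosphor images, on an already-extracted 1-D lane profile.
#' After optional rolling-minimum baseline subtraction (morphological
#' opening: rolling min followed by rolling max) and optional smoothing for
#' peak finding, every local maximum whose height exceeds
#' `minProminence x max(density)` becomes a band. Each band is fit by least
#' squares over the window between its flanking local minima with a single
#' Gaussian plus a free constant offset (the offset absorbs residual baseline
#' and the tails of neighbouring bands); the reported area is the analytic
#' integral `A * sigma * sqrt(2*pi)` of the fitted Gaussian component.
#'
#' @param profile a [LaneProfile-class].
#' @param minProminence height threshold as a fraction of the maximum
#'   (baseline-subtracted) density, in (0, 1).
#' @param baselineWindow width (in samples) of the rolling-minimum baseline
#'   window; 0 disables baseline subtraction.
#' @param smoothWindow width (in samples) of a moving-average filter used
#'   only for locating maxima/minima; 0 disables.
#' @return a [PeakSet-class] (empty for a flat or all-zero trace).
#' @export
detectBands <- function(profile, minProminence = 0.05,
                        baselineWindow = 0L, smoothWindow = 0L) {
  stopifnot(is(profile, "LaneProfile"))
  if (minProminence <= 0 || minProminence >= 1)
    stop("minProminence must be in (0, 1)", call. = FALSE)
  x <- profile@trace$migration
  y <- profile@trace$density
  if (!length(y)) stop("trace is empty", call. = FALSE)
  if (baselineWindow > 1L) {
    baseline <- rollingMax(rollingMin(y, as.integer(baselineWindow)),
                           as.integer(baselineWindow))
    y <- pmax(0, y - baseline)
  }
  ys <- if (smoothWindow > 1L) movingAverage(y, as.integer(smoothWindow))
        else y
  top <- max(ys)
  if (top <= 0) return(PeakSet())
  n <- length(ys)
  # strict local maxima (first point of a plateau)
  isMax <- which(ys[2:(n - 1L)] > ys[1:(n - 2L)] &
                 ys[2:(n - 1L)] >= ys[3:n]) + 1L
  isMax <- isMax[ys[isMax] >= minProminence * top]
  if (!length(isMax)) return(PeakSet())
  # flanking minima delimit each fit window
  isMin <- which(ys[2:(n - 1L)] <= ys[1:(n - 2L)] &
                 ys[2:(n - 1L)] <= ys[3:n]) + 1L
  bounds <- sort(unique(c(1L, isMin, n)))
  fits <- lapply(isMax, function(p) {
    lo <- max(bounds[bounds < p])
    hi <- min(bounds[bounds > p])
    fitGaussianBand(x[lo:hi], y[lo:hi], x[p], ys[p])
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) return(PeakSet())
  ctr <- vapply(fits, `[[`, numeric(1), "center")
  o <- order(ctr)
  PeakSet(center = ctr[o],
          width = vapply(fits, `[[`, numeric(1), "width")[o],
          area = vapply(fits, `[[`, numeric(1), "area")[o])
}

# Least-squares single-Gaussian + constant-offset fit over one band window.
fitGaussianBand <- function(x, y, mu0, h0) {
  if (length(x) < 5L || h0 <= 0) return(NULL)
  # initial sd from half width at half maximum
  above <- x[y >= h0 / 2]
  s0 <- max(diff(range(above)) / 2.355, diff(x)[1L])
  par0 <- c(logA = log(h0), mu = mu0, logS = log(s0), off = 0)
  ss <- function(p) {
    pred <- exp(p[1L]) * exp(-(x - p[2L])^2 / (2 * exp(p[3L])^2)) + p[4L]
    sum((y - pred)^2)
  }
  fit <- try(stats::optim(par0, ss, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  A <- exp(fit$par[[1L]]); mu <- fit$par[[2L]]; s <- exp(fit$par[[3L]])
  if (!is.finite(A) || !is.finite(s) || mu < min(x) || mu > max(x))
    return(NULL)
  list(center = mu, width = s, area = A * s * sqrt(2 * pi))
}

#' Assign detected bands to nucleotide positions
#'
#' Given anchor pairs (nucleotide, migration center) — e.g. from a
#' sequencing ladder — each band is assigned the nucleotide whose predicted
#' center (piecewise-linear interpolation between anchors, linear
#' extrapolation beyond them) is nearest to the band's fitted center.
#' Assignments are forced strictly monotone: when two bands round to the same
#' nucleotide, the larger-area band keeps it and the other is marked
#' unassigned.
#'
#' @param peakSet a [PeakSet-class].
#' @param anchors data.frame with co-monotone `position` (nucleotide) and
#'   `center` (migration) columns, at least 2 rows.
#' @return the [PeakSet-class] with `position` filled in.
#' @export
assignPositions <- function(peakSet, anchors) {
  stopifnot(is(peakSet, "PeakSet"))
  if (nrow(anchors) < 2L)
    stop("need at least 2 anchors", call. = FALSE)
  o <- order(anchors$center)
  anchors <- anchors[o, ]
  if (is.unsorted(anchors$position, strictly = TRUE))
    stop("anchor nucleotides and centers must be co-monotone",
         call. = FALSE)
  pk <- peakSet@peaks
  if (!nrow(pk)) return(peakSet)
  # invert the piecewise-linear nucleotide -> center map
  frac <- linInterp(anchors$center, anchors$position, pk$center)
  cand <- round(frac)
  # nearest predicted center decides between floor and ceiling
  for (i in seq_along(cand)) {
    lo <- floor(frac[i]); hi <- ceiling(frac[i])
    if (lo != hi) {
      dLo <- abs(linInterp(anchors$position, anchors$center, lo) -
                   pk$center[i])
      dHi <- abs(linInterp(anchors$position, anchors$center, hi) -
                   pk$center[i])
      cand[i] <- if (dLo <= dHi) lo else hi
    }
  }
  pos <- as.integer(cand)
  # resolve collisions: larger area wins, loser unassigned
  repeat {
    dup <- which(!is.na(pos) & duplicated(pos) |
                   !is.na(pos) & duplicated(pos, fromLast = TRUE))
    if (!length(dup)) break
    v <- pos[dup[1L]]
    grp <- which(!is.na(pos) & pos == v)
    keep <- grp[which.max(pk$area[grp])]
    pos[setdiff(grp, keep)] <- NA_integer_
  }
  pk$position <- pos
  new("PeakSet", peaks = pk)
}

#' Assemble the four index lanes into a BandTable
#'
#' Restricts to nucleotide positions quantified (assigned) in all four lanes;
#' positions covered in some but not all lanes are dropped and counted in
#' `metadata(x)$missing`.
#'
#' @param peakSets named list of four assigned [PeakSet-class] objects with
#'   names `V1_control`, `V1_ligand`, `T2_control`, `T2_ligand`.
#' @return a [BandTable-class].
#' @export
buildBandTable <- function(peakSets) {
  roles <- indexLaneRoles()
  if (!setequal(names(peakSets), roles) || anyDuplicated(names(peakSets)))
    stop("peakSets must be named exactly ",
         paste(roles, collapse = ", "), call. = FALSE)
  peakSets <- peakSets[roles]
  perLane <- lapply(peakSets, function(ps) {
    pk <- ps@peaks
    pk <- pk[!is.na(pk$position), c("position", "area")]
    pk
  })
  allPos <- sort(unique(unlist(lapply(perLane, `[[`, "position"))))
  common <- allPos
  for (pl in perLane) common <- intersect(common, pl$position)
  common <- sort(common)
  dropped <- setdiff(allPos, common)
  if (!length(common)) {
    warning("no position was quantified in all four lanes")
    mat <- matrix(numeric(0), nrow = 0, ncol = 4L,
                  dimnames = list(NULL, roles))
  } else {
    mat <- vapply(perLane, function(pl) {
      pl$area[match(common, pl$position)]
    }, numeric(length(common)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L,
                                         dimnames = list(NULL, roles))
    rownames(mat) <- common
  }
  laneDf <- data.frame(
    laneId = roles,
    enzyme = sub("_.*", "", roles),
    condition = sub(".*_", "", roles),
    row.names = roles, stringsAsFactors = FALSE)
  BandTable(mat, laneDf, positions = as.integer(common),
            missing = list(positions = dropped, n = length(dropped)))
}

#' Write / read a BandTable as long-format TSV
#'
#' Columns `position`, `lane_id`, `intensity`.
#'
#' @param bandTable a [BandTable-class].
#' @param path file path.
#' @return `path` (writer, invisibly) or a [BandTable-class] (reader).
#' @export
writeBandTableTsv <- function(bandTable, path) {
  mat <- bandIntensities(bandTable)
  pos <- positions(bandTable)
  df <- data.frame(
    position = rep(pos, times = ncol(mat)),
    lane_id = rep(colnames(mat), each = length(pos)),
    intensity = as.vector(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBandTableTsv
#' @export
readBandTableTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("position", "lane_id", "intensity")
  if (!all(need %in% names(df)))
    stop("band table TSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lanes <- unique(df$lane_id)
  pos <- sort(unique(df$position))
  mat <- matrix(NA_real_, nrow = length(pos), ncol = length(lanes),
                dimnames = list(pos, lanes))
  mat[cbind(match(df$position, pos), match(df$lane_id, lanes))] <-
    df$intensity
  laneDf <- data.frame(
    laneId = lanes,
    enzyme = sub("_.*", "", lanes),
    condition = sub(".*_", "", lanes),
    row.names = lanes, stringsAsFactors = FALSE)
  BandTable(mat, laneDf, positions = as.integer(pos))
}
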