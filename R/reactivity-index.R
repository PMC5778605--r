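#' Per-nucleotide cleavage index from the four footprinting lanes
#'
#' For each position the index is
#' `[(V1_ligand + eps) / (V1_control + eps)] / [(T2_ligand + eps) /
#' (T2_control + eps)]`: the ligand-induced change in duplex-specific (V1)
#' cleavage, corrected by the single-strand-specific (T2) lanes, which cancel
#' lane loading and local accessibility. An index above 1 means the position
#' became more structured upon ligand binding. With the default
#' `pseudocount = 0`, positions carrying a zero intensity in any used lane
#' are excluded (never emitted as Inf/NaN) and counted in the metadata.
#'
#' @param bandTable a [BandTable-class] whose lanes are exactly
#'   {V1,T2} x {control,ligand}.
#' @param pseudocount nonnegative intensity offset `eps`.
#' @param logBase base of the reported log index (default 10).
#' @return a [S4Vectors::DataFrame] with columns `position`, `index`,
#'   `log_index`; `metadata()` records `n_excluded`, `excluded_positions`
#'   and `log_base`.
#' @seealso [fitNull()], [callSignificant()], [regionSummary()]
#' @export
computeIndex <- function(bandTable, pseudocount = 0, logBase = 10) {
  stopifnot(is(bandTable, "BandTable"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  info <- laneInfo(bandTable)
  mat <- bandIntensities(bandTable)
  pickLane <- function(enzyme, condition) {
    j <- which(info$enzyme == enzyme & info$condition == condition)
    if (length(j) != 1L)
      stop(sprintf("need exactly one %s/%s lane, found %d",
                   enzyme, condition, length(j)), call. = FALSE)
    mat[, j] + pseudocount
  }
  v1l <- pickLane("V1", "ligand");  v1c <- pickLane("V1", "control")
  t2l <- pickLane("T2", "ligand");  t2c <- pickLane("T2", "control")
  pos <- positions(bandTable)
  bad <- is.na(v1l) | is.na(v1c) | is.na(t2l) | is.na(t2c) |
    v1l <= 0 | v1c <= 0 | t2l <= 0 | t2c <= 0
  if (any(bad))
    warning(sum(bad), " position(s) excluded (zero or missing intensity)")
  idx <- unname((v1l[!bad] / v1c[!bad]) / (t2l[!bad] / t2c[!bad]))
  out <- S4Vectors::DataFrame(position = pos[!bad], index = idx,
                              log_index = log(idx, base = logBase))
  S4Vectors::metadata(out) <- list(
    n_excluded = sum(bad), excluded_positions = pos[bad],
    log_base = logBase, pseudocount = pseudocount)
  out
}

#' Fit the empirical Gaussian null of the log index
#'
#' Plain (non-robust) mean and sample standard deviation over *all* usable
#' positions — including any genuinely changed ones. This mirrors standard
#' footprinting practice: the null is the bulk of the empirical log-index
#' distribution, and its fit degrades gracefully as the changed fraction
#' grows. `robust = TRUE` substitutes median and 1.4826*MAD.
#'
#' @param records output of [computeIndex()] (needs a `log_index` column).
#' @param k SD multiplier stored for downstream calling (default 2).
#' @param robust use median/MAD instead of mean/SD.
#' @return a [NullModel-class].
#' @export
fitNull <- function(records, k = 2, robust = FALSE) {
  li <- records$log_index
  li <- li[is.finite(li)]
  if (length(li) < 2L)
    stop("need at least 2 usable positions to fit the null", call. = FALSE)
  lb <- S4Vectors::metadata(records)$log_base
  if (is.null(lb)) lb <- 10
  if (robust) {
    m <- stats::median(li)
    s <- stats::mad(li)
  } else {
    m <- mean(li)
    s <- stats::sd(li)
  }
  new("NullModel", mean = m, sd = s, n = length(li), k = k,
      logBase = lb, robust = robust)
}

#' Call positions whose log index deviates beyond k SD of the null
#'
#' Computes `z = (log_index - mean) / sd` and flags `positive` when
#' `z > k`, `negative` when `z < -k` (strict inequalities; a position at
#' exactly k SD is not called). A positive flag means increased structure
#' (V1 up relative to T2) upon ligand addition.
#'
#' @param records output of [computeIndex()].
#' @param null a [NullModel-class]; its `sd` must be > 0.
#' @param k SD multiplier; defaults to the one stored in `null`.
#' @return `records` with added `z` and `flag` (`none`/`positive`/
#'   `negative`) columns.
#' @export
callSignificant <- function(records, null, k = NULL) {
  stopifnot(is(null, "NullModel"))
  if (null@sd <= 0)
    stop("degenerate null (sd = 0): cannot call significance",
         call. = FALSE)
  if (is.null(k)) k <- null@k
  z <- (records$log_index - null@mean) / null@sd
  flag <- rep("none", length(z))
  flag[z > k] <- "positive"
  flag[z < -k] <- "negative"
  records$z <- z
  records$flag <- factor(flag, levels = c("none", "positive", "negative"))
  records
}

#' Summarize flagged positions per annotated region
#'
#' Counts analyzed and flagged positions (by sign) within each region of the
#' transcript plus an `unannotated` catch-all, and reports the flag density
#' `n_flagged / n_positions`. Positions inside overlapping regions are
#' counted once per region they belong to (noted in the `overlapping`
#' attribute of the result).
#'
#' @param records flagged records from [callSignificant()].
#' @param regionsDf region table: data.frame with `name`, `start`, `end`
#'   (and optionally `kind`), or an [AnnotatedTranscript-class].
#' @return data.frame with one row per region (plus `unannotated`):
#'   `region`, `n_positions`, `n_flagged`, `n_positive`, `n_negative`,
#'   `density`.
#' @export
regionSummary <- function(records, regionsDf) {
  if (is(regionsDf, "AnnotatedTranscript")) {
    rg <- regionsDf@regions
    regionsDf <- data.frame(name = names(rg),
                            start = IRanges::start(rg),
                            end = IRanges::end(rg),
                            stringsAsFactors = FALSE)
  }
  if (!"flag" %in% colnames(records))
    stop("records are not flagged; run callSignificant() first",
         call. = FALSE)
  pos <- records$position
  flag <- as.character(records$flag)
  inAny <- rep(FALSE, length(pos))
  rows <- lapply(seq_len(nrow(regionsDf)), function(i) {
    hit <- pos >= regionsDf$start[i] & pos <= regionsDf$end[i]
    inAny <<- inAny | hit
    f <- flag[hit]
    data.frame(region = regionsDf$name[i],
               n_positions = sum(hit),
               n_flagged = sum(f != "none"),
               n_positive = sum(f == "positive"),
               n_negative = sum(f == "negative"),
               stringsAsFactors = FALSE)
  })
  f0 <- flag[!inAny]
  rows <- c(rows, list(data.frame(
    region = "unannotated", n_positions = sum(!inAny),
    n_flagged = sum(f0 != "none"), n_positive = sum(f0 == "positive"),
    n_negative = sum(f0 == "negative"), stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  out$density <- ifelse(out$n_positions > 0,
                        out$n_flagged / out$n_positions, NA_real_)
  nOverlap <- sum(vapply(seq_along(pos), function(i) {
    sum(pos[i] >= regionsDf$start & pos[i] <= regionsDf$end)
  }, numeric(1)) > 1)
  attr(out, "overlapping") <- nOverlap
  out
}

#' Write per-position reactivity records to TSV
#'
#' @param records flagged records from [callSignificant()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReactivityTsv <- function(records, path) {
  df <- as.data.frame(records)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
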