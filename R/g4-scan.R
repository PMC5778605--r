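#' Scan an RNA sequence for G-quadruplex candidate regions
#'
#' Four or more G-tracts in reasonable proximity can fold into a quadruplex.
#' The scanner finds all minimal windows of `nTracts` consecutive maximal
#' G-runs of length >= `minTract` whose inter-tract gaps (loops) are each in
#' `[loopMin, loopMax]` and whose span does not exceed `maxSpan`, then merges
#' overlapping windows into one candidate per locus (G-rich loci typically
#' admit many registers). Tracts are maximal runs of G in the full sequence,
#' so loops may contain isolated Gs shorter than `minTract` but never a full
#' tract. RNA is single-stranded: only the given strand is scanned, no
#' reverse complement.
#'
#' @param sequence RNA sequence (character or [Biostrings::RNAString]).
#' @param minTract minimum G-run length per tract (default 3).
#' @param loopMin,loopMax allowed loop lengths, nt (defaults 1 and 7).
#' @param nTracts number of tracts required (default 4).
#' @param maxSpan maximum span of a single register, nt (default 45).
#' @return an [IRanges::IRanges] of merged candidates with mcols
#'   `n_tracts`, `tract_starts`, `tract_lengths`, `loops`
#'   ([S4Vectors::IntegerList] columns).
#' @examples
#' scanG4("GGGAGGGAGGGAGGG")
#' @export
scanG4 <- function(sequence, minTract = 3L, loopMin = 1L, loopMax = 7L,
                   nTracts = 4L, maxSpan = 45L) {
  if (minTract < 1L || loopMin < 1L || nTracts < 2L || maxSpan < 1L)
    stop("scan parameters must be positive", call. = FALSE)
  if (loopMin > loopMax) stop("loopMin must be <= loopMax", call. = FALSE)
  s <- asRnaChar(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minTract
  tStart <- starts[keep]
  tEnd <- ends[keep]
  nT <- length(tStart)
  emptyOut <- function() {
    out <- IRanges::IRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      n_tracts = integer(), tract_starts = IRanges::IntegerList(),
      tract_lengths = IRanges::IntegerList(),
      loops = IRanges::IntegerList())
    out
  }
  if (nT < nTracts) return(emptyOut())
  gaps <- tStart[-1L] - tEnd[-nT] - 1L
  gapOK <- gaps >= loopMin & gaps <= loopMax
  wins <- list()
  for (i in seq_len(nT - nTracts + 1L)) {
    j <- i + nTracts - 1L
    if (all(gapOK[i:(j - 1L)]) && tEnd[j] - tStart[i] + 1L <= maxSpan)
      wins[[length(wins) + 1L]] <- c(tStart[i], tEnd[j])
  }
  if (!length(wins)) return(emptyOut())
  w <- do.call(rbind, wins)
  cand <- IRanges::reduce(IRanges::IRanges(start = w[, 1L], end = w[, 2L]))
  ts <- tl <- lp <- vector("list", length(cand))
  for (k in seq_along(cand)) {
    inReg <- tStart >= IRanges::start(cand)[k] &
      tEnd <= IRanges::end(cand)[k]
    ts[[k]] <- tStart[inReg]
    tl[[k]] <- tEnd[inReg] - tStart[inReg] + 1L
    lp[[k]] <- if (sum(inReg) > 1L)
      tStart[inReg][-1L] - tEnd[inReg][-sum(inReg)] - 1L else integer()
  }
  S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
    n_tracts = lengths(ts),
    tract_starts = IRanges::IntegerList(ts),
    tract_lengths = IRanges::IntegerList(tl),
    loops = IRanges::IntegerList(lp))
  cand
}

#' Annotate G4 candidates with region overlap and splice-site proximity
#'
#' For each candidate, reports which annotated regions it overlaps and its
#' signed distance to each splice site. The distance is 0 when the site
#' falls inside the candidate; positive when the site lies upstream (5') of
#' the candidate (`candidate_start - site`), negative when downstream
#' (`candidate_end - site`). A candidate is flagged proximal to a site when
#' `|distance| <= windowNt`.
#'
#' @param candidates [IRanges::IRanges] from [scanG4()].
#' @param transcript an [AnnotatedTranscript-class] supplying regions and
#'   splice sites.
#' @param windowNt proximity window, nt (default 50).
#' @return data.frame with one row per candidate x splice site: `candidate`,
#'   `start`, `end`, `regions` (comma-joined names), `site`, `distance`,
#'   `proximal`. Empty inputs give an empty data.frame.
#' @export
overlapAnnotate <- function(candidates, transcript, windowNt = 50L) {
  empty <- data.frame(candidate = integer(), start = integer(),
                      end = integer(), regions = character(),
                      site = character(), distance = integer(),
                      proximal = logical(), stringsAsFactors = FALSE)
  if (!length(candidates)) return(empty)
  rg <- transcript@regions
  hits <- IRanges::findOverlaps(candidates, rg)
  regNames <- vapply(seq_along(candidates), function(i) {
    nm <- names(rg)[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    paste(nm, collapse = ",")
  }, character(1))
  ss <- transcript@spliceSites
  if (!length(ss)) ss <- stats::setNames(integer(), character())
  rows <- list()
  for (i in seq_along(candidates)) {
    st <- IRanges::start(candidates)[i]
    en <- IRanges::end(candidates)[i]
    if (length(ss)) {
      for (k in seq_along(ss)) {
        d <- if (ss[k] >= st && ss[k] <= en) 0L
             else if (ss[k] < st) st - ss[k]
             else en - ss[k]
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = i, start = st, end = en, regions = regNames[i],
          site = names(ss)[k], distance = as.integer(d),
          proximal = abs(d) <= windowNt, stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = i, start = st, end = en, regions = regNames[i],
        site = NA_character_, distance = NA_integer_, proximal = NA,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
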