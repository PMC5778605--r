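#' Construct an annotated transcript
#'
#' @param id identifier string.
#' @param sequence RNA sequence (character or [Biostrings::RNAString]).
#' @param regions data.frame with columns `name`, `start`, `end`, `kind`
#'   (1-based inclusive transcript coordinates), or an [IRanges::IRanges]
#'   with names and an mcols `kind` column. May be empty.
#' @param spliceSites named integer vector of 5' splice-site positions.
#' @return an [AnnotatedTranscript-class].
#' @export
AnnotatedTranscript <- function(id, sequence, regions = NULL,
                                spliceSites = integer()) {
  seq <- Biostrings::RNAString(asRnaChar(sequence))
  if (is.null(regions)) {
    rg <- IRanges::IRanges()
  } else if (is(regions, "IRanges")) {
    rg <- regions
  } else {
    rg <- IRanges::IRanges(start = as.integer(regions$start),
                           end = as.integer(regions$end),
                           names = as.character(regions$name))
    S4Vectors::mcols(rg)$kind <- as.character(regions$kind)
  }
  ss <- spliceSites
  storage.mode(ss) <- "integer"
  new("AnnotatedTranscript", id = as.character(id), seq = seq,
      regions = rg, spliceSites = ss)
}

#' Generate a G4-bearing synthetic transcript with known region layout
#'
#' Builds a random transcript whose flanking sequence is G4-free by
#' construction (no run of three or more consecutive G is ever emitted
#' outside the planned G4-candidate regions) and whose `g4_candidate` regions
#' each contain a planted quadruplex motif: `nTracts` G-tracts of at least
#' `tractLen` guanines separated by G-free loops of 1-7 nt. The layout
#' emulates a Bcl-X-like pre-mRNA in which two G4-forming blocks sit next to
#' the two alternative 5' splice sites; the real sequence identity is not
#' reproduced, only the geometry that the downstream statistics depend on.
#'
#' @param plan list with elements `id`, `length`, `regions` (data.frame
#'   `name`,`start`,`end`,`kind`) and optional `spliceSites` (named integer).
#'   See [defaultTranscriptPlan()].
#' @param seed integer seed; the same `(plan, seed)` reproduces the sequence
#'   exactly.
#' @param nTracts,tractLen,loopMax geometry of the planted G4 motifs.
#' @return an [AnnotatedTranscript-class].
#' @examples
#' tx <- makeTranscript(defaultTranscriptPlan(), seed = 1)
#' tx
#' scanG4(as.character(transcriptSeq(tx)))
#' @export
makeTranscript <- function(plan, seed, nTracts = 4L, tractLen = 3L,
                           loopMax = 7L) {
  stopifnot(is.list(plan), !is.null(plan$length), !is.null(plan$regions))
  len <- as.integer(plan$length)
  rg <- plan$regions
  if (any(rg$start < 1L) || any(rg$end > len) || any(rg$start > rg$end))
    stop("region plan exceeds sequence length or has start > end",
         call. = FALSE)
  g4 <- rg[rg$kind == "g4_candidate", , drop = FALSE]
  if (nrow(g4) > 1L) {
    o <- order(g4$start)
    if (any(g4$start[o][-1L] <= g4$end[o][-nrow(g4)]))
      stop("g4_candidate regions must not overlap", call. = FALSE)
  }
  minW <- nTracts * tractLen + (nTracts - 1L)
  if (any(g4$end - g4$start + 1L < minW))
    stop(sprintf("g4_candidate regions must be at least %d nt wide", minW),
         call. = FALSE)

  withSeed(seed, {
    # Background: sample with G allowed but never three in a row, so the
    # flanks can never satisfy the tract pattern.
    base <- c("A", "C", "G", "U")
    p <- c(A = 0.30, C = 0.25, G = 0.20, U = 0.25)
    chars <- character(len)
    gRun <- 0L
    for (i in seq_len(len)) {
      if (gRun >= 2L) {
        ch <- sample(c("A", "C", "U"), 1L, prob = p[c("A", "C", "U")])
      } else {
        ch <- sample(base, 1L, prob = p)
      }
      gRun <- if (ch == "G") gRun + 1L else 0L
      chars[i] <- ch
    }
    # Plant a quadruplex motif inside each g4_candidate region.
    for (j in seq_len(nrow(g4))) {
      w <- g4$end[j] - g4$start[j] + 1L
      # choose loop lengths that fit the region width
      spare <- w - nTracts * tractLen
      loops <- rep(1L, nTracts - 1L)
      extra <- spare - (nTracts - 1L)
      while (extra > 0L) {
        k <- sample.int(nTracts - 1L, 1L)
        if (loops[k] < loopMax) {
          loops[k] <- loops[k] + 1L
          extra <- extra - 1L
        } else if (all(loops >= loopMax)) break
      }
      motif <- character(0)
      for (t in seq_len(nTracts)) {
        motif <- c(motif, rep("G", tractLen))
        if (t < nTracts)
          motif <- c(motif, sample(c("A", "C", "U"), loops[t],
                                   replace = TRUE))
      }
      pad <- w - length(motif)
      padL <- if (pad > 0L) sample.int(pad + 1L, 1L) - 1L else 0L
      filled <- c(sample(c("A", "C", "U"), padL, replace = TRUE),
                  motif,
                  sample(c("A", "C", "U"), pad - padL, replace = TRUE))
      chars[g4$start[j]:g4$end[j]] <- filled
      # keep planted tracts from fusing with background Gs at the boundary
      if (g4$start[j] > 1L && chars[g4$start[j] - 1L] == "G")
        chars[g4$start[j] - 1L] <- "A"
      if (g4$end[j] < len && chars[g4$end[j] + 1L] == "G")
        chars[g4$end[j] + 1L] <- "A"
    }
    ss <- plan$spliceSites
    if (is.null(ss)) ss <- integer()
    AnnotatedTranscript(
      id = if (is.null(plan$id)) "synthetic_transcript" else plan$id,
      sequence = paste(chars, collapse = ""),
      regions = rg, spliceSites = ss)
  })
}

#' Default Bcl-X-like transcript plan
#'
#' A 681-nt layout with two planted G4-candidate blocks (`Q2`, `Q5`) adjacent
#' to two alternative 5' splice sites (`XS`, `XL`), plus stem/loop/other decoy
#' regions used to check that flag densities concentrate where effects are
#' planted.
#'
#' @return a plan list for [makeTranscript()].
#' @export
defaultTranscriptPlan <- function() {
  list(
    id = "bclx_like_681",
    length = 681L,
    regions = data.frame(
      name = c("P1_stem", "Q2", "L3_loop", "Q5", "threeSS_region"),
      start = c(60L, 141L, 250L, 441L, 600L),
      end   = c(100L, 165L, 290L, 465L, 640L),
      kind  = c("stem", "g4_candidate", "loop", "g4_candidate", "other"),
      stringsAsFactors = FALSE
    ),
    spliceSites = c(XS = 180L, XL = 480L)
  )
}

#' Write a transcript to FASTA
#'
#' @param transcript an [AnnotatedTranscript-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTranscriptFasta <- function(transcript, path) {
  set <- Biostrings::RNAStringSet(transcript@seq)
  names(set) <- transcript@id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a transcript (first record) from FASTA
#'
#' @param path FASTA file; `T` is read as `U`.
#' @param regions optional region data.frame (see [AnnotatedTranscript()]).
#' @param spliceSites optional named integer vector.
#' @return an [AnnotatedTranscript-class].
#' @export
readTranscriptFasta <- function(path, regions = NULL,
                                spliceSites = integer()) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path, call. = FALSE)
  AnnotatedTranscript(id = names(set)[1L],
                      sequence = as.character(set[[1L]]),
                      regions = regions, spliceSites = spliceSites)
}

#' Write transcript regions as a BED-like table
#'
#' Four tab-separated columns: transcript id, start, end, region name, plus a
#' fifth `kind` column. Coordinates are written 1-based inclusive (transcript
#' coordinates, not genomic BED half-open).
#'
#' @param transcript an [AnnotatedTranscript-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(transcript, path) {
  rg <- transcript@regions
  df <- data.frame(
    chrom = rep(transcript@id, length(rg)),
    start = IRanges::start(rg),
    end = IRanges::end(rg),
    name = names(rg),
    kind = S4Vectors::mcols(rg)$kind
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like region table (1-based inclusive coordinates)
#'
#' @param path file with columns chrom, start, end, name and optionally kind.
#' @return data.frame with `name`, `start`, `end`, `kind`.
#' @export
readRegionsBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("region file needs at least 4 columns", call. = FALSE)
  out <- data.frame(name = as.character(df[[4L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    kind = if (ncol(df) >= 5L) as.character(df[[5L]])
                           else "other",
                    stringsAsFactors = FALSE)
  out
}
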