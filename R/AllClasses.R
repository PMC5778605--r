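#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importClassesFrom Biostrings RNAString
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom stats sd rlnorm rnorm dnorm approx optim optimize uniroot
#'   median mad setNames
#' @importFrom utils read.table write.table head tail packageVersion
NULL

#' Annotated transcript with named structural regions and splice sites
#'
#' Container for a single pre-mRNA sequence together with its named regions
#' (G4 candidates, stems, loops, splice-site neighbourhoods) and the positions
#' of alternative 5' splice sites. Coordinates are 1-based inclusive along the
#' transcript.
#'
#' @slot id single identifier string.
#' @slot seq a [Biostrings::RNAString] over {A,C,G,U}.
#' @slot regions an [IRanges::IRanges] with unique names and an mcols column
#'   `kind`, one of `g4_candidate`, `stem`, `loop`, `splice_site`, `other`.
#' @slot spliceSites named integer vector of 5' splice-site positions
#'   (e.g. `XS`, `XL`), each within the sequence.
#'
#' @seealso [makeTranscript()], [scanG4()], [regionSummary()]
#' @export
setClass("AnnotatedTranscript",
  slots = c(
    id = "character",
    seq = "RNAString",
    regions = "IRanges",
    spliceSites = "integer"
  )
)

setValidity("AnnotatedTranscript", function(object) {
  msg <- character()
  len <- length(object@seq)
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  rg <- object@regions
  if (length(rg)) {
    if (is.null(names(rg)) || anyDuplicated(names(rg)))
      msg <- c(msg, "region names must be present and unique")
    if (any(IRanges::start(rg) < 1L) || any(IRanges::end(rg) > len))
      msg <- c(msg, "regions must lie within the sequence")
    kinds <- mcols(rg)$kind
    ok <- c("g4_candidate", "stem", "loop", "splice_site", "other")
    if (is.null(kinds) || !all(kinds %in% ok))
      msg <- c(msg, sprintf("region 'kind' must be one of %s",
                            paste(ok, collapse = ", ")))
  }
  ss <- object@spliceSites
  if (length(ss)) {
    if (is.null(names(ss)) || anyDuplicated(names(ss)))
      msg <- c(msg, "splice sites must be uniquely named")
    if (any(ss < 1L | ss > len))
      msg <- c(msg, "splice sites must lie within the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated footprinting experiment
#'
#' Records the per-position, per-enzyme, per-condition true cleavage
#' reactivities used by [simulateFootprint()], the set of positions whose
#' T2-corrected ligand/control ratio differs from 1 (with the expected sign of
#' the log cleavage index), and the nuisance parameters (lane loading scales,
#' multiplicative noise CV). Used to score recovery downstream.
#'
#' @slot trueReactivity numeric array `positions x enzyme(V1,T2) x
#'   condition(control,ligand)` of true reactivities (dimnames carry the
#'   analyzed positions).
#' @slot changedPositions data.frame with columns `position` and `sign`
#'   (`"+"`/`"-"`): positions where the V1-over-T2 fold ratio is not 1.
#' @slot laneScales named positive numerics, one per lane.
#' @slot noiseCV coefficient of variation of the multiplicative noise.
#' @slot positions integer vector of analyzed positions.
#' @export
setClass("FootprintTruth",
  slots = c(
    trueReactivity = "array",
    changedPositions = "data.frame",
    laneScales = "numeric",
    noiseCV = "numeric",
    positions = "integer"
  )
)

setValidity("FootprintTruth", function(object) {
  msg <- character()
  if (any(object@laneScales <= 0)) msg <- c(msg, "lane scales must be > 0")
  if (object@noiseCV < 0) msg <- c(msg, "noiseCV must be >= 0")
  if (!all(c("position", "sign") %in% names(object@changedPositions)))
    msg <- c(msg, "changedPositions needs 'position' and 'sign' columns")
  if (length(msg)) msg else TRUE
})

#' Per-nucleotide intensity matrix across footprinting lanes
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] holding one `intensity`
#' assay (rows = nucleotide positions quantified in every lane, columns =
#' lanes) with lane metadata (`enzyme`, `condition`) in `colData` and the
#' nucleotide `position` in `rowData`. The cleavage-index statistic
#' ([computeIndex()]) requires exactly the lane set
#' {V1,T2} x {control,ligand}.
#'
#' @seealso [BandTable()], [buildBandTable()], [computeIndex()]
#' @export
setClass("BandTable", contains = "SummarizedExperiment")

setValidity("BandTable", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "BandTable requires an 'intensity' assay")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("enzyme", "condition") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'enzyme' and 'condition'")
  if (!"position" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must have 'position'")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(!is.na(a) & a < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One gel lane as a densitometry trace
#'
#' A 1-D densitometry readout of a single electrophoresis lane: density as a
#' function of migration distance, plus (for simulated lanes) the generating
#' band model mapping nucleotide positions to band centers, widths and areas.
#'
#' @slot laneId single string.
#' @slot enzyme one of `"V1"`, `"T1"`, `"T2"`, `"none"`.
#' @slot condition single string, e.g. `"control"` or `"ligand_10uM"`.
#' @slot trace data.frame with strictly increasing `migration` and
#'   nonnegative `density`.
#' @slot bandModel data.frame with `position`, `center`, `width`, `area`
#'   (0 rows when the truth is unknown, i.e. real data).
#' @seealso [simulateLaneTraces()], [detectBands()]
#' @export
setClass("LaneProfile",
  slots = c(
    laneId = "character",
    enzyme = "character",
    condition = "character",
    trace = "data.frame",
    bandModel = "data.frame"
  )
)

setValidity("LaneProfile", function(object) {
  msg <- character()
  tr <- object@trace
  if (!all(c("migration", "density") %in% names(tr)))
    msg <- c(msg, "trace needs 'migration' and 'density' columns")
  else {
    if (is.unsorted(tr$migration, strictly = TRUE))
      msg <- c(msg, "migration coordinates must be strictly increasing")
    if (any(tr$density < 0)) msg <- c(msg, "densities must be >= 0")
  }
  if (!object@enzyme %in% c("V1", "T1", "T2", "none"))
    msg <- c(msg, "enzyme must be one of V1, T1, T2, none")
  bm <- object@bandModel
  if (nrow(bm)) {
    if (is.unsorted(bm$center, strictly = TRUE))
      msg <- c(msg, "band centers must be strictly increasing")
    if (any(bm$width <= 0)) msg <- c(msg, "band widths must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Detected gel bands in one lane
#'
#' Result of [detectBands()]: one row per fitted band with its migration
#' `center`, Gaussian `width` (sd), integrated `area`, and (after
#' [assignPositions()]) the assigned nucleotide `position` (`NA` =
#' unassigned).
#'
#' @slot peaks data.frame with columns `center`, `width`, `area`, `position`.
#' @export
setClass("PeakSet", slots = c(peaks = "data.frame"))

setValidity("PeakSet", function(object) {
  msg <- character()
  pk <- object@peaks
  need <- c("center", "width", "area", "position")
  if (!all(need %in% names(pk)))
    return(sprintf("peaks needs columns %s", paste(need, collapse = ", ")))
  if (nrow(pk)) {
    if (is.unsorted(pk$center, strictly = TRUE))
      msg <- c(msg, "peak centers must be strictly increasing")
    if (any(pk$area < 0)) msg <- c(msg, "areas must be >= 0")
    assigned <- pk$position[!is.na(pk$position)]
    if (is.unsorted(assigned, strictly = TRUE))
      msg <- c(msg, "assigned positions must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Empirical Gaussian null for the log cleavage index
#'
#' Mean and standard deviation of log(index) over all analyzed positions —
#' deliberately including any true changes, so the null is exactly the plain
#' empirical fit practitioners apply to footprinting indices — plus the SD
#' multiplier used for significance calling (default 2).
#'
#' @slot mean mean of log(index).
#' @slot sd sample standard deviation of log(index).
#' @slot n number of positions used.
#' @slot k SD multiplier for calling (default 2).
#' @slot logBase base of the logarithm (default 10).
#' @slot robust TRUE when fitted as median / 1.4826*MAD instead.
#' @seealso [fitNull()], [callSignificant()]
#' @export
setClass("NullModel",
  slots = c(mean = "numeric", sd = "numeric", n = "integer",
            k = "numeric", logBase = "numeric", robust = "logical")
)

setValidity("NullModel", function(object) {
  msg <- character()
  if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (object@n < 2L) msg <- c(msg, "a valid null needs n >= 2")
  if (object@k <= 0) msg <- c(msg, "k must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fluorescence emission spectrum of one sample
#'
#' Wavelength grid and emission intensities recorded at a fixed excitation
#' wavelength (default 321 nm for the ellipticine ligand assays).
#'
#' @slot sampleId single string.
#' @slot excitation excitation wavelength, nm.
#' @slot wavelength strictly increasing grid, nm.
#' @slot intensity nonnegative intensities, arbitrary units.
#' @seealso [simulateSpectrum()], [peakEmission()], [compareToFree()]
#' @export
setClass("EmissionSpectrum",
  slots = c(sampleId = "character", excitation = "numeric",
            wavelength = "numeric", intensity = "numeric")
)

setValidity("EmissionSpectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@intensity))
    msg <- c(msg, "wavelength and intensity must have equal length")
  if (is.unsorted(object@wavelength, strictly = TRUE))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parameters generating a two-state binding emission spectrum
#'
#' Truth object for [simulateSpectrum()]: a one-site mass-action binding
#' model (dissociation constant, total RNA and ligand concentrations) and the
#' emission Gaussians of the free and bound ligand species.
#'
#' @slot kd dissociation constant, uM (> 0).
#' @slot rnaConc,ligandConc total concentrations, uM (>= 0).
#' @slot freeCenter,boundCenter emission peak centers, nm.
#' @slot freeIntensity,boundIntensity peak amplitudes, a.u.
#' @slot freeWidth,boundWidth Gaussian sd of each emission band, nm.
#' @slot excitation excitation wavelength, nm.
#' @export
setClass("SpectrumTruth",
  slots = c(kd = "numeric", rnaConc = "numeric", ligandConc = "numeric",
            freeCenter = "numeric", freeIntensity = "numeric",
            freeWidth = "numeric",
            boundCenter = "numeric", boundIntensity = "numeric",
            boundWidth = "numeric", excitation = "numeric")
)

setValidity("SpectrumTruth", function(object) {
  msg <- character()
  if (object@kd <= 0) msg <- c(msg, "kd must be > 0")
  if (object@rnaConc < 0 || object@ligandConc < 0)
    msg <- c(msg, "concentrations must be >= 0")
  if (object@freeWidth <= 0 || object@boundWidth <= 0)
    msg <- c(msg, "peak widths must be > 0")
  if (length(msg)) msg else TRUE
})
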