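#' @rdname AnnotatedTranscript-class
#' @param x,object an object.
#' @export
setGeneric("transcriptSeq", function(x) standardGeneric("transcriptSeq"))

#' @rdname AnnotatedTranscript-class
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname AnnotatedTranscript-class
#' @export
setGeneric("spliceSites", function(x) standardGeneric("spliceSites"))

#' @rdname BandTable-class
#' @export
setGeneric("laneInfo", function(x) standardGeneric("laneInfo"))

#' @rdname BandTable-class
#' @export
setGeneric("bandIntensities", function(x) standardGeneric("bandIntensities"))

#' @rdname BandTable-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname PeakSet-class
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

setMethod("transcriptSeq", "AnnotatedTranscript", function(x) x@seq)
setMethod("regions", "AnnotatedTranscript", function(x) x@regions)
setMethod("spliceSites", "AnnotatedTranscript", function(x) x@spliceSites)

setMethod("laneInfo", "BandTable", function(x)
  SummarizedExperiment::colData(x))
setMethod("bandIntensities", "BandTable", function(x)
  SummarizedExperiment::assay(x, "intensity"))
setMethod("positions", "BandTable", function(x)
  SummarizedExperiment::rowData(x)$position)

setMethod("peaks", "PeakSet", function(x) x@peaks)

setMethod("show", "AnnotatedTranscript", function(object) {
  cat("AnnotatedTranscript '", object@id, "': ",
      length(object@seq), " nt\n", sep = "")
  rg <- object@regions
  if (length(rg)) {
    kinds <- S4Vectors::mcols(rg)$kind
    cat("  regions (", length(rg), "): ",
        paste(sprintf("%s[%d-%d,%s]", names(rg), IRanges::start(rg),
                      IRanges::end(rg), kinds), collapse = " "), "\n",
        sep = "")
  }
  if (length(object@spliceSites))
    cat("  splice sites: ",
        paste(names(object@spliceSites), object@spliceSites,
              sep = "@", collapse = " "), "\n", sep = "")
})

setMethod("show", "BandTable", function(object) {
  cat("BandTable: ", nrow(object), " positions x ", ncol(object),
      " lanes\n", sep = "")
  cd <- SummarizedExperiment::colData(object)
  cat("  lanes: ", paste(rownames(cd), collapse = ", "), "\n", sep = "")
  mi <- S4Vectors::metadata(object)$missing
  if (!is.null(mi) && length(mi$positions))
    cat("  positions dropped (incomplete lanes): ",
        length(mi$positions), "\n", sep = "")
})

setMethod("show", "NullModel", function(object) {
  cat(sprintf(
    "NullModel (log base %g%s): mean %.4g, sd %.4g, n = %d, call at %g SD\n",
    object@logBase, if (object@robust) ", robust" else "",
    object@mean, object@sd, object@n, object@k))
})

setMethod("show", "PeakSet", function(object) {
  pk <- object@peaks
  cat("PeakSet: ", nrow(pk), " bands, ",
      sum(!is.na(pk$position)), " assigned\n", sep = "")
})

setMethod("show", "LaneProfile", function(object) {
  cat("LaneProfile '", object@laneId, "' (", object@enzyme, ", ",
      object@condition, "): ", nrow(object@trace), " trace points",
      if (nrow(object@bandModel))
        sprintf(", %d modelled bands", nrow(object@bandModel)) else "",
      "\n", sep = "")
})

setMethod("show", "EmissionSpectrum", function(object) {
  cat("EmissionSpectrum '", object@sampleId, "': ",
      length(object@wavelength), " points, ",
      min(object@wavelength), "-", max(object@wavelength),
      " nm (excitation ", object@excitation, " nm)\n", sep = "")
})
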