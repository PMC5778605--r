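#' Locate the emission peak of a spectrum
#'
#' Argmax of the (optionally moving-average smoothed) spectrum, refined by
#' quadratic interpolation through the maximum and its two neighbours for
#' sub-grid peak position. A flat spectrum yields an NA "no peak" result.
#'
#' @param spectrum an [EmissionSpectrum-class] (>= 5 grid points).
#' @param smoothWindow moving-average window in grid points (0 = none).
#' @return list with `peak_nm` and `peak_intensity` (both `NA` for a flat
#'   spectrum).
#' @export
peakEmission <- function(spectrum, smoothWindow = 0L) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  wl <- spectrum@wavelength
  y <- spectrum@intensity
  if (length(wl) < 5L) stop("need at least 5 grid points", call. = FALSE)
  if (smoothWindow > 1L) y <- movingAverage(y, as.integer(smoothWindow))
  if (diff(range(y)) == 0)
    return(list(peak_nm = NA_real_, peak_intensity = NA_real_))
  i <- which.max(y)
  if (i == 1L || i == length(y))
    return(list(peak_nm = wl[i], peak_intensity = y[i]))
  # quadratic vertex through (i-1, i, i+1)
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(list(peak_nm = wl[i], peak_intensity = y2))
  delta <- 0.5 * (y1 - y3) / denom
  h <- wl[i + 1L] - wl[i]
  list(peak_nm = wl[i] + delta * h,
       peak_intensity = y2 - 0.25 * (y1 - y3) * delta)
}

#' Classify a sample spectrum against the free-ligand spectrum
#'
#' Interpolates both spectra to their common wavelength range, computes the
#' fold enhancement of peak intensity and the signed peak shift, and calls a
#' binder when both `fold_vs_free >= foldThreshold` and `|shift_nm| >=
#' shiftThreshold`.
#'
#' @param sample,free [EmissionSpectrum-class] objects.
#' @param foldThreshold minimum fold enhancement for a binder call
#'   (default 3).
#' @param shiftThreshold minimum absolute peak shift in nm (default 20).
#' @param smoothWindow passed to [peakEmission()].
#' @return one-row data.frame: `sample_id`, `peak_nm`, `peak_intensity`,
#'   `fold_vs_free`, `shift_nm`, `call` (`"binder"`/`"non-binder"`).
#' @export
compareToFree <- function(sample, free, foldThreshold = 3,
                          shiftThreshold = 20, smoothWindow = 0L) {
  stopifnot(is(sample, "EmissionSpectrum"), is(free, "EmissionSpectrum"))
  lo <- max(min(sample@wavelength), min(free@wavelength))
  hi <- min(max(sample@wavelength), max(free@wavelength))
  if (lo >= hi) stop("spectra do not share a wavelength range",
                     call. = FALSE)
  common <- sort(unique(c(
    sample@wavelength[sample@wavelength >= lo & sample@wavelength <= hi],
    free@wavelength[free@wavelength >= lo & free@wavelength <= hi])))
  regrid <- function(sp) new("EmissionSpectrum",
    sampleId = sp@sampleId, excitation = sp@excitation,
    wavelength = common,
    intensity = stats::approx(sp@wavelength, sp@intensity,
                              xout = common)$y)
  pS <- peakEmission(regrid(sample), smoothWindow)
  pF <- peakEmission(regrid(free), smoothWindow)
  if (is.na(pF$peak_intensity) || pF$peak_intensity <= 0)
    stop("free-ligand spectrum has no positive peak", call. = FALSE)
  fold <- pS$peak_intensity / pF$peak_intensity
  shift <- pS$peak_nm - pF$peak_nm
  data.frame(sample_id = sample@sampleId,
             peak_nm = pS$peak_nm, peak_intensity = pS$peak_intensity,
             fold_vs_free = fold, shift_nm = shift,
             call = if (!is.na(fold) && !is.na(shift) &&
                        fold >= foldThreshold &&
                        abs(shift) >= shiftThreshold) "binder"
                    else "non-binder",
             stringsAsFactors = FALSE)
}

#' Fraction of ligand bound under one-site mass action
#'
#' Solves the one-site binding quadratic for the complex concentration `x`:
#' `x^2 - (R + L + Kd) x + R L = 0`, taking the physical root
#' `x in [0, min(R, L)]`, and returns the fraction of total ligand bound,
#' `x / L`.
#'
#' @param kd dissociation constant (> 0), same units as the concentrations.
#' @param rnaTotal,ligandTotal total concentrations (>= 0).
#' @return bound fraction in `[0, min(1, rnaTotal/ligandTotal)]`; 0 when
#'   either total is 0.
#' @examples
#' boundFraction(kd = 1, rnaTotal = 1, ligandTotal = 20)
#' @export
boundFraction <- function(kd, rnaTotal, ligandTotal) {
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (rnaTotal < 0 || ligandTotal < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  if (rnaTotal == 0 || ligandTotal == 0) return(0)
  b <- rnaTotal + ligandTotal + kd
  x <- (b - sqrt(b^2 - 4 * rnaTotal * ligandTotal)) / 2
  min(max(x / ligandTotal, 0), 1)
}

#' Write binding calls to TSV
#'
#' @param calls data.frame of rows from [compareToFree()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBindingTsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an emission spectrum TSV (wavelength_nm, intensity)
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param path file path.
#' @param sampleId,excitation metadata for the reader.
#' @return `path` (writer, invisibly) or an [EmissionSpectrum-class]
#'   (reader).
#' @export
writeSpectrumTsv <- function(spectrum, path) {
  utils::write.table(
    data.frame(wavelength_nm = spectrum@wavelength,
               intensity = spectrum@intensity),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTsv
#' @export
readSpectrumTsv <- function(path, sampleId = basename(path),
                            excitation = 321) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  new("EmissionSpectrum", sampleId = sampleId, excitation = excitation,
      wavelength = df$wavelength_nm, intensity = df$intensity)
}
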