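#' Simulate a radiolabeled splicing-gel band table
#'
#' Body-labeling with [alpha-32P]GTP makes a band's intensity proportional to
#' the molar amount of the species times the number of guanosines it carries.
#' This generator applies exactly that proportionality plus multiplicative
#' lognormal measurement noise.
#'
#' @param molar named nonnegative numerics: true molar amount per species
#'   (typically `pre_mRNA`, `mRNA_XL`, `mRNA_XS`).
#' @param gCounts named positive integers: guanosine count per species body
#'   (same names as `molar`).
#' @param noiseCV coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return data.frame with `species`, `intensity`, `g_count`.
#' @examples
#' simulateSpliceGel(c(mRNA_XS = 1, mRNA_XL = 1),
#'                   c(mRNA_XS = 120, mRNA_XL = 60),
#'                   noiseCV = 0, seed = 1)
#' @export
simulateSpliceGel <- function(molar, gCounts, noiseCV = 0, seed) {
  if (any(molar < 0)) stop("molar amounts must be >= 0", call. = FALSE)
  if (!all(names(molar) %in% names(gCounts)))
    stop("every species in 'molar' needs a g count", call. = FALSE)
  gCounts <- gCounts[names(molar)]
  if (any(gCounts < 1))
    stop("g counts must be >= 1 (a species with no G is invisible)",
         call. = FALSE)
  withSeed(seed, {
    noise <- lognormNoise(length(molar), noiseCV)
    data.frame(species = names(molar),
               intensity = as.numeric(molar) * as.numeric(gCounts) * noise,
               g_count = as.integer(gCounts),
               stringsAsFactors = FALSE)
  })
}

#' Construct the truth of a two-state binding emission spectrum
#'
#' @param kd dissociation constant, uM.
#' @param rnaConc,ligandConc total concentrations, uM.
#' @param freePeak,boundPeak numeric `c(center_nm, intensity)` of the free
#'   and bound emission bands.
#' @param freeWidth,boundWidth Gaussian sd of each band, nm.
#' @param excitation excitation wavelength, nm.
#' @return a [SpectrumTruth-class].
#' @export
SpectrumTruth <- function(kd, rnaConc, ligandConc,
                          freePeak = c(493, 1), boundPeak = c(558, 15),
                          freeWidth = 25, boundWidth = 25,
                          excitation = 321) {
  new("SpectrumTruth", kd = kd, rnaConc = rnaConc, ligandConc = ligandConc,
      freeCenter = freePeak[1L], freeIntensity = freePeak[2L],
      freeWidth = freeWidth,
      boundCenter = boundPeak[1L], boundIntensity = boundPeak[2L],
      boundWidth = boundWidth, excitation = excitation)
}

#' Simulate a fluorescence emission spectrum under two-state binding
#'
#' The spectrum is the bound-fraction-weighted sum of the free and bound
#' emission Gaussians, `(1-f) * free + f * bound`, where `f` is the fraction
#' of ligand bound under one-site mass action ([boundFraction()]), plus
#' additive Gaussian noise (clipped at zero).
#'
#' @param truth a [SpectrumTruth-class].
#' @param wavelength strictly increasing grid covering both peak centers, nm.
#' @param noiseSD sd of the additive intensity noise (a.u.).
#' @param seed integer seed (ignored when `noiseSD = 0`).
#' @param sampleId identifier stored in the spectrum.
#' @return an [EmissionSpectrum-class].
#' @export
simulateSpectrum <- function(truth, wavelength = seq(400, 700, by = 1),
                             noiseSD = 0, seed = 1,
                             sampleId = "sample") {
  stopifnot(is(truth, "SpectrumTruth"))
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  rng <- range(wavelength)
  if (truth@freeCenter < rng[1L] || truth@freeCenter > rng[2L] ||
      truth@boundCenter < rng[1L] || truth@boundCenter > rng[2L])
    stop("wavelength grid must cover both peak centers", call. = FALSE)
  f <- boundFraction(truth@kd, truth@rnaConc, truth@ligandConc)
  shape <- function(c0, w) exp(-(wavelength - c0)^2 / (2 * w^2))
  intens <- (1 - f) * truth@freeIntensity * shape(truth@freeCenter,
                                                  truth@freeWidth) +
    f * truth@boundIntensity * shape(truth@boundCenter, truth@boundWidth)
  if (noiseSD > 0) {
    intens <- withSeed(seed,
      pmax(0, intens + stats::rnorm(length(intens), 0, noiseSD)))
  }
  new("EmissionSpectrum", sampleId = sampleId,
      excitation = truth@excitation,
      wavelength = as.numeric(wavelength), intensity = intens)
}

# Calibrate the bound-species amplitude so the noiseless composite spectrum
# peaks at exactly foldTarget times the free-spectrum peak, given the bound
# fraction f. Used by the preset panels to reproduce a stated enhancement.
calibrateBoundIntensity <- function(foldTarget, f, freeCenter = 493,
                                    freeIntensity = 1, freeWidth = 25,
                                    boundCenter = 558, boundWidth = 25) {
  if (f <= 0) stop("bound fraction must be > 0 to calibrate", call. = FALSE)
  compositeMax <- function(A) {
    g <- function(l) (1 - f) * freeIntensity *
      exp(-(l - freeCenter)^2 / (2 * freeWidth^2)) +
      f * A * exp(-(l - boundCenter)^2 / (2 * boundWidth^2))
    # two local maxima at most, near the two centers
    m1 <- stats::optimize(g, c(freeCenter - 3 * freeWidth,
                               (freeCenter + boundCenter) / 2),
                          maximum = TRUE)$objective
    m2 <- stats::optimize(g, c((freeCenter + boundCenter) / 2,
                               boundCenter + 3 * boundWidth),
                          maximum = TRUE)$objective
    max(m1, m2)
  }
  target <- foldTarget * freeIntensity
  stats::uniroot(function(A) compositeMax(A) - target,
                 lower = 0, upper = 1e9, tol = 1e-10)$root
}
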